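#' Hand-crafted spatiotemporal features for one 30-s epoch
#'
#' The classical actigraphy feature set: per-axis moments, movement-intensity
#' (ENMO) statistics, inter-axis correlations, device-angle (arm angle, roll,
#' pitch) statistics, and spectral shape of the dynamic component. Spectral
#' features are computed on the vector magnitude minus its mean under a Hann
#' window (removing DC/gravity leakage); the dominant frequency is searched
#' in 0.3-15 Hz. Correlations involving a constant axis are defined as 0.
#' Deterministic: the same epoch always yields the same vector.
#'
#' @param epochs An `epoch_array`, or a single 900 x 3 matrix.
#' @return A tibble with one row per epoch and 30 named feature columns, all
#'   finite for any non-empty epoch.
#' @export
extract_features <- function(epochs) {
  if (is.matrix(epochs)) {
    epochs <- new_epoch_array(
      array(epochs, dim = c(1, nrow(epochs), 3)),
      tibble::tibble(epoch_start = as.POSIXct(NA), segment = 1L, wear = TRUE)
    )
  }
  m <- n_epochs(epochs)
  if (m == 0) {
    return(tibble::as_tibble(matrix(numeric(), 0, length(FEATURE_NAMES),
      dimnames = list(NULL, FEATURE_NAMES)
    )))
  }
  out <- matrix(0, m, length(FEATURE_NAMES), dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(m)) {
    sig <- epochs$signals[i, , , drop = TRUE]
    dim(sig) <- c(dim(epochs$signals)[2], 3)
    out[i, ] <- epoch_features_one(sig, hz = epochs$hz)
  }
  tibble::as_tibble(out)
}

FEATURE_NAMES <- c(
  "x_mean", "x_sd", "x_range", "y_mean", "y_sd", "y_range",
  "z_mean", "z_sd", "z_range", "enmo_mean", "enmo_sd", "enmo_mad",
  "corr_xy", "corr_xz", "corr_yz", "zangle_mean", "zangle_asd",
  "roll_mean", "roll_sd", "pitch_mean", "pitch_sd",
  "mag_mean", "mag_sd", "mag_p2p", "mag_skew", "mag_kurt",
  "dom_freq", "dom_power", "power_1_3hz", "spectral_entropy"
)

epoch_features_one <- function(sig, hz = 30) {
  x <- sig[, 1]
  y <- sig[, 2]
  z <- sig[, 3]
  mag <- sqrt(x^2 + y^2 + z^2)
  enmo <- pmax(mag - 1, 0)

  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) {
      return(0)
    }
    cor(a, b)
  }
  # angles in degrees; z-angle (arm angle) relative to horizontal
  zang <- atan2(z, sqrt(x^2 + y^2)) * 180 / pi
  roll <- atan2(y, z) * 180 / pi
  pitch <- atan2(x, sqrt(y^2 + z^2)) * 180 / pi

  # spectral shape from the summed per-axis periodograms (mean-removed, Hann
  # window): orientation-invariant, and unlike the vector magnitude it does
  # not rectify oscillations orthogonal to gravity onto twice their frequency
  n <- length(x)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  pw <- Mod(fft((x - mean(x)) * hann))^2 +
    Mod(fft((y - mean(y)) * hann))^2 +
    Mod(fft((z - mean(z)) * hann))^2
  freqs <- (seq_len(n) - 1) * hz / n
  half <- seq_len(floor(n / 2))
  pw <- pw[half]
  freqs <- freqs[half]
  band <- freqs >= 0.3 & freqs <= 15
  if (any(band) && sum(pw[band]) > 0) {
    k <- which(band)[which.max(pw[band])]
    dom_freq <- freqs[k]
    dom_power <- pw[k]
  } else {
    dom_freq <- 0
    dom_power <- 0
  }
  p13 <- sum(pw[freqs >= 1 & freqs <= 3])
  ptot <- sum(pw)
  spec_ent <- if (ptot > 0) {
    pn <- pw / ptot
    pn <- pn[pn > 0]
    -sum(pn * log(pn))
  } else {
    0
  }

  m2 <- mean((mag - mean(mag))^2)
  m3 <- mean((mag - mean(mag))^3)
  m4 <- mean((mag - mean(mag))^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 - 3 else 0

  c(
    x_mean = mean(x), x_sd = sd(x), x_range = diff(range(x)),
    y_mean = mean(y), y_sd = sd(y), y_range = diff(range(y)),
    z_mean = mean(z), z_sd = sd(z), z_range = diff(range(z)),
    enmo_mean = mean(enmo), enmo_sd = sd(enmo), enmo_mad = median(abs(enmo - median(enmo))),
    corr_xy = safe_cor(x, y), corr_xz = safe_cor(x, z), corr_yz = safe_cor(y, z),
    zangle_mean = mean(zang), zangle_asd = mean(abs(diff(zang))),
    roll_mean = mean(roll), roll_sd = sd(roll),
    pitch_mean = mean(pitch), pitch_sd = sd(pitch),
    mag_mean = mean(mag), mag_sd = sd(mag), mag_p2p = diff(range(mag)),
    mag_skew = skew, mag_kurt = kurt,
    dom_freq = dom_freq, dom_power = dom_power,
    power_1_3hz = p13, spectral_entropy = spec_ent
  )
}

#' Train the random-forest stage classifier
#'
#' The comparison method: a probability random forest on [extract_features()]
#' output. Out-of-bag class-probability estimates are retained so the HMM
#' emission calibration can be fitted without leaking training predictions.
#'
#' @param features Tibble of per-epoch features (one row per epoch).
#' @param labels Factor of stage labels (5-, 3- or 2-class), aligned to
#'   `features`.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return A `somnokit_rf` object: the fitted forest, its class levels, and
#'   the out-of-bag probability matrix.
#' @export
train_rf <- function(features, labels, n_trees = 500, seed = 1) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) abort("training labels must contain at least 2 classes")
  if (nrow(features) != length(labels)) abort("features and labels must align")
  df <- as.data.frame(features)
  df$.stage <- labels
  fit <- ranger::ranger(
    dependent.variable.name = ".stage", data = df,
    num.trees = n_trees, probability = TRUE,
    respect.unordered.factors = TRUE, seed = seed, num.threads = 1
  )
  oob <- fit$predictions # OOB class probabilities, rows align with training data
  structure(
    list(forest = fit, classes = levels(labels), oob_probs = oob),
    class = "somnokit_rf"
  )
}

#' Predict per-epoch class probabilities from a trained forest
#'
#' @param object A `somnokit_rf`.
#' @param features New per-epoch feature tibble.
#' @param ... Unused.
#' @return Matrix of class probabilities (epochs x classes).
#' @export
predict.somnokit_rf <- function(object, features, ...) {
  p <- predict(object$forest, data = as.data.frame(features), num.threads = 1)$predictions
  p[, object$classes, drop = FALSE]
}

#' @export
print.somnokit_rf <- function(x, ...) {
  cat(sprintf(
    "<somnokit_rf> %d trees, classes: %s, OOB error %.3f\n",
    x$forest$num.trees, paste(x$classes, collapse = "/"), x$forest$prediction.error
  ))
  invisible(x)
}
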