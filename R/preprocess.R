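#' Read a raw tri-axial recording from delimited text
#'
#' Expects a header with `time,x,y,z` columns: ISO-8601 timestamps and
#' acceleration in g. Rows with unparseable numbers or timestamps are dropped
#' and counted (`attr(rec, "n_dropped")`). A file that cannot be parsed at
#' all (missing columns, no valid rows) raises a classed error
#' (`somnokit_parse_error`) which [qc_screen()] maps to an excluded record.
#'
#' @param path Path to a delimited text file.
#' @param sample_hz Nominal device rate; if `NULL`, estimated as the inverse
#'   median timestamp spacing.
#' @param meta Optional device metadata (`device_id`, `dominant_wrist`,
#'   `shift_worker`, `dst_crossover`).
#' @return A `raw_recording` tibble (`time`, `x`, `y`, `z`).
#' @export
read_raw <- function(path, sample_hz = NULL, meta = list()) {
  df <- tryCatch(
    suppressWarnings(readr::read_csv(
      path,
      col_types = readr::cols(
        time = readr::col_character(),
        x = readr::col_double(), y = readr::col_double(), z = readr::col_double()
      ),
      show_col_types = FALSE
    )),
    error = function(e) abort(paste("cannot parse", path), class = "somnokit_parse_error")
  )
  if (!all(c("time", "x", "y", "z") %in% names(df))) {
    abort("missing time/x/y/z columns", class = "somnokit_parse_error")
  }
  tm <- as.POSIXct(df$time,
    tz = "UTC",
    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")
  )
  ok <- !is.na(tm) & !is.na(df$x) & !is.na(df$y) & !is.na(df$z)
  n_dropped <- sum(!ok)
  df <- df[ok, ]
  tm <- tm[ok]
  if (nrow(df) == 0) abort("no valid samples", class = "somnokit_parse_error")
  if (is.unsorted(as.numeric(tm), strictly = TRUE)) {
    o <- order(tm)
    tm <- tm[o]
    df <- df[o, ]
    dup <- c(FALSE, diff(as.numeric(tm)) <= 0)
    n_dropped <- n_dropped + sum(dup)
    df <- df[!dup, ]
    tm <- tm[!dup]
  }
  if (is.null(sample_hz)) {
    sample_hz <- if (nrow(df) > 1) 1 / median(diff(as.numeric(tm))) else NA_real_
  }
  new_raw_recording(
    tibble::tibble(time = tm, x = df$x, y = df$y, z = df$z),
    sample_hz = sample_hz, meta = meta, n_dropped = n_dropped
  )
}

# Segment ids: consecutive samples more than `gap_s` apart start a new
# contiguous segment. Interpolation and epoching never cross segments.
segment_ids <- function(times, gap_s = 5) {
  c(0L, cumsum(diff(as.numeric(times)) > gap_s)) + 1L
}

#' Resample a recording to a uniform 30 Hz grid
#'
#' Per-axis linear interpolation onto a 1/30-s grid anchored at the first
#' timestamp of each contiguous segment. Gaps longer than 5 s are never
#' interpolated across — they split the recording into segments (interpolating
#' over an off-wrist gap would fabricate data). Input already on a uniform
#' 30 Hz grid passes through unchanged (to within floating point).
#'
#' @param rec A `raw_recording`.
#' @param gap_s Gap threshold in seconds that splits segments.
#' @return A `raw_recording` at 30 Hz with a `segment` column.
#' @export
resample_30hz <- function(rec, gap_s = 5) {
  if (nrow(rec) == 0) abort("empty recording")
  seg <- segment_ids(rec$time, gap_s)
  t_num <- as.numeric(rec$time)
  pieces <- lapply(split(seq_along(seg), seg), function(idx) {
    if (length(idx) < 2) {
      return(NULL)
    }
    t_seg <- t_num[idx]
    grid <- seq(t_seg[1], t_seg[length(t_seg)], by = 1 / EPOCH_HZ)
    tibble::tibble(
      t = grid,
      x = approx(t_seg, rec$x[idx], xout = grid)$y,
      y = approx(t_seg, rec$y[idx], xout = grid)$y,
      z = approx(t_seg, rec$z[idx], xout = grid)$y,
      segment = seg[idx[1]]
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (is.null(out) || nrow(out) == 0) abort("no segment long enough to resample")
  new_raw_recording(
    tibble::tibble(
      time = as.POSIXct(out$t, tz = "UTC", origin = "1970-01-01"),
      x = out$x, y = out$y, z = out$z, segment = out$segment
    ),
    sample_hz = EPOCH_HZ, meta = attr(rec, "meta"), n_dropped = attr(rec, "n_dropped") %||% 0L
  )
}

#' Clip acceleration values to +/- 3 g
#'
#' Values already inside the range are unchanged; clipping is idempotent.
#'
#' @param rec A `raw_recording`.
#' @param bound Clip bound in g.
#' @return The clipped recording.
#' @export
clip_3g <- function(rec, bound = 3) {
  for (ax in c("x", "y", "z")) {
    rec[[ax]] <- pmin(pmax(rec[[ax]], -bound), bound)
  }
  rec
}

#' Divide a 30 Hz recording into consecutive 30-second epochs
#'
#' Each contiguous segment contributes `floor(duration / 30 s)` epochs; a
#' trailing partial window is dropped. Epochs are half-open
#' `[start, start + 30 s)` intervals holding exactly 900 samples per axis.
#'
#' @param rec A `raw_recording` at 30 Hz (see [resample_30hz()]).
#' @return An `epoch_array`: list with `signals` (m x 900 x 3 array), `info`
#'   (tibble `epoch_start`, `segment`, `wear`), `hz`, `epoch_s`.
#' @export
make_epochs <- function(rec) {
  hz <- attr(rec, "sample_hz") %||% NA_real_
  if (!isTRUE(abs(hz - EPOCH_HZ) < 1e-6)) abort("recording must be resampled to 30 Hz first")
  seg <- rec[["segment"]] %||% segment_ids(rec$time)
  sig_list <- list()
  info_list <- list()
  for (s in unique(seg)) {
    idx <- which(seg == s)
    n_full <- length(idx) %/% EPOCH_N
    if (n_full == 0) next
    used <- idx[seq_len(n_full * EPOCH_N)]
    arr <- array(0, dim = c(n_full, EPOCH_N, 3))
    for (a in 1:3) {
      arr[, , a] <- matrix(rec[[c("x", "y", "z")[a]]][used], nrow = n_full, byrow = TRUE)
    }
    sig_list[[length(sig_list) + 1L]] <- arr
    info_list[[length(info_list) + 1L]] <- tibble::tibble(
      epoch_start = rec$time[used[1L + (seq_len(n_full) - 1L) * EPOCH_N]],
      segment = s
    )
  }
  if (length(sig_list) == 0) {
    return(new_epoch_array(array(0, dim = c(0, EPOCH_N, 3)),
      tibble::tibble(
        epoch_start = as.POSIXct(character(), tz = "UTC"),
        segment = integer(), wear = logical()
      )
    ))
  }
  m_tot <- sum(vapply(sig_list, function(a) dim(a)[1], integer(1)))
  signals <- array(0, dim = c(m_tot, EPOCH_N, 3))
  at <- 0L
  for (a in sig_list) {
    signals[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  info <- dplyr::bind_rows(info_list)
  info$wear <- TRUE
  new_epoch_array(signals, info)
}

new_epoch_array <- function(signals, info) {
  structure(
    list(signals = signals, info = info, hz = EPOCH_HZ, epoch_s = EPOCH_S),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf(
    "<epoch_array> %d epochs of %d s @ %d Hz (%d wear, %d non-wear)\n",
    n_epochs(x), x$epoch_s, x$hz, sum(x$info$wear), sum(!x$info$wear)
  ))
  invisible(x)
}

#' @export
length.epoch_array <- function(x) n_epochs(x)

n_epochs <- function(epochs) dim(epochs$signals)[1]

# Per-epoch, per-axis standard deviations (m x 3), in g.
epoch_axis_sd <- function(epochs) {
  m <- n_epochs(epochs)
  out <- matrix(0, m, 3)
  for (a in 1:3) {
    x <- epochs$signals[, , a, drop = FALSE]
    dim(x) <- dim(epochs$signals)[1:2]
    mu <- rowMeans(x)
    out[, a] <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  }
  out
}

# Per-epoch mean truncated ENMO in mg: mean over samples of
# max(||(x,y,z)|| - 1 g, 0).
epoch_enmo_mg <- function(epochs) {
  m <- n_epochs(epochs)
  if (m == 0) {
    return(numeric(0))
  }
  mag <- sqrt(epochs$signals[, , 1]^2 + epochs$signals[, , 2]^2 + epochs$signals[, , 3]^2)
  dim(mag) <- dim(epochs$signals)[1:2]
  1000 * rowMeans(pmax(mag - 1, 0))
}

epoch_mean_magnitude <- function(epochs) {
  mag <- sqrt(epochs$signals[, , 1]^2 + epochs$signals[, , 2]^2 + epochs$signals[, , 3]^2)
  dim(mag) <- dim(epochs$signals)[1:2]
  rowMeans(mag)
}

#' Flag non-wear epochs
#'
#' An epoch is stationary iff the within-epoch standard deviation of each of
#' x, y and z is below `sd_thresh_mg`. Maximal runs of stationary epochs
#' lasting strictly more than `min_run_min` minutes are flagged non-wear; all
#' other epochs are wear. Runs are evaluated within contiguous segments.
#'
#' @param epochs An `epoch_array`.
#' @param sd_thresh_mg Stationarity threshold on per-axis sd, in mg
#'   (default 13).
#' @param min_run_min Minimum run duration in minutes for non-wear, strict
#'   (default 60; an exactly-60-minute still run stays wear).
#' @return The `epoch_array` with `info$wear` updated.
#' @export
detect_nonwear <- function(epochs, sd_thresh_mg = 13, min_run_min = 60) {
  m <- n_epochs(epochs)
  if (m == 0) {
    return(epochs)
  }
  sds <- epoch_axis_sd(epochs)
  stationary <- rowSums(sds < sd_thresh_mg / 1000) == 3L
  wear <- rep(TRUE, m)
  for (s in unique(epochs$info$segment)) {
    idx <- which(epochs$info$segment == s)
    r <- rle(stationary[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (r$values[j] && r$lengths[j] * EPOCH_S / 60 > min_run_min) {
        wear[idx[starts[j]:ends[j]]] <- FALSE
      }
    }
  }
  epochs$info$wear <- wear
  epochs
}

#' Quality-control screen for a processed recording
#'
#' Replicates recording-level exclusion rules: a recording is excluded when
#' it could not be parsed, when its mean truncated ENMO over wear epochs
#' exceeds 200 mg (unrealistically high values), or when it appears poorly
#' calibrated. The calibration check requires the median stationary-epoch
#' vector magnitude to lie within 1 g +/- 30 mg (a still wrist should read
#' exactly gravity); recordings with no stationary epochs pass the check by
#' default. Never raises: always returns a report.
#'
#' @param epochs An `epoch_array` with wear flags set, or `NULL` when parsing
#'   failed.
#' @param parsed Set `FALSE` when the raw file could not be parsed.
#' @param enmo_max_mg Exclusion threshold on recording-level mean ENMO (mg).
#' @param calib_tol_mg Calibration tolerance around 1 g (mg).
#' @return A one-row tibble (`qc_report`): `parsed`, `mean_enmo_mg`,
#'   `calibrated`, `excluded`, `reasons` (comma-separated; empty iff not
#'   excluded).
#' @export
qc_screen <- function(epochs, parsed = TRUE, enmo_max_mg = 200, calib_tol_mg = 30) {
  reasons <- character()
  mean_enmo <- NA_real_
  calibrated <- NA
  if (!parsed || is.null(epochs)) {
    reasons <- "parse"
    parsed <- FALSE
  } else {
    wear <- epochs$info$wear
    enmo <- epoch_enmo_mg(epochs)
    mean_enmo <- if (any(wear)) mean(enmo[wear]) else NA_real_
    if (isTRUE(mean_enmo > enmo_max_mg)) reasons <- c(reasons, "high_values")
    sds <- epoch_axis_sd(epochs)
    stationary <- rowSums(sds < 13 / 1000) == 3L
    if (any(stationary)) {
      med_mag <- median(epoch_mean_magnitude(epochs)[stationary])
      calibrated <- abs(med_mag - 1) <= calib_tol_mg / 1000
    } else {
      calibrated <- TRUE
    }
    if (!calibrated) reasons <- c(reasons, "calibration")
  }
  structure(
    tibble::tibble(
      parsed = parsed,
      mean_enmo_mg = mean_enmo,
      calibrated = calibrated,
      excluded = length(reasons) > 0,
      reasons = paste(reasons, collapse = ",")
    ),
    class = c("qc_report", class(tibble::tibble()))
  )
}

#' One-call preprocessing pipeline
#'
#' `read -> resample to 30 Hz -> clip to +/- 3 g -> epoch -> non-wear ->
#' QC screen`. Parse failures are captured in the QC report rather than
#' raised.
#'
#' @param path Path to a `time,x,y,z` delimited file.
#' @param sd_thresh_mg,min_run_min Non-wear parameters, see
#'   [detect_nonwear()].
#' @param meta Optional device metadata.
#' @return List with `epochs` (or `NULL`) and `qc` report.
#' @export
preprocess_recording <- function(path, sd_thresh_mg = 13, min_run_min = 60, meta = list()) {
  rec <- tryCatch(read_raw(path, meta = meta), somnokit_parse_error = function(e) NULL)
  if (is.null(rec)) {
    return(list(epochs = NULL, qc = qc_screen(NULL, parsed = FALSE)))
  }
  epochs <- rec |>
    resample_30hz() |>
    clip_3g() |>
    make_epochs() |>
    detect_nonwear(sd_thresh_mg = sd_thresh_mg, min_run_min = min_run_min)
  list(epochs = epochs, qc = qc_screen(epochs))
}

#' Persist / restore an epoch store
#'
#' Writes an epoch array as a directory holding a delimited manifest
#' (`manifest.csv`: epoch starts, segment, wear flags) and the signal payload
#' (`signals.rds`).
#'
#' @param epochs An `epoch_array`.
#' @param dir Directory path.
#' @return `dir` (or the restored `epoch_array` for `read_epochs`).
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- epochs$info
  manifest$epoch_start <- format(manifest$epoch_start, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  saveRDS(epochs$signals, file.path(dir, "signals.rds"))
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"), show_col_types = FALSE)
  info <- tibble::tibble(
    epoch_start = as.POSIXct(manifest$epoch_start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"),
    segment = manifest$segment, wear = manifest$wear
  )
  new_epoch_array(readRDS(file.path(dir, "signals.rds")), info)
}
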