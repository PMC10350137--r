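#' Construct a hypnogram
#'
#' A hypnogram is a tibble with one row per 30-second epoch, holding the epoch
#' start time and the sleep stage. Stages live in one of three label spaces:
#' the five AASM stages (`W`, `N1`, `N2`, `N3`, `R`), the three-class space
#' (`W`, `NREM`, `R`) where the NREM stages are pooled, or the two-class space
#' (`W`, `S`) where all sleep is pooled.
#'
#' @param epoch_start `POSIXct` vector of epoch start times (30 s apart within
#'   a contiguous block).
#' @param stage Character or factor vector of stage labels.
#' @param scheme One of `"five_class"`, `"three_class"`, `"two_class"`.
#' @return A tibble of class `hypnogram` with columns `epoch_start`, `stage`.
#' @export
hypnogram <- function(epoch_start, stage, scheme = c("five_class", "three_class", "two_class")) {
  scheme <- match.arg(scheme)
  levels <- stage_levels(scheme)
  stage <- as.character(stage)
  bad <- setdiff(unique(stage), levels)
  if (length(bad) > 0) {
    abort(sprintf("stage labels outside the %s space: %s", scheme, paste(bad, collapse = ", ")))
  }
  if (length(epoch_start) != length(stage)) {
    abort("epoch_start and stage must have equal length")
  }
  out <- tibble::tibble(epoch_start = epoch_start, stage = factor(stage, levels = levels))
  structure(out, class = c("hypnogram", class(out)), scheme = scheme)
}

stage_levels <- function(scheme) {
  switch(scheme,
    five_class = STAGES5,
    three_class = STAGES3,
    two_class = STAGES2,
    abort(sprintf("unknown scheme '%s'", scheme))
  )
}

hypnogram_scheme <- function(h) attr(h, "scheme") %||% "five_class"

#' Collapse five-stage labels or probabilities to three or two classes
#'
#' Three-class pools N1/N2/N3 into `NREM` (keeping `W` and `R`); two-class
#' pools everything except wake into `S` (sleep). Probabilities collapse by
#' summation, so the collapsed vectors stay on the probability simplex; when a
#' hard label is needed afterwards, take the argmax of the collapsed
#' probabilities (collapse-then-argmax), which uses the full posterior mass.
#'
#' @param x A `hypnogram`, a factor/character vector of five-stage labels, or
#'   a numeric matrix of per-epoch probabilities with columns `W,N1,N2,N3,R`.
#' @param scheme `"three_class"` or `"two_class"`.
#' @return Same shape as the input, in the collapsed label space.
#' @examples
#' collapse(factor("N3", levels = c("W", "N1", "N2", "N3", "R")), "three_class")
#' @export
collapse <- function(x, scheme = c("three_class", "two_class")) {
  scheme <- match.arg(scheme)
  if (inherits(x, "hypnogram")) {
    if (hypnogram_scheme(x) != "five_class") {
      abort("collapse() expects five-class input")
    }
    return(hypnogram(x$epoch_start, collapse_labels(as.character(x$stage), scheme), scheme))
  }
  if (is.matrix(x)) {
    return(collapse_probs(x, scheme))
  }
  chr <- as.character(x)
  ok <- is.na(chr) | chr %in% STAGES5
  if (!all(ok)) abort("labels outside the five-class space")
  factor(collapse_labels(chr, scheme), levels = stage_levels(scheme))
}

collapse_labels <- function(stage, scheme) {
  if (scheme == "three_class") {
    out <- ifelse(stage %in% c("N1", "N2", "N3"), "NREM", stage)
  } else {
    out <- ifelse(stage == "W", "W", "S")
  }
  out[is.na(stage)] <- NA_character_
  out
}

collapse_probs <- function(p, scheme) {
  if (ncol(p) != 5) abort("probability matrix must have 5 columns (W,N1,N2,N3,R)")
  cn <- colnames(p) %||% STAGES5
  if (!all(STAGES5 %in% cn)) abort("probability columns must be named W,N1,N2,N3,R")
  p <- p[, match(STAGES5, cn), drop = FALSE]
  colnames(p) <- STAGES5
  if (scheme == "three_class") {
    out <- cbind(
      W = p[, "W"],
      NREM = p[, "N1"] + p[, "N2"] + p[, "N3"],
      R = p[, "R"]
    )
  } else {
    out <- cbind(W = p[, "W"], S = p[, "N1"] + p[, "N2"] + p[, "N3"] + p[, "R"])
  }
  out
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf(
    "<hypnogram> %d epochs (%s), %s\n",
    nrow(x), hypnogram_scheme(x),
    if (nrow(x) > 0) paste(format(x$epoch_start[1]), "...") else "empty"
  ))
  NextMethod()
}

#' Plot a hypnogram as a step trace
#'
#' @param object A `hypnogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hypnogram <- function(object, ...) {
  scheme <- hypnogram_scheme(object)
  ord <- switch(scheme,
    five_class = c("W", "R", "N1", "N2", "N3"),
    three_class = c("W", "R", "NREM"),
    two_class = c("W", "S")
  )
  df <- tibble::tibble(
    time = object$epoch_start,
    stage = factor(as.character(object$stage), levels = rev(ord))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$stage, group = 1)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
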