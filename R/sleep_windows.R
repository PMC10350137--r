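#' Detect candidate time-in-bed windows from sleep/wake labels
#'
#' Maximal runs of `S` (sleep) epochs in a smoothed two-class sequence become
#' candidate time-in-bed windows; runs shorter than `min_len_min` minutes are
#' discarded as spurious micro-runs. `NA` labels (non-wear) break runs.
#'
#' @param labels Two-class (`W`/`S`) label vector over consecutive 30-s
#'   epochs, or a two-class [hypnogram()].
#' @param epoch_start Epoch start times (taken from the hypnogram when one is
#'   given).
#' @param min_len_min Minimum candidate length in minutes (default 30).
#' @return A tibble of windows: `start`, `end` (half-open), `source`
#'   (`"detected"`), `merged_from`.
#' @export
detect_time_in_bed <- function(labels, epoch_start = NULL, min_len_min = 30) {
  if (inherits(labels, "hypnogram")) {
    epoch_start <- labels$epoch_start
    labels <- labels$stage
  }
  labels <- as.character(labels)
  if (is.null(epoch_start)) abort("epoch_start is required")
  if (length(labels) != length(epoch_start)) abort("labels and epoch_start must align")
  bad <- setdiff(unique(labels[!is.na(labels)]), STAGES2)
  if (length(bad) > 0) abort("labels must be two-class (W/S)")
  is_sleep <- !is.na(labels) & labels == "S"
  if (!any(is_sleep)) {
    return(empty_windows())
  }
  r <- rle(is_sleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * EPOCH_S / 60 >= min_len_min)
  tibble::tibble(
    start = epoch_start[starts[keep]],
    end = epoch_start[ends[keep]] + EPOCH_S,
    source = "detected",
    merged_from = 1L
  )
}

empty_windows <- function() {
  tibble::tibble(
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    source = character(), merged_from = integer()
  )
}

#' Merge nearby time-in-bed windows
#'
#' Consecutive windows separated by a gap of at most `gap_max_min` minutes
#' are unioned (the gap is absorbed into the merged window). The operation is
#' idempotent and, after sorting, independent of input order.
#'
#' @param windows Window tibble (`start`, `end`), sorted or not,
#'   non-overlapping.
#' @param gap_max_min Maximum gap to merge across, inclusive (default 60).
#' @return Merged window tibble with `merged_from` counts.
#' @export
merge_windows <- function(windows, gap_max_min = 60) {
  if (nrow(windows) <= 1) {
    return(windows)
  }
  windows <- dplyr::arrange(windows, .data$start)
  if (any(as.numeric(windows$start[-1]) < as.numeric(windows$end[-nrow(windows)]))) {
    abort("windows overlap; merge_windows expects non-overlapping input")
  }
  merged_from <- windows[["merged_from"]] %||% rep(1L, nrow(windows))
  out_start <- windows$start[1]
  out_end <- windows$end[1]
  out_n <- merged_from[1]
  res <- list()
  for (i in 2:nrow(windows)) {
    gap_min <- as.numeric(windows$start[i] - out_end, units = "mins")
    if (gap_min <= gap_max_min) {
      out_end <- windows$end[i]
      out_n <- out_n + merged_from[i]
    } else {
      res[[length(res) + 1L]] <- tibble::tibble(
        start = out_start, end = out_end,
        source = "detected", merged_from = out_n
      )
      out_start <- windows$start[i]
      out_end <- windows$end[i]
      out_n <- merged_from[i]
    }
  }
  res[[length(res) + 1L]] <- tibble::tibble(
    start = out_start, end = out_end,
    source = "detected", merged_from = out_n
  )
  dplyr::bind_rows(res)
}

#' Select the longest window per noon-to-noon interval
#'
#' Each merged window is assigned to the noon-to-noon civil day containing
#' its midpoint; within each interval the longest window wins, ties broken by
#' earlier start. The overnight sleep estimate for a day is then staged from
#' this window.
#'
#' @param windows Merged window tibble.
#' @return Tibble with `noon_day` (the `Date` whose noon opens the interval)
#'   and the selected window columns; days without a window are absent.
#' @export
longest_per_noon_interval <- function(windows) {
  if (nrow(windows) == 0) {
    return(dplyr::mutate(empty_windows(), noon_day = as.Date(character()), .before = 1))
  }
  mid <- windows$start + as.numeric(windows$end - windows$start, units = "secs") / 2
  # noon-to-noon day: shift midpoints back 12 h, take the civil date
  noon_day <- as.Date(format(mid - 12 * 3600, "%Y-%m-%d"))
  windows |>
    dplyr::mutate(
      noon_day = noon_day,
      .len = as.numeric(.data$end - .data$start, units = "secs")
    ) |>
    dplyr::group_by(.data$noon_day) |>
    dplyr::arrange(dplyr::desc(.data$.len), .data$start, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".len") |>
    dplyr::relocate("noon_day")
}

#' Overnight sleep duration within a window
#'
#' Minutes scored as sleep (REM or NREM; anything but wake) within the
#' window: `0.5 min x` the count of sleep epochs. Epochs with missing labels
#' (non-wear) inside the window raise by default; with
#' `missing = "as_wake"` they stay part of time-in-bed but contribute no
#' sleep.
#'
#' @param window One-row window tibble (or list with `start`, `end`).
#' @param labels A three- or two-class [hypnogram()] covering the window.
#' @param missing `"error"` or `"as_wake"`.
#' @return Minutes of sleep (numeric scalar).
#' @export
overnight_sleep_duration <- function(window, labels, missing = c("error", "as_wake")) {
  missing <- match.arg(missing)
  stages <- window_stages(window, labels, missing)
  sum(!is.na(stages) & stages != "W") * EPOCH_S / 60
}

# Stage labels for every epoch of [start, end); validates coverage.
window_stages <- function(window, labels, missing = "error") {
  if (!inherits(labels, "hypnogram")) abort("labels must be a hypnogram")
  start <- window$start[1]
  end <- window$end[1]
  n_expected <- round(as.numeric(end - start, units = "secs") / EPOCH_S)
  wanted <- start + EPOCH_S * (seq_len(n_expected) - 1L)
  idx <- match(as.numeric(wanted), as.numeric(labels$epoch_start))
  stages <- as.character(labels$stage)[idx]
  if (anyNA(idx) || anyNA(stages)) {
    if (missing == "error") abort("missing labels inside the window")
    stages[is.na(stages)] <- NA_character_
  }
  stages
}

#' Free-living window pipeline: detect, merge, select
#'
#' Chains [detect_time_in_bed()] (no length floor at this stage),
#' [merge_windows()], a minimum-length filter on the *merged* windows, and
#' [longest_per_noon_interval()]; windows whose share of missing (non-wear)
#' epochs exceeds 20% are flagged low-confidence. The length floor is
#' applied after merging because brief within-sleep wake bouts legitimately
#' fragment the raw sleep runs; filtering before merging would discard real
#' sleep and break windows at ordinary awakenings.
#'
#' @inheritParams detect_time_in_bed
#' @param gap_max_min Merge gap, minutes.
#' @return Tibble of per-noon-day selected windows with `prop_missing` and
#'   `low_confidence`.
#' @export
sleep_windows_pipeline <- function(labels, epoch_start = NULL, min_len_min = 30, gap_max_min = 60) {
  if (inherits(labels, "hypnogram")) {
    epoch_start <- labels$epoch_start
    labels <- as.character(labels$stage)
  }
  windows <- detect_time_in_bed(labels, epoch_start, min_len_min = 0) |>
    merge_windows(gap_max_min = gap_max_min)
  windows <- windows[as.numeric(windows$end - windows$start, units = "mins") >= min_len_min, ] |>
    longest_per_noon_interval()
  if (nrow(windows) == 0) {
    return(dplyr::mutate(windows, prop_missing = numeric(), low_confidence = logical()))
  }
  windows$prop_missing <- vapply(seq_len(nrow(windows)), function(i) {
    n_total <- round(as.numeric(windows$end[i] - windows$start[i], units = "secs") / EPOCH_S)
    inside <- epoch_start >= windows$start[i] & epoch_start < windows$end[i]
    n_known <- sum(inside & !is.na(labels))
    1 - n_known / n_total
  }, numeric(1))
  windows$low_confidence <- windows$prop_missing > 0.2
  windows
}
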