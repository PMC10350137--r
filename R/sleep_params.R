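#' Per-night sleep parameters from a staged time-in-bed window
#'
#' The seven per-night summary measures, on 30-s epoch counts within the
#' half-open window:
#' * total sleep duration `TST = 0.5 min x #(REM or NREM epochs)`;
#' * sleep efficiency `SE = 100 x TST / window duration` (time in bed);
#' * sleep onset = first sleep epoch in the window; `WASO = 0.5 min x`
#'   the wake epochs from onset to the window end;
#' * REM and NREM durations by epoch count, and their ratios as percentages
#'   of TST.
#'
#' A window with no sleep epochs reports `TST = 0`, `SE = 0` and WASO (and
#' the ratios) as missing. Epochs partition the window, so
#' `REM + NREM = TST` and `pre-onset wake + WASO + TST = window duration`
#' hold exactly.
#'
#' @param window One-row window tibble (`start`, `end`).
#' @param labels A three-class [hypnogram()] (`W`/`NREM`/`R`) covering the
#'   window. Five-class input is collapsed first.
#' @param missing Handling of unlabeled epochs inside the window: `"error"`
#'   (default) or `"as_wake"` (non-wear stays in bed but contributes no
#'   sleep).
#' @return A one-row tibble of class `sleep_parameters`:
#'   `total_sleep_duration`, `sleep_efficiency`, `waso`, `rem_duration`,
#'   `nrem_duration`, `rem_ratio`, `nrem_ratio`, `window_start`,
#'   `window_end`, `time_in_bed`.
#' @export
compute_params <- function(window, labels, missing = c("error", "as_wake")) {
  missing <- match.arg(missing)
  if (inherits(labels, "hypnogram") && hypnogram_scheme(labels) == "five_class") {
    labels <- collapse(labels, "three_class")
  }
  if (hypnogram_scheme(labels) != "three_class") {
    abort("labels must be three-class (W/NREM/R)")
  }
  stages <- window_stages(window, labels, missing)
  stages[is.na(stages)] <- "W" # only reachable with missing = "as_wake"
  tib_min <- length(stages) * EPOCH_S / 60
  n_rem <- sum(stages == "R")
  n_nrem <- sum(stages == "NREM")
  tst <- (n_rem + n_nrem) * EPOCH_S / 60
  rem <- n_rem * EPOCH_S / 60
  nrem <- n_nrem * EPOCH_S / 60
  if (tst == 0) {
    waso <- NA_real_
    se <- 0
    rem_ratio <- NA_real_
    nrem_ratio <- NA_real_
  } else {
    onset <- which(stages != "W")[1]
    waso <- sum(stages[onset:length(stages)] == "W") * EPOCH_S / 60
    se <- 100 * tst / tib_min
    rem_ratio <- 100 * rem / tst
    nrem_ratio <- 100 * nrem / tst
  }
  structure(
    tibble::tibble(
      total_sleep_duration = tst, sleep_efficiency = se, waso = waso,
      rem_duration = rem, nrem_duration = nrem,
      rem_ratio = rem_ratio, nrem_ratio = nrem_ratio,
      window_start = window$start[1], window_end = window$end[1],
      time_in_bed = tib_min
    ),
    class = c("sleep_parameters", class(tibble::tibble()))
  )
}

#' Weekly summary of daily sleep parameters under wear criteria
#'
#' Averages daily parameters over valid days only. A day is valid when it
#' has at least `min_wear_h` hours of device wear; the summary itself is
#' valid when at least `min_days` valid days remain and they include at
#' least one weekday and one weekend day (weekday/weekend from the civil
#' calendar date whose noon opens the noon-to-noon interval). Defaults are
#' the wear criteria under which weekly means remain reliable (ICC > 0.75
#' against complete wear): 22 h/day for at least 3 days.
#'
#' @param daily Tibble with one row per noon-to-noon day: `noon_day`
#'   (`Date`), `wear_hours`, and the parameter columns of
#'   [compute_params()].
#' @param min_wear_h Minimum wear per valid day, hours.
#' @param min_days Minimum number of valid days.
#' @return A one-row tibble: mean of each parameter over valid days,
#'   `n_valid_days`, `wear_hours_per_day`, `includes_weekday`,
#'   `includes_weekend`, `valid`.
#' @export
weekly_summary <- function(daily, min_wear_h = 22, min_days = 3) {
  params <- c(
    "total_sleep_duration", "sleep_efficiency", "waso",
    "rem_duration", "nrem_duration", "rem_ratio", "nrem_ratio"
  )
  params <- intersect(params, names(daily))
  ok <- !is.na(daily$wear_hours) & daily$wear_hours >= min_wear_h
  valid_days <- daily[ok, ]
  dow <- as.integer(format(valid_days$noon_day, "%u"))
  includes_weekday <- any(dow <= 5)
  includes_weekend <- any(dow >= 6)
  valid <- nrow(valid_days) >= min_days && includes_weekday && includes_weekend
  means <- lapply(params, function(p) {
    if (nrow(valid_days) == 0) NA_real_ else mean(valid_days[[p]], na.rm = TRUE)
  })
  names(means) <- params
  tibble::as_tibble(c(
    means,
    list(
      n_valid_days = nrow(valid_days),
      wear_hours_per_day = if (nrow(valid_days) == 0) NA_real_ else mean(valid_days$wear_hours),
      includes_weekday = includes_weekday,
      includes_weekend = includes_weekend,
      valid = valid
    )
  ))
}

#' Categorize weekly sleep into exposure groups
#'
#' Duration classes on weekly mean overnight sleep duration: short (< 6 h),
#' normal (6 to 7.9 h), long (>= 8 h). Sleep efficiency is dichotomized at
#' `efficiency_split` (typically the cohort median).
#'
#' @param summary A valid [weekly_summary()] row.
#' @param efficiency_split Low/high split on weekly mean sleep efficiency
#'   (percent).
#' @return Tibble with `duration_class` (factor short/normal/long) and
#'   `efficiency_class` (factor low/high).
#' @export
categorize_exposures <- function(summary, efficiency_split) {
  if (!isTRUE(summary$valid)) abort("cannot categorize an invalid weekly summary")
  dur_h <- summary$total_sleep_duration / 60
  duration_class <- if (dur_h < 6) "short" else if (dur_h < 8) "normal" else "long"
  efficiency_class <- if (summary$sleep_efficiency < efficiency_split) "low" else "high"
  tibble::tibble(
    duration_class = factor(duration_class, levels = c("short", "normal", "long")),
    efficiency_class = factor(efficiency_class, levels = c("low", "high"))
  )
}
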