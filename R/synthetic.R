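#' Per-stage wrist-movement profile
#'
#' Movement intensity differs strongly by sleep stage: wake shows frequent
#' large arm movements, N1 occasional repositioning, N2 and REM sparse small
#' movements (REM as short low-amplitude twitches), and N3 near stillness.
#' The profile parameterises, per stage, a sparse-burst movement model:
#' Poisson-distributed movement bursts (exponentially damped random-direction
#' impulses) superimposed on Gaussian sensor noise and slow orientation drift
#' of the gravity vector.
#'
#' `contrast` scales the between-stage differences with one knob: rates,
#' amplitudes and noise levels are interpolated geometrically between the
#' across-stage geometric mean (`contrast = 0`, all stages statistically
#' identical, so no classifier can beat chance) and the preset values
#' (`contrast = 1`). Values above 1 extrapolate to wider separation.
#'
#' @param preset `"default"` for a plausible adult wrist profile, or
#'   `"high_contrast"` for widely separated stage signatures (useful for
#'   model sanity checks where the staging problem should be easy).
#' @param contrast Non-negative scalar separability knob (default 1).
#' @return A tibble with columns `stage`, `burst_rate` (bursts/min),
#'   `burst_amplitude` (g), `baseline_noise_sd` (g), `orientation_drift_sd`
#'   (rad per epoch).
#' @export
movement_profile <- function(preset = c("default", "high_contrast"), contrast = 1) {
  preset <- match.arg(preset)
  prof <- switch(preset,
    default = tibble::tribble(
      ~stage, ~burst_rate, ~burst_amplitude, ~baseline_noise_sd, ~orientation_drift_sd,
      "W", 8.0, 0.80, 0.020, 0.020,
      "N1", 3.0, 0.40, 0.010, 0.010,
      "N2", 1.0, 0.25, 0.005, 0.005,
      "N3", 0.2, 0.15, 0.003, 0.003,
      "R", 2.0, 0.15, 0.006, 0.005
    ),
    high_contrast = tibble::tribble(
      ~stage, ~burst_rate, ~burst_amplitude, ~baseline_noise_sd, ~orientation_drift_sd,
      "W", 12.0, 1.00, 0.030, 0.020,
      "N1", 4.0, 0.50, 0.012, 0.010,
      "N2", 0.5, 0.30, 0.004, 0.005,
      "N3", 0.1, 0.15, 0.002, 0.003,
      "R", 5.0, 0.10, 0.015, 0.005
    )
  )
  if (!is.numeric(contrast) || length(contrast) != 1 || contrast < 0) {
    abort("contrast must be a non-negative scalar")
  }
  if (contrast != 1) {
    for (col in c("burst_rate", "burst_amplitude", "baseline_noise_sd", "orientation_drift_sd")) {
      v <- prof[[col]]
      gm <- exp(mean(log(v)))
      prof[[col]] <- gm * (v / gm)^contrast
    }
  }
  prof
}

#' Stage dynamics: the generative model of a night
#'
#' Bundles a first-order Markov chain over the five AASM stages at 30-s epoch
#' resolution (transition matrix + initial distribution) with a per-stage
#' [movement_profile()]. The default transition matrix encodes mean bout
#' lengths of roughly 2 min for within-night wake, 1 min for N1, and 10 min
#' for N2, N3 and REM — fixture constants with plausible AASM bout structure,
#' not estimates of any study population.
#'
#' @param transition 5x5 row-stochastic matrix over (W, N1, N2, N3, R);
#'   default as described.
#' @param initial Probability 5-vector for the first epoch.
#' @param profile Movement profile tibble, see [movement_profile()].
#' @return A list of class `stage_dynamics`.
#' @export
stage_dynamics <- function(transition = NULL, initial = NULL, profile = movement_profile()) {
  if (is.null(transition)) {
    transition <- matrix(
      c(
        0.75, 0.20, 0.04, 0.00, 0.01,
        0.10, 0.50, 0.35, 0.00, 0.05,
        0.01, 0.02, 0.95, 0.01, 0.01,
        0.01, 0.00, 0.04, 0.95, 0.00,
        0.02, 0.02, 0.01, 0.00, 0.95
      ),
      nrow = 5, byrow = TRUE, dimnames = list(STAGES5, STAGES5)
    )
  }
  if (is.null(initial)) {
    initial <- c(W = 0.6, N1 = 0.3, N2 = 0.1, N3 = 0, R = 0)
  }
  dyn <- structure(
    list(transition = transition, initial = initial, profile = profile),
    class = "stage_dynamics"
  )
  validate_dynamics(dyn)
  dyn
}

#' Stationary distribution of a stage transition matrix
#'
#' The left eigenvector of the transition matrix for eigenvalue 1,
#' normalised to a probability vector. Useful as an `initial` distribution
#' when a time-homogeneous stage sequence (no time-of-night trend) is
#' wanted, e.g. in chance-level checks.
#'
#' @param transition Row-stochastic matrix (or a [stage_dynamics()]).
#' @return Named probability vector.
#' @export
stationary_distribution <- function(transition) {
  if (inherits(transition, "stage_dynamics")) transition <- transition$transition
  ev <- eigen(t(transition))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v <- v / sum(v)
  setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(transition))
}

validate_dynamics <- function(dyn) {
  tm <- dyn$transition
  if (!is.matrix(tm) || any(dim(tm) != c(5, 5))) {
    abort("transition must be a 5x5 matrix over (W, N1, N2, N3, R)")
  }
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9)) {
    abort("transition matrix must be row-stochastic (rows sum to 1, entries >= 0)")
  }
  init <- dyn$initial
  if (length(init) != 5 || any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    abort("initial must be a probability 5-vector")
  }
  prof <- dyn$profile
  need <- c("stage", "burst_rate", "burst_amplitude", "baseline_noise_sd", "orientation_drift_sd")
  if (!all(need %in% names(prof)) || !setequal(prof$stage, STAGES5)) {
    abort("profile must give burst/noise/drift parameters for all five stages")
  }
  num <- as.matrix(prof[setdiff(need, "stage")])
  if (any(!is.finite(num)) || any(num < 0)) abort("profile parameters must be finite and >= 0")
  invisible(dyn)
}

#' Simulate a five-stage hypnogram from stage dynamics
#'
#' Samples a Markov chain over (W, N1, N2, N3, R) at 30-s epoch resolution.
#'
#' @param dynamics A [stage_dynamics()] object.
#' @param n_epochs Number of 30-s epochs (>= 1).
#' @param seed Integer seed; identical seeds give identical hypnograms.
#' @param start_time First epoch start (`POSIXct`); timestamps are
#'   timezone-naive local times, represented in UTC.
#' @return A five-class [hypnogram()].
#' @export
simulate_hypnogram <- function(dynamics, n_epochs, seed = 1,
                               start_time = as.POSIXct("2022-06-08 23:00:00", tz = "UTC")) {
  validate_dynamics(dynamics)
  if (!is.numeric(n_epochs) || n_epochs < 1) abort("n_epochs must be >= 1")
  n_epochs <- as.integer(n_epochs)
  states <- withr::with_seed(seed, markov_path(dynamics$transition, dynamics$initial, n_epochs))
  hypnogram(
    start_time + EPOCH_S * (seq_len(n_epochs) - 1L),
    STAGES5[states],
    scheme = "five_class"
  )
}

# Sample a Markov chain path; uses inverse-CDF draws so the path is fully
# determined by the RNG stream.
markov_path <- function(transition, initial, n) {
  cum_tm <- t(apply(transition, 1, cumsum))
  u <- runif(n)
  s <- integer(n)
  s[1] <- findInterval(u[1], cumsum(initial), left.open = TRUE) + 1L
  for (i in seq_len(n - 1L)) {
    s[i + 1L] <- findInterval(u[i + 1L], cum_tm[s[i], ], left.open = TRUE) + 1L
  }
  pmin(s, 5L)
}

#' Simulate raw tri-axial accelerometry for a hypnogram
#'
#' Generates a gravity-dominated wrist signal: a unit gravity vector whose
#' orientation performs a slow random walk, plus stage-dependent Gaussian
#' sensor noise and sparse Poisson movement bursts (exponentially damped
#' impulses in random directions, decay ~0.25 s). With all movement sources
#' zero the vector magnitude is exactly 1 g.
#'
#' @param hyp A five-class [hypnogram()].
#' @param dynamics A [stage_dynamics()] whose profile supplies per-stage
#'   movement parameters.
#' @param sample_hz Output sample rate (30, 50 or 100 Hz).
#' @param seed Integer seed.
#' @param meta Optional device metadata list.
#' @return A `raw_recording`: tibble with `time`, `x`, `y`, `z` (g) plus
#'   `sample_hz` and `meta` attributes.
#' @export
simulate_accel <- function(hyp, dynamics, sample_hz = 30, seed = 1, meta = list()) {
  validate_dynamics(dynamics)
  if (!inherits(hyp, "hypnogram") || hypnogram_scheme(hyp) != "five_class") {
    abort("hyp must be a five-class hypnogram")
  }
  if (nrow(hyp) == 0) abort("hypnogram is empty")
  if (!sample_hz %in% c(30, 50, 100)) abort("sample_hz must be one of 30, 50, 100")

  prof <- dynamics$profile[match(as.character(hyp$stage), dynamics$profile$stage), ]
  n_ep <- nrow(hyp)
  n_per <- as.integer(EPOCH_S * sample_hz)
  dt <- 1 / sample_hz

  acc <- withr::with_seed(seed, {
    # Orientation random walk at epoch granularity, interpolated per sample.
    theta_ep <- cumsum(c(runif(1, 0, pi), rnorm(n_ep, 0, prof$orientation_drift_sd)))
    phi_ep <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n_ep, 0, prof$orientation_drift_sd)))
    out <- matrix(0, nrow = n_ep * n_per, ncol = 3)
    tau <- 0.25 # burst decay time constant, seconds
    frac <- (seq_len(n_per) - 1L) / n_per
    for (i in seq_len(n_ep)) {
      th <- theta_ep[i] + frac * (theta_ep[i + 1L] - theta_ep[i])
      ph <- phi_ep[i] + frac * (phi_ep[i + 1L] - phi_ep[i])
      sig <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      if (prof$baseline_noise_sd[i] > 0) {
        sig <- sig + matrix(rnorm(3L * n_per, 0, prof$baseline_noise_sd[i]), ncol = 3)
      }
      if (prof$burst_rate[i] > 0 && prof$burst_amplitude[i] > 0) {
        n_b <- rpois(1, prof$burst_rate[i] * EPOCH_S / 60)
        if (n_b > 0) {
          t0 <- runif(n_b, 0, EPOCH_S)
          amp <- prof$burst_amplitude[i] * (0.5 + rexp(n_b, 2))
          for (b in seq_len(n_b)) {
            dir <- rnorm(3)
            dir <- dir / sqrt(sum(dir^2))
            rel <- (seq_len(n_per) - 1L) * dt - t0[b]
            env <- ifelse(rel >= 0, exp(-rel / tau), 0)
            sig <- sig + amp[b] * outer(env, dir)
          }
        }
      }
      out[((i - 1L) * n_per + 1L):(i * n_per), ] <- sig
    }
    out
  })

  t0 <- hyp$epoch_start[1]
  times <- t0 + (seq_len(n_ep * n_per) - 1L) * dt
  new_raw_recording(
    tibble::tibble(time = times, x = acc[, 1], y = acc[, 2], z = acc[, 3]),
    sample_hz = sample_hz, meta = meta
  )
}

new_raw_recording <- function(df, sample_hz, meta = list(), n_dropped = 0L) {
  meta <- utils::modifyList(
    list(device_id = NA_character_, dominant_wrist = TRUE, shift_worker = FALSE, dst_crossover = FALSE),
    meta
  )
  structure(
    df,
    class = c("raw_recording", class(tibble::tibble())),
    sample_hz = sample_hz, meta = meta, n_dropped = n_dropped
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d samples @ %g Hz nominal\n",
    nrow(x), attr(x, "sample_hz") %||% NA
  ))
  NextMethod()
}

#' Free-living recording scenario
#'
#' Describes a multi-day wear period: nightly time-in-bed schedule (with
#' weekday/weekend shift and Gaussian night-to-night jitter), optional
#' afternoon naps, and off-wrist gaps. Days run noon-to-noon starting at
#' `start_date` 12:00.
#'
#' @param n_days Number of nights (>= 1).
#' @param bed_time_mean,rise_time_mean Clock times `"HH:MM"`.
#' @param bed_time_sd_min,rise_time_sd_min Night-to-night jitter, minutes.
#' @param nap_probability Probability of an afternoon nap per day.
#' @param wear_gap_rate Expected off-wrist gaps per day.
#' @param sample_hz Device sample rate (30, 50 or 100).
#' @param seed Integer seed.
#' @param weekday_weekend_shift_min Minutes by which bed and rise shift later
#'   on Friday/Saturday nights.
#' @param start_date First day (a `Date` or `"YYYY-MM-DD"`).
#' @return A list of class `freeliving_scenario`.
#' @export
freeliving_scenario <- function(n_days = 7, bed_time_mean = "23:00", bed_time_sd_min = 30,
                                rise_time_mean = "07:00", rise_time_sd_min = 30,
                                nap_probability = 0.1, wear_gap_rate = 0.2,
                                sample_hz = 30, seed = 1,
                                weekday_weekend_shift_min = 30,
                                start_date = "2022-06-06") {
  if (!is.numeric(n_days) || n_days < 1) abort("n_days must be >= 1")
  if (!sample_hz %in% c(30, 50, 100)) abort("sample_hz must be one of 30, 50, 100")
  if (nap_probability < 0 || nap_probability > 1) abort("nap_probability must be in [0, 1]")
  if (wear_gap_rate < 0) abort("wear_gap_rate must be >= 0")
  structure(
    list(
      n_days = as.integer(n_days), bed_time_mean = bed_time_mean,
      bed_time_sd_min = bed_time_sd_min, rise_time_mean = rise_time_mean,
      rise_time_sd_min = rise_time_sd_min, nap_probability = nap_probability,
      wear_gap_rate = wear_gap_rate, sample_hz = sample_hz, seed = as.integer(seed),
      weekday_weekend_shift_min = weekday_weekend_shift_min,
      start_date = as.Date(start_date)
    ),
    class = "freeliving_scenario"
  )
}

clock_to_secs <- function(hhmm) {
  parts <- as.numeric(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  3600 * parts[1] + 60 * parts[2]
}

#' Simulate a free-living multi-day recording with ground truth
#'
#' Builds the full epoch-level truth for `n_days` noon-to-noon days: one
#' overnight time-in-bed interval per night (stages sampled from the
#' dynamics' Markov chain), optional afternoon naps, wake everywhere else.
#' Off-wrist gaps are drawn as Poisson events with log-normal durations
#' (median 60 min) and removed from the accelerometer trace (the truth
#' hypnogram is kept complete). A sleep diary reports bed and rise times with
#' N(0, 10 min) jitter around truth, mimicking self-report error.
#'
#' @param scenario A [freeliving_scenario()].
#' @param dynamics A [stage_dynamics()].
#' @param accel If `FALSE`, skip raw-signal synthesis (epoch-level truth
#'   only); multi-day raw traces are large, and window-logic work only needs
#'   labels.
#' @return A list with elements `recording` (`raw_recording` or `NULL`),
#'   `truth` (list: `hypnogram` five-class over the whole period, `windows`
#'   tibble of time-in-bed intervals with `start`, `end`, `type`), `diary`
#'   (tibble `night`, `bed`, `rise`), `gaps` (tibble `start`, `end`) and the
#'   scenario.
#' @export
simulate_freeliving <- function(scenario, dynamics = stage_dynamics(), accel = TRUE) {
  if (!inherits(scenario, "freeliving_scenario")) abort("scenario must be a freeliving_scenario")
  validate_dynamics(dynamics)
  sc <- scenario
  period_start <- as.POSIXct(paste(sc$start_date, "12:00:00"), tz = "UTC")
  period_end <- period_start + sc$n_days * 86400
  n_ep <- as.integer(as.numeric(period_end - period_start, units = "secs") / EPOCH_S)
  epoch_start <- period_start + EPOCH_S * (seq_len(n_ep) - 1L)

  sim <- withr::with_seed(sc$seed, {
    windows <- list()
    diary <- list()
    for (d in seq_len(sc$n_days)) {
      day0 <- as.POSIXct(paste(sc$start_date + (d - 1L), "00:00:00"), tz = "UTC")
      dow <- format(sc$start_date + (d - 1L), "%u") # night of day d: Fri=5/Sat=6 shift
      shift <- if (dow %in% c("5", "6")) sc$weekday_weekend_shift_min * 60 else 0
      bed_secs <- clock_to_secs(sc$bed_time_mean)
      if (bed_secs < 12 * 3600) bed_secs <- bed_secs + 86400 # past-midnight bed times
      bed <- day0 + bed_secs + shift + rnorm(1, 0, sc$bed_time_sd_min * 60)
      rise <- day0 + 86400 + clock_to_secs(sc$rise_time_mean) + shift + rnorm(1, 0, sc$rise_time_sd_min * 60)
      if (rise <= bed + 3600) rise <- bed + 3600
      windows[[length(windows) + 1L]] <- tibble::tibble(start = bed, end = rise, type = "night")
      diary[[d]] <- tibble::tibble(
        night = d,
        bed = bed + rnorm(1, 0, 600),
        rise = rise + rnorm(1, 0, 600)
      )
      if (runif(1) < sc$nap_probability) {
        nap_start <- day0 + clock_to_secs("14:00") + rnorm(1, 0, 3600)
        nap_end <- nap_start + runif(1, 1800, 5400)
        windows[[length(windows) + 1L]] <- tibble::tibble(start = nap_start, end = nap_end, type = "nap")
      }
    }
    windows <- dplyr::arrange(dplyr::bind_rows(windows), .data$start)
    windows$start <- round_to_epoch(windows$start, period_start)
    windows$end <- round_to_epoch(windows$end, period_start)

    stages <- rep("W", n_ep)
    for (w in seq_len(nrow(windows))) {
      idx <- which(epoch_start >= windows$start[w] & epoch_start < windows$end[w])
      if (length(idx) > 0) {
        stages[idx] <- STAGES5[markov_path(dynamics$transition, dynamics$initial, length(idx))]
      }
    }

    gaps <- tibble::tibble(start = as.POSIXct(character(), tz = "UTC"), end = as.POSIXct(character(), tz = "UTC"))
    if (sc$wear_gap_rate > 0) {
      n_gaps <- rpois(1, sc$wear_gap_rate * sc$n_days)
      if (n_gaps > 0) {
        g_start <- period_start + runif(n_gaps, 0, as.numeric(period_end - period_start, units = "secs"))
        g_dur <- rlnorm(n_gaps, log(3600), 0.5)
        gaps <- tibble::tibble(start = g_start, end = pmin(g_start + g_dur, period_end))
        gaps <- dplyr::arrange(gaps, .data$start)
      }
    }
    list(stages = stages, windows = windows, diary = dplyr::bind_rows(diary), gaps = gaps)
  })

  truth_hyp <- hypnogram(epoch_start, sim$stages, "five_class")
  rec <- NULL
  if (accel) {
    rec <- simulate_accel(truth_hyp, dynamics, sample_hz = sc$sample_hz, seed = sc$seed + 1000L)
    if (nrow(sim$gaps) > 0) {
      keep <- rep(TRUE, nrow(rec))
      for (g in seq_len(nrow(sim$gaps))) {
        keep[rec$time >= sim$gaps$start[g] & rec$time < sim$gaps$end[g]] <- FALSE
      }
      rec <- new_raw_recording(
        tibble::as_tibble(rec)[keep, ],
        sample_hz = sc$sample_hz, meta = attr(rec, "meta")
      )
    }
  }
  list(
    recording = rec,
    truth = list(hypnogram = truth_hyp, windows = sim$windows),
    diary = sim$diary, gaps = sim$gaps, scenario = sc
  )
}

round_to_epoch <- function(t, origin) {
  origin + EPOCH_S * round(as.numeric(t - origin, units = "secs") / EPOCH_S)
}

#' Simulate a cohort of free-living subjects with stable sleep phenotypes
#'
#' Wraps [simulate_freeliving()] with per-subject random offsets of the bed
#' and rise time means (normal, sd `between_subject_sd_min`), giving the
#' cohort stable between-person differences in habitual sleep timing and
#' duration — the variance component that reliability analyses (ICC) are
#' about.
#'
#' @param n_subjects Number of subjects.
#' @param scenario Template [freeliving_scenario()]; each subject gets a
#'   shifted copy and a subject-specific seed.
#' @param dynamics A [stage_dynamics()].
#' @param between_subject_sd_min Between-subject sd of habitual bed/rise
#'   times, minutes.
#' @param seed Cohort-level seed.
#' @param accel Forwarded to [simulate_freeliving()].
#' @return List of per-subject [simulate_freeliving()] results.
#' @export
simulate_cohort <- function(n_subjects, scenario = freeliving_scenario(), dynamics = stage_dynamics(),
                            between_subject_sd_min = 45, seed = 1, accel = FALSE) {
  offs <- withr::with_seed(seed, matrix(rnorm(2 * n_subjects, 0, between_subject_sd_min), ncol = 2))
  shift_clock <- function(hhmm, mins) {
    s <- (clock_to_secs(hhmm) + round(mins) * 60) %% 86400
    sprintf("%02d:%02d", s %/% 3600, (s %% 3600) %/% 60)
  }
  lapply(seq_len(n_subjects), function(i) {
    sc <- scenario
    sc$bed_time_mean <- shift_clock(sc$bed_time_mean, offs[i, 1])
    sc$rise_time_mean <- shift_clock(sc$rise_time_mean, offs[i, 2])
    sc$seed <- scenario$seed + 131L * i
    simulate_freeliving(sc, dynamics, accel = accel)
  })
}

#' Simulate one labeled night (epochs + hypnogram)
#'
#' Convenience glue for model experiments: a hypnogram from the dynamics, the
#' matching raw signal, and its 30-s/30-Hz epoch array.
#'
#' @inheritParams simulate_hypnogram
#' @return List with `epochs` (an `epoch_array`) and `hypnogram`.
#' @export
simulate_labeled_night <- function(dynamics, n_epochs, seed = 1,
                                   start_time = as.POSIXct("2022-06-08 23:00:00", tz = "UTC")) {
  hyp <- simulate_hypnogram(dynamics, n_epochs, seed = seed, start_time = start_time)
  rec <- simulate_accel(hyp, dynamics, sample_hz = 30, seed = seed + 10000L)
  list(epochs = make_epochs(rec), hypnogram = hyp)
}

#' Write a raw recording / hypnogram as delimited text
#'
#' Recordings are written with header `time,x,y,z` (ISO-8601 timestamps,
#' acceleration in g); hypnograms as `epoch_start,stage`.
#'
#' @param rec A `raw_recording`.
#' @param h A `hypnogram`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- tibble::tibble(
    time = format(rec$time, "%Y-%m-%dT%H:%M:%OS3"),
    x = rec$x, y = rec$y, z = rec$z
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
write_hypnogram <- function(h, path) {
  readr::write_csv(
    tibble::tibble(
      epoch_start = format(h$epoch_start, "%Y-%m-%dT%H:%M:%S"),
      stage = as.character(h$stage)
    ),
    path
  )
  invisible(path)
}

#' @rdname write_recording
#' @param scheme Label space of the stored stages.
#' @export
read_hypnogram <- function(path, scheme = "five_class") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  hypnogram(
    as.POSIXct(df$epoch_start, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")),
    df$stage, scheme
  )
}
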