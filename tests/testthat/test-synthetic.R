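test_that("stage dynamics are validated", {
  bad <- matrix(0.3, 5, 5, dimnames = list(somnokit:::STAGES5, somnokit:::STAGES5))
  expect_error(stage_dynamics(transition = bad), "row-stochastic")
  expect_error(stage_dynamics(initial = c(0.5, 0.5, 0.5, 0, 0)), "probability 5-vector")
  prof <- movement_profile()
  prof$burst_rate[1] <- -1
  expect_error(stage_dynamics(profile = prof), "finite")
  expect_silent(validate <- stage_dynamics())
  expect_equal(rowSums(validate$transition), rep(1, 5), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("hypnogram simulation follows the chain", {
  # absorbing chain: identity transitions keep the initial stage forever
  dyn <- stage_dynamics(transition = diag(5), initial = c(0, 0, 1, 0, 0))
  h <- simulate_hypnogram(dyn, 100, seed = 1)
  expect_equal(as.character(h$stage), rep("N2", 100))

  # uniform chain: stage frequencies approach 1/5 (law of large numbers)
  dyn_u <- stage_dynamics(transition = matrix(0.2, 5, 5), initial = rep(0.2, 5))
  h_u <- simulate_hypnogram(dyn_u, 50000, seed = 1)
  freqs <- table(h_u$stage) / 50000
  expect_true(all(freqs >= 0.19 & freqs <= 0.21))

  # seeded determinism and stage coverage of a default night
  h1 <- simulate_hypnogram(stage_dynamics(), 960, seed = 7)
  h2 <- simulate_hypnogram(stage_dynamics(), 960, seed = 7)
  expect_identical(h1$stage, h2$stage)
  expect_true(all(c("W", "N2", "R") %in% as.character(h1$stage)))

  expect_error(simulate_hypnogram(stage_dynamics(), 0), "n_epochs")
})

test_that("accelerometry preserves gravity and orders movement by stage", {
  prof0 <- movement_profile()
  prof0[, c("burst_rate", "burst_amplitude", "baseline_noise_sd")] <- 0
  dyn0 <- stage_dynamics(profile = prof0)
  h <- hypnogram(
    as.POSIXct("2022-06-08 23:00:00", tz = "UTC") + 30 * (0:9),
    rep("N3", 10), "five_class"
  )
  rec <- simulate_accel(h, dyn0, seed = 2)
  mag <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  expect_true(all(abs(mag - 1) < 1e-6))

  # per-stage mean ENMO ordering of the default profile: W > N1 > (N2,R) > N3
  dyn <- stage_dynamics()
  enmo <- vapply(somnokit:::STAGES5, function(s) {
    hh <- hypnogram(h$epoch_start[1] + 30 * (0:299), rep(s, 300), "five_class")
    mean(somnokit:::epoch_enmo_mg(make_epochs(simulate_accel(hh, dyn, seed = 42))))
  }, numeric(1))
  expect_gt(enmo[["W"]], enmo[["N1"]])
  expect_gt(enmo[["N1"]], enmo[["N2"]])
  expect_gt(enmo[["N1"]], enmo[["R"]])
  expect_gt(min(enmo[["N2"]], enmo[["R"]]), enmo[["N3"]])

  # ENMO means are monotone in the profile's burst rate (rank correlation 1)
  rate <- stage_dynamics()$profile$burst_rate[match(somnokit:::STAGES5, stage_dynamics()$profile$stage)]
  expect_equal(cor(rank(enmo), rank(rate)), 1)

  # wake night vs N3 night contrast
  h_w <- hypnogram(h$epoch_start[1] + 30 * (0:199), rep("W", 200), "five_class")
  h_3 <- hypnogram(h$epoch_start[1] + 30 * (0:199), rep("N3", 200), "five_class")
  e_w <- mean(somnokit:::epoch_enmo_mg(make_epochs(simulate_accel(h_w, dyn, seed = 3))))
  e_3 <- mean(somnokit:::epoch_enmo_mg(make_epochs(simulate_accel(h_3, dyn, seed = 3))))
  expect_gt(e_w, 3 * e_3)

  # seeded determinism, empty-hypnogram error
  r1 <- simulate_accel(h, stage_dynamics(), seed = 5)
  r2 <- simulate_accel(h, stage_dynamics(), seed = 5)
  expect_identical(r1$x, r2$x)
  empty <- hypnogram(as.POSIXct(character(), tz = "UTC"), character(), "five_class")
  expect_error(simulate_accel(empty, stage_dynamics()), "empty")
})

test_that("contrast knob collapses stage differences at zero", {
  p0 <- movement_profile(contrast = 0)
  expect_true(all(abs(p0$burst_rate - p0$burst_rate[1]) < 1e-12))
  expect_true(all(abs(p0$baseline_noise_sd - p0$baseline_noise_sd[1]) < 1e-12))
  p1 <- movement_profile(contrast = 1)
  expect_equal(p1, movement_profile())
  expect_error(movement_profile(contrast = -1), "non-negative")
})

test_that("free-living simulation produces consistent truth", {
  # deterministic schedule: exactly one truth window [23:00, 07:00)
  sc <- freeliving_scenario(
    n_days = 1, bed_time_sd_min = 0, rise_time_sd_min = 0,
    nap_probability = 0, wear_gap_rate = 0, seed = 3,
    weekday_weekend_shift_min = 0
  )
  fl <- simulate_freeliving(sc, stage_dynamics(), accel = FALSE)
  expect_equal(nrow(fl$truth$windows), 1)
  expect_equal(format(fl$truth$windows$start, "%H:%M"), "23:00")
  expect_equal(format(fl$truth$windows$end, "%H:%M"), "07:00")

  # 7 days: one overnight window per noon-to-noon interval
  sc7 <- freeliving_scenario(n_days = 7, nap_probability = 0, wear_gap_rate = 0, seed = 11)
  fl7 <- simulate_freeliving(sc7, stage_dynamics(), accel = FALSE)
  nights <- fl7$truth$windows[fl7$truth$windows$type == "night", ]
  expect_equal(nrow(nights), 7)
  mid <- nights$start + as.numeric(nights$end - nights$start, units = "secs") / 2
  expect_equal(length(unique(as.Date(format(mid - 12 * 3600, "%Y-%m-%d")))), 7)
  expect_equal(nrow(fl7$diary), 7)

  # no gaps requested -> contiguous trace; gaps requested -> missing fraction in (0, 0.5)
  sc_a <- freeliving_scenario(n_days = 1, wear_gap_rate = 0, nap_probability = 0, seed = 2)
  fl_a <- simulate_freeliving(sc_a, stage_dynamics(), accel = TRUE)
  expect_equal(nrow(fl_a$recording), 86400 * 30)
  sc_g <- freeliving_scenario(n_days = 3, wear_gap_rate = 2, nap_probability = 0, seed = 5)
  fl_g <- simulate_freeliving(sc_g, stage_dynamics(), accel = FALSE)
  expect_gt(nrow(fl_g$gaps), 0)
  gap_frac <- sum(as.numeric(fl_g$gaps$end - fl_g$gaps$start, units = "secs")) / (3 * 86400)
  expect_gt(gap_frac, 0)
  expect_lt(gap_frac, 0.5)

  # bit-identical reruns
  fl7b <- simulate_freeliving(sc7, stage_dynamics(), accel = FALSE)
  expect_identical(fl7$truth$hypnogram$stage, fl7b$truth$hypnogram$stage)
  expect_identical(fl7$truth$windows, fl7b$truth$windows)
})

test_that("recordings and hypnograms round-trip through delimited text", {
  dyn <- stage_dynamics()
  h <- simulate_hypnogram(dyn, 5, seed = 1)
  rec <- simulate_accel(h, dyn, seed = 1)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f1)
  write_hypnogram(h, f2)
  rec2 <- read_raw(f1)
  expect_equal(nrow(rec2), nrow(rec))
  expect_equal(rec2$x, rec$x, tolerance = 1e-6)
  h2 <- read_hypnogram(f2)
  expect_equal(as.character(h2$stage), as.character(h$stage))
})
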