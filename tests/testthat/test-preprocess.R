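write_raw_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_raw parses well-formed files and counts malformed rows", {
  f <- write_raw_file(c(
    "time,x,y,z",
    "2022-06-08T23:00:00.000,0.1,0.2,0.9",
    "2022-06-08T23:00:00.033,0.1,0.2,0.9",
    "2022-06-08T23:00:00.066,0.1,0.2,0.9"
  ))
  rec <- read_raw(f)
  expect_s3_class(rec, "raw_recording")
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "n_dropped"), 0L)

  f_bad <- write_raw_file(c(
    "time,x,y,z",
    "2022-06-08T23:00:00.000,0.1,0.2,0.9",
    "2022-06-08T23:00:00.033,oops,0.2,0.9",
    "2022-06-08T23:00:00.066,0.1,0.2,0.9"
  ))
  rec_bad <- read_raw(f_bad)
  expect_equal(nrow(rec_bad), 2)
  expect_equal(attr(rec_bad, "n_dropped"), 1L)

  f_empty <- write_raw_file(character())
  expect_error(read_raw(f_empty), class = "somnokit_parse_error")
  f_nocols <- write_raw_file(c("a,b", "1,2"))
  expect_error(read_raw(f_nocols), class = "somnokit_parse_error")
})

make_rec <- function(t_secs, x, y, z, hz) {
  somnokit:::new_raw_recording(
    tibble::tibble(
      time = as.POSIXct("2022-06-08 23:00:00", tz = "UTC") + t_secs,
      x = x, y = y, z = z
    ),
    sample_hz = hz
  )
}

test_that("resampling to 30 Hz interpolates linearly and splits at gaps", {
  # constant 100 Hz signal for 60 s -> constant 30 Hz, full grid
  t100 <- seq(0, 60, by = 0.01)
  rec <- make_rec(t100, rep(1, length(t100)), rep(0, length(t100)), rep(0, length(t100)), 100)
  out <- resample_30hz(rec)
  expect_equal(nrow(out), 1801)
  expect_true(all(out$x == 1) && all(out$y == 0))

  # 1 Hz sinusoid sampled at 100 Hz matches analytic values at 30 Hz points
  rec_s <- make_rec(t100, sin(2 * pi * t100), rep(0, length(t100)), rep(1, length(t100)), 100)
  out_s <- resample_30hz(rec_s)
  t30 <- as.numeric(out_s$time - out_s$time[1], units = "secs")
  expect_lt(max(abs(out_s$x - sin(2 * pi * t30))), 0.01)

  # identity on an existing 30 Hz grid
  t30g <- seq(0, 30, by = 1 / 30)
  rec30 <- make_rec(t30g, rnorm(length(t30g)), rnorm(length(t30g)), rnorm(length(t30g)), 30)
  out30 <- resample_30hz(rec30)
  expect_equal(nrow(out30), length(t30g))
  expect_lt(max(abs(out30$x - rec30$x)), 1e-9)

  # a > 5 s gap splits segments rather than interpolating across
  t_gap <- c(seq(0, 61, by = 1 / 30), seq(70, 115, by = 1 / 30))
  n <- length(t_gap)
  rec_g <- make_rec(t_gap, rep(0, n), rep(0, n), rep(1, n), 30)
  out_g <- resample_30hz(rec_g)
  expect_equal(length(unique(out_g$segment)), 2)
  ep <- make_epochs(out_g)
  expect_equal(length(ep), 3) # floor(61/30) + floor(45/30)
})

test_that("clipping enforces +/- 3 g and is idempotent", {
  rec <- make_rec(c(0, 1 / 30, 2 / 30), c(5.2, -3.7, 0.98), c(0, 0, 0), c(1, 1, 1), 30)
  out <- clip_3g(rec)
  expect_equal(out$x, c(3, -3, 0.98))
  expect_identical(clip_3g(out)$x, out$x)
})

test_that("epoching floors to whole 30-s windows", {
  t95 <- seq(0, 95, by = 1 / 30)
  rec <- resample_30hz(make_rec(t95, rnorm(length(t95)), rnorm(length(t95)), rnorm(length(t95)), 30))
  ep <- make_epochs(rec)
  expect_equal(length(ep), 3)
  expect_equal(dim(ep$signals), c(3, 900, 3))

  t60 <- seq(0, 60, by = 1 / 30)
  rec60 <- resample_30hz(make_rec(t60, rnorm(length(t60)), rnorm(length(t60)), rnorm(length(t60)), 30))
  ep60 <- make_epochs(rec60)
  expect_equal(length(ep60), 2)
  expect_equal(as.numeric(diff(ep60$info$epoch_start), units = "secs"), 30)

  t10 <- seq(0, 10, by = 1 / 30)
  ep10 <- make_epochs(resample_30hz(make_rec(t10, rnorm(length(t10)), rnorm(length(t10)), rnorm(length(t10)), 30)))
  expect_equal(length(ep10), 0)
})

still_then_moving <- function(n_still, n_moving, seed = 1) {
  set.seed(seed)
  m <- n_still + n_moving
  sig <- array(0, dim = c(m, 900, 3))
  sig[, , 3] <- 1
  if (n_moving > 0) {
    for (i in (n_still + 1):m) sig[i, , 1] <- 0.3 * sin(seq_len(900) / 5) + rnorm(900, 0, 0.1)
  }
  toy_epochs(sig)
}

test_that("non-wear needs stationarity for strictly more than 60 minutes", {
  # 90 min perfectly still -> all 180 epochs non-wear
  ep <- detect_nonwear(still_then_moving(180, 0))
  expect_true(all(!ep$info$wear))

  # 45 min still bounded by movement -> all wear
  ep45 <- detect_nonwear(still_then_moving(90, 20))
  expect_true(all(ep45$info$wear))

  # exactly 60 min still -> wear (strict inequality)
  ep60 <- detect_nonwear(still_then_moving(120, 10))
  expect_true(all(ep60$info$wear))

  # 61 min -> the still run flips to non-wear, the moving tail stays wear
  ep61 <- detect_nonwear(still_then_moving(122, 10))
  expect_true(all(!ep61$info$wear[1:122]))
  expect_true(all(ep61$info$wear[123:132]))

  # adding a constant offset to a stationary run leaves detection unchanged
  ep_off <- still_then_moving(122, 10)
  ep_off$signals[1:122, , 1] <- ep_off$signals[1:122, , 1] + 0.5
  ep_off <- detect_nonwear(ep_off)
  expect_identical(ep_off$info$wear, ep61$info$wear)

  # wear + non-wear partition the epochs
  expect_equal(sum(ep61$info$wear) + sum(!ep61$info$wear), length(ep61))
})

test_that("qc_screen applies the exclusion rules without raising", {
  # quiet recording at rest: mean ENMO a few mg, calibrated, kept
  dyn <- stage_dynamics()
  h <- hypnogram(
    as.POSIXct("2022-06-08 23:00:00", tz = "UTC") + 30 * (0:59),
    rep("N2", 60), "five_class"
  )
  ep <- detect_nonwear(make_epochs(simulate_accel(h, dyn, seed = 1)))
  qc <- qc_screen(ep)
  expect_false(qc$excluded)
  expect_lt(qc$mean_enmo_mg, 200)

  # constant 1.5 g magnitude -> ENMO 500 mg -> excluded (and uncalibrated)
  ep_hot <- constant_epochs(10, c(0, 0, 1.5))
  qc_hot <- qc_screen(ep_hot)
  expect_equal(qc_hot$mean_enmo_mg, 500, tolerance = 1e-9)
  expect_true(qc_hot$excluded)
  expect_match(qc_hot$reasons, "high_values")

  # stationary magnitude 1.05 g: calibration check fails
  qc_cal <- qc_screen(constant_epochs(10, c(0, 0, 1.05)))
  expect_false(qc_cal$calibrated)
  expect_match(qc_cal$reasons, "calibration")

  # parse failure propagates through the pipeline as an excluded report
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("not,a,recording", f)
  res <- preprocess_recording(f)
  expect_null(res$epochs)
  expect_false(res$qc$parsed)
  expect_true(res$qc$excluded)
  expect_equal(res$qc$reasons, "parse")
})

test_that("epoch stores round-trip through disk", {
  ep <- still_then_moving(4, 2)
  d <- withr::local_tempdir()
  write_epochs(ep, d)
  ep2 <- read_epochs(d)
  expect_equal(ep2$signals, ep$signals)
  expect_equal(ep2$info$wear, ep$info$wear)
})
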