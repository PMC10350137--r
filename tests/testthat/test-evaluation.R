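test_that("confusion matrices count truth rows by prediction columns", {
  cm <- confusion(rep(c("A", "B"), c(60, 40)), rep(c("A", "B"), c(60, 40)), classes = c("A", "B"))
  expect_equal(unclass(cm), matrix(c(60L, 0L, 0L, 40L), 2, 2), ignore_attr = TRUE)
  cm2 <- confusion(rep("A", 100), rep("B", 100), classes = c("A", "B"))
  expect_equal(as.vector(cm2), c(0L, 0L, 100L, 0L))
  set.seed(3)
  truth <- sample(c("A", "B", "C"), 50, replace = TRUE)
  pred <- sample(c("A", "B", "C"), 50, replace = TRUE)
  cm3 <- confusion(truth, pred, classes = c("A", "B", "C"))
  expect_equal(rowSums(cm3), table(factor(truth, c("A", "B", "C"))), ignore_attr = TRUE)
  expect_error(confusion(c("A", "X"), c("A", "A"), classes = c("A", "B")), "outside")
})

test_that("cohen's kappa matches hand computations", {
  expect_equal(cohen_kappa(matrix(c(50, 0, 0, 50), 2, 2)), 1)
  # p_o = 0.8, p_e = 0.5 -> kappa 0.6
  expect_equal(cohen_kappa(matrix(c(45, 15, 5, 35), 2, 2)), 0.6)
  # marginally independent matrix -> 0
  expect_equal(cohen_kappa(matrix(c(30, 20, 30, 20), 2, 2)), 0)
  # degenerate: all mass in one cell
  expect_equal(cohen_kappa(matrix(c(10, 0, 0, 0), 2, 2)), 1)
  expect_error(cohen_kappa(matrix(0, 2, 2)), "empty")
})

test_that("macro F1 and balanced accuracy match hand computations", {
  perfect <- matrix(c(50, 0, 0, 50), 2, 2)
  expect_equal(macro_f1(perfect), 1)
  expect_equal(balanced_accuracy(perfect), 1)

  # recalls 1.0 and 0.5 -> balanced accuracy 0.75
  cm_r <- matrix(c(40, 20, 0, 20), 2, 2)
  expect_equal(balanced_accuracy(cm_r), 0.75)

  # [[45,5],[15,35]]: F1_A = 0.818, F1_B = 0.778 -> macro 0.798
  cm_h <- matrix(c(45, 15, 5, 35), 2, 2)
  f1_a <- 2 * (45 / 60) * (45 / 50) / (45 / 60 + 45 / 50)
  f1_b <- 2 * (35 / 40) * (35 / 50) / (35 / 40 + 35 / 50)
  expect_equal(macro_f1(cm_h), (f1_a + f1_b) / 2)

  # an absent-and-unpredicted class is skipped, not scored zero
  cm_abs <- matrix(c(45, 15, 0, 5, 35, 0, 0, 0, 0), 3, 3)
  expect_equal(macro_f1(cm_abs), macro_f1(cm_h))
})

test_that("bland-altman bias and limits follow the 1.96-sd convention", {
  ba0 <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba <- bland_altman(c(0, 10, 20), c(10, 10, 10)) # diffs -10, 0, 10; sd = 10
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, -19.6)
  expect_equal(ba$loa_high, 19.6)

  ba2 <- bland_altman(c(40, 50, 60), c(10, 10, 10)) # diffs 30, 40, 50
  expect_equal(ba2$bias, 40)
  expect_equal(ba2$loa_low, 40 - 19.6)
  expect_equal(ba2$loa_high, 40 + 19.6)

  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("subject-wise folds partition subjects and oracle scores are perfect", {
  set.seed(2)
  nights <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:10), each = 2),
    data = replicate(20, sample(c("W", "S"), 50, replace = TRUE), simplify = FALSE)
  )
  nights$labels <- nights$data # oracle: the "data" are the labels themselves
  fit <- function(data_list, label_list) NULL
  predict_oracle <- function(model, data) data

  rep1 <- subjectwise_cv(nights, fit, predict_oracle, k = 5, seed = 9, classes = c("S", "W"))
  rep2 <- subjectwise_cv(nights, fit, predict_oracle, k = 5, seed = 9, classes = c("S", "W"))
  expect_identical(rep1$folds, rep2$folds)
  expect_equal(sort(names(rep1$folds)), sort(unique(nights$subject)))
  expect_equal(unname(table(rep1$folds)), rep(2L, 5), ignore_attr = TRUE)

  expect_equal(rep1$per_subject$kappa, rep(1, 10))
  sw <- rep1$subject_wise
  expect_equal(sw$mean[sw$metric == "kappa"], 1)
  expect_equal(sw$sd[sw$metric == "kappa"], 0)
  expect_equal(rep1$pooled$value, rep(1, 3))

  expect_error(subjectwise_cv(nights[1:6, ], fit, predict_oracle, k = 5), "at least k")

  # a single-class subject gets a missing kappa
  one_class <- tibble::tibble(
    subject = c("a", "b"),
    truth = c("W", "S"), pred = c("W", "S")
  )
  df <- tibble::tibble(
    subject = rep(c("a", "b"), each = 4),
    truth = c(rep("W", 4), c("W", "S", "W", "S")),
    pred = c(rep("W", 4), c("W", "S", "W", "S"))
  )
  ps <- per_subject_metrics(df, classes = c("S", "W"))
  expect_true(is.na(ps$kappa[ps$subject == "a"]))
  expect_equal(ps$kappa[ps$subject == "b"], 1)
})

test_that("stratified reports group per-subject metrics", {
  ps <- tibble::tibble(
    subject = c("a", "b", "c"),
    kappa = c(0.5, 0.7, 0.9), macro_f1 = c(0.6, 0.8, 1), balanced_accuracy = c(0.5, 0.6, 0.7),
    n_epochs = c(10, 10, 10)
  )
  one <- stratified_report(ps, tibble::tibble(subject = c("a", "b", "c"), group = "all"))
  expect_equal(one$mean[one$metric == "kappa"], mean(ps$kappa))

  two <- stratified_report(ps, tibble::tibble(subject = c("a", "b", "c"), group = c("g1", "g1", "g2")))
  expect_true(is.na(two$sd[two$group == "g2" & two$metric == "kappa"]))
  expect_equal(two$n[two$group == "g1" & two$metric == "kappa"], 2)

  dropped <- stratified_report(ps, tibble::tibble(subject = c("a", "b"), group = "g"))
  expect_equal(attr(dropped, "omitted_subjects"), "c")
})

test_that("ICC(2,1) behaves as absolute agreement", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc(x, x), 1)
  expect_error(icc(rep(1, 5), rep(2, 5)), "zero variance")
  expect_equal(icc(rep(1, 5), rep(1, 5)), 1)

  set.seed(1)
  base <- rnorm(200, 400, 60)
  noisy <- base + rnorm(200, 0, 300) # noise >> between-subject sd
  expect_lt(icc(base, noisy), 0.3)
  tiny <- base + rnorm(200, 0, 0.6) # noise = between-subject sd / 100
  expect_gt(icc(base, tiny), 0.99)

  # hand-checked against the two-way ANOVA definition on a fixed table
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  dat <- rbind(a, b)
  n <- 6
  k <- 2
  msr <- var(colMeans(dat)) * k
  msc <- var(rowMeans(dat)) * n
  grand <- mean(dat)
  sse <- sum((dat - grand)^2) - (n - 1) * msr - (k - 1) * msc
  mse <- sse / ((n - 1) * (k - 1))
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc(a, b), expected)
})

test_that("wear-time censoring degrades ICC monotonically", {
  subjects <- wear_cohort()
  g <- wear_missingness_sim(subjects,
    hours_grid = c(16, 20, 24), days_grid = c(3, 7),
    reps = 3, seed = 1
  )
  full <- g$icc[g$hours == 24 & g$days == 7]
  expect_equal(full, 1)
  for (d in c(3, 7)) {
    series <- g$icc[g$days == d][order(g$hours[g$days == d])]
    expect_true(all(diff(series) > -0.05)) # non-decreasing in wear hours (stochastic)
  }
  expect_false(is.null(attr(g, "minimal")))
  expect_error(wear_missingness_sim(subjects, hours_grid = 25), "hours_grid")
  expect_error(wear_missingness_sim(subjects, days_grid = 8), "days_grid")
})
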