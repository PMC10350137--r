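test_that("configuration is validated", {
  expect_error(sleepnet_config(kernel = 4), "odd")
  expect_error(sleepnet_config(channels = c(8L, 8L)), "per block")
  expect_error(sleepnet_config(dropout = 1), "dropout")
  paper <- sleepnet_config("paper_scale")
  expect_equal(paper$encoder_blocks, 8L)
})

test_that("collapsing pools stages and conserves probability", {
  five <- factor(c("N3", "N1", "W", "R"), levels = somnokit:::STAGES5)
  expect_equal(as.character(collapse(five, "three_class")), c("NREM", "NREM", "W", "R"))
  expect_equal(as.character(collapse(five, "two_class")), c("S", "S", "W", "S"))

  p <- matrix(c(0.1, 0.2, 0.3, 0.1, 0.3), 1, 5, dimnames = list(NULL, somnokit:::STAGES5))
  expect_equal(unname(collapse(p, "three_class")[1, ]), c(0.1, 0.6, 0.3))
  expect_equal(unname(collapse(p, "two_class")[1, ]), c(0.1, 0.9))

  set.seed(1)
  raw <- matrix(rexp(50 * 5), 50, 5)
  probs <- raw / rowSums(raw)
  colnames(probs) <- somnokit:::STAGES5
  expect_equal(rowSums(collapse(probs, "three_class")), rep(1, 50), tolerance = 1e-6)
  expect_equal(rowSums(collapse(probs, "two_class")), rep(1, 50), tolerance = 1e-6)

  # collapse-then-argmax can differ from argmax-then-collapse: posterior mass
  # spread over the NREM stages should win over a single largest wake prob
  p_split <- matrix(c(0.4, 0.2, 0.2, 0.2, 0), 1, 5, dimnames = list(NULL, somnokit:::STAGES5))
  collapsed <- collapse(p_split, "three_class")
  expect_equal(colnames(collapsed)[which.max(collapsed)], "NREM")
  expect_equal(somnokit:::STAGES5[which.max(p_split)], "W")

  expect_error(collapse(factor("X"), "three_class"), "five-class")
})

test_that("ssl transforms have the declared algebraic properties", {
  set.seed(2)
  win <- matrix(rnorm(900 * 3), 900, 3)

  # find seeds deterministically covering the no-op and all-applied cases
  spec <- ssl_task_spec()
  none_seed <- NULL
  for (s in 1:200) {
    tr <- ssl_transform(win, spec, seed = s)
    if (all(tr$task_labels == 0)) {
      none_seed <- s
      break
    }
  }
  expect_false(is.null(none_seed))
  tr_none <- ssl_transform(win, spec, seed = none_seed)
  expect_identical(tr_none$window, win)

  # reversal makes an increasing ramp decreasing; applying it twice restores
  ramp <- matrix(seq_len(900), 900, 3)
  spec_rev <- ssl_task_spec(tasks = "reversal", apply_prob = 0.999)
  tr_rev <- ssl_transform(ramp, spec_rev, seed = 1)
  expect_equal(tr_rev$task_labels[["reversal"]], 1)
  expect_true(all(diff(tr_rev$window[, 1]) < 0))
  expect_identical(tr_rev$window[rev(seq_len(900)), ], ramp)

  # permutation preserves the multiset of segment contents (property, many draws)
  spec_perm <- ssl_task_spec(tasks = "permutation", apply_prob = 0.999, permutation_segments = 4)
  for (s in 1:50) {
    w <- matrix(rnorm(900 * 3), 900, 3)
    tr <- ssl_transform(w, spec_perm, seed = s)
    if (tr$task_labels[["permutation"]] == 0) next
    segs <- function(m) lapply(0:3, function(j) m[j * 225 + 1:225, , drop = FALSE])
    key <- function(seg) paste(signif(seg, 10), collapse = ",")
    expect_setequal(vapply(segs(tr$window), key, character(1)), vapply(segs(w), key, character(1)))
    expect_false(identical(tr$window, w))
  }

  # time warp always returns 900 samples
  spec_w <- ssl_task_spec(tasks = "time_warp", apply_prob = 0.999)
  tr_w <- ssl_transform(win, spec_w, seed = 3)
  expect_equal(dim(tr_w$window), c(900, 3))

  expect_error(ssl_task_spec(tasks = character()), "at least one")
})

test_that("backpropagation matches finite differences on a tiny network", {
  cfg <- sleepnet_config(
    encoder_blocks = 2, channels = c(3L, 4L), kernel = 3,
    lstm_hidden = 3, fc_hidden = 5, seed = 1
  )
  set.seed(5)
  x <- array(rnorm(4 * 900 * 3, 0, 0.5), dim = c(4, 900, 3))
  y <- c(1L, 3L, 5L, 2L)
  w <- rep(1, 5)
  params <- withr::with_seed(2, c(somnokit:::encoder_init(cfg), somnokit:::seq_head_init(cfg)))
  # nudge all parameters off zero so no ReLU sits exactly at its kink
  for (nm in names(params)) params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), 0, 0.05)

  loss_fn <- function(p) {
    enc <- somnokit:::encoder_fwd(p, x, cfg)
    head <- somnokit:::seq_head_fwd(p, enc$out, cfg, train = FALSE)
    somnokit:::wce_fwd_bwd(head$out, y, w)$loss
  }
  enc <- somnokit:::encoder_fwd(params, x, cfg)
  head <- somnokit:::seq_head_fwd(params, enc$out, cfg, train = FALSE)
  l <- somnokit:::wce_fwd_bwd(head$out, y, w)
  hb <- somnokit:::seq_head_bwd(head$cache, l$dlogits)
  grads <- c(hb$grads, somnokit:::encoder_bwd(enc$cache, hb$dfeats, cfg))

  eps <- 1e-5
  set.seed(9)
  for (nm in sample(names(params), 12)) {
    i <- sample(length(params[[nm]]), 1)
    p2 <- params
    p2[[nm]][i] <- p2[[nm]][i] + eps
    p3 <- params
    p3[[nm]][i] <- p3[[nm]][i] - eps
    num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
    rel <- abs(num - grads[[nm]][i]) / max(1e-6, abs(num) + abs(grads[[nm]][i]))
    expect_lt(rel, 1e-4)
  }
})

test_that("predictions are simplex-valued, deterministic, and respect wear", {
  model <- hi_sleepnet()
  night <- hi_nights()[[16]]
  ep <- night$epochs
  ep$info$wear[5:8] <- FALSE
  p1 <- predict_stages(model, ep)
  p2 <- predict_stages(model, ep)
  expect_identical(p1, p2)
  probs <- as.matrix(p1[, somnokit:::STAGES5])
  expect_true(all(is.na(probs[5:8, ])))
  ok <- p1$wear
  expect_equal(rowSums(probs[ok, ]), rep(1, sum(ok)), tolerance = 1e-6)
  lab <- predicted_stages(p1, "three_class")
  expect_true(all(is.na(lab[5:8])))
  expect_true(all(!is.na(lab[ok])))
})

test_that("the model can overfit a single night", {
  night <- simulate_labeled_night(dyn_high(), 60, seed = 77)
  m <- train_sleepnet(list(night), sleepnet_config(epochs = 40, lr = 5e-3, seed = 1))
  pred <- predicted_stages(predict_stages(m, night$epochs), "five_class")
  acc <- mean(as.character(pred) == as.character(night$hypnogram$stage))
  expect_gte(acc, 0.95)
})

test_that("pretraining loss descends and reversal becomes detectable", {
  enc <- ssl_encoder()
  expect_lt(enc$loss_trace[5], enc$loss_trace[1])
  acc <- ssl_task_accuracy(enc, ssl_corpus()[1201:1600, , ], seed = 2)
  expect_gte(acc[["reversal"]], 0.9)
})

test_that("training rejects malformed nights", {
  night <- hi_nights()[[1]]
  bad <- night
  bad$hypnogram <- hypnogram(night$hypnogram$epoch_start, rep("W", 120), "five_class")
  expect_error(train_sleepnet(list(bad), sleepnet_config(epochs = 1)), "2 classes")
  short <- night
  short$hypnogram <- night$hypnogram[1:10, ]
  expect_error(train_sleepnet(list(short), sleepnet_config(epochs = 1)), "align")
})
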