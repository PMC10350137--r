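# Shared fixtures. Heavy objects (trained models, simulated cohorts) are
# built lazily and cached for the whole test run, so module tests and the
# acceptance suite reuse the same artifacts.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

dyn_default <- function() stage_dynamics()
dyn_high <- function() stage_dynamics(profile = movement_profile("high_contrast"))

# Zero-contrast dynamics started from the chain's stationary distribution:
# with identical movement statistics in every stage, and no time-of-night
# trend in the stage marginals, no predictor can beat chance.
dyn_zero <- function() {
  tm <- stage_dynamics()$transition
  stage_dynamics(
    initial = stationary_distribution(tm),
    profile = movement_profile(contrast = 0)
  )
}

# Wake-rich dynamics for the self-supervision corpus (free-living data are
# dominated by daytime movement).
dyn_wake <- function() {
  stage_dynamics(
    transition = matrix(
      c(
        0.97, 0.02, 0.01, 0, 0,
        0.30, 0.50, 0.15, 0, 0.05,
        0.05, 0.05, 0.80, 0.05, 0.05,
        0.02, 0, 0.08, 0.90, 0,
        0.05, 0.05, 0.05, 0, 0.85
      ), 5, 5,
      byrow = TRUE, dimnames = list(somnokit:::STAGES5, somnokit:::STAGES5)
    ),
    initial = c(W = 1, N1 = 0, N2 = 0, N3 = 0, R = 0)
  )
}

# Build a single-segment epoch_array from an m x 900 x 3 signal array.
toy_epochs <- function(signals, wear = NULL, t0 = as.POSIXct("2022-06-08 23:00:00", tz = "UTC")) {
  m <- dim(signals)[1]
  info <- tibble::tibble(
    epoch_start = t0 + 30 * (seq_len(m) - 1L),
    segment = 1L,
    wear = wear %||% rep(TRUE, m)
  )
  somnokit:::new_epoch_array(signals, info)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

constant_epochs <- function(m, xyz = c(0, 0, 1)) {
  sig <- array(0, dim = c(m, 900, 3))
  for (a in 1:3) sig[, , a] <- xyz[a]
  toy_epochs(sig)
}

## --- heavy cached fixtures -------------------------------------------------

hi_nights <- function() {
  cached("hi_nights", function() {
    lapply(1:20, function(i) simulate_labeled_night(dyn_high(), 120, seed = 1000 + i))
  })
}

hi_feats <- function() {
  cached("hi_feats", function() lapply(hi_nights(), function(n) extract_features(n$epochs)))
}

hi_labels5 <- function() lapply(hi_nights(), function(n) as.character(n$hypnogram$stage))

hi_rf <- function() {
  cached("hi_rf", function() {
    train_rf_hmm(hi_feats()[1:15], hi_labels5()[1:15], n_trees = 300, seed = 1)
  })
}

hi_sleepnet <- function() {
  cached("hi_sleepnet", function() train_sleepnet(hi_nights()[1:15], sleepnet_config(seed = 1)))
}

zero_nights <- function() {
  cached("zero_nights", function() {
    lapply(1:12, function(i) simulate_labeled_night(dyn_zero(), 120, seed = 7000 + i))
  })
}

zero_sleepnet <- function() {
  cached("zero_sleepnet", function() {
    train_sleepnet(zero_nights()[1:9], sleepnet_config(epochs = 6, seed = 1))
  })
}

ssl_corpus <- function() {
  cached("ssl_corpus", function() {
    corpus <- lapply(1:4, function(i) simulate_labeled_night(dyn_wake(), 400, seed = 900 + i))
    xs <- array(0, dim = c(1600, 900, 3))
    at <- 0
    for (n in corpus) {
      a <- n$epochs$signals
      xs[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    xs
  })
}

# Pretrained on the first 1,200 corpus windows; the last 400 stay held out.
ssl_encoder <- function() {
  cached("ssl_encoder", function() {
    pretrain_ssl(ssl_corpus()[1:1200, , ],
      config = sleepnet_config(epochs = 10, lr = 5e-3, seed = 1),
      batch_size = 32
    )
  })
}

wear_cohort <- function() {
  cached("wear_cohort", function() {
    subs <- simulate_cohort(
      25,
      freeliving_scenario(n_days = 7, wear_gap_rate = 0, nap_probability = 0),
      dyn_default(),
      seed = 11
    )
    lapply(subs, function(s) s$truth)
  })
}

## --- small independent oracles --------------------------------------------

# Exhaustive maximum a-posteriori path search (oracle for Viterbi).
brute_force_path <- function(scores, params, floor = 1e-6) {
  k <- length(params$classes)
  n <- nrow(scores)
  emis <- pmax(scores %*% t(exp(params$log_emission)), floor)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    lp <- params$log_initial[pth[1]] + log(emis[1, pth[1]])
    if (n > 1) {
      for (t in 2:n) lp <- lp + params$log_transition[pth[t - 1], pth[t]] + log(emis[t, pth[t]])
    }
    if (lp > best) {
      best <- lp
      best_path <- pth
    }
  }
  params$classes[best_path]
}

# Evaluate a trained sleep stager on held-out nights in the 3-class space.
eval_three_class <- function(model, nights, idx) {
  pred <- lapply(idx, function(i) predicted_stages(predict_stages(model, nights[[i]]$epochs), "three_class"))
  truth <- lapply(idx, function(i) collapse(nights[[i]]$hypnogram, "three_class")$stage)
  confusion(
    unlist(lapply(truth, as.character)),
    unlist(lapply(pred, as.character)),
    classes = c("W", "NREM", "R")
  )
}

rf_predict_three <- function(model, feats) {
  probs <- predict(model$rf, feats)
  collapsed <- somnokit:::collapse_probs(probs[, somnokit:::STAGES5], "three_class")
  colnames(collapsed)[max.col(collapsed, ties.method = "first")]
}
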