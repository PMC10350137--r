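#' Specification of the self-supervised pretraining tasks
#'
#' The encoder is pretrained by discriminating spatiotemporal
#' transformations of unlabelled 30-s windows: time reversal, segment
#' permutation, and time warping. Each enabled task is applied independently
#' with probability `apply_prob`, and a per-task binary head must detect
#' whether it was applied.
#'
#' @param tasks Subset of `c("reversal", "permutation", "time_warp")`; at
#'   least one.
#' @param permutation_segments Number of equal segments to shuffle
#'   (non-identity shuffles only).
#' @param warp_factor_range Time-warp resampling factor range.
#' @param apply_prob Per-task application probability in (0, 1).
#' @return A list of class `ssl_task_spec`.
#' @export
ssl_task_spec <- function(tasks = c("reversal", "permutation", "time_warp"),
                          permutation_segments = 4, warp_factor_range = c(0.5, 2),
                          apply_prob = 0.5) {
  if (length(tasks) < 1) abort("at least one task must be enabled")
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (apply_prob <= 0 || apply_prob >= 1) abort("apply_prob must be in (0, 1)")
  if (EPOCH_N %% permutation_segments != 0) abort("segments must divide the window length")
  structure(
    list(
      tasks = tasks, permutation_segments = as.integer(permutation_segments),
      warp_factor_range = warp_factor_range, apply_prob = apply_prob
    ),
    class = "ssl_task_spec"
  )
}

#' Apply random self-supervision transformations to a window
#'
#' * reversal: time-reverse all axes;
#' * permutation: split into equal segments and shuffle their order (a
#'   non-identity shuffle is guaranteed when applied), preserving the
#'   multiset of segment contents;
#' * time_warp: resample the window to a random factor in
#'   `warp_factor_range`, then crop (or edge-pad) back to 900 samples.
#'
#' @param window A 900 x 3 matrix (one 30-s, 30-Hz epoch).
#' @param spec An [ssl_task_spec()].
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as during training).
#' @return List with `window` (900 x 3) and `task_labels`, a named 0/1
#'   vector over (reversal, permutation, time_warp) recording which tasks
#'   were applied (disabled tasks are 0).
#' @export
ssl_transform <- function(window, spec = ssl_task_spec(), seed = NULL) {
  run <- function() {
    w <- window
    labels <- c(reversal = 0, permutation = 0, time_warp = 0)
    n <- nrow(w)
    if ("reversal" %in% spec$tasks && runif(1) < spec$apply_prob) {
      w <- w[rev(seq_len(n)), , drop = FALSE]
      labels["reversal"] <- 1
    }
    if ("permutation" %in% spec$tasks && runif(1) < spec$apply_prob) {
      s <- spec$permutation_segments
      len <- n %/% s
      perm <- sample(s)
      while (all(perm == seq_len(s))) perm <- sample(s)
      idx <- unlist(lapply(perm, function(j) (j - 1L) * len + seq_len(len)))
      w <- w[idx, , drop = FALSE]
      labels["permutation"] <- 1
    }
    if ("time_warp" %in% spec$tasks && runif(1) < spec$apply_prob) {
      f <- runif(1, spec$warp_factor_range[1], spec$warp_factor_range[2])
      n2 <- max(2L, round(n * f))
      grid <- seq(1, n, length.out = n2)
      ww <- apply(w, 2, function(col) approx(seq_len(n), col, xout = grid)$y)
      if (n2 >= n) {
        w <- ww[seq_len(n), , drop = FALSE]
      } else {
        w <- rbind(ww, ww[rep(n2, n - n2), , drop = FALSE])
      }
      labels["time_warp"] <- 1
    }
    list(window = w, task_labels = labels)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Pretrain the encoder with multi-task self-supervision
#'
#' Optimises the sum of per-task binary cross-entropy losses through linear
#' heads on the encoder's pooled output, over minibatches of randomly
#' transformed unlabelled windows. Returns the encoder (plus heads), ready
#' to pass as `init_encoder` to [train_sleepnet()].
#'
#' @param epochs An `epoch_array` (or plain `[n, 900, 3]` array) of
#'   unlabelled windows; at least ~1,000 windows recommended.
#' @param spec An [ssl_task_spec()].
#' @param config A [sleepnet_config()] (encoder geometry, `lr`, `epochs`,
#'   `seed`; minibatch size is `64` windows).
#' @param batch_size Windows per gradient step.
#' @param verbose Print per-epoch loss.
#' @return A `sleepnet_encoder` object (`params`, `config`, `spec`,
#'   `loss_trace`).
#' @export
pretrain_ssl <- function(epochs, spec = ssl_task_spec(), config = sleepnet_config(),
                         batch_size = 64, verbose = FALSE) {
  x_all <- if (inherits(epochs, "epoch_array")) epochs$signals else epochs
  n <- dim(x_all)[1]
  if (n < 2) abort("need unlabelled windows to pretrain on")
  cfg <- config
  task_names <- c("reversal", "permutation", "time_warp")
  e_dim <- encoder_dim(cfg)

  params <- withr::with_seed(cfg$seed, {
    p <- encoder_init(cfg)
    for (tn in task_names) {
      p[[sprintf("ssl.%s.W", tn)]] <- dense_init(e_dim, 1)
      p[[sprintf("ssl.%s.b", tn)]] <- 0
    }
    p
  })
  state <- adam_new(params)
  trace <- numeric(cfg$epochs)

  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = batch_size)) {
        take <- ord[start:min(start + batch_size - 1, n)]
        B <- length(take)
        xb <- array(0, dim = c(B, EPOCH_N, 3))
        yb <- matrix(0, B, 3, dimnames = list(NULL, task_names))
        for (j in seq_len(B)) {
          win <- x_all[take[j], , ]
          dim(win) <- c(EPOCH_N, 3)
          tr <- ssl_transform(win, spec)
          xb[j, , ] <- tr$window
          yb[j, ] <- tr$task_labels[task_names]
        }
        enc <- encoder_fwd(params, xb, cfg)
        loss <- 0
        denc <- matrix(0, B, e_dim)
        grads <- list()
        for (tn in intersect(spec$tasks, task_names)) {
          d <- dense_fwd(enc$out, params[[sprintf("ssl.%s.W", tn)]], params[[sprintf("ssl.%s.b", tn)]])
          u <- drop(d$out)
          y <- yb[, tn]
          loss <- loss + mean(log1p(exp(-abs(u))) + pmax(u, 0) - y * u)
          du <- matrix((sigm(u) - y) / B, ncol = 1)
          g <- dense_bwd(d$cache, du)
          grads[[sprintf("ssl.%s.W", tn)]] <- g$dW
          grads[[sprintf("ssl.%s.b", tn)]] <- g$db
          denc <- denc + g$dx
        }
        grads <- c(grads, encoder_bwd(enc$cache, denc, cfg))
        upd <- adam_step(params, grads, state, lr = cfg$lr)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, loss)
      }
      trace[ep] <- mean(losses)
      if (verbose) message(sprintf("ssl epoch %d loss %.4f", ep, trace[ep]))
    }
  })
  structure(
    list(params = params, config = cfg, spec = spec, loss_trace = trace),
    class = "sleepnet_encoder"
  )
}

#' Evaluate a pretrained encoder's task-detection accuracy
#'
#' Applies fresh random transformations to held-out windows and scores each
#' task head's binary accuracy.
#'
#' @param encoder A `sleepnet_encoder` from [pretrain_ssl()].
#' @param epochs Held-out windows (`epoch_array` or array).
#' @param seed Seed for the evaluation transformations.
#' @return Named accuracy vector over the enabled tasks.
#' @export
ssl_task_accuracy <- function(encoder, epochs, seed = 1) {
  x_all <- if (inherits(epochs, "epoch_array")) epochs$signals else epochs
  n <- dim(x_all)[1]
  cfg <- encoder$config
  task_names <- intersect(encoder$spec$tasks, c("reversal", "permutation", "time_warp"))
  withr::with_seed(seed, {
    xb <- array(0, dim = c(n, EPOCH_N, 3))
    yb <- matrix(0, n, length(task_names), dimnames = list(NULL, task_names))
    for (j in seq_len(n)) {
      win <- x_all[j, , ]
      dim(win) <- c(EPOCH_N, 3)
      tr <- ssl_transform(win, encoder$spec)
      xb[j, , ] <- tr$window
      yb[j, ] <- tr$task_labels[task_names]
    }
    enc <- encoder_fwd(encoder$params, xb, cfg)
    vapply(task_names, function(tn) {
      u <- drop(dense_fwd(
        enc$out, encoder$params[[sprintf("ssl.%s.W", tn)]],
        encoder$params[[sprintf("ssl.%s.b", tn)]]
      )$out)
      mean((u > 0) == (yb[, tn] > 0.5))
    }, numeric(1))
  })
}
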