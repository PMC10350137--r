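#' Configuration for the deep sleep stager
#'
#' The model classifies each 30-s accelerometer epoch into the five AASM
#' stages using three components: a 1D-convolutional residual encoder
#' (pre-activation blocks, stride-2 downsampling, global average pooling to a
#' fixed-length per-epoch feature vector), a bi-directional LSTM consuming
#' the whole night of epoch features, and two fully-connected layers
#' producing 5-class logits. The default is a desk-scale configuration; the
#' `"paper_scale"` preset uses 8 residual blocks (17 convolutional layers,
#' the ResNet-17-class architecture) with wide channels.
#'
#' @param preset `"small"` (default) or `"paper_scale"`.
#' @param encoder_blocks Number of residual blocks.
#' @param channels Per-block output widths (length `encoder_blocks`); the
#'   stem convolution outputs `channels[1]`.
#' @param kernel Odd convolution kernel width.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param fc_hidden Width of the first fully-connected layer (the second
#'   maps to the 5 classes).
#' @param dropout Dropout probability on the first FC layer during training.
#' @param lr Adam learning rate.
#' @param epochs Training passes over the nights.
#' @param batch_nights Nights per gradient step (gradients accumulate).
#' @param seed Integer seed for initialisation and shuffling.
#' @return A list of class `sleepnet_config`.
#' @export
sleepnet_config <- function(preset = c("small", "paper_scale"),
                            encoder_blocks = NULL, channels = NULL, kernel = 7,
                            lstm_hidden = NULL, fc_hidden = NULL, dropout = 0,
                            lr = 3e-3, epochs = 12, batch_nights = 1, seed = 1) {
  preset <- match.arg(preset)
  if (preset == "small") {
    encoder_blocks <- encoder_blocks %||% 4L
    channels <- channels %||% c(8L, 12L, 16L, 20L)
    lstm_hidden <- lstm_hidden %||% 16L
    fc_hidden <- fc_hidden %||% 32L
  } else {
    encoder_blocks <- encoder_blocks %||% 8L
    channels <- channels %||% c(16L, 16L, 32L, 32L, 64L, 64L, 128L, 128L)
    lstm_hidden <- lstm_hidden %||% 128L
    fc_hidden <- fc_hidden %||% 512L
  }
  if (kernel %% 2 != 1) abort("kernel must be odd")
  if (length(channels) != encoder_blocks) abort("channels must have one width per block")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(
    list(
      encoder_blocks = as.integer(encoder_blocks), channels = as.integer(channels),
      kernel = as.integer(kernel), lstm_hidden = as.integer(lstm_hidden),
      fc_hidden = as.integer(fc_hidden), n_classes = 5L, dropout = dropout,
      lr = lr, epochs = as.integer(epochs), batch_nights = as.integer(batch_nights),
      seed = as.integer(seed)
    ),
    class = "sleepnet_config"
  )
}

encoder_channels_in <- function(cfg, block) if (block == 1) cfg$channels[1] else cfg$channels[block - 1]

encoder_init <- function(cfg) {
  k <- cfg$kernel
  p <- list()
  p[["enc.conv0.W"]] <- he_init(k, 3, cfg$channels[1])
  p[["enc.conv0.b"]] <- rep(0, cfg$channels[1])
  for (b in seq_len(cfg$encoder_blocks)) {
    cin <- encoder_channels_in(cfg, b)
    cout <- cfg$channels[b]
    p[[sprintf("enc.b%d.g1", b)]] <- rep(1, cin)
    p[[sprintf("enc.b%d.be1", b)]] <- rep(0, cin)
    p[[sprintf("enc.b%d.Wa", b)]] <- he_init(k, cin, cout)
    p[[sprintf("enc.b%d.ba", b)]] <- rep(0, cout)
    p[[sprintf("enc.b%d.g2", b)]] <- rep(1, cout)
    p[[sprintf("enc.b%d.be2", b)]] <- rep(0, cout)
    p[[sprintf("enc.b%d.Wb", b)]] <- he_init(k, cout, cout)
    p[[sprintf("enc.b%d.bb", b)]] <- rep(0, cout)
    p[[sprintf("enc.b%d.Ws", b)]] <- he_init(1, cin, cout)
    p[[sprintf("enc.b%d.bs", b)]] <- rep(0, cout)
  }
  p[["enc.bnf.g"]] <- rep(1, encoder_dim(cfg))
  p[["enc.bnf.be"]] <- rep(0, encoder_dim(cfg))
  p
}

encoder_dim <- function(cfg) cfg$channels[cfg$encoder_blocks]

# Pre-activation residual encoder: per-window gravity (DC) removal, stem
# conv, then per block BN -> ReLU -> conv(stride 2) -> BN -> ReLU -> conv,
# with a 1x1 stride-2 projection shortcut from the block's post-activation
# input; final BN-ReLU and global average pooling give the per-epoch
# feature vector.
encoder_fwd <- function(params, x, cfg) {
  k <- cfg$kernel
  pad <- (k - 1L) %/% 2L
  ctr <- center_fwd(x)
  c0 <- conv1d_fwd(ctr$out, params[["enc.conv0.W"]], params[["enc.conv0.b"]], stride = 2, pad = pad)
  h <- c0$out
  blocks <- vector("list", cfg$encoder_blocks)
  for (b in seq_len(cfg$encoder_blocks)) {
    n1 <- bn_fwd(h, params[[sprintf("enc.b%d.g1", b)]], params[[sprintf("enc.b%d.be1", b)]])
    a <- relu_fwd(n1$out)
    m1 <- conv1d_fwd(a$out, params[[sprintf("enc.b%d.Wa", b)]], params[[sprintf("enc.b%d.ba", b)]],
      stride = 2, pad = pad
    )
    n2 <- bn_fwd(m1$out, params[[sprintf("enc.b%d.g2", b)]], params[[sprintf("enc.b%d.be2", b)]])
    r1 <- relu_fwd(n2$out)
    m2 <- conv1d_fwd(r1$out, params[[sprintf("enc.b%d.Wb", b)]], params[[sprintf("enc.b%d.bb", b)]],
      stride = 1, pad = pad
    )
    sc <- conv1d_fwd(a$out, params[[sprintf("enc.b%d.Ws", b)]], params[[sprintf("enc.b%d.bs", b)]],
      stride = 2, pad = 0
    )
    h <- m2$out + sc$out
    blocks[[b]] <- list(
      n1 = n1$cache, a = a$cache, m1 = m1$cache, n2 = n2$cache,
      r1 = r1$cache, m2 = m2$cache, sc = sc$cache
    )
  }
  nf <- bn_fwd(h, params[["enc.bnf.g"]], params[["enc.bnf.be"]])
  fr <- relu_fwd(nf$out)
  gp <- gap_fwd(fr$out)
  list(
    out = gp$out,
    cache = list(c0 = c0$cache, blocks = blocks, nf = nf$cache, fr = fr$cache, gp = gp$cache)
  )
}

encoder_bwd <- function(cache, dout, cfg) {
  grads <- list()
  dnf <- relu_bwd(cache$fr, gap_bwd(cache$gp, dout))
  gnf <- bn_bwd(cache$nf, dnf)
  grads[["enc.bnf.g"]] <- gnf$dgamma
  grads[["enc.bnf.be"]] <- gnf$dbeta
  dh <- gnf$dx
  for (b in rev(seq_len(cfg$encoder_blocks))) {
    bc <- cache$blocks[[b]]
    g2 <- conv1d_bwd(bc$m2, dh)
    grads[[sprintf("enc.b%d.Wb", b)]] <- g2$dW
    grads[[sprintf("enc.b%d.bb", b)]] <- g2$db
    gn2 <- bn_bwd(bc$n2, relu_bwd(bc$r1, g2$dx))
    grads[[sprintf("enc.b%d.g2", b)]] <- gn2$dgamma
    grads[[sprintf("enc.b%d.be2", b)]] <- gn2$dbeta
    g1 <- conv1d_bwd(bc$m1, gn2$dx)
    grads[[sprintf("enc.b%d.Wa", b)]] <- g1$dW
    grads[[sprintf("enc.b%d.ba", b)]] <- g1$db
    gs <- conv1d_bwd(bc$sc, dh)
    grads[[sprintf("enc.b%d.Ws", b)]] <- gs$dW
    grads[[sprintf("enc.b%d.bs", b)]] <- gs$db
    da <- relu_bwd(bc$a, g1$dx + gs$dx)
    gn1 <- bn_bwd(bc$n1, da)
    grads[[sprintf("enc.b%d.g1", b)]] <- gn1$dgamma
    grads[[sprintf("enc.b%d.be1", b)]] <- gn1$dbeta
    dh <- gn1$dx
  }
  g0 <- conv1d_bwd(cache$c0, dh)
  grads[["enc.conv0.W"]] <- g0$dW
  grads[["enc.conv0.b"]] <- g0$db
  grads
}

seq_head_init <- function(cfg) {
  e <- encoder_dim(cfg)
  h <- cfg$lstm_hidden
  p <- list()
  fw <- lstm_init(e, h)
  bw <- lstm_init(e, h)
  p[["head.lstm_f.Wx"]] <- fw$Wx
  p[["head.lstm_f.Wh"]] <- fw$Wh
  p[["head.lstm_f.b"]] <- fw$b
  p[["head.lstm_b.Wx"]] <- bw$Wx
  p[["head.lstm_b.Wh"]] <- bw$Wh
  p[["head.lstm_b.b"]] <- bw$b
  p[["head.fc1.W"]] <- dense_init(2 * h, cfg$fc_hidden)
  p[["head.fc1.b"]] <- rep(0, cfg$fc_hidden)
  p[["head.fc2.W"]] <- dense_init(cfg$fc_hidden, cfg$n_classes)
  p[["head.fc2.b"]] <- rep(0, cfg$n_classes)
  p
}

lstm_params <- function(params, dir) {
  list(
    Wx = params[[sprintf("head.lstm_%s.Wx", dir)]],
    Wh = params[[sprintf("head.lstm_%s.Wh", dir)]],
    b = params[[sprintf("head.lstm_%s.b", dir)]]
  )
}

seq_head_fwd <- function(params, feats, cfg, train = FALSE) {
  Tn <- nrow(feats)
  f <- lstm_fwd(feats, lstm_params(params, "f"))
  b <- lstm_fwd(feats[rev(seq_len(Tn)), , drop = FALSE], lstm_params(params, "b"))
  Hcat <- cbind(f$out, b$out[rev(seq_len(Tn)), , drop = FALSE])
  d1 <- dense_fwd(Hcat, params[["head.fc1.W"]], params[["head.fc1.b"]])
  r1 <- relu_fwd(d1$out)
  h1 <- r1$out
  drop_mask <- NULL
  if (train && cfg$dropout > 0) {
    drop_mask <- matrix(runif(length(h1)) >= cfg$dropout, nrow(h1), ncol(h1)) / (1 - cfg$dropout)
    h1 <- h1 * drop_mask
  }
  d2 <- dense_fwd(h1, params[["head.fc2.W"]], params[["head.fc2.b"]])
  list(
    out = d2$out,
    cache = list(f = f$cache, b = b$cache, d1 = d1$cache, r1 = r1$cache, d2 = d2$cache, drop = drop_mask, Tn = Tn)
  )
}

seq_head_bwd <- function(cache, dlogits) {
  grads <- list()
  g2 <- dense_bwd(cache$d2, dlogits)
  grads[["head.fc2.W"]] <- g2$dW
  grads[["head.fc2.b"]] <- g2$db
  dh1 <- g2$dx
  if (!is.null(cache$drop)) dh1 <- dh1 * cache$drop
  g1 <- dense_bwd(cache$d1, relu_bwd(cache$r1, dh1))
  grads[["head.fc1.W"]] <- g1$dW
  grads[["head.fc1.b"]] <- g1$db
  Tn <- cache$Tn
  h <- ncol(g1$dx) / 2
  gf <- lstm_bwd(cache$f, g1$dx[, seq_len(h), drop = FALSE])
  gb <- lstm_bwd(cache$b, g1$dx[rev(seq_len(Tn)), h + seq_len(h), drop = FALSE])
  grads[["head.lstm_f.Wx"]] <- gf$dWx
  grads[["head.lstm_f.Wh"]] <- gf$dWh
  grads[["head.lstm_f.b"]] <- gf$db
  grads[["head.lstm_b.Wx"]] <- gb$dWx
  grads[["head.lstm_b.Wh"]] <- gb$dWh
  grads[["head.lstm_b.b"]] <- gb$db
  list(grads = grads, dfeats = gf$dx + gb$dx[rev(seq_len(Tn)), , drop = FALSE])
}

normalize_nights <- function(nights) {
  if (is.data.frame(nights)) {
    nights <- purrr::map(seq_len(nrow(nights)), function(i) {
      list(epochs = nights$epochs[[i]], hypnogram = nights$hypnogram[[i]])
    })
  }
  lapply(nights, function(n) {
    if (!inherits(n$epochs, "epoch_array")) abort("each night needs an epoch_array")
    stages <- as.character(n$hypnogram$stage)
    bad <- setdiff(unique(stages), STAGES5)
    if (length(bad) > 0) abort(paste("labels outside {W,N1,N2,N3,R}:", paste(bad, collapse = ",")))
    if (length(stages) != n_epochs(n$epochs)) abort("labels and epochs must align")
    list(x = n$epochs$signals, y = match(stages, STAGES5), wear = n$epochs$info$wear)
  })
}

#' Train the deep sleep stager on labelled nights
#'
#' End-to-end training of encoder + bi-LSTM + FC layers with class-weighted
#' (inverse-frequency) 5-class cross-entropy; each night is consumed as one
#' whole sequence so the recurrent layer sees the full temporal context.
#' Non-wear epochs are masked out of the loss. Deterministic for a fixed
#' seed at a fixed thread count.
#'
#' @param nights A tibble with list-columns `epochs` (each an
#'   `epoch_array`) and `hypnogram` (each a five-class [hypnogram()]), or a
#'   list of `list(epochs, hypnogram)` pairs.
#' @param config A [sleepnet_config()].
#' @param init_encoder Optional pretrained encoder (from [pretrain_ssl()])
#'   used to initialise the convolutional weights.
#' @param verbose Print per-epoch mean loss.
#' @return A `sleepnet` model object (parameters + config + training loss
#'   trace).
#' @export
train_sleepnet <- function(nights, config = sleepnet_config(), init_encoder = NULL, verbose = FALSE) {
  data <- normalize_nights(nights)
  if (length(data) == 0) abort("no training nights")
  all_y <- unlist(lapply(data, function(d) d$y[d$wear]))
  if (length(unique(all_y)) < 2) abort("training nights must contain at least 2 classes")
  counts <- tabulate(all_y, nbins = 5)
  class_w <- ifelse(counts > 0, sum(counts) / (sum(counts > 0) * pmax(counts, 1)), 0)

  cfg <- config
  trace <- numeric(cfg$epochs)
  params <- withr::with_seed(cfg$seed, {
    p <- c(encoder_init(cfg), seq_head_init(cfg))
    if (!is.null(init_encoder)) {
      enc_names <- grep("^enc\\.", names(init_encoder$params), value = TRUE)
      p[enc_names] <- init_encoder$params[enc_names]
    }
    p
  })
  state <- adam_new(params)

  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(data))
      acc <- NULL
      in_batch <- 0L
      losses <- numeric(0)
      for (ni in ord) {
        d <- data[[ni]]
        enc <- encoder_fwd(params, d$x, cfg)
        head <- seq_head_fwd(params, enc$out, cfg, train = TRUE)
        loss <- wce_fwd_bwd(head$out, d$y, class_w, mask = d$wear)
        losses <- c(losses, loss$loss)
        hb <- seq_head_bwd(head$cache, loss$dlogits)
        eb <- encoder_bwd(enc$cache, hb$dfeats, cfg)
        acc <- grad_accum(acc, c(hb$grads, eb))
        in_batch <- in_batch + 1L
        if (in_batch >= cfg$batch_nights || ni == ord[length(ord)]) {
          upd <- adam_step(params, acc, state, lr = cfg$lr)
          params <- upd$params
          state <- upd$state
          acc <- NULL
          in_batch <- 0L
        }
      }
      trace[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d loss %.4f", ep, trace[ep]))
    }
  })
  structure(
    list(params = params, config = cfg, classes = STAGES5, loss_trace = trace),
    class = "sleepnet"
  )
}

#' @export
print.sleepnet <- function(x, ...) {
  cat(sprintf(
    "<sleepnet> %d residual blocks, lstm %d, %d parameters; final loss %.4f\n",
    x$config$encoder_blocks, x$config$lstm_hidden,
    sum(vapply(x$params, length, integer(1))),
    tail(x$loss_trace, 1)
  ))
  invisible(x)
}

#' @rdname train_sleepnet
#' @param x A `sleepnet` model.
#' @param ... Unused.
#' @export
glance.sleepnet <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, integer(1))),
    encoder_blocks = x$config$encoder_blocks,
    epochs = x$config$epochs,
    final_loss = tail(x$loss_trace, 1)
  )
}

#' Predict per-epoch stage probabilities for a night
#'
#' Wear epochs are scored as a single sequence through the recurrent layer;
#' non-wear epochs are emitted as missing (all-`NA` probability rows), never
#' as a stage. Inference is deterministic.
#'
#' @param model A trained `sleepnet`.
#' @param epochs An `epoch_array`.
#' @return A `stage_prediction` tibble: `epoch_start`, `wear` and
#'   probability columns `W`, `N1`, `N2`, `N3`, `R` (each row on the
#'   probability simplex for wear epochs).
#' @export
predict_stages <- function(model, epochs) {
  m <- n_epochs(epochs)
  probs <- matrix(NA_real_, m, 5, dimnames = list(NULL, STAGES5))
  wear <- epochs$info$wear
  if (m > 0 && any(wear)) {
    x <- epochs$signals[wear, , , drop = FALSE]
    enc <- encoder_fwd(model$params, x, model$config)
    head <- seq_head_fwd(model$params, enc$out, model$config, train = FALSE)
    probs[wear, ] <- softmax_rows(head$out)
  }
  out <- dplyr::bind_cols(
    tibble::tibble(epoch_start = epochs$info$epoch_start, wear = wear),
    tibble::as_tibble(probs)
  )
  structure(out, class = c("stage_prediction", class(out)))
}

#' Hard stage labels from a prediction
#'
#' Collapses the five-class probabilities first (summing posterior mass) and
#' then takes the argmax, so e.g. a posterior spread over N1/N2/N3 wins as
#' NREM even when wake has the single largest stage probability.
#'
#' @param pred A `stage_prediction`.
#' @param scheme `"five_class"`, `"three_class"` or `"two_class"`.
#' @return Factor of labels with `NA` for non-wear epochs.
#' @export
predicted_stages <- function(pred, scheme = c("five_class", "three_class", "two_class")) {
  scheme <- match.arg(scheme)
  p <- as.matrix(pred[, STAGES5])
  if (scheme != "five_class") p <- collapse_probs(p, scheme)
  classes <- stage_levels(scheme)
  lab <- rep(NA_character_, nrow(p))
  ok <- stats::complete.cases(p)
  if (any(ok)) lab[ok] <- classes[max.col(p[ok, , drop = FALSE], ties.method = "first")]
  factor(lab, levels = classes)
}
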