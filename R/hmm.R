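#' Fit hidden-Markov smoothing parameters from labelled sequences
#'
#' The smoother treats the true stage sequence as the hidden chain and the
#' classifier output as noisy emissions. Transition probabilities are
#' row-normalised bigram counts of the true labels (optionally with add-one
#' smoothing); the emission calibration matrix is the row-normalised
#' confusion of argmax predictions against truth (probability that the
#' classifier outputs j given true state i); the initial distribution is the
#' empirical stage frequency.
#'
#' @param truth_seqs List of factor/character sequences of true labels (one
#'   per night), or a single sequence.
#' @param pred_probs Matrix of classifier probabilities (rows aligned to the
#'   concatenated truth sequences, columns named by class), or a vector of
#'   predicted labels.
#' @param classes Class levels (defaults to levels found in the truth).
#' @param smoothing Additive smoothing count (default 1; use 0 to disable).
#' @return An `hmm_params` object with `classes`, `log_transition`,
#'   `log_emission`, `log_initial` (all log-probabilities; rows normalise to
#'   1 in probability space).
#' @export
fit_hmm <- function(truth_seqs, pred_probs, classes = NULL, smoothing = 1) {
  if (!is.list(truth_seqs)) truth_seqs <- list(truth_seqs)
  truth_seqs <- lapply(truth_seqs, as.character)
  if (sum(lengths(truth_seqs)) == 0) abort("empty truth sequences")
  all_truth <- unlist(truth_seqs)
  if (is.null(classes)) classes <- sort(unique(all_truth))
  k <- length(classes)

  if (is.matrix(pred_probs)) {
    if (nrow(pred_probs) != length(all_truth)) abort("predictions and truth must align")
    pred_lab <- colnames(pred_probs)[max.col(pred_probs, ties.method = "first")]
  } else {
    pred_lab <- as.character(pred_probs)
    if (length(pred_lab) != length(all_truth)) abort("predictions and truth must align")
  }

  trans <- matrix(smoothing, k, k, dimnames = list(classes, classes))
  for (s in truth_seqs) {
    if (length(s) > 1) {
      from <- factor(s[-length(s)], levels = classes)
      to <- factor(s[-1], levels = classes)
      trans <- trans + table(from, to)
    }
  }
  trans <- trans / pmax(rowSums(trans), .Machine$double.eps)

  emis <- matrix(smoothing, k, k, dimnames = list(classes, classes))
  emis <- emis + table(factor(all_truth, levels = classes), factor(pred_lab, levels = classes))
  emis <- emis / pmax(rowSums(emis), .Machine$double.eps)

  init <- table(factor(all_truth, levels = classes))
  init <- as.numeric(init) / sum(init)

  structure(
    list(
      classes = classes,
      log_transition = log(pmax(as.matrix(trans), 1e-300)),
      log_emission = log(pmax(as.matrix(emis), 1e-300)),
      log_initial = log(pmax(init, 1e-300)),
      transition = as.matrix(trans), emission = as.matrix(emis), initial = init
    ),
    class = "hmm_params"
  )
}

#' Viterbi smoothing of per-epoch classifier scores
#'
#' Returns the maximum a-posteriori state path under the fitted HMM. The
#' emission likelihood of hidden state i at epoch t is the calibration-mixed
#' classifier output `sum_j P(output = j | true = i) * score[t, j]`, floored
#' at 1e-6 before taking logs; all work is done in the log domain.
#'
#' @param scores Matrix (epochs x classes) of classifier probabilities or
#'   non-negative scores, columns in `params$classes` order (or named).
#' @param params An `hmm_params` object.
#' @param floor Lower bound applied to emission likelihoods before logs.
#' @return Factor of smoothed labels (length `nrow(scores)`; empty input
#'   gives an empty factor).
#' @export
viterbi_smooth <- function(scores, params, floor = 1e-6) {
  classes <- params$classes
  k <- length(classes)
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = k)
  if (!is.null(colnames(scores))) scores <- scores[, classes, drop = FALSE]
  n <- nrow(scores)
  if (n == 0) {
    return(factor(character(), levels = classes))
  }
  if (ncol(scores) != k) abort("scores must have one column per class")

  # emission log-likelihoods: calibration matrix applied to classifier output
  emis_lik <- pmax(scores %*% t(exp(params$log_emission)), floor)
  log_b <- log(emis_lik) # n x k, column i = hidden state i

  delta <- matrix(-Inf, n, k)
  back <- matrix(1L, n, k)
  delta[1, ] <- params$log_initial + log_b[1, ]
  if (n > 1) {
    for (t in 2:n) {
      cand <- delta[t - 1, ] + params$log_transition # k x k: from x to
      back[t, ] <- max.col(t(cand), ties.method = "first")
      delta[t, ] <- cand[cbind(back[t, ], seq_len(k))] + log_b[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  factor(classes[path], levels = classes)
}

#' Train the full RF + HMM baseline on labelled nights
#'
#' Fits the random forest on pooled per-epoch features, then fits the HMM
#' smoothing parameters from the true label sequences and the forest's
#' out-of-bag probabilities (so calibration is not contaminated by training
#' fit).
#'
#' @param feature_list List of per-night feature tibbles.
#' @param label_list List of per-night label sequences (same class space).
#' @param n_trees,seed Forest parameters.
#' @param smoothing HMM additive smoothing.
#' @return A `somnokit_rf_hmm` object.
#' @export
train_rf_hmm <- function(feature_list, label_list, n_trees = 500, seed = 1, smoothing = 1) {
  features <- dplyr::bind_rows(feature_list)
  labels <- factor(unlist(lapply(label_list, as.character)))
  rf <- train_rf(features, labels, n_trees = n_trees, seed = seed)
  oob <- rf$oob_probs
  oob[!is.finite(oob)] <- 1 / length(rf$classes)
  hmm <- fit_hmm(lapply(label_list, as.character), oob[, rf$classes, drop = FALSE],
    classes = rf$classes, smoothing = smoothing
  )
  structure(list(rf = rf, hmm = hmm, classes = rf$classes), class = "somnokit_rf_hmm")
}

#' Predict smoothed labels for one night with the RF + HMM baseline
#'
#' @param object A `somnokit_rf_hmm`.
#' @param features Per-epoch features for one night (in epoch order).
#' @param smooth Apply Viterbi smoothing (default) or return raw argmax.
#' @param ... Unused.
#' @return Factor of per-epoch labels.
#' @export
predict.somnokit_rf_hmm <- function(object, features, smooth = TRUE, ...) {
  probs <- predict(object$rf, features)
  if (!smooth) {
    return(factor(object$classes[max.col(probs, ties.method = "first")], levels = object$classes))
  }
  viterbi_smooth(probs, object$hmm)
}
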