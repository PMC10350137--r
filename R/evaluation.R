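#' Confusion matrix of per-epoch predictions
#'
#' Counts with truth in rows and predictions in columns, both ordered by the
#' declared class list. `NA` pairs (e.g. non-wear epochs) are dropped.
#'
#' @param truth,pred Factor/character vectors of equal length.
#' @param classes Declared class order; defaults to the union of levels.
#' @return Integer k x k matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) abort("truth and pred must have equal length")
  keep <- !is.na(truth) & !is.na(pred)
  truth <- truth[keep]
  pred <- pred[keep]
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad) > 0) abort(paste("labels outside declared classes:", paste(bad, collapse = ", ")))
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  structure(matrix(as.integer(cm), nrow = length(classes), dimnames = list(truth = classes, pred = classes)),
    class = c("confusion_matrix", "matrix", "array")
  )
}

#' Cohen's kappa from a confusion matrix
#'
#' Unweighted kappa, `(p_o - p_e) / (1 - p_e)`, with chance agreement from
#' the marginal products. Degenerate case `p_e = 1` (all mass in one cell
#' row/column pair) is defined as 1 when observed agreement is also 1, else 0.
#'
#' @param cm A square count matrix (truth rows x prediction columns).
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) abort("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    return(if (abs(po - 1) < 1e-12) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Macro-averaged F1 and balanced accuracy
#'
#' Macro-F1 is the unweighted mean of per-class F1 over classes that are
#' present in the truth or predicted at least once (a class that never
#' occurs and is never predicted is skipped rather than contributing 0, so a
#' night without REM is not penalised for it). Balanced accuracy is the mean
#' per-class recall over classes present in the truth.
#'
#' @param cm A square count matrix (truth rows x prediction columns).
#' @return A scalar.
#' @export
macro_f1 <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) <= 0) abort("empty confusion matrix")
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  active <- support > 0 | predicted > 0
  f1 <- vapply(which(active), function(i) {
    prec <- if (predicted[i] > 0) tp[i] / predicted[i] else 0
    rec <- if (support[i] > 0) tp[i] / support[i] else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

#' @rdname macro_f1
#' @export
balanced_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) <= 0) abort("empty confusion matrix")
  support <- rowSums(cm)
  mean(diag(cm)[support > 0] / support[support > 0])
}

#' Bland-Altman agreement between a device and a reference
#'
#' Differences are taken device minus reference; the bias is their mean and
#' the 95% limits of agreement are `bias +/- 1.96 * sd` (sample sd, n - 1
#' denominator).
#'
#' @param device,reference Paired numeric vectors (one value per night).
#' @return A one-row tibble: `bias`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(device, reference) {
  if (length(device) != length(reference)) abort("device and reference must be paired")
  keep <- !is.na(device) & !is.na(reference)
  d <- device[keep] - reference[keep]
  if (length(d) < 2) abort("Bland-Altman needs at least 2 complete pairs")
  bias <- mean(d)
  s <- sd(d)
  tibble::tibble(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s, n = length(d))
}

#' Bland-Altman plot
#'
#' @param device,reference Paired numeric vectors.
#' @param ylab Axis label for the differences.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(device, reference, ylab = "device - reference") {
  ba <- bland_altman(device, reference)
  df <- tibble::tibble(mean = (device + reference) / 2, diff = device - reference)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high), linetype = 2) +
    ggplot2::labs(x = "mean of methods", y = ylab) +
    ggplot2::theme_minimal()
}

#' Per-subject agreement metrics
#'
#' @param df Tibble with columns `subject`, `truth`, `pred` (one row per
#'   scored epoch).
#' @param classes Declared class order.
#' @return Tibble with one row per subject: `kappa` (NA when the subject has
#'   a single truth class), `macro_f1`, `balanced_accuracy`, `n_epochs`.
#' @export
per_subject_metrics <- function(df, classes = NULL) {
  df |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(g, key) {
      cm <- confusion(g$truth, g$pred, classes = classes)
      tibble::tibble(
        kappa = if (sum(rowSums(cm) > 0) < 2) NA_real_ else cohen_kappa(cm),
        macro_f1 = macro_f1(cm),
        balanced_accuracy = balanced_accuracy(cm),
        n_epochs = sum(cm)
      )
    }) |>
    dplyr::ungroup()
}

#' Subject-wise k-fold cross-validation
#'
#' Folds partition subjects (never splitting one subject's nights across
#' train and test). For each fold, `fit_fun` is trained on the training
#' subjects' nights and `predict_fun` scores each test night. Metrics are
#' reported both subject-wise (mean +/- sd over per-subject pooled epochs,
#' subjects weighted equally) and pooled epoch-to-epoch over all epochs.
#'
#' @param nights Tibble with columns `subject`, and list-columns `data` (per
#'   night model input) and `labels` (per night truth sequence).
#' @param fit_fun `function(data_list, label_list) -> model`.
#' @param predict_fun `function(model, data) -> label vector` for one night.
#' @param k Number of folds (requires >= k subjects).
#' @param seed Fold-assignment seed; identical seeds give identical folds.
#' @param classes Declared class order.
#' @return An `agreement_report`: list with `per_subject` tibble,
#'   `subject_wise` summary tibble, `pooled` tibble, `confusion` matrix and
#'   `predictions` tibble.
#' @export
subjectwise_cv <- function(nights, fit_fun, predict_fun, k = 5, seed = 1, classes = NULL) {
  subjects <- unique(nights$subject)
  if (length(subjects) < k) abort("need at least k subjects for k folds")
  fold_of <- withr::with_seed(seed, {
    setNames(rep_len(seq_len(k), length(subjects))[sample(length(subjects))], subjects)
  })
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    test_subj <- subjects[fold_of[subjects] == f]
    tr <- nights[!nights$subject %in% test_subj, ]
    te <- nights[nights$subject %in% test_subj, ]
    model <- fit_fun(tr$data, tr$labels)
    preds[[f]] <- purrr::map_dfr(seq_len(nrow(te)), function(i) {
      tibble::tibble(
        subject = te$subject[i],
        truth = as.character(te$labels[[i]]),
        pred = as.character(predict_fun(model, te$data[[i]]))
      )
    })
  }
  preds <- dplyr::bind_rows(preds)
  agreement_report(preds, classes = classes, folds = fold_of)
}

#' Assemble an agreement report from pooled per-epoch predictions
#'
#' @param preds Tibble with `subject`, `truth`, `pred`.
#' @param classes Declared class order.
#' @param folds Optional named fold assignment (kept for provenance).
#' @return An `agreement_report`.
#' @export
agreement_report <- function(preds, classes = NULL, folds = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(preds$truth, preds$pred)))
  per_subject <- per_subject_metrics(preds, classes = classes)
  subject_wise <- per_subject |>
    tidyr::pivot_longer(c("kappa", "macro_f1", "balanced_accuracy"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n_subjects = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  cm <- confusion(preds$truth, preds$pred, classes = classes)
  pooled <- tibble::tibble(
    metric = c("kappa", "macro_f1", "balanced_accuracy"),
    value = c(cohen_kappa(cm), macro_f1(cm), balanced_accuracy(cm))
  )
  structure(
    list(
      per_subject = per_subject, subject_wise = subject_wise,
      pooled = pooled, confusion = cm, predictions = preds, folds = folds
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat("subject-wise (mean +/- sd over subjects):\n")
  print(as.data.frame(x$subject_wise), row.names = FALSE)
  cat("pooled epoch-to-epoch:\n")
  print(as.data.frame(x$pooled), row.names = FALSE)
  invisible(x)
}

#' @rdname agreement_report
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @export
tidy.agreement_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$subject_wise, value = "mean"), scope = "subject_wise"),
    dplyr::mutate(x$pooled, scope = "pooled")
  ) |>
    dplyr::select("scope", "metric", "value", dplyr::any_of(c("sd", "n_subjects")))
}

#' @rdname agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  pooled <- setNames(x$pooled$value, x$pooled$metric)
  tibble::tibble(
    kappa = pooled[["kappa"]], macro_f1 = pooled[["macro_f1"]],
    balanced_accuracy = pooled[["balanced_accuracy"]],
    n_epochs = sum(x$confusion), n_subjects = nrow(x$per_subject)
  )
}

#' Stratified performance summary
#'
#' @param per_subject Tibble of per-subject metrics (see
#'   [per_subject_metrics()]).
#' @param groups Tibble with `subject` and a `group` column (e.g. age band,
#'   sex), or a named vector.
#' @return Tibble: per group, mean +/- sd of each metric and n; groups of
#'   size 1 report `sd` as `NA`; subjects with no group are omitted with a
#'   note attribute.
#' @export
stratified_report <- function(per_subject, groups) {
  if (!is.data.frame(groups)) {
    groups <- tibble::tibble(subject = names(groups), group = unname(groups))
  }
  df <- dplyr::inner_join(per_subject, groups, by = "subject")
  dropped <- setdiff(per_subject$subject, df$subject)
  out <- df |>
    tidyr::pivot_longer(c("kappa", "macro_f1", "balanced_accuracy"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) > 1) sd(.data$value, na.rm = TRUE) else NA_real_,
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  attr(out, "omitted_subjects") <- dropped
  out
}

#' Intraclass correlation, ICC(2,1)
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC between two
#' paired measurements per subject (e.g. weekly means from degraded vs
#' complete wear). Zero-variance input is defined as 1 when the pairs are
#' identical and raises otherwise.
#'
#' @param x,y Paired numeric vectors across subjects (n >= 2).
#' @return ICC in \[-1, 1\].
#' @export
icc <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 2) abort("ICC needs at least 2 subjects")
  if (var(x) + var(y) == 0) {
    if (all(x == y)) {
      return(1)
    }
    abort("zero variance with unequal pairs: ICC undefined")
  }
  dat <- rbind(x, y) # k = 2 raters (rows) x n subjects (cols)
  k <- 2
  grand <- mean(dat)
  row_means <- colMeans(dat) # per-subject means
  col_means <- rowMeans(dat) # per-rater means
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Wear-time missingness simulation
#'
#' Quantifies how much device wear is needed for stable weekly sleep
#' estimates. Starting from subjects with complete 7-day wear, each grid cell
#' `(h hours/day, d days)` randomly keeps `d` of the 7 days and censors each
#' kept day's wear down to `h` hours by removing one contiguous block of
#' `24 - h` hours at a uniformly random start (wear gaps are contiguous in
#' practice; uniform per-epoch censoring is available via
#' `censor = "uniform"`). Weekly mean overnight sleep duration is recomputed
#' from the censored labels (censored epochs contribute no sleep) and
#' compared with the complete-data weekly means via [icc()], averaged over
#' `reps` replicates.
#'
#' @param subjects List of per-subject free-living truths, each a list with
#'   `hypnogram` (five-class, full 7 noon-to-noon days) and `windows` (truth
#'   time-in-bed tibble), as produced by [simulate_freeliving()].
#' @param hours_grid Wear hours per day to evaluate (<= 24).
#' @param days_grid Number of days to evaluate (<= 7).
#' @param reps Replicates per cell.
#' @param seed Integer seed.
#' @param censor `"block"` (default) or `"uniform"`.
#' @return An `icc_grid`: tibble `hours`, `days`, `icc`, plus the minimal
#'   criterion (fewest days, then fewest hours) with ICC > 0.75 as attribute
#'   `minimal`.
#' @export
wear_missingness_sim <- function(subjects, hours_grid = c(16, 20, 22, 24),
                                 days_grid = c(3, 5, 7), reps = 5, seed = 1,
                                 censor = c("block", "uniform")) {
  censor <- match.arg(censor)
  if (any(hours_grid > 24) || any(hours_grid <= 0)) abort("hours_grid must be in (0, 24]")
  if (any(days_grid > 7) || any(days_grid < 1)) abort("days_grid must be in [1, 7]")

  per_day <- lapply(subjects, subject_day_sleep_epochs)
  complete_means <- vapply(per_day, function(s) mean(vapply(s, sum, numeric(1))) * EPOCH_S / 60, numeric(1))

  grid <- tidyr::expand_grid(hours = hours_grid, days = days_grid)
  grid$icc <- withr::with_seed(seed, {
    purrr::map2_dbl(grid$hours, grid$days, function(h, d) {
      vals <- vapply(seq_len(reps), function(r) {
        degraded <- vapply(per_day, function(s) {
          keep_days <- sample(7, d)
          day_tot <- vapply(keep_days, function(dd) {
            sleep <- s[[dd]]
            n_ep <- length(sleep)
            kept <- rep(TRUE, n_ep)
            n_drop <- round((24 - h) * 3600 / EPOCH_S)
            if (n_drop > 0) {
              if (censor == "block") {
                start <- sample.int(n_ep, 1)
                idx <- ((start + seq_len(n_drop) - 2L) %% n_ep) + 1L
                kept[idx] <- FALSE
              } else {
                kept[sample(n_ep, min(n_drop, n_ep))] <- FALSE
              }
            }
            sum(sleep & kept) * EPOCH_S / 60
          }, numeric(1))
          mean(day_tot)
        }, numeric(1))
        if (var(degraded) + var(complete_means) == 0 && all(degraded == complete_means)) {
          return(1)
        }
        icc(degraded, complete_means)
      }, numeric(1))
      mean(vals)
    })
  })
  passing <- grid[grid$icc > 0.75, ]
  minimal <- if (nrow(passing) > 0) {
    passing[order(passing$days, passing$hours), ][1, ]
  } else {
    NULL
  }
  structure(grid, class = c("icc_grid", class(grid)), minimal = minimal)
}

# Per noon-to-noon day: logical vector over the day's epochs, TRUE where the
# truth stage is sleep inside a truth time-in-bed window.
subject_day_sleep_epochs <- function(subject) {
  if (!is.null(subject$truth)) subject <- subject$truth
  hyp <- subject$hypnogram
  windows <- subject$windows
  in_window <- rep(FALSE, nrow(hyp))
  for (w in seq_len(nrow(windows))) {
    in_window <- in_window |
      (hyp$epoch_start >= windows$start[w] & hyp$epoch_start < windows$end[w])
  }
  sleep <- in_window & as.character(hyp$stage) != "W"
  day_idx <- floor(as.numeric(hyp$epoch_start - hyp$epoch_start[1], units = "days"))
  lapply(0:6, function(d) sleep[day_idx == d])
}
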