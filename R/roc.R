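# Placement values: for each positive score, the fraction of negatives it
# outranks (ties credited 0.5), and symmetrically for negatives. These are
# the structural components of the DeLong AUC variance estimator.
.placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(s) {
    (sum(neg < s) + 0.5 * sum(neg == s)) / length(neg)
  }, numeric(1))
  v01 <- vapply(neg, function(s) {
    (sum(pos > s) + 0.5 * sum(pos == s)) / length(pos)
  }, numeric(1))
  list(v10 = v10, v01 = v01)
}

.check_two_classes <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  labels
}

#' Tie-aware AUC with ROC curve and DeLong variance
#'
#' The AUC is computed as the Mann-Whitney U-statistic (the probability that
#' a positive case outranks a negative one, ties credited 0.5). Its variance
#' is the structural-components (placement-value) estimator,
#' `S10/n_pos + S01/n_neg`.
#'
#' @param scores numeric classifier scores (e.g. predicted probabilities).
#' @param labels binary outcome (1 = depressed).
#' @return object of class `"roc_result"`: `auc`, `var_auc`, `n_pos`,
#'   `n_neg`, a `curve` tibble of (FPR, TPR) points over all thresholds, and
#'   the placement values.
#' @export
auc_mw <- function(scores, labels) {
  labels <- .check_two_classes(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
  pl <- .placements(scores, labels)
  var_auc <- (if (m > 1) var(pl$v10) / m else 0) +
    (if (n > 1) var(pl$v01) / n else 0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels == 1L] >= t),
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(scores[labels == 0L] >= t),
                     numeric(1)))
  structure(list(auc = auc, var_auc = var_auc, n_pos = m, n_neg = n,
                 curve = tibble::tibble(threshold = c(Inf, thr),
                                        fpr = fpr, tpr = tpr),
                 placements = pl),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (SE %.4f; %d positives, %d negatives)\n",
              x$auc, sqrt(x$var_auc), x$n_pos, x$n_neg))
  invisible(x)
}

.auc_comparison <- function(auc_1, auc_2, var_diff, paired) {
  d <- auc_1 - auc_2
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) < 1e-12) {
      stat <- 0
    } else {
      stop("zero variance of the AUC difference with unequal AUCs",
           call. = FALSE)
    }
  } else {
    stat <- d^2 / var_diff
  }
  structure(list(auc_1 = auc_1, auc_2 = auc_2, statistic = stat,
                 p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
                 paired = paired),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("%s AUC comparison: %.4f vs %.4f, chi-square(1) = %.3f, P = %.4g\n",
              if (x$paired) "Paired" else "Unpaired",
              x$auc_1, x$auc_2, x$statistic, x$p_value))
  invisible(x)
}

#' Compare two correlated AUCs (DeLong-type chi-square test)
#'
#' For two classifiers scored on the *same* observations, the AUC difference
#' is tested with `chi2 = (AUC_a - AUC_b)^2 / Var(AUC_a - AUC_b)`, the
#' variance of the difference coming from the covariance of shared placement
#' values; p-value from chi-square with 1 df (equivalently a two-sided z
#' test).
#'
#' @param scores_a,scores_b score vectors of the two classifiers on the same
#'   observations.
#' @param labels shared binary outcome.
#' @return an `"auc_comparison"` object.
#' @export
compare_paired <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired comparison requires score vectors of equal length",
         call. = FALSE)
  }
  labels <- .check_two_classes(labels)
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  .auc_comparison(auc_a, auc_b, max(var_diff, 0), paired = TRUE)
}

#' Compare two AUCs from independent samples
#'
#' `chi2 = (auc_1 - auc_2)^2 / (var_1 + var_2)` with the structural-
#' components variances; p-value from chi-square with 1 df. Used to compare
#' screening accuracy between patient groups (e.g. adherence levels).
#'
#' @param roc_1,roc_2 [auc_mw()] results from independent samples.
#' @return an `"auc_comparison"` object.
#' @export
compare_unpaired <- function(roc_1, roc_2) {
  stopifnot(inherits(roc_1, "roc_result"), inherits(roc_2, "roc_result"))
  .auc_comparison(roc_1$auc, roc_2$auc, roc_1$var_auc + roc_2$var_auc,
                  paired = FALSE)
}

#' Partition observations into near-equal folds
#'
#' Fold sizes differ by at most one. If `labels` are supplied, the partition
#' is re-drawn (up to `max_redraws` times) until every fold contains both
#' classes.
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param labels optional binary labels used to reject degenerate folds.
#' @param seed integer seed.
#' @param max_redraws attempts before giving up.
#' @return integer fold assignment of length `n`.
#' @export
partition_folds <- function(n, k = 5L, labels = NULL, seed = 1L,
                            max_redraws = 20L) {
  if (n < k) stop("fewer observations than folds", call. = FALSE)
  withr::local_seed(seed)
  for (attempt in seq_len(max_redraws)) {
    fold <- sample(rep(seq_len(k), length.out = n))
    if (is.null(labels)) return(fold)
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[fold == f])) == 2L
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not draw a partition with both classes in every fold after ",
       max_redraws, " attempts", call. = FALSE)
}

#' Five-fold cross-validated screening AUC
#'
#' Observations (patient-window rows) are randomly partitioned into
#' `n_folds` near-equal folds. For each fold, the dichotomization cut-offs
#' are recomputed on the four training folds (ratio/frequency approaches
#' only), the random-intercept logistic model is fitted on the training
#' rows, and probabilities are predicted for the held-out rows. Cut-offs and
#' model never see held-out rows.
#'
#' @param tables a [cohort_tables()] or `generated_cohort`.
#' @param approach indicator-building approach.
#' @param seed integer seed for the partition.
#' @param cutoffs optional fixed [cutoff_set()]; when supplied, the per-fold
#'   cut-off search is skipped (the average approach never needs cut-offs).
#' @param window_len,exclude_same_day see [build_indicator_table()].
#' @param n_folds number of folds (default 5).
#' @param quad_points quadrature nodes for the fold fits.
#' @return list with `fold_auc`, `pooled_auc` (AUC of pooled out-of-fold
#'   predictions), `fold` assignment, per-fold cut-offs, out-of-fold
#'   `predictions`, and `training_keys` (per fold, the rows the cut-offs and
#'   fit were computed on).
#' @export
five_fold_cv <- function(tables, approach = c("ratio", "average", "frequency"),
                         seed = 1L, cutoffs = NULL, window_len = 14L,
                         exclude_same_day = FALSE, n_folds = 5L,
                         quad_points = 15L) {
  approach <- match.arg(approach)
  if (inherits(tables, "generated_cohort")) tables <- tables$tables
  base_cut <- if (is.null(cutoffs)) cutoff_set(7, 4, 6) else cutoffs
  # the fixed cut-offs are only used to enumerate the modelled windows; the
  # per-fold indicators are rebuilt below
  ind0 <- suppressMessages(build_indicator_table(
    tables, approach = if (approach == "average") "average" else approach,
    cutoffs = base_cut, window_len = window_len,
    exclude_same_day = exclude_same_day))
  if (nrow(ind0) < n_folds) stop("too few complete windows", call. = FALSE)
  fold <- partition_folds(nrow(ind0), k = n_folds, labels = ind0$depressed,
                          seed = seed)

  keys <- ind0[, c("patient_id", "window_end", "depressed")]
  preds <- rep(NA_real_, nrow(ind0))
  fold_auc <- numeric(n_folds)
  fold_cutoffs <- vector("list", n_folds)
  training_keys <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train_keys <- keys[fold != f, c("patient_id", "window_end")]
    training_keys[[f]] <- train_keys
    cs <- if (approach == "average") NULL
          else if (!is.null(cutoffs)) cutoffs
          else optimize_all(tables, approach = approach,
                            window_len = window_len,
                            exclude_same_day = exclude_same_day,
                            windows = train_keys,
                            quad_points = quad_points)$cutoffs
    ind <- suppressMessages(build_indicator_table(
      tables, approach = approach, cutoffs = cs, window_len = window_len,
      exclude_same_day = exclude_same_day))
    ind <- dplyr::semi_join(ind, keys[, c("patient_id", "window_end")],
                            by = c("patient_id", "window_end"))
    ind <- ind[order(match(paste(ind$patient_id, ind$window_end),
                           paste(keys$patient_id, keys$window_end))), ]
    train <- ind[fold != f, ]
    test <- ind[fold == f, ]
    fit <- fit_relogit(design_from_indicators(train),
                       quad_points = quad_points)
    ptest <- predict_prob(fit, as.matrix(test[, c("sleep", "mood", "anxiety")]))
    preds[fold == f] <- ptest
    fold_auc[f] <- auc_mw(ptest, test$depressed)$auc
    fold_cutoffs[[f]] <- cs
  }
  pooled <- auc_mw(preds, ind0$depressed)
  list(fold_auc = fold_auc, pooled_auc = pooled$auc, pooled_roc = pooled,
       fold = fold, fold_cutoffs = fold_cutoffs,
       predictions = tibble::tibble(keys, fold = fold, prob = preds),
       training_keys = training_keys, approach = approach, seed = seed)
}
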