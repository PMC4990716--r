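#' Candidate dichotomization cut-offs for an item
#'
#' Candidates are the integer scale values from 1 to the scale maximum: for
#' the 0-10 anxiety and sleep scales that is 10 candidates, for the 0-7 mood
#' scale 7. (Under the strict `score > cutoff` rule a cut-off equal to the
#' scale maximum flags no day; a cut-off of 0 on a 0-10 scale would flag
#' nearly every day and is excluded.)
#'
#' @param item one of `"sleep"`, `"mood"`, `"anxiety"`.
#' @return integer vector of candidate cut-offs.
#' @export
candidate_cutoffs <- function(item) {
  rng <- item_scale(item)
  seq.int(1L, rng[2])
}

# Single-item AUC at one cut-off: rebuild the item's indicator over the
# pre-assigned windows, fit Depressed ~ item alone, score by population-level
# predicted probability. A constant indicator carries no ranking information
# and scores AUC 0.5 without a fit.
.single_item_auc <- function(assigned_item, outcomes, item, approach, cutoff,
                             quad_points) {
  assigned_item$value <- as.numeric(
    dichotomize_day(assigned_item$score, cutoff))
  agg <- dplyr::summarise(
    dplyr::group_by(assigned_item, .data$patient_id, .data$window_end),
    indicator = if (approach == "ratio") build_ratio(.data$value)
                else as.numeric(build_frequency(.data$value)),
    .groups = "drop")
  agg <- dplyr::inner_join(
    agg, outcomes[, c("patient_id", "test_date", "depressed")],
    by = c(patient_id = "patient_id", window_end = "test_date"))
  if (sd(agg$indicator) == 0) return(0.5)
  fit <- suppressWarnings(suppressMessages(
    fit_relogit(panel_design(agg$depressed,
                             matrix(agg$indicator, ncol = 1,
                                    dimnames = list(NULL, item)),
                             agg$patient_id),
                quad_points = quad_points)))
  auc_mw(predict_prob(fit, matrix(agg$indicator, ncol = 1)), agg$depressed)$auc
}

#' AUC-maximizing cut-off search for one rating item
#'
#' For each candidate cut-off, the item's biweekly indicator is rebuilt, a
#' single-predictor random-intercept logistic model
#' (`Depressed ~ item`) is fitted, and the AUC of its predicted
#' probabilities is computed; the candidate with the highest AUC wins, ties
#' broken toward the smaller cut-off (the more sensitive screen).
#'
#' @param tables a [cohort_tables()] or `generated_cohort`.
#' @param item rating item to optimize.
#' @param approach `"ratio"` or `"frequency"` (the average approach needs no
#'   cut-off).
#' @param window_len,exclude_same_day see [assign_windows()].
#' @param windows optional data frame of (`patient_id`, `window_end`) keys
#'   restricting the search to those windows (used by cross-validation to
#'   keep held-out folds unseen).
#' @param quad_points quadrature nodes for the single-predictor fits.
#' @return object of class `"cutoff_search"`: `item`, `approach`, `table`
#'   (tibble of candidate cut-off and AUC), `best_cutoff`, `best_auc`.
#' @export
optimize_cutoff <- function(tables, item, approach = c("ratio", "frequency"),
                            window_len = 14L, exclude_same_day = FALSE,
                            windows = NULL, quad_points = 15L) {
  approach <- match.arg(approach)
  if (inherits(tables, "generated_cohort")) tables <- tables$tables
  if (nrow(tables$outcomes) == 0L) stop("cohort has no outcomes", call. = FALSE)
  scale_ok <- item_scale(item)  # validates the item name

  assigned <- assign_windows(tables$ratings, tables$outcomes,
                             window_len = window_len,
                             exclude_same_day = exclude_same_day)
  assigned <- assigned[assigned$item == item, ]
  outcomes <- tables$outcomes
  if (!is.null(windows)) {
    assigned <- dplyr::semi_join(assigned, windows,
                                 by = c("patient_id", "window_end"))
    outcomes <- dplyr::semi_join(
      outcomes, dplyr::rename(windows, test_date = "window_end"),
      by = c("patient_id", "test_date"))
  }
  if (nrow(assigned) == 0L) {
    stop("no ", item, " ratings fall inside the modelled windows",
         call. = FALSE)
  }

  cands <- candidate_cutoffs(item)
  aucs <- vapply(cands, function(cc) {
    .single_item_auc(assigned, outcomes, item, approach, cc, quad_points)
  }, numeric(1))
  if (all(abs(aucs - 0.5) < .Machine$double.eps^0.5) &&
      sd(assigned$score) == 0) {
    # every candidate degenerate: the item never varies
    message("all candidate cut-offs for ", item,
            " are uninformative (constant ratings); returning the smallest")
  }
  best <- which.max(aucs)  # which.max takes the first (smallest) maximizer
  structure(list(item = item, approach = approach,
                 table = tibble::tibble(cutoff = cands, auc = aucs),
                 best_cutoff = cands[best], best_auc = aucs[best]),
            class = "cutoff_search")
}

#' @export
print.cutoff_search <- function(x, ...) {
  cat(sprintf("Cut-off search (%s approach) for %s: best cutoff %d (AUC %.4f)\n",
              x$approach, x$item, x$best_cutoff, x$best_auc))
  invisible(x)
}

#' Optimize the cut-offs of all three items
#'
#' Runs [optimize_cutoff()] independently per item (the search is item-wise:
#' each simplified model uses one predictor at a time).
#'
#' @inheritParams optimize_cutoff
#' @return list with `cutoffs` (a [cutoff_set()]) and `searches` (the three
#'   `"cutoff_search"` results).
#' @export
optimize_all <- function(tables, approach = c("ratio", "frequency"),
                         window_len = 14L, exclude_same_day = FALSE,
                         windows = NULL, quad_points = 15L) {
  approach <- match.arg(approach)
  searches <- lapply(.items, function(it) {
    optimize_cutoff(tables, it, approach = approach, window_len = window_len,
                    exclude_same_day = exclude_same_day, windows = windows,
                    quad_points = quad_points)
  })
  names(searches) <- .items
  best <- lapply(searches, `[[`, "best_cutoff")
  list(cutoffs = cutoff_set(best$sleep, best$mood, best$anxiety),
       searches = searches)
}
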