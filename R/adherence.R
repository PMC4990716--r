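#' Adherence metrics for one patient
#'
#' Four dimensions of adherence to daily self-reporting:
#' * **activeness** - number of distinct days with at least one reported
#'   rating;
#' * **timeliness** - number of those days whose earliest report date equals
#'   the target date (reported without delay; any back-fill counts as
#'   delayed);
#' * **duration** - `floor(span / period_days)`, the number of complete
#'   biweekly intervals between the first and last reported day;
#' * **persistence** - number of distinct calendar biweekly bins (anchored
#'   at `calendar_origin`) containing at least one reported day.
#'
#' @param ratings daily ratings of a single patient.
#' @param period_days biweekly period length (default 14).
#' @param calendar_origin date anchoring the persistence bins (study start).
#' @return one-row tibble with `patient_id` and the four metrics.
#' @export
adherence_metrics <- function(ratings, period_days = 14L, calendar_origin) {
  if (nrow(ratings) == 0L) {
    stop("patient has no ratings; exclude rating-less patients upstream",
         call. = FALSE)
  }
  if (length(unique(ratings$patient_id)) != 1L) {
    stop("adherence_metrics expects ratings of a single patient",
         call. = FALSE)
  }
  calendar_origin <- as.Date(calendar_origin)
  by_day <- dplyr::summarise(
    dplyr::group_by(ratings, .data$target_date),
    first_report = min(.data$report_date), .groups = "drop")
  activeness <- nrow(by_day)
  timeliness <- sum(by_day$first_report == by_day$target_date)
  span <- as.integer(max(by_day$target_date) - min(by_day$target_date))
  duration <- span %/% period_days
  bins <- as.integer(by_day$target_date - calendar_origin) %/% period_days
  persistence <- length(unique(bins))
  tibble::tibble(patient_id = ratings$patient_id[1],
                 activeness = as.integer(activeness),
                 timeliness = as.integer(timeliness),
                 duration = as.integer(duration),
                 persistence = as.integer(persistence))
}

#' Adherence profiles for every patient in a cohort
#'
#' @param tables a [cohort_tables()] or `generated_cohort`.
#' @param period_days biweekly period length.
#' @param calendar_origin anchor for persistence bins; defaults to the
#'   earliest target date in the cohort.
#' @return tibble of [adherence_metrics()] rows, one per patient.
#' @export
adherence_profiles <- function(tables, period_days = 14L,
                               calendar_origin = NULL) {
  if (inherits(tables, "generated_cohort")) tables <- tables$tables
  ratings <- tables$ratings
  if (is.null(calendar_origin)) calendar_origin <- min(ratings$target_date)
  dplyr::bind_rows(lapply(split(ratings, ratings$patient_id),
                          adherence_metrics, period_days = period_days,
                          calendar_origin = calendar_origin))
}

#' Cluster patients by their adherence profiles
#'
#' The four metrics are standardized to zero mean and unit variance (their
#' raw scales differ by an order of magnitude) and clustered with Lloyd's
#' k-means, keeping the best within-cluster sum of squares over
#' `n_restarts` seeded random initializations. Zero-variance features are
#' dropped with a warning.
#'
#' @param profiles output of [adherence_profiles()].
#' @param k number of clusters (2 for higher/lower, 3 adds a middle group).
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @return object of class `"adherence_clusters"`: `k`, `centers`
#'   (standardized), `scaling`, `assignment` (named integer vector), `wcss`,
#'   `features`, `seed`, `n_restarts`.
#' @export
kmeans_cluster <- function(profiles, k = 2L, n_restarts = 50L, seed = 1L) {
  feats <- c("activeness", "timeliness", "duration", "persistence")
  X <- as.matrix(profiles[, feats])
  if (k > nrow(X)) stop("k exceeds the number of patients", call. = FALSE)
  keep <- apply(X, 2L, sd) > 0
  if (!all(keep)) {
    warning("zero-variance feature(s) dropped: ",
            paste(feats[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0L) stop("all features are constant", call. = FALSE)
  }
  Xs <- scale(X)
  withr::local_seed(seed)
  km <- kmeans(Xs, centers = k, nstart = n_restarts, iter.max = 100L,
               algorithm = "Lloyd")
  structure(list(k = k, centers = km$centers,
                 scaling = list(center = attr(Xs, "scaled:center"),
                                scale = attr(Xs, "scaled:scale")),
                 assignment = setNames(km$cluster, profiles$patient_id),
                 wcss = km$tot.withinss, features = colnames(X),
                 seed = seed, n_restarts = n_restarts),
            class = "adherence_clusters")
}

#' Name clusters higher/middle/lower by mean activeness
#'
#' Clusters are ordered by their mean (raw) activeness; the cluster with the
#' highest mean is labelled `"higher"`, the lowest `"lower"` (with
#' `"middle"` in between for k = 3). Ties are broken by mean persistence,
#' with a message.
#'
#' @param model an [kmeans_cluster()] result.
#' @param profiles the profiles the model was fitted on.
#' @return named character vector mapping `patient_id` to group label.
#' @export
label_groups <- function(model, profiles) {
  stopifnot(inherits(model, "adherence_clusters"))
  cl <- model$assignment[profiles$patient_id]
  mean_act <- tapply(profiles$activeness, cl, mean)
  mean_per <- tapply(profiles$persistence, cl, mean)
  if (anyDuplicated(mean_act)) {
    message("tied mean activeness between clusters; tie broken by mean ",
            "persistence")
  }
  ord <- order(mean_act, mean_per, decreasing = TRUE)  # highest first
  labs <- switch(as.character(model$k),
                 `2` = c("higher", "lower"),
                 `3` = c("higher", "middle", "lower"),
                 paste0("group", seq_len(model$k)))
  lab_by_cluster <- setNames(labs, names(mean_act)[ord])
  setNames(unname(lab_by_cluster[as.character(cl)]), profiles$patient_id)
}

#' Group patients by biweekly response rate only
#'
#' The one-dimensional grouping used by earlier adherence work: per patient,
#' the mean over their PHQ-9 windows of (reported days in window) /
#' `window_len`, clustered by 1-D k-means with k = 2; the higher-rate
#' cluster is labelled `"higher"`. If every patient has the same rate the
#' grouping is degenerate and all patients are labelled `"higher"` with a
#' warning.
#'
#' @param tables a [cohort_tables()] or `generated_cohort`.
#' @param window_len biweekly window length.
#' @param seed integer seed for the k-means restarts.
#' @return named character vector mapping `patient_id` to
#'   `"higher"`/`"lower"`.
#' @export
response_rate_grouping <- function(tables, window_len = 14L, seed = 1L) {
  if (inherits(tables, "generated_cohort")) tables <- tables$tables
  assigned <- assign_windows(tables$ratings, tables$outcomes,
                             window_len = window_len)
  days <- dplyr::summarise(
    dplyr::group_by(assigned, .data$patient_id, .data$window_end),
    n_days = dplyr::n_distinct(.data$target_date), .groups = "drop")
  # windows with zero reported days count as rate 0
  all_win <- tibble::tibble(patient_id = tables$outcomes$patient_id,
                            window_end = tables$outcomes$test_date)
  days <- dplyr::left_join(all_win, days, by = c("patient_id", "window_end"))
  days$n_days[is.na(days$n_days)] <- 0L
  rate <- dplyr::summarise(dplyr::group_by(days, .data$patient_id),
                           rate = mean(.data$n_days / window_len),
                           .groups = "drop")
  if (sd(rate$rate) == 0) {
    warning("all patients have identical response rates; single effective ",
            "group", call. = FALSE)
    return(setNames(rep("higher", nrow(rate)), rate$patient_id))
  }
  withr::local_seed(seed)
  km <- kmeans(matrix(rate$rate, ncol = 1), centers = 2L, nstart = 50L,
               iter.max = 100L, algorithm = "Lloyd")
  hi <- which.max(km$centers)
  setNames(ifelse(km$cluster == hi, "higher", "lower"), rate$patient_id)
}

# run cut-off search + fit + predict inside one group's observations
.group_roc <- function(tables, patients, approach, window_len,
                       exclude_same_day, quad_points, cutoffs = NULL) {
  sub <- list(
    ratings = tables$ratings[tables$ratings$patient_id %in% patients, ],
    outcomes = tables$outcomes[tables$outcomes$patient_id %in% patients, ])
  class(sub) <- "cohort_tables"
  if (approach != "average" && is.null(cutoffs)) {
    cutoffs <- optimize_all(sub, approach = approach,
                            window_len = window_len,
                            exclude_same_day = exclude_same_day,
                            quad_points = quad_points)$cutoffs
  }
  ind <- suppressMessages(build_indicator_table(
    sub, approach = approach, cutoffs = cutoffs, window_len = window_len,
    exclude_same_day = exclude_same_day))
  if (nrow(ind) == 0L || length(unique(ind$depressed)) < 2L) {
    stop("degenerate group: no complete windows or a single outcome class",
         call. = FALSE)
  }
  fit <- suppressWarnings(fit_relogit(design_from_indicators(ind),
                                      quad_points = quad_points))
  roc <- auc_mw(predict_prob(fit, as.matrix(ind[, .items])), ind$depressed)
  list(roc = roc, fit = fit, cutoffs = cutoffs, n_obs = nrow(ind))
}

#' Compare screening accuracy between adherence groups
#'
#' The full screening pipeline (cut-off search, random-intercept logistic
#' fit, population-level prediction) is run separately within each group's
#' observations; the two group AUCs are compared with the independent-sample
#' chi-square test.
#'
#' @param tables a [cohort_tables()] or `generated_cohort`.
#' @param grouping named character vector mapping `patient_id` to
#'   `"higher"`/`"lower"` (from [label_groups()] or
#'   [response_rate_grouping()]).
#' @param approach indicator-building approach.
#' @param window_len,exclude_same_day see [build_indicator_table()].
#' @param quad_points quadrature nodes.
#' @return list with `comparison` (an `"auc_comparison"`, higher group
#'   first), `higher` and `lower` (per-group ROC, fit, cut-offs, n_obs).
#' @export
group_auc_comparison <- function(tables, grouping,
                                 approach = c("ratio", "average", "frequency"),
                                 window_len = 14L, exclude_same_day = FALSE,
                                 quad_points = 15L) {
  approach <- match.arg(approach)
  if (inherits(tables, "generated_cohort")) tables <- tables$tables
  for (g in c("higher", "lower")) {
    if (!any(grouping == g)) stop("group '", g, "' is empty", call. = FALSE)
  }
  res <- lapply(c(higher = "higher", lower = "lower"), function(g) {
    tryCatch(.group_roc(tables, names(grouping)[grouping == g], approach,
                        window_len, exclude_same_day, quad_points),
             error = function(e) {
               stop("group '", g, "': ", conditionMessage(e), call. = FALSE)
             })
  })
  list(comparison = compare_unpaired(res$higher$roc, res$lower$roc),
       higher = res$higher, lower = res$lower, approach = approach)
}

#' Robustness filters on a cohort
#'
#' * `"first_24_weeks"` keeps each patient's ratings and outcomes within 168
#'   days of their own first reported day (guards against persistence bias
#'   from unequal collection lengths);
#' * `"drop_late_starters"` removes patients whose first reported day falls
#'   in the final 84 days (12 weeks) of the study window;
#' * `"none"` is the identity.
#'
#' @param tables a [cohort_tables()] or `generated_cohort` (tables are
#'   returned either way).
#' @param mode filter to apply.
#' @param study_end end of the study window for `"drop_late_starters"`;
#'   defaults to the latest target date observed.
#' @return filtered `cohort_tables`.
#' @export
robustness_filters <- function(tables,
                               mode = c("none", "first_24_weeks",
                                        "drop_late_starters"),
                               study_end = NULL) {
  mode <- match.arg(mode)
  if (inherits(tables, "generated_cohort")) tables <- tables$tables
  if (mode == "none") return(tables)
  first_day <- dplyr::summarise(
    dplyr::group_by(tables$ratings, .data$patient_id),
    first = min(.data$target_date), .groups = "drop")
  if (mode == "first_24_weeks") {
    r <- dplyr::inner_join(tables$ratings, first_day, by = "patient_id")
    r <- r[as.integer(r$target_date - r$first) < 168L, ]
    o <- dplyr::inner_join(tables$outcomes, first_day, by = "patient_id")
    o <- o[as.integer(o$test_date - o$first) < 168L, ]
    out <- list(ratings = r[, names(tables$ratings)],
                outcomes = o[, names(tables$outcomes)])
  } else {
    if (is.null(study_end)) study_end <- max(tables$ratings$target_date)
    keep <- first_day$patient_id[first_day$first <= as.Date(study_end) - 84L]
    out <- list(
      ratings = tables$ratings[tables$ratings$patient_id %in% keep, ],
      outcomes = tables$outcomes[tables$outcomes$patient_id %in% keep, ])
  }
  if (nrow(out$ratings) == 0L || nrow(out$outcomes) == 0L) {
    stop("robustness filter '", mode, "' left an empty cohort", call. = FALSE)
  }
  class(out) <- "cohort_tables"
  out
}
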