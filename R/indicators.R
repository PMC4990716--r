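#' Dichotomization cut-offs for the three rating items
#'
#' @param sleep,mood,anxiety integer cut-offs, each within its item's scale.
#'   A day counts as depressed when its score is strictly above the cut-off.
#' @return named list of class `"cutoff_set"`.
#' @export
cutoff_set <- function(sleep, mood, anxiety) {
  cs <- list(sleep = as.integer(sleep), mood = as.integer(mood),
             anxiety = as.integer(anxiety))
  for (it in .items) {
    rng <- .item_scales[[it]]
    if (is.na(cs[[it]]) || cs[[it]] < rng[1] || cs[[it]] > rng[2]) {
      stop("cutoff for ", it, " must lie in [", rng[1], ", ", rng[2], "]",
           call. = FALSE)
    }
  }
  structure(cs, class = "cutoff_set")
}

#' Assign daily ratings to biweekly PHQ-9 windows
#'
#' A rating with target date `d` belongs to the window of the PHQ-9 test on
#' date `t` iff `t - (window_len - 1) <= d <= t` (the window is the 14 days
#' ending on, and including, the test date). If a patient's tests are closer
#' together than `window_len` days, a rating is assigned to the earliest
#' matching window only, with a warning. Ratings outside every window are
#' dropped.
#'
#' @param ratings validated daily-ratings tibble.
#' @param outcomes validated PHQ-9 tibble.
#' @param window_len window length in days (default 14).
#' @param exclude_same_day drop ratings whose target date equals the test
#'   date (robustness subsample).
#' @return the assigned ratings with an added `window_end` column.
#' @export
assign_windows <- function(ratings, outcomes, window_len = 14L,
                           exclude_same_day = FALSE) {
  win <- outcomes[, c("patient_id", "test_date")]
  joined <- dplyr::inner_join(ratings, win, by = "patient_id",
                              relationship = "many-to-many")
  joined <- dplyr::filter(joined,
                          .data$target_date <= .data$test_date,
                          .data$target_date > .data$test_date - window_len)
  if (isTRUE(exclude_same_day)) {
    joined <- dplyr::filter(joined, .data$target_date != .data$test_date)
  }
  # earliest window wins when PHQ-9 tests are < window_len days apart
  key <- c("patient_id", "target_date", "item")
  joined <- dplyr::arrange(joined, .data$patient_id, .data$target_date,
                           .data$item, .data$test_date)
  dup <- duplicated(joined[, key])
  if (any(dup)) {
    warning(sum(dup), " rating(s) fell inside overlapping windows; ",
            "each was assigned to the earliest window only", call. = FALSE)
    joined <- joined[!dup, ]
  }
  dplyr::rename(joined, window_end = "test_date")
}

#' Dichotomize a day's rating score
#'
#' A day is flagged depressed (1) iff its score is *strictly above* the
#' cut-off; a score equal to the cut-off counts as a normal day.
#'
#' @param score integer score(s) on the item's scale.
#' @param cutoff integer cut-off.
#' @return binary integer vector.
#' @export
dichotomize_day <- function(score, cutoff) {
  as.integer(score > cutoff)
}

#' Ratio-approach indicator for one window
#'
#' Share of reported days flagged as depressed: count of 1s divided by the
#' number of reported days. Undefined (NA) when no days were reported.
#'
#' @param binary_days dichotomized values of the reported days.
#' @return a value in `[0, 1]`, or `NA` for an empty window.
#' @export
build_ratio <- function(binary_days) {
  if (length(binary_days) == 0L) return(NA_real_)
  mean(binary_days)
}

#' Frequency-approach indicator for one window
#'
#' Count of reported days flagged as depressed during the window.
#'
#' @param binary_days dichotomized values of the reported days.
#' @return integer count (0 for an empty window).
#' @export
build_frequency <- function(binary_days) {
  as.integer(sum(binary_days))
}

#' Average-approach indicator for one window
#'
#' Arithmetic mean of the raw (non-dichotomized) scores of the reported
#' days. Undefined (NA) when no days were reported.
#'
#' @param scores raw integer scores of the reported days.
#' @return mean score, or `NA` for an empty window.
#' @export
build_average <- function(scores) {
  if (length(scores) == 0L) return(NA_real_)
  mean(scores)
}

#' Build the biweekly indicator table under one approach
#'
#' One row per (patient, PHQ-9 window) with the three item indicators, the
#' per-item reported-day counts and the binary depressed outcome. Windows in
#' which *any* item has zero reported days are dropped (the ratio and
#' average indicators are undefined on empty sets; dropping uniformly keeps
#' the three approaches comparable on identical observations).
#'
#' @param tables a [cohort_tables()] object (or a `generated_cohort`).
#' @param approach one of `"ratio"`, `"average"`, `"frequency"`.
#' @param cutoffs a [cutoff_set()]; required for ratio/frequency, ignored
#'   for average.
#' @param window_len window length in days.
#' @param exclude_same_day see [assign_windows()].
#' @return tibble with columns `patient_id`, `window_end`, `approach`,
#'   `sleep`, `mood`, `anxiety`, `n_sleep`, `n_mood`, `n_anxiety`,
#'   `depressed`.
#' @export
build_indicator_table <- function(tables, approach = c("ratio", "average",
                                                       "frequency"),
                                  cutoffs = NULL, window_len = 14L,
                                  exclude_same_day = FALSE) {
  approach <- match.arg(approach)
  if (inherits(tables, "generated_cohort")) tables <- tables$tables
  if (approach != "average" && is.null(cutoffs)) {
    stop("the ", approach, " approach requires a cutoff_set", call. = FALSE)
  }
  assigned <- assign_windows(tables$ratings, tables$outcomes,
                             window_len = window_len,
                             exclude_same_day = exclude_same_day)
  out <- tables$outcomes
  if (nrow(assigned) == 0L || nrow(out) == 0L) {
    return(.empty_indicator_table())
  }

  val <- switch(approach,
    average = assigned$score,
    {
      cut_by_item <- unlist(cutoffs[assigned$item], use.names = FALSE)
      dichotomize_day(assigned$score, cut_by_item)
    })
  assigned$value <- as.numeric(val)

  agg <- dplyr::summarise(
    dplyr::group_by(assigned, .data$patient_id, .data$window_end, .data$item),
    indicator = switch(approach,
                       ratio = build_ratio(.data$value),
                       frequency = as.numeric(build_frequency(.data$value)),
                       average = build_average(.data$value)),
    n_reported = dplyr::n(), .groups = "drop")

  wide <- tidyr::pivot_wider(agg, names_from = "item",
                             values_from = c("indicator", "n_reported"),
                             names_glue = "{.value}_{item}")
  for (it in .items) {
    for (col in paste0(c("indicator_", "n_reported_"), it)) {
      if (!col %in% names(wide)) wide[[col]] <- NA_real_
    }
  }
  wide <- dplyr::left_join(
    wide, out[, c("patient_id", "test_date", "depressed")],
    by = c(patient_id = "patient_id", window_end = "test_date"))

  complete <- !is.na(wide$n_reported_sleep) & wide$n_reported_sleep > 0 &
    !is.na(wide$n_reported_mood) & wide$n_reported_mood > 0 &
    !is.na(wide$n_reported_anxiety) & wide$n_reported_anxiety > 0
  n_dropped <- sum(!complete) + (nrow(out) - nrow(wide))
  if (n_dropped > 0) {
    message(n_dropped, " window(s) dropped: at least one item had no ",
            "reported days")
  }
  wide <- wide[complete, ]
  tibble::tibble(
    patient_id = wide$patient_id,
    window_end = wide$window_end,
    approach = approach,
    sleep = wide$indicator_sleep,
    mood = wide$indicator_mood,
    anxiety = wide$indicator_anxiety,
    n_sleep = as.integer(wide$n_reported_sleep),
    n_mood = as.integer(wide$n_reported_mood),
    n_anxiety = as.integer(wide$n_reported_anxiety),
    depressed = as.integer(wide$depressed))
}

.empty_indicator_table <- function() {
  tibble::tibble(patient_id = character(), window_end = as.Date(character()),
                 approach = character(), sleep = numeric(), mood = numeric(),
                 anxiety = numeric(), n_sleep = integer(), n_mood = integer(),
                 n_anxiety = integer(), depressed = integer())
}
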