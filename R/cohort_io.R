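#' @importFrom rlang .data
#' @importFrom stats var sd setNames optim plogis qlogis rnorm runif rbinom rgeom
#'   pchisq qnorm kmeans cor integrate dnorm
#' @importFrom utils head
NULL

# Item scales: sleep is stored as dissatisfaction (0 good .. 10 bad), mood
# 0 (none) .. 7 (very severe), anxiety 0 (none) .. 10 (very severe).
.item_scales <- list(
  sleep   = c(0L, 10L),
  mood    = c(0L, 7L),
  anxiety = c(0L, 10L)
)

.items <- names(.item_scales)

#' Range of a rating item's scale
#'
#' @param item one of `"sleep"`, `"mood"`, `"anxiety"`.
#' @return integer vector `c(min, max)` of the item's scale. Sleep is on the
#'   dissatisfaction scale (already reversed so that higher = worse).
#' @export
item_scale <- function(item) {
  if (!item %in% .items) {
    stop("unknown rating item: '", item, "' (expected one of ",
         paste(.items, collapse = ", "), ")", call. = FALSE)
  }
  .item_scales[[item]]
}

#' Reverse a sleep-satisfaction score onto the dissatisfaction scale
#'
#' The tracker collects sleep *satisfaction* (0 bad .. 10 good); the analysis
#' uses sleep *dissatisfaction* (0 good .. 10 bad) so that all three items
#' increase with severity. The reversal `10 - s` is an involution and is
#' applied exactly once, at ingest.
#'
#' @param score integer scores in `[0, 10]`.
#' @return the reversed scores.
#' @export
reverse_sleep <- function(score) {
  10L - score
}

.assert_cols <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop(what, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
}

#' Validate a table of daily ratings
#'
#' Checks item names, per-item score ranges, report-date ordering
#' (back-filling is allowed, future-dating is not), and uniqueness of
#' (patient, target_date, item). Error messages name the offending row.
#'
#' @param ratings a data frame with columns `patient_id`, `target_date`,
#'   `report_date`, `item`, `score`.
#' @return the validated tibble (invisibly classed columns coerced).
#' @export
validate_ratings <- function(ratings) {
  .assert_cols(ratings, c("patient_id", "target_date", "report_date",
                          "item", "score"), "daily ratings")
  ratings <- tibble::as_tibble(ratings)
  ratings$patient_id <- as.character(ratings$patient_id)
  ratings$target_date <- as.Date(ratings$target_date)
  ratings$report_date <- as.Date(ratings$report_date)
  ratings$item <- as.character(ratings$item)
  ratings$score <- as.integer(ratings$score)

  bad_item <- which(!ratings$item %in% .items)
  if (length(bad_item) > 0) {
    stop("row ", bad_item[1], ": unknown item '", ratings$item[bad_item[1]], "'",
         call. = FALSE)
  }
  lo <- vapply(.item_scales, `[`, integer(1), 1L)[ratings$item]
  hi <- vapply(.item_scales, `[`, integer(1), 2L)[ratings$item]
  bad_score <- which(is.na(ratings$score) | ratings$score < lo | ratings$score > hi)
  if (length(bad_score) > 0) {
    i <- bad_score[1]
    stop("row ", i, ": field 'score' = ", ratings$score[i],
         " outside the ", ratings$item[i], " scale [", lo[i], ", ", hi[i], "]",
         call. = FALSE)
  }
  bad_date <- which(is.na(ratings$target_date) | is.na(ratings$report_date) |
                      ratings$report_date < ratings$target_date)
  if (length(bad_date) > 0) {
    i <- bad_date[1]
    stop("row ", i, ": field 'report_date' (", ratings$report_date[i],
         ") precedes target_date (", ratings$target_date[i], ")",
         call. = FALSE)
  }
  key <- paste(ratings$patient_id, ratings$target_date, ratings$item)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    i <- dup[1]
    stop("row ", i, ": duplicate rating for (", ratings$patient_id[i], ", ",
         ratings$target_date[i], ", ", ratings$item[i], ")", call. = FALSE)
  }
  ratings
}

#' Validate a table of biweekly PHQ-9 outcomes
#'
#' @param outcomes a data frame with columns `patient_id`, `test_date`,
#'   `score` (and optionally `depressed`, which is recomputed).
#' @param depression_cutoff PHQ-9 total score at or above which a test counts
#'   as depressed (default 5).
#' @return tibble with a binary `depressed` column derived as
#'   `score >= depression_cutoff`.
#' @export
validate_phq9 <- function(outcomes, depression_cutoff = 5L) {
  .assert_cols(outcomes, c("patient_id", "test_date", "score"), "PHQ-9 table")
  outcomes <- tibble::as_tibble(outcomes)
  outcomes$patient_id <- as.character(outcomes$patient_id)
  outcomes$test_date <- as.Date(outcomes$test_date)
  outcomes$score <- as.integer(outcomes$score)

  bad <- which(is.na(outcomes$score) | outcomes$score < 0L | outcomes$score > 27L)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": field 'score' = ", outcomes$score[bad[1]],
         " outside the PHQ-9 range [0, 27]", call. = FALSE)
  }
  key <- paste(outcomes$patient_id, outcomes$test_date)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    i <- dup[1]
    stop("row ", i, ": duplicate PHQ-9 test for (", outcomes$patient_id[i],
         ", ", outcomes$test_date[i], ")", call. = FALSE)
  }
  outcomes$depressed <- as.integer(outcomes$score >= depression_cutoff)
  outcomes[, c("patient_id", "test_date", "score", "depressed")]
}

#' Read daily mental-health ratings from CSV
#'
#' Expects the header `patient_id,target_date,report_date,item,score` with
#' ISO-8601 dates. If the file stores sleep as raw *satisfaction* (the scale
#' the tracker presents), set `raw_sleep_is_satisfaction = TRUE` and scores
#' are reversed to dissatisfaction (`10 - raw`) on ingest.
#'
#' @param path CSV file path.
#' @param raw_sleep_is_satisfaction logical; reverse sleep scores on ingest.
#' @return validated tibble of daily ratings.
#' @export
read_daily_ratings <- function(path, raw_sleep_is_satisfaction = FALSE) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    target_date = readr::col_date(),
    report_date = readr::col_date(),
    item = readr::col_character(),
    score = readr::col_integer()
  ))
  if (isTRUE(raw_sleep_is_satisfaction)) {
    is_sleep <- df$item == "sleep"
    raw <- df$score[is_sleep]
    if (any(!is.na(raw) & (raw < 0L | raw > 10L))) {
      i <- which(is_sleep)[which(!is.na(raw) & (raw < 0L | raw > 10L))[1]]
      stop("row ", i, ": field 'score' = ", df$score[i],
           " outside the sleep satisfaction scale [0, 10]", call. = FALSE)
    }
    df$score[is_sleep] <- reverse_sleep(raw)
  }
  validate_ratings(df)
}

#' Read biweekly PHQ-9 outcomes from CSV
#'
#' Expects the header `patient_id,test_date,score`. The binary depression
#' label is derived on ingest as `score >= depression_cutoff`.
#'
#' @inheritParams validate_phq9
#' @param path CSV file path.
#' @return validated tibble with the derived `depressed` column.
#' @export
read_phq9 <- function(path, depression_cutoff = 5L) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    test_date = readr::col_date(),
    score = readr::col_integer()
  ))
  validate_phq9(df, depression_cutoff = depression_cutoff)
}

#' Assemble and validate a cohort from its two tables
#'
#' @param ratings daily ratings table (see [validate_ratings()]).
#' @param outcomes PHQ-9 table (see [validate_phq9()]).
#' @param depression_cutoff passed to [validate_phq9()].
#' @return a list with elements `ratings` and `outcomes`, class
#'   `"cohort_tables"`. Outcome patients with no ratings at all are kept but
#'   flagged with a warning (their windows can never enter the model).
#' @export
cohort_tables <- function(ratings, outcomes, depression_cutoff = 5L) {
  ratings <- validate_ratings(ratings)
  outcomes <- validate_phq9(outcomes, depression_cutoff = depression_cutoff)
  orphans <- setdiff(unique(outcomes$patient_id), unique(ratings$patient_id))
  if (length(orphans) > 0) {
    warning("patient(s) with PHQ-9 outcomes but no daily ratings: ",
            paste(head(orphans, 5), collapse = ", "),
            if (length(orphans) > 5) " ..." else "", call. = FALSE)
  }
  structure(list(ratings = ratings, outcomes = outcomes),
            class = "cohort_tables")
}

# canonical column order per known table shape, so writes are stable
.canonical_order <- function(df) {
  schemas <- list(
    c("patient_id", "target_date", "report_date", "item", "score"),
    c("patient_id", "test_date", "score", "depressed"),
    c("patient_id", "window_end", "approach", "sleep", "mood", "anxiety",
      "n_sleep", "n_mood", "n_anxiety", "depressed"),
    c("patient_id", "activeness", "timeliness", "duration", "persistence",
      "cluster")
  )
  for (s in schemas) {
    if (setequal(names(df), s)) return(df[, s])
  }
  df
}

#' Write a pipeline table to CSV
#'
#' Columns are emitted in the canonical order for known pipeline schemas and
#' floats are formatted deterministically, so writing the same table twice
#' yields byte-identical files.
#'
#' @param table a pipeline data frame (ratings, outcomes, indicators,
#'   adherence profiles, ...).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  table <- .canonical_order(tibble::as_tibble(table))
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
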