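# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# a single patient's ratings table from day offsets relative to an origin
make_ratings <- function(patient_id, days, item = "mood", score = 3L,
                         delay = 0L, origin = as.Date("2013-04-01")) {
  tibble::tibble(
    patient_id = patient_id,
    target_date = origin + days,
    report_date = origin + days + delay,
    item = item,
    score = as.integer(score))
}

make_phq9 <- function(patient_id, days, score,
                      origin = as.Date("2013-04-01")) {
  tibble::tibble(patient_id = patient_id, test_date = origin + days,
                 score = as.integer(score))
}

# small valid cohort: 3 patients, daily mood+sleep+anxiety over two windows
make_small_cohort <- function(origin = as.Date("2013-04-01")) {
  ratings <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(p) {
    dplyr::bind_rows(
      make_ratings(p, 1:28, "mood", rep(c(2L, 5L), 14), origin = origin),
      make_ratings(p, 1:28, "sleep", rep(c(3L, 8L), 14), origin = origin),
      make_ratings(p, 1:28, "anxiety", rep(c(2L, 7L), 14), origin = origin))
  }))
  outcomes <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(p) {
    make_phq9(p, c(14, 28), c(3L, 9L), origin = origin)
  }))
  cohort_tables(ratings, outcomes)
}

# binary panel data with known coefficients and random-intercept SD
simulate_panel <- function(n_patients, n_windows, beta, sigma_b, seed,
                           x_fun = function(n) runif(n)) {
  withr::local_seed(seed)
  p <- length(beta) - 1L
  g <- rep(seq_len(n_patients), each = n_windows)
  X <- matrix(x_fun(n_patients * n_windows * p), ncol = p)
  colnames(X) <- c("sleep", "mood", "anxiety")[seq_len(p)]
  b <- rnorm(n_patients, 0, sigma_b)[g]
  eta <- beta[1] + drop(X %*% beta[-1]) + b
  y <- rbinom(length(eta), 1L, plogis(eta))
  panel_design(y, X, paste0("p", g))
}

# exhaustive O(pos x neg) AUC oracle: credit 1 / 0.5 / 0 per pair
auc_pair_counting <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

expect_no_message_tables <- function(tables) {
  invisible(tables)
}
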