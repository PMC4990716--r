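#' Adherence class parameters for the cohort simulator
#'
#' @param class label for the class.
#' @param share fraction of patients in this class (shares must sum to 1).
#' @param p_report daily probability that the patient submits ratings.
#' @param p_delay probability that a submitted rating is back-filled late.
#' @param delay_max_days maximum back-fill delay in days (delay is uniform on
#'   `1..delay_max_days`).
#' @param dropout_hazard per-biweekly-period probability of stopping app use.
#' @param noise_multiplier multiplier on the day-level rating noise SD.
#' @return one-row tibble of class parameters.
#' @export
adherence_class <- function(class, share, p_report, p_delay,
                            delay_max_days = 3L, dropout_hazard = 0.05,
                            noise_multiplier = 1) {
  tibble::tibble(class = class, share = share, p_report = p_report,
                 p_delay = p_delay, delay_max_days = as.integer(delay_max_days),
                 dropout_hazard = dropout_hazard,
                 noise_multiplier = noise_multiplier)
}

.default_classes <- function() {
  adherence_class("all", share = 1, p_report = 0.8, p_delay = 0.2,
                  delay_max_days = 3L, dropout_hazard = 0.08,
                  noise_multiplier = 1)
}

#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the data-collection design of a mobile
#' mental-health tracker study: daily sleep-dissatisfaction/mood/anxiety
#' ratings on their bounded integer scales, a PHQ-9 test every
#' `phq9_period_days` days, patient-level heterogeneity (Gaussian random
#' intercept `tau`), a biweekly AR(1) latent severity state shared by ratings
#' and PHQ-9, day-level reporting gaps, delayed (back-filled) reports, and
#' per-period dropout. Adherence classes differ in report quantity and
#' measurement noise.
#'
#' @param n_patients number of patients.
#' @param n_weeks study length in weeks (default 48, i.e. 24 biweekly
#'   periods).
#' @param phq9_period_days days between PHQ-9 tests (default 14).
#' @param mu baseline latent severity.
#' @param tau SD of the patient random intercept.
#' @param rho AR(1) coefficient of the biweekly latent state (`|rho| < 1`).
#' @param sigma_state SD of the latent-state innovations.
#' @param sigma_day SD of day-level rating noise (per item, before the
#'   class noise multiplier).
#' @param loading named per-item slope linking the daily latent state to the
#'   rating scale.
#' @param item_offset named per-item intercept on the rating scale.
#' @param phq9_slope slope linking the biweekly latent state to the PHQ-9
#'   total score.
#' @param phq9_noise SD of PHQ-9 measurement noise.
#' @param depression_cutoff PHQ-9 cutoff defining the depressed label.
#' @param adherence_classes tibble of [adherence_class()] rows.
#' @param start_date study start date (calendar origin).
#' @param seed integer seed; mandatory for reproducible generation.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients,
                       n_weeks = 48L,
                       phq9_period_days = 14L,
                       mu = 2.25,
                       tau = 1,
                       rho = 0.5,
                       sigma_state = 1,
                       sigma_day = 1,
                       loading = c(sleep = 1, mood = 0.7, anxiety = 1),
                       item_offset = c(sleep = 2.5, mood = 1.5, anxiety = 2),
                       phq9_slope = 2,
                       phq9_noise = 2,
                       depression_cutoff = 5L,
                       adherence_classes = .default_classes(),
                       start_date = as.Date("2013-04-01"),
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_weeks = as.integer(n_weeks),
              phq9_period_days = as.integer(phq9_period_days), mu = mu,
              tau = tau, rho = rho, sigma_state = sigma_state,
              sigma_day = sigma_day, loading = loading,
              item_offset = item_offset, phq9_slope = phq9_slope,
              phq9_noise = phq9_noise,
              depression_cutoff = as.integer(depression_cutoff),
              adherence_classes = tibble::as_tibble(adherence_classes),
              start_date = as.Date(start_date), seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' Validate a simulator configuration
#'
#' @param cfg a `sim_config` list.
#' @return the config, classed `"sim_config"`; errors on degenerate settings.
#' @export
validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (cfg$n_weeks < 2L) stop("n_weeks must cover at least one period", call. = FALSE)
  if (cfg$tau < 0 || cfg$sigma_state < 0 || cfg$sigma_day < 0 ||
      cfg$phq9_noise < 0) {
    stop("tau and all noise SDs must be nonnegative", call. = FALSE)
  }
  if (abs(cfg$rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  ac <- cfg$adherence_classes
  if (abs(sum(ac$share) - 1) > 1e-8) {
    stop("adherence class shares must sum to 1", call. = FALSE)
  }
  probs <- c(ac$p_report, ac$p_delay, ac$dropout_hazard)
  if (any(probs < 0 | probs > 1)) {
    stop("class probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(ac$noise_multiplier < 0)) {
    stop("noise_multiplier must be nonnegative", call. = FALSE)
  }
  if (!all(.items %in% names(cfg$loading)) ||
      !all(.items %in% names(cfg$item_offset))) {
    stop("loading and item_offset must name sleep, mood and anxiety",
         call. = FALSE)
  }
  structure(cfg, class = c("sim_config", "list"))
}

.clamp_int <- function(x, lo, hi) {
  pmin.int(pmax.int(as.integer(round(x)), lo), hi)
}

#' Simulate a synthetic cohort
#'
#' Per patient: a random intercept `u_i ~ N(0, tau^2)` and a stationary AR(1)
#' biweekly latent state give severity `s_it = mu + u_i + x_it`; PHQ-9 total
#' at each period end (while the patient is still active) is
#' `clamp(round(phq9_slope * s_it + noise), 0, 27)`; each day's latent value
#' adds day-level noise and maps onto each item's bounded integer scale via
#' its offset and loading. Days are reported with probability `p_report`
#' until dropout (geometric per biweekly period); a reported day is delayed
#' with probability `p_delay` (report date = target date + Uniform
#' `{1..delay_max_days}`), else reported on time. Entry is staggered
#' uniformly over the study window. PHQ-9 tests lapse after dropout.
#'
#' @param config a [sim_config()].
#' @return list of class `"generated_cohort"` with elements `tables` (a
#'   [cohort_tables()] pair that passes validation), `truth` (per-patient
#'   adherence class; per-window latent state, PHQ-9 score and depressed
#'   status) and `config`.
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  withr::local_seed(config$seed)
  p <- config$phq9_period_days
  total_days <- config$n_weeks * 7L
  ac <- config$adherence_classes

  class_idx <- sample.int(nrow(ac), config$n_patients, replace = TRUE,
                          prob = ac$share)
  # entry staggered uniformly, but always leaving room for one full period
  entry <- sample.int(total_days - p + 1L, config$n_patients,
                      replace = TRUE) - 1L

  rat <- vector("list", config$n_patients)
  tru <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    cls <- ac[class_idx[i], ]
    pid <- sprintf("p%03d", i)
    n_avail <- (total_days - entry[i]) %/% p
    n_active <- if (cls$dropout_hazard <= 0) n_avail else
      min(n_avail, 1L + rgeom(1L, cls$dropout_hazard))
    u_i <- rnorm(1L, 0, config$tau)
    # stationary AR(1) latent state per biweekly period
    x <- numeric(n_active)
    x[1] <- rnorm(1L, 0, config$sigma_state / sqrt(1 - config$rho^2))
    if (n_active > 1L) {
      for (t in 2:n_active) {
        x[t] <- config$rho * x[t - 1L] + rnorm(1L, 0, config$sigma_state)
      }
    }
    s <- config$mu + u_i + x
    score <- .clamp_int(config$phq9_slope * s + rnorm(n_active, 0, config$phq9_noise),
                        0L, 27L)
    test_dates <- config$start_date + entry[i] + p * seq_len(n_active)
    tru[[i]] <- tibble::tibble(
      patient_id = pid, period = seq_len(n_active), test_date = test_dates,
      latent = s, score = score,
      depressed = as.integer(score >= config$depression_cutoff),
      class = cls$class)

    days <- seq_len(n_active * p)                 # day offsets within activity
    reported <- runif(length(days)) < cls$p_report
    days <- days[reported]
    if (length(days) == 0L) next
    day_base <- s[(days - 1L) %/% p + 1L]
    target <- config$start_date + entry[i] + days
    delayed <- runif(length(days)) < cls$p_delay
    delay <- integer(length(days))
    if (any(delayed)) {
      delay[delayed] <- sample.int(cls$delay_max_days, sum(delayed),
                                   replace = TRUE)
    }
    report <- target + delay
    per_item <- lapply(.items, function(it) {
      # day-level noise is drawn independently per item
      day_state <- day_base +
        rnorm(length(days), 0, config$sigma_day * cls$noise_multiplier)
      sc <- .clamp_int(config$item_offset[[it]] + config$loading[[it]] * day_state,
                       .item_scales[[it]][1], .item_scales[[it]][2])
      tibble::tibble(patient_id = pid, target_date = target,
                     report_date = report, item = it, score = sc)
    })
    rat[[i]] <- dplyr::bind_rows(per_item)
  }

  ratings <- dplyr::bind_rows(rat)
  truth_windows <- dplyr::bind_rows(tru)
  if (nrow(ratings) == 0L) {
    stop("degenerate configuration: no ratings generated", call. = FALSE)
  }
  outcomes <- truth_windows[, c("patient_id", "test_date", "score")]
  tables <- suppressWarnings(
    cohort_tables(ratings, outcomes,
                  depression_cutoff = config$depression_cutoff))
  classes <- tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(config$n_patients)),
    class = ac$class[class_idx], entry_day = entry)
  structure(list(tables = tables,
                 truth = list(classes = classes, windows = truth_windows),
                 config = config),
            class = "generated_cohort")
}

#' Two-class configuration contrasting high and low adherence
#'
#' Builds a [sim_config()] with a higher-adherence class (25% of patients)
#' and a lower-adherence class (75%, mirroring the roughly 20/58 split seen
#' in tracker cohorts). The low class reports fewer days, back-fills more,
#' drops out earlier and rates with inflated day-level noise; the gaps are
#' parameters, and a zero gap makes the two classes identical.
#'
#' @param n_patients number of patients.
#' @param report_gap reduction of the low class's daily reporting
#'   probability (high class reports with probability 0.9).
#' @param delay_gap increase of the low class's delay probability (high
#'   class: 0.1).
#' @param dropout_gap increase of the low class's per-period dropout hazard
#'   (high class: 0.02).
#' @param noise_ratio low-class day-level noise multiplier (high class: 1).
#' @param share_high fraction of patients in the higher-adherence class.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config` with classes `"higher"` and `"lower"`.
#' @export
make_adherence_contrast_config <- function(n_patients,
                                           report_gap = 0.35,
                                           delay_gap = 0.25,
                                           dropout_gap = 0.13,
                                           noise_ratio = 2,
                                           share_high = 0.25,
                                           ...) {
  classes <- dplyr::bind_rows(
    adherence_class("higher", share = share_high, p_report = 0.9,
                    p_delay = 0.1, delay_max_days = 3L,
                    dropout_hazard = 0.02, noise_multiplier = 1),
    adherence_class("lower", share = 1 - share_high,
                    p_report = 0.9 - report_gap, p_delay = 0.1 + delay_gap,
                    delay_max_days = 3L, dropout_hazard = 0.02 + dropout_gap,
                    noise_multiplier = noise_ratio))
  sim_config(n_patients = n_patients, adherence_classes = classes, ...)
}
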