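#' Configuration for an end-to-end pipeline run
#'
#' Exactly one data source must be given: either the paths to the two
#' cohort CSVs, or a [sim_config()] for a synthetic cohort.
#'
#' @param ratings_path,phq9_path CSV paths of an existing cohort.
#' @param sim a [sim_config()] (alternative to the CSV paths).
#' @param approaches which indicator approaches to run.
#' @param window_len biweekly window length in days.
#' @param depression_cutoff PHQ-9 cutoff for the depressed label.
#' @param exclude_same_day run on the robustness subsample that drops
#'   ratings reported on PHQ-9 test days.
#' @param raw_sleep_is_satisfaction see [read_daily_ratings()].
#' @param cv run five-fold cross-validation per approach.
#' @param adherence run the adherence clustering and group comparison.
#' @param adherence_k number of adherence clusters.
#' @param quad_points quadrature nodes for every model fit.
#' @param seed integer seed governing every stochastic stage.
#' @param out_dir output directory.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(ratings_path = NULL, phq9_path = NULL, sim = NULL,
                       approaches = c("ratio", "average", "frequency"),
                       window_len = 14L, depression_cutoff = 5L,
                       exclude_same_day = FALSE,
                       raw_sleep_is_satisfaction = FALSE,
                       cv = FALSE, adherence = TRUE, adherence_k = 2L,
                       quad_points = 15L, seed = 1L, out_dir = NULL) {
  from_csv <- !is.null(ratings_path) || !is.null(phq9_path)
  if (from_csv && is.null(sim)) {
    if (is.null(ratings_path) || is.null(phq9_path)) {
      stop("both ratings_path and phq9_path are required", call. = FALSE)
    }
  } else if (!from_csv && !is.null(sim)) {
    sim <- validate_sim_config(sim)
  } else {
    stop("exactly one data source: either CSV paths or a sim_config",
         call. = FALSE)
  }
  approaches <- match.arg(approaches, several.ok = TRUE)
  structure(list(ratings_path = ratings_path, phq9_path = phq9_path,
                 sim = sim, approaches = approaches,
                 window_len = as.integer(window_len),
                 depression_cutoff = as.integer(depression_cutoff),
                 exclude_same_day = isTRUE(exclude_same_day),
                 raw_sleep_is_satisfaction = isTRUE(raw_sleep_is_satisfaction),
                 cv = isTRUE(cv), adherence = isTRUE(adherence),
                 adherence_k = as.integer(adherence_k),
                 quad_points = as.integer(quad_points),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  res
}

.fit_to_list <- function(fit) {
  list(beta = as.list(fit$beta), sigma_b = fit$sigma_b, loglik = fit$loglik,
       se = as.list(fit$se), vcov = unname(apply(fit$vcov, 1L, as.list)),
       n_obs = fit$n_obs, n_patients = fit$n_patients,
       quad_points = fit$quad_points, converged = fit$converged)
}

#' Run the full screening pipeline
#'
#' Orchestrates every stage for each requested approach: cohort
#' simulation/ingest, window assignment and indicator construction, cut-off
#' optimization (ratio/frequency), random-intercept logistic fit, in-sample
#' ROC with paired comparisons against the ratio approach, optional
#' five-fold cross-validation, and the adherence analysis (profiles,
#' k-means grouping, response-rate grouping, per-group AUC comparison).
#' When `config$out_dir` is set, each stage's result is written there
#' (`indicators_<approach>.csv`, `cutoffs.json`, `fit.json`, `roc.json`,
#' `cv.json`, `adherence.csv`, `comparison.json`, `summary.txt`), each JSON
#' carrying the config hash and seed.
#'
#' @param config a [run_config()].
#' @return list of class `"run_report"` with per-approach results and the
#'   adherence comparisons.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg_hash <- rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
  provenance <- list(config_hash = cfg_hash, seed = config$seed)

  tables <- .stage("ingest", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed
      simulate_cohort(validate_sim_config(sim))$tables
    } else {
      cohort_tables(
        read_daily_ratings(config$ratings_path,
                           config$raw_sleep_is_satisfaction),
        read_phq9(config$phq9_path, config$depression_cutoff),
        depression_cutoff = config$depression_cutoff)
    }
  })

  per_approach <- list()
  for (ap in config$approaches) {
    cs <- if (ap == "average") NULL else
      .stage(paste0("cutoffs_", ap), {
        optimize_all(tables, approach = ap, window_len = config$window_len,
                     exclude_same_day = config$exclude_same_day,
                     quad_points = config$quad_points)$cutoffs
      })
    ind <- .stage(paste0("indicators_", ap), {
      suppressMessages(build_indicator_table(
        tables, approach = ap, cutoffs = cs,
        window_len = config$window_len,
        exclude_same_day = config$exclude_same_day))
    })
    fit <- .stage(paste0("fit_", ap), {
      fit_relogit(design_from_indicators(ind),
                  quad_points = config$quad_points)
    })
    roc <- auc_mw(predict_prob(fit, as.matrix(ind[, .items])), ind$depressed)
    cv <- if (config$cv) {
      .stage(paste0("crossval_", ap), {
        five_fold_cv(tables, approach = ap, seed = config$seed,
                     window_len = config$window_len,
                     exclude_same_day = config$exclude_same_day,
                     quad_points = config$quad_points)
      })
    }
    per_approach[[ap]] <- list(cutoffs = cs, indicators = ind, fit = fit,
                               roc = roc, cv = cv,
                               probs = predict_prob(fit,
                                                    as.matrix(ind[, .items])))
  }

  # paired comparisons against the ratio approach on shared observations
  paired <- list()
  if ("ratio" %in% config$approaches) {
    ref <- per_approach$ratio
    ref_key <- paste(ref$indicators$patient_id, ref$indicators$window_end)
    for (ap in setdiff(config$approaches, "ratio")) {
      other <- per_approach[[ap]]
      key <- paste(other$indicators$patient_id, other$indicators$window_end)
      shared <- intersect(ref_key, key)
      paired[[paste0("ratio_vs_", ap)]] <- compare_paired(
        ref$probs[match(shared, ref_key)],
        other$probs[match(shared, key)],
        ref$indicators$depressed[match(shared, ref_key)])
    }
  }

  adherence_res <- if (config$adherence) {
    .stage("adherence", {
      profiles <- adherence_profiles(tables,
                                     period_days = config$window_len)
      model <- kmeans_cluster(profiles, k = config$adherence_k,
                              seed = config$seed)
      grouping <- label_groups(model, profiles)
      rate_grouping <- response_rate_grouping(tables,
                                              window_len = config$window_len,
                                              seed = config$seed)
      comparisons <- lapply(
        setNames(config$approaches, config$approaches),
        function(ap) {
          tryCatch(
            group_auc_comparison(tables, grouping, approach = ap,
                                 window_len = config$window_len,
                                 exclude_same_day = config$exclude_same_day,
                                 quad_points = config$quad_points),
            error = function(e) {
              warning("adherence comparison (", ap, ") skipped: ",
                      conditionMessage(e), call. = FALSE)
              NULL
            })
        })
      profiles$cluster <- unname(grouping[profiles$patient_id])
      list(profiles = profiles, model = model, grouping = grouping,
           rate_grouping = rate_grouping, comparisons = comparisons)
    })
  }

  report <- structure(list(per_approach = per_approach, paired = paired,
                           adherence = adherence_res, tables = tables,
                           config = config, provenance = provenance),
                      class = "run_report")
  if (!is.null(config$out_dir)) .write_run_outputs(report)
  report
}

.write_run_outputs <- function(report) {
  dir.create(report$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(f) file.path(report$config$out_dir, f)
  prov <- report$provenance

  cutoffs_json <- list(provenance = prov)
  fits_json <- list(provenance = prov)
  roc_json <- list(provenance = prov)
  cv_json <- list(provenance = prov)
  for (ap in names(report$per_approach)) {
    pa <- report$per_approach[[ap]]
    write_table(pa$indicators, od(paste0("indicators_", ap, ".csv")))
    if (!is.null(pa$cutoffs)) cutoffs_json[[ap]] <- unclass(pa$cutoffs)
    fits_json[[ap]] <- .fit_to_list(pa$fit)
    roc_json[[ap]] <- list(auc = pa$roc$auc, var_auc = pa$roc$var_auc,
                           n_pos = pa$roc$n_pos, n_neg = pa$roc$n_neg,
                           curve = as.list(pa$roc$curve))
    if (!is.null(pa$cv)) {
      cv_json[[ap]] <- list(fold_auc = pa$cv$fold_auc,
                            pooled_auc = pa$cv$pooled_auc)
    }
  }
  .write_json(cutoffs_json, od("cutoffs.json"))
  .write_json(fits_json, od("fit.json"))
  .write_json(roc_json, od("roc.json"))
  if (report$config$cv) .write_json(cv_json, od("cv.json"))

  comparison_json <- list(provenance = prov)
  for (nm in names(report$paired)) {
    cmp <- report$paired[[nm]]
    comparison_json$paired[[nm]] <- list(auc_1 = cmp$auc_1, auc_2 = cmp$auc_2,
                                         statistic = cmp$statistic,
                                         p_value = cmp$p_value)
  }
  if (!is.null(report$adherence)) {
    write_table(report$adherence$profiles, od("adherence.csv"))
    for (ap in names(report$adherence$comparisons)) {
      gc <- report$adherence$comparisons[[ap]]
      if (is.null(gc)) next
      comparison_json$adherence[[ap]] <- list(
        auc_higher = gc$comparison$auc_1, auc_lower = gc$comparison$auc_2,
        statistic = gc$comparison$statistic,
        p_value = gc$comparison$p_value,
        n_obs_higher = gc$higher$n_obs, n_obs_lower = gc$lower$n_obs)
    }
  }
  .write_json(comparison_json, od("comparison.json"))
  writeLines(.summary_lines(report), od("summary.txt"))
  invisible(report)
}

.summary_lines <- function(report) {
  lines <- c(
    "Depression screening pipeline summary",
    sprintf("config hash: %s   seed: %d", report$provenance$config_hash,
            report$provenance$seed),
    if (report$config$exclude_same_day)
      "subsample: robustness subsample excluding same-day ratings",
    "")
  for (ap in names(report$per_approach)) {
    pa <- report$per_approach[[ap]]
    lines <- c(lines, sprintf(
      "%-9s approach: AUC %.4f on %d observations (%d patients)%s",
      ap, pa$roc$auc, pa$fit$n_obs, pa$fit$n_patients,
      if (!is.null(pa$cv)) sprintf("; pooled CV AUC %.4f", pa$cv$pooled_auc)
      else ""))
    if (!is.null(pa$cutoffs)) {
      lines <- c(lines, sprintf("          cut-offs: sleep %d, mood %d, anxiety %d",
                                pa$cutoffs$sleep, pa$cutoffs$mood,
                                pa$cutoffs$anxiety))
    }
  }
  for (nm in names(report$paired)) {
    cmp <- report$paired[[nm]]
    lines <- c(lines, sprintf(
      "%s: AUC %.4f vs %.4f, chi-square(1) = %.3f, P = %.4g",
      gsub("_", " ", nm), cmp$auc_1, cmp$auc_2, cmp$statistic, cmp$p_value))
  }
  if (!is.null(report$adherence)) {
    for (ap in names(report$adherence$comparisons)) {
      gc <- report$adherence$comparisons[[ap]]
      if (is.null(gc)) next
      lines <- c(lines, sprintf(
        "adherence (%s): higher AUC %.4f (n=%d) vs lower %.4f (n=%d), P = %.4g",
        ap, gc$comparison$auc_1, gc$higher$n_obs, gc$comparison$auc_2,
        gc$lower$n_obs, gc$comparison$p_value))
    }
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(paste(.summary_lines(x), collapse = "\n"), "\n")
  invisible(x)
}
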