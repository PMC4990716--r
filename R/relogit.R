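#' Design for a random-intercept logistic panel model
#'
#' @param outcome binary outcome vector (one element per patient-window).
#' @param predictors numeric matrix or data frame of indicator values; an
#'   intercept column is added by [fit_relogit()], do not include one.
#' @param group patient identifier per row.
#' @return list of class `"panel_design"`.
#' @export
panel_design <- function(outcome, predictors, group) {
  predictors <- as.matrix(predictors)
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("x", seq_len(ncol(predictors)))
  }
  storage.mode(predictors) <- "double"
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(predictors) ||
      length(group) != nrow(predictors)) {
    stop("outcome, predictors and group must have equal length", call. = FALSE)
  }
  if (anyNA(outcome) || anyNA(predictors)) {
    stop("panel design must not contain missing values; drop incomplete ",
         "windows upstream", call. = FALSE)
  }
  if (!all(outcome %in% c(0L, 1L))) {
    stop("outcome must be binary", call. = FALSE)
  }
  structure(list(y = outcome, X = predictors, group = as.character(group)),
            class = "panel_design")
}

#' Design from an indicator table
#'
#' @param indicators output of [build_indicator_table()].
#' @param items predictor columns to use (default the three rating items).
#' @return a [panel_design()].
#' @export
design_from_indicators <- function(indicators,
                                   items = c("sleep", "mood", "anxiety")) {
  panel_design(indicators$depressed,
               as.matrix(indicators[, items, drop = FALSE]),
               indicators$patient_id)
}

# Marginal log-likelihood (and gradient) of the random-intercept logistic
# model by Gauss-Hermite quadrature. theta = (beta, log sigma_b). Change of
# variable b = sqrt(2) * sigma_b * z turns the Gaussian integral into
# sum_k w_k/sqrt(pi) * prod_t f(y_it | b_k).
.relogit_parts <- function(theta, y, Xi, gidx, gh, grad = FALSE) {
  p <- ncol(Xi)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1L])
  K <- length(gh$x)
  G <- max(gidx)
  eta0 <- drop(Xi %*% beta)
  b <- sqrt(2) * sigma * gh$x
  logw <- log(gh$w) - 0.5 * log(pi)

  A <- matrix(0, G, K)            # per-patient conditional loglik at node k
  R <- if (grad) matrix(0, G, K)  # per-patient sum of residuals at node k
  Gx <- if (grad) array(0, dim = c(G, K, p))
  for (k in seq_len(K)) {
    eta <- eta0 + b[k]
    ll <- plogis(ifelse(y == 1L, eta, -eta), log.p = TRUE)
    A[, k] <- rowsum(ll, gidx, reorder = TRUE)
    if (grad) {
      r <- y - plogis(eta)
      R[, k] <- rowsum(r, gidx, reorder = TRUE)
      Gx[, k, ] <- rowsum(r * Xi, gidx, reorder = TRUE)
    }
  }
  a <- sweep(A, 2L, logw, `+`)
  m <- apply(a, 1L, max)
  lse <- m + log(rowSums(exp(a - m)))
  out <- list(loglik = sum(lse))
  if (grad) {
    W <- exp(a - lse)             # posterior node weights per patient
    gbeta <- vapply(seq_len(p), function(j) sum(W * Gx[, , j]), numeric(1))
    glogsig <- sum(W * R * rep(b, each = G))
    out$gradient <- c(gbeta, glogsig)
  }
  out
}

#' Fit a random-intercept logistic panel model
#'
#' Maximum-likelihood estimation of
#' `P(y_it = 1 | b_i) = logistic(x_it' beta + b_i)`, `b_i ~ N(0, sigma_b^2)`,
#' where the patient-level intercept `b_i` absorbs unobserved heterogeneity.
#' The marginal likelihood integral over `b_i` is evaluated by (non-adaptive)
#' Gauss-Hermite quadrature; `sigma_b` is optimized on the log scale, and a
#' boundary estimate (`sigma_b -> 0`, where the model collapses to pooled
#' logistic regression) is reported as 0 with a message. The coefficient
#' covariance is the inverse observed information at the optimum.
#'
#' @param design a [panel_design()].
#' @param quad_points number of quadrature nodes (default 15).
#' @param start optional starting values `(beta, log sigma_b)`; defaults to
#'   the pooled logistic fit with `sigma_b = 0.5`.
#' @return object of class `"relogit_fit"`: `beta` (named, including
#'   `(Intercept)`), `sigma_b`, `loglik`, `vcov` (coefficients), `se`,
#'   `n_obs`, `n_patients`, `quad_points`, `converged`, plus the full-
#'   parameter covariance `vcov_full` (last entry on the `log sigma_b`
#'   scale).
#' @export
fit_relogit <- function(design, quad_points = 15L, start = NULL) {
  stopifnot(inherits(design, "panel_design"))
  y <- design$y
  Xi <- cbind(`(Intercept)` = 1, design$X)
  gfac <- factor(design$group)
  if (nlevels(gfac) < 2L) {
    stop("at least 2 patients are required (sigma_b is unidentifiable ",
         "from a single patient)", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  gidx <- as.integer(gfac)
  gh <- pracma::gaussHermite(quad_points)
  p <- ncol(Xi)

  if (is.null(start)) {
    b0 <- tryCatch(
      stats::glm.fit(Xi, y, family = stats::binomial())$coefficients,
      error = function(e) rep(0, p))
    b0[!is.finite(b0)] <- 0
    start <- c(b0, log(0.5))
  }

  negll <- function(th) -.relogit_parts(th, y, Xi, gidx, gh)$loglik
  neggr <- function(th) -.relogit_parts(th, y, Xi, gidx, gh, grad = TRUE)$gradient
  opt <- optim(start, negll, neggr, method = "L-BFGS-B",
               lower = c(rep(-Inf, p), log(1e-6)),
               upper = c(rep(Inf, p), log(50)),
               control = list(maxit = 500L), hessian = TRUE)

  theta <- unname(opt$par)
  beta <- setNames(theta[seq_len(p)], colnames(Xi))
  sigma_b <- exp(theta[p + 1L])
  converged <- opt$convergence == 0L
  if (max(abs(beta)) > 15) {
    converged <- FALSE
    warning("coefficients diverged (possible complete separation); ",
            "partial results returned", call. = FALSE)
  } else if (!converged) {
    warning("optimizer did not converge: ", opt$message, call. = FALSE)
  }
  boundary <- sigma_b < 1e-3
  if (boundary) {
    message("sigma_b estimated at the boundary; reported as 0 ",
            "(model collapses to pooled logistic regression)")
    sigma_b <- 0
  }

  vcov_full <- tryCatch(solve(opt$hessian),
                        error = function(e) matrix(NA_real_, p + 1L, p + 1L))
  if (boundary || anyNA(vcov_full) || any(diag(vcov_full) < 0)) {
    # information for log sigma_b degenerates at the boundary: invert the
    # beta block only
    vcov_beta <- tryCatch(solve(opt$hessian[seq_len(p), seq_len(p)]),
                          error = function(e) matrix(NA_real_, p, p))
  } else {
    vcov_beta <- vcov_full[seq_len(p), seq_len(p)]
  }
  dimnames(vcov_beta) <- list(colnames(Xi), colnames(Xi))

  structure(list(beta = beta, sigma_b = sigma_b, loglik = -opt$value,
                 vcov = vcov_beta, vcov_full = vcov_full,
                 se = sqrt(pmax(diag(vcov_beta), 0)),
                 n_obs = length(y), n_patients = nlevels(gfac),
                 quad_points = as.integer(quad_points),
                 converged = converged),
            class = "relogit_fit")
}

#' @export
print.relogit_fit <- function(x, ...) {
  cat("Random-intercept logistic panel model",
      sprintf("(%d obs, %d patients, %d quadrature nodes)\n",
              x$n_obs, x$n_patients, x$quad_points))
  tab <- cbind(estimate = x$beta, se = x$se,
               z = x$beta / x$se,
               p = 2 * stats::pnorm(-abs(x$beta / x$se)))
  print(round(tab, 4))
  cat(sprintf("sigma_b = %.4f   loglik = %.4f   converged = %s\n",
              x$sigma_b, x$loglik, x$converged))
  invisible(x)
}

#' Population-level predicted probabilities
#'
#' Evaluates `logistic(x' beta)` with the random intercept set to zero: the
#' prediction for a new patient, for whom no posterior of `b_i` exists. This
#' is the score fed to the ROC analysis.
#'
#' @param fit a [fit_relogit()] result.
#' @param predictors matrix or data frame whose columns match the fitted
#'   predictors (no intercept column).
#' @return probability vector.
#' @export
predict_prob <- function(fit, predictors) {
  stopifnot(inherits(fit, "relogit_fit"))
  X <- as.matrix(predictors)
  want <- names(fit$beta)[-1]
  if (ncol(X) != length(want)) {
    stop("predictor dimension mismatch: fit has ", length(want),
         " predictor(s), input has ", ncol(X), call. = FALSE)
  }
  if (!is.null(colnames(X)) && all(want %in% colnames(X))) {
    X <- X[, want, drop = FALSE]
  }
  plogis(drop(cbind(1, X) %*% fit$beta))
}

#' Multiplicative change in the odds of depression
#'
#' `exp(delta * beta_name)`: the factor by which the odds of being depressed
#' change when the named indicator increases by `delta` (e.g. `delta = 0.1`
#' for a one-tenth-unit increase of a ratio indicator), other indicators
#' held fixed.
#'
#' @param fit a [fit_relogit()] result, or a named coefficient vector.
#' @param predictor_name name of the predictor.
#' @param delta increase in the predictor.
#' @return the odds multiplier.
#' @export
odds_multiplier <- function(fit, predictor_name, delta) {
  beta <- if (inherits(fit, "relogit_fit")) fit$beta else fit
  if (!predictor_name %in% names(beta)) {
    stop("unknown predictor: '", predictor_name, "'", call. = FALSE)
  }
  exp(delta * beta[[predictor_name]])
}
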