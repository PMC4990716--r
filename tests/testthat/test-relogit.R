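test_that("with no patient heterogeneity the fit collapses to pooled logistic", {
  design <- simulate_panel(80, 6, beta = c(-1, 2, -1.5, 1), sigma_b = 0,
                           seed = 103)
  fit <- suppressMessages(fit_relogit(design))
  pooled <- stats::glm.fit(cbind(1, design$X), design$y,
                           family = stats::binomial())
  expect_equal(fit$sigma_b, 0)
  expect_equal(unname(fit$beta), unname(pooled$coefficients),
               tolerance = 1e-4)
  expect_equal(fit$loglik,
               sum(stats::dbinom(design$y, 1,
                                 plogis(drop(cbind(1, design$X) %*%
                                               pooled$coefficients)),
                                 log = TRUE)),
               tolerance = 1e-6)
})

test_that("the quadrature log-likelihood matches dense numerical integration", {
  # tiny fixture: 3 patients x 8 observations with mixed outcomes
  withr::local_seed(77)
  x <- round(runif(24), 2)
  eta <- -0.5 + 1.5 * x + rep(c(-0.5, 0, 0.5), each = 8)
  design <- panel_design(
    outcome = rbinom(24, 1, plogis(eta)),
    predictors = matrix(x, ncol = 1, dimnames = list(NULL, "x")),
    group = rep(c("a", "b", "c"), each = 8))
  fit <- suppressMessages(suppressWarnings(fit_relogit(design,
                                                       quad_points = 31)))

  brute_loglik <- function(beta, sigma) {
    total <- 0
    for (g in unique(design$group)) {
      idx <- design$group == g
      f <- function(b) {
        vapply(b, function(bb) {
          eta <- beta[1] + beta[2] * design$X[idx, 1] + bb
          prod(plogis(eta)^design$y[idx] *
                 (1 - plogis(eta))^(1 - design$y[idx])) *
            dnorm(bb, 0, sigma)
        }, numeric(1))
      }
      total <- total + log(integrate(f, -12 * sigma, 12 * sigma,
                                     rel.tol = 1e-12)$value)
    }
    total
  }
  # at the fitted optimum (if interior) and at fixed interior parameters
  sigma <- max(fit$sigma_b, 0.4)
  ll_quad <- moodscreen:::.relogit_parts(
    c(fit$beta, log(sigma)), design$y, cbind(1, design$X),
    as.integer(factor(design$group)), pracma::gaussHermite(31))$loglik
  expect_equal(ll_quad, brute_loglik(fit$beta, sigma), tolerance = 1e-6)

  theta0 <- c(-0.4, 1.2)
  ll_quad0 <- moodscreen:::.relogit_parts(
    c(theta0, log(0.8)), design$y, cbind(1, design$X),
    as.integer(factor(design$group)), pracma::gaussHermite(31))$loglik
  expect_equal(ll_quad0, brute_loglik(theta0, 0.8), tolerance = 1e-6)
})

test_that("the analytic gradient matches finite differences", {
  design <- simulate_panel(12, 4, beta = c(-0.5, 1.2, -0.8, 0.5),
                           sigma_b = 0.8, seed = 103)
  y <- design$y
  Xi <- cbind(1, design$X)
  gidx <- as.integer(factor(design$group))
  gh <- pracma::gaussHermite(15)
  theta <- c(-0.4, 1.0, -0.6, 0.4, log(0.7))
  got <- moodscreen:::.relogit_parts(theta, y, Xi, gidx, gh,
                                     grad = TRUE)$gradient
  f <- function(th) moodscreen:::.relogit_parts(th, y, Xi, gidx, gh)$loglik
  h <- 1e-6
  fd <- vapply(seq_along(theta), function(j) {
    e <- rep(0, length(theta)); e[j] <- h
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, numeric(1))
  expect_equal(got, fd, tolerance = 1e-5)
})

test_that("increasing quadrature nodes leaves the log-likelihood stable", {
  design <- simulate_panel(60, 8, beta = c(-1, 1.5, 1, -0.5), sigma_b = 1,
                           seed = 104)
  fit15 <- fit_relogit(design, quad_points = 15)
  ll31 <- moodscreen:::.relogit_parts(
    c(fit15$beta, log(fit15$sigma_b)), design$y, cbind(1, design$X),
    as.integer(factor(design$group)), pracma::gaussHermite(31))$loglik
  expect_lt(abs(fit15$loglik - ll31), 1e-4)
})

test_that("the likelihood is invariant to patient relabeling and row order", {
  design <- simulate_panel(30, 5, beta = c(-1, 2, 1, 0.5), sigma_b = 1,
                           seed = 105)
  fit <- fit_relogit(design)
  withr::local_seed(9)
  perm <- sample(length(design$y))
  relabel <- setNames(sample(sprintf("q%02d", 1:30)), unique(design$group))
  shuffled <- panel_design(design$y[perm], design$X[perm, ],
                           unname(relabel[design$group[perm]]))
  fit2 <- fit_relogit(shuffled)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-4)
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  design <- simulate_panel(100, 8, beta = c(-1, 2, 1.2, -0.8), sigma_b = 1,
                           seed = 106)
  fit <- fit_relogit(design, quad_points = 25)
  df <- data.frame(y = design$y, design$X, g = design$group)
  ref <- lme4::glmer(y ~ sleep + mood + anxiety + (1 | g), data = df,
                     family = stats::binomial(), nAGQ = 25L)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$sigma_b,
               sqrt(unname(unlist(lme4::VarCorr(ref)))), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
})

test_that("estimated sigma_b tracks the true heterogeneity", {
  taus <- c(0.2, 0.8, 1.6, 2.5)
  est <- vapply(seq_along(taus), function(i) {
    d <- simulate_panel(120, 8, beta = c(-1, 1.5, 1, 0.5), sigma_b = taus[i],
                        seed = 200 + i)
    suppressMessages(fit_relogit(d))$sigma_b
  }, numeric(1))
  expect_equal(order(est), seq_along(taus))
})

test_that("degenerate designs are rejected and separation is flagged", {
  expect_error(panel_design(c(1, 0), matrix(c(1, NA), ncol = 1), c("a", "b")),
               "missing")
  one_pat <- panel_design(c(1L, 0L), matrix(c(0.1, 0.9), ncol = 1),
                          c("a", "a"))
  expect_error(fit_relogit(one_pat), "2 patients")
  one_class <- panel_design(rep(1L, 4), matrix(runif(4), ncol = 1),
                            c("a", "a", "b", "b"))
  expect_error(fit_relogit(one_class), "both classes")
  # perfectly separated predictor
  sep <- panel_design(rep(c(0L, 1L), each = 10),
                      matrix(rep(c(0, 1), each = 10), ncol = 1,
                             dimnames = list(NULL, "x")),
                      rep(letters[1:10], 2))
  expect_warning(fit_sep <- suppressMessages(fit_relogit(sep)), "separation")
  expect_false(fit_sep$converged)
})

test_that("population-level predictions are the logistic of x'beta", {
  fit <- structure(list(beta = c(`(Intercept)` = -1.965, sleep = 2.722,
                                 mood = 1.783, anxiety = 1.782)),
                   class = "relogit_fit")
  p0 <- predict_prob(fit, matrix(0, 1, 3,
                                 dimnames = list(NULL,
                                                 c("sleep", "mood",
                                                   "anxiety"))))
  expect_equal(p0, plogis(-1.965), tolerance = 1e-12)
  # monotone in predictors with positive coefficients
  grid <- matrix(0, 5, 3, dimnames = list(NULL, c("sleep", "mood",
                                                  "anxiety")))
  grid[, 1] <- seq(0, 1, length.out = 5)
  expect_true(all(diff(predict_prob(fit, grid)) > 0))
  # beta = 0 gives 0.5 everywhere
  fit0 <- structure(list(beta = c(`(Intercept)` = 0, x = 0)),
                    class = "relogit_fit")
  expect_equal(predict_prob(fit0, matrix(runif(6), ncol = 1)), rep(0.5, 6))
  expect_error(predict_prob(fit, matrix(0, 1, 2)), "dimension mismatch")
})

test_that("odds multipliers are exp(delta * beta)", {
  beta <- c(`(Intercept)` = -1.965, sleep = 2.722, mood = 1.783)
  expect_equal(odds_multiplier(beta, "sleep", 0.1), exp(0.2722))
  expect_equal(odds_multiplier(beta, "sleep", 0), 1)
  expect_error(odds_multiplier(beta, "calm", 0.1), "unknown predictor")
})
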