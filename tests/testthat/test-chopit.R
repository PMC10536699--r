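make_params <- function(p = 2, J = 5, omega = 0.5, seed = 1) {
  set.seed(seed)
  gam <- rbind(c(-1.8, log(0.9), log(0.8), log(0.9)),
               matrix(stats::rnorm(4 * p, 0, 0.12), p))
  chopit_params(beta = stats::setNames(stats::rnorm(p, 0, 0.3), paste0("x", 1:p)),
                omega = omega, gamma = gam,
                theta = c(-1.5, -0.7, 0, 0.7, 1.5)[1:J] ,
                sigma = stats::runif(J, 0.8, 1.2),
                covariates = paste0("x", 1:p), levels = 1:J)
}

make_X <- function(n, p = 2, seed = 2) {
  set.seed(seed)
  X <- cbind(stats::rbinom(n, 1, 0.5), stats::rnorm(n),
             stats::rbinom(n, 1, 0.3), stats::runif(n))[, 1:p, drop = FALSE]
  colnames(X) <- paste0("x", 1:p)
  X
}

test_that("a symmetric threshold halves the probability mass", {
  # top threshold at 0, latent mean 0, no random effect: P(top category) = 1/2
  pars <- make_params(p = 1, J = 1, omega = 0)
  pars$beta[] <- 0
  pars$gamma <- matrix(0, 2, 4)
  pars$gamma[1, ] <- c(-3, 0, 0, 0)  # thresholds -3, -2, -1, 0
  dat <- chopit_frame(make_X(1, 1), y = 5L)
  expect_equal(chopit_loglik(pars, dat, "comm"), log(0.5), tolerance = 1e-10)
})

test_that("per-respondent category contributions are a distribution", {
  pars <- make_params(p = 2, J = 5, omega = 0.7)
  X <- make_X(1, 2)
  tot <- 0
  for (k in 1:5) {
    dat <- chopit_frame(X, y = k)
    tot <- tot + exp(chopit_loglik(pars, dat, "comm"))
  }
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("the analytic gradient matches finite differences", {
  pars <- make_params(p = 3, J = 4, omega = 0.5, seed = 7)
  X <- make_X(60, 3, seed = 8)
  dat <- simulate_chopit(pars, X, seed = 9)
  d <- anchormi:::chopit_prepare(dat, pars$covariates, "comm")
  gh <- pracma::gaussHermite(15)
  par <- anchormi:::chopit_pack(pars)
  ga <- attr(anchormi:::chopit_nll(par, d, gh, TRUE, TRUE), "gradient")
  gn <- anchormi:::fd_jacobian(function(x)
    as.numeric(anchormi:::chopit_nll(x, d, gh, TRUE, FALSE)), par, h = 1e-6)
  expect_lt(max(abs(ga - as.numeric(gn)) / (abs(ga) + 1)), 1e-6)
})

test_that("quadrature is stable in the number of nodes", {
  pars <- make_params(p = 2, J = 5, omega = 0.8, seed = 11)
  X <- make_X(120, 2, seed = 12)
  dat <- simulate_chopit(pars, X, seed = 13)
  l15 <- chopit_loglik(pars, dat, "comm", quadrature_nodes = 15)
  l31 <- chopit_loglik(pars, dat, "comm", quadrature_nodes = 31)
  expect_lt(abs(l15 - l31) / nrow(dat), 1e-4)
  expect_error(chopit_loglik(pars, dat, "comm", quadrature_nodes = 3), "at least 5")
  bad <- pars; bad$beta[1] <- Inf
  expect_error(chopit_loglik(bad, dat, "comm"), "non-finite")
})

test_that("quadrature equals the closed-form integral for the self component", {
  # one observation per respondent: the random-effect integral collapses to a
  # probit with inflated scale sqrt(1 + omega^2)
  pars <- make_params(p = 2, J = 5, omega = 0.6, seed = 14)
  X <- make_X(40, 2, seed = 15)
  dat <- simulate_chopit(pars, X, seed = 16)
  for (s in hsr_indicators()) for (l in 1:5) dat[[paste0("v_", s, "_", l)]] <- NA_integer_
  d <- anchormi:::chopit_prepare(dat, pars$covariates, "comm")
  thr <- thresholds_from_gamma(d$V, pars$gamma)
  mu <- drop(d$X %*% pars$beta)
  sc <- sqrt(1 + pars$omega^2)
  k <- d$y
  hi <- ifelse(k == 5, Inf, thr[cbind(seq_len(nrow(thr)), pmin(k, 4))])
  lo <- ifelse(k == 1, -Inf, thr[cbind(seq_len(nrow(thr)), pmax(k - 1, 1))])
  exact <- sum(log(stats::pnorm((hi - mu) / sc) - stats::pnorm((lo - mu) / sc)))
  expect_equal(chopit_loglik(pars, dat, "comm"), exact, tolerance = 1e-9)
})

test_that("predicted thresholds follow the linear/exponential construction", {
  set.seed(17)
  gam <- rbind(stats::rnorm(4), matrix(stats::rnorm(12, 0, 0.3), 3))
  V <- cbind(1, matrix(stats::rnorm(30), 10, 3))
  got <- thresholds_from_gamma(V, gam)
  for (i in 1:10) {
    t1 <- sum(gam[, 1] * V[i, ])
    t2 <- t1 + exp(sum(gam[, 2] * V[i, ]))
    t3 <- t2 + exp(sum(gam[, 3] * V[i, ]))
    t4 <- t3 + exp(sum(gam[, 4] * V[i, ]))
    expect_equal(unname(got[i, ]), c(t1, t2, t3, t4), tolerance = 1e-12)
    expect_true(all(diff(got[i, ]) > 0))
  }
  # zero slopes: everyone gets the intercept-implied thresholds
  gam0 <- gam; gam0[-1, ] <- 0
  g0 <- thresholds_from_gamma(V, gam0)
  expect_true(all(apply(g0, 2, function(cl) max(abs(cl - cl[1]))) < 1e-12))
  expect_error(thresholds_from_gamma(V[, 1:3], gam), "do not match")
})

test_that("the null slope is recovered and the MLE beats the truth", {
  pars <- make_params(p = 2, J = 5, omega = 0, seed = 18)
  pars$gamma[2, ] <- 0   # x1 has no threshold effect
  pars$beta[] <- c(0, 0.3)
  X <- make_X(1000, 2, seed = 19)
  dat <- simulate_chopit(pars, X, seed = 20)
  fit <- fit_chopit(dat, covariates = pars$covariates, indicator = "comm")
  expect_true(fit$convergence$converged)
  expect_gte(fit$loglik, chopit_loglik(pars, dat, "comm") - 1e-6)
  g_x1 <- fit$params$gamma["x1", ]
  se_x1 <- fit$se[grep("^gamma_x1", names(fit$se))]
  expect_true(all(abs(g_x1) < 3 * se_x1))
})

test_that("without vignettes the proportional fit is a plain ordered probit", {
  skip_if_not_installed("MASS")
  set.seed(21)
  n <- 400
  X <- make_X(n, 2, seed = 21)
  y <- as.integer(cut(drop(X %*% c(0.6, -0.4)) + stats::rnorm(n),
                      c(-Inf, -1.2, -0.3, 0.5, 1.4, Inf)))
  dat <- chopit_frame(X, y = y)
  fit <- fit_chopit(dat, covariates = colnames(X), indicator = "comm",
                    slopes = "proportional")
  pol <- MASS::polr(factor(y) ~ x1 + x2, data = data.frame(y = y, X),
                    method = "probit")
  expect_equal(fit$loglik, as.numeric(stats::logLik(pol)), tolerance = 1e-6)
  expect_equal(unname(fit$params$gamma[2:3, 1]), unname(-stats::coef(pol)),
               tolerance = 1e-4)
  thr <- cumsum(c(fit$params$gamma[1, 1], exp(fit$params$gamma[1, -1])))
  expect_equal(unname(thr), unname(pol$zeta), tolerance = 1e-4)
})

test_that("degenerate inputs fail informatively", {
  X <- make_X(30, 2)
  dat <- chopit_frame(X, y = rep(3L, 30))
  expect_error(fit_chopit(dat, covariates = colnames(X), indicator = "comm"),
               "2 observed categories")
  X2 <- cbind(X, x3 = X[, 1])
  dat2 <- chopit_frame(X2, y = rep(c(1L, 4L), 15))
  expect_error(fit_chopit(dat2, covariates = colnames(X2), indicator = "comm"),
               "rank deficient")
  dat3 <- chopit_frame(X, y = rep(c(1L, 4L), 15))
  expect_error(fit_chopit(dat3, covariates = colnames(X), indicator = "time"),
               "observations than parameters|2 observed categories")
})

test_that("threshold screening keeps real associations and drops constants", {
  set.seed(22)
  n <- 200
  dat <- simulate_survey(hsr_population(), n_per_group = c(english = n, arabic = n),
                         seed = 22)
  # a constant threshold variable is never selected
  thl <- data.frame(id = dat$id, indicator = "aut", k = 1, value = 1.7)
  scr <- screen_threshold_covariates(thl, dat, alpha = 0.05)
  expect_equal(nrow(scr$selected), 0)
  # a noisy copy of an indicator is selected overwhelmingly
  thl2 <- data.frame(id = dat$id, indicator = "comm", k = 2,
                     value = 0.8 * dat$y_comm + stats::rnorm(2 * n, 0, 0.6))
  scr2 <- screen_threshold_covariates(thl2, dat, alpha = 0.05)
  expect_equal(scr2$selected$threshold, "thr_comm_k2")
  expect_lt(min(scr2$paths$p[scr2$paths$target == "comm"]), 1e-10)
  expect_error(screen_threshold_covariates(thl2[0, ], dat), "no complete rows")
})

test_that("indicator-specific threshold DIF screens onto its own indicator", {
  # communication thresholds driven by insurance; no factor regression, so the
  # association can only flow through communication's own category use
  spec <- hsr_population()
  spec$factor_reg[] <- 0
  for (g in spec$groups) spec$gamma[[g]]$comm["insurance", ] <-
    spec$gamma[[g]]$comm["insurance", ] + 0.9
  dat <- simulate_survey(spec, n_per_group = c(english = 600, arabic = 600),
                         seed = 23)
  X <- anchormi:::encode_covariates(dat, c("gender", "age", "insurance"))
  V <- cbind(1, X)
  thl <- NULL
  for (s in c("comm", "aut")) {
    thr <- thresholds_from_gamma(V, spec$gamma$english[[s]])
    for (k in 1:4) thl <- rbind(thl, data.frame(id = dat$id, indicator = s,
                                                k = k, value = thr[, k]))
  }
  scr <- screen_threshold_covariates(thl, dat, alpha = 0.001)
  sel_comm <- scr$selected[scr$selected$indicator == "comm", ]
  expect_gt(nrow(sel_comm), 0)
  comm_paths <- scr$paths[scr$paths$threshold %in% sel_comm$threshold, ]
  expect_true("comm" %in% comm_paths$target)
})
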