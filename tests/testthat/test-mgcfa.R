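test_that("sample moments match hand arithmetic and duplicate-invariance", {
  d <- data.frame(group = "g", a = c(1, 2, 6, 3), b = c(2, 2, 5, 3),
                  cc = c(0, 1, 2, 1))
  m <- moments_from_data(d, c("a", "b", "cc"))$g
  expect_equal(m$n, 4)
  expect_equal(unname(m$mean), c(3, 3, 1))
  # divisor-n covariance by hand
  expect_equal(m$cov["a", "a"], mean((d$a - 3)^2))
  expect_equal(m$cov["a", "b"], mean((d$a - 3) * (d$b - 3)))
  d2 <- rbind(d, d)
  m2 <- moments_from_data(d2, c("a", "b", "cc"))$g
  expect_equal(m2$mean, m$mean)
  expect_equal(m2$cov, m$cov)
  expect_error(moments_from_data(d[1:3, ], c("a", "b", "cc")), "too few")
  d$b <- 1
  expect_error(moments_from_data(d, c("a", "b")), "zero-variance.*b")
})

test_that("large-sample moments approach the model-implied population values", {
  set.seed(41)
  lam <- c(0.8, 0.7, 0.6, 0.75)
  th <- c(0.36, 0.51, 0.64, 0.44)
  tau <- c(3.5, 4, 3.8, 4.2)
  n <- 1e5
  Y <- sim_cfa_group(n, lam, tau, th)
  d <- data.frame(group = "g", Y)
  m <- moments_from_data(d, names(d)[-1])$g
  pop <- tcrossprod(lam) + diag(th)
  se_mean <- sqrt(diag(pop) / n)
  expect_true(all(abs(m$mean - tau) < 4 * se_mean))
  expect_true(max(abs(m$cov - pop)) < 4 * max(pop) / sqrt(n) * 2)
})

test_that("population moments from known parameters are recovered exactly", {
  lam <- c(0.7, 0.85, 0.55, 0.75, 0.6, 0.8, 0.65)
  tau <- c(3.6, 4.2, 4.0, 3.8, 3.9, 3.7, 4.0)
  th <- c(0.5, 0.3, 0.6, 0.45, 0.55, 0.35, 0.6)
  p <- 7
  for (level in c("configural", "metric", "scalar")) {
    lam2 <- if (level == "configural") lam * 0.85 else lam
    tau2 <- if (level == "scalar") tau else tau + 0.15
    e1 <- implied_moments(lam, tau, th, n = 150, label = "g1")
    e2 <- implied_moments(lam2, tau2, th * 1.1, n = 90, label = "g2")
    moms <- as_group_moments(list(g1 = e1, g2 = e2), p)
    fit <- fit_mgcfa(cfa_model(paste0("v", 1:p), level = level), moms)
    expect_lt(fit$chisq, 1e-6)
    est <- fit$estimates
    lab1 <- if (level == "configural") paste0("lambda_v", 1:p, "_g1") else paste0("lambda_v", 1:p)
    expect_lt(max(abs(est[lab1] - lam)), 1e-5)
    tlab <- if (level == "scalar") paste0("tau_v", 1:p) else paste0("tau_v", 1:p, "_g1")
    expect_lt(max(abs(est[tlab] - tau)), 1e-5)
    expect_lt(max(abs(est[paste0("theta_v", 1:p, "_g1")] - th)), 1e-5)
  }
})

test_that("a just-identified single-group model fits perfectly with df 0", {
  e <- implied_moments(c(0.7, 0.8, 0.6), c(4, 4, 4), c(0.5, 0.4, 0.6),
                       n = 200, label = "g1")
  e$cov <- e$cov + diag(0.03, 3)  # any admissible 3x3 moments
  e$logdet <- determinant(e$cov)$modulus[1]
  moms <- as_group_moments(list(g1 = e), 3)
  fit <- fit_mgcfa(cfa_model(paste0("v", 1:3)), moms)
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 1e-6)
  expect_equal(fit$rmsea, 0)
  expect_match(fit$rmsea_flag, "df = 0")
})

test_that("degrees of freedom follow the closed-form count per model shape", {
  moms <- sim_cfa_moments(42)
  p <- 7; G <- 2
  count <- function(level, nrescov = 0, q = 0, npaths = 0) {
    npar <- switch(level, configural = G * (2 * p) + G * p,
                   metric = p + G * p + G * p,
                   scalar = p + p + G * p)
    npar <- npar + nrescov + G * npaths + G * (q * (q + 1) / 2 + q)
    G * ((p + q) * (p + q + 3) / 2) - npar
  }
  for (level in c("configural", "metric", "scalar")) {
    fit <- fit_mgcfa(cfa_model(paste0("y", 1:7), level = level), moms)
    expect_equal(fit$df, count(level))
  }
  fit <- fit_mgcfa(cfa_model(paste0("y", 1:7), rescov = list(c("y1", "y2"))), moms)
  expect_equal(fit$df, count("configural", nrescov = 1))
  # covariate model: q covariates, saturated among themselves, all paths free
  set.seed(43)
  d <- data.frame(group = rep(c("g1", "g2"), each = 150),
                  sim_cfa_group(300, rep(0.7, 7), rep(4, 7), rep(0.51, 7)))
  names(d)[-1] <- paste0("y", 1:7)
  d$x1 <- stats::rnorm(300); d$x2 <- stats::rbinom(300, 1, 0.4)
  fitc <- fit_covariate_model(cfa_model(paste0("y", 1:7), covariates = c("x1", "x2")), d)
  expect_equal(fitc$df, count("configural", q = 2, npaths = 14))
})

test_that("metric misfit on unequal-loading moments matches an independent optimizer", {
  lam <- c(0.7, 0.8, 0.6, 0.75)
  e1 <- implied_moments(lam, rep(4, 4), rep(0.5, 4), n = 150, label = "g1")
  e2 <- implied_moments(lam * c(0.5, 1, 1.2, 1), rep(4, 4), rep(0.5, 4),
                        n = 100, label = "g2")
  moms <- as_group_moments(list(g1 = e1, g2 = e2), 4)
  fit <- fit_mgcfa(cfa_model(paste0("v", 1:4), level = "metric"), moms)
  expect_gt(fit$chisq, 1)
  oracle <- oracle_min_chisq(moms, 4, "metric")
  expect_equal(fit$chisq, oracle, tolerance = 1e-4)
})

test_that("fit indices follow their defining formulas", {
  f <- list(chisq = 30, df = 30, G = 2, N = 300, logl = -1000, npar = 20,
            baseline = list(chisq = 500, df = 42))
  idx <- fit_indices(f)
  expect_equal(idx$cfi, 1)
  expect_equal(idx$rmsea, 0)
  expect_equal(idx$abic, 2000 + 20 * log(302 / 24))
  f2 <- list(chisq = 80, df = 30, G = 2, N = 300, logl = -1000, npar = 20,
             baseline = list(chisq = 1e6, df = 42))
  idx2 <- fit_indices(f2)
  expect_equal(idx2$cfi, 1 - 50 / (1e6 - 42))
  expect_equal(idx2$rmsea, sqrt(2) * sqrt(50 / (30 * 300)))
  f3 <- list(chisq = 0, df = 10, G = 1, N = 100, logl = -50, npar = 5,
             baseline = list(chisq = 1e6, df = 20))
  expect_equal(fit_indices(f3)$cfi, 1)
})

test_that("the chi-square difference test behaves at its reference points", {
  expect_equal(lrt_difference(list(chisq = 13.84, df = 5), list(chisq = 10, df = 4))$p,
               stats::pchisq(3.84, 1, lower.tail = FALSE))
  lt <- lrt_difference(list(chisq = 10, df = 5), list(chisq = 10, df = 4))
  expect_equal(lt$delta_chisq, 0)
  expect_equal(lt$p, 1)
  expect_error(lrt_difference(list(chisq = 10, df = 4), list(chisq = 9, df = 4)),
               "not nested")
  expect_warning(lrt_difference(list(chisq = 9, df = 5), list(chisq = 10, df = 4)),
                 "floored")
  # true constraints: metric adds no misfit on equal-group population moments
  lam <- c(0.7, 0.8, 0.6, 0.75, 0.66)
  e1 <- implied_moments(lam, rep(4, 5), rep(0.5, 5), n = 150, label = "g1")
  e2 <- implied_moments(lam, rep(4, 5), rep(0.5, 5), n = 100, label = "g2")
  moms <- as_group_moments(list(g1 = e1, g2 = e2), 5)
  fc <- fit_mgcfa(cfa_model(paste0("v", 1:5)), moms)
  fm <- fit_mgcfa(cfa_model(paste0("v", 1:5), level = "metric"), moms)
  expect_lt(lrt_difference(fm, fc)$delta_chisq, 1e-6)
})

test_that("modification indices find an omitted error covariance", {
  moms <- sim_cfa_moments(44, n = c(300, 300),
                          rescov = list(list(i = 2, j = 3, value = 0.17)))
  fit <- fit_mgcfa(cfa_model(paste0("y", 1:7)), moms)
  mi <- modification_indices(fit)
  expect_equal(sort(c(mi$a[1], mi$b[1])), c("y2", "y3"))
  expect_true(all(mi$mi >= 0))
  # score statistic approximates the refit chi-square drop
  refit <- fit_mgcfa(cfa_model(paste0("y", 1:7), rescov = list(c("y2", "y3"))), moms)
  dchi <- fit$chisq - refit$chisq
  expect_lt(abs(mi$mi[1] - dchi) / dchi, 0.15)
  # expected parameter change points toward the true value
  expect_gt(mi$epc[1], 0)
})

test_that("the invariance sequence supports all levels on no-DIF moments", {
  lam <- c(0.7, 0.8, 0.6, 0.75, 0.66, 0.7, 0.72)
  e1 <- implied_moments(lam, rep(4, 7), rep(0.5, 7), n = 150, label = "g1")
  e2 <- implied_moments(lam, rep(4, 7), rep(0.5, 7), n = 100, label = "g2")
  moms <- as_group_moments(list(g1 = e1, g2 = e2), 7)
  rep <- invariance_sequence(cfa_model(paste0("v", 1:7)), moms)
  expect_equal(rep$table$decision, rep("supported", 3))
  expect_true(all(diff(rep$table$chisq) >= -1e-8))  # nesting monotonicity
})

test_that("chi-square never decreases along the constraint sequence on data", {
  for (seed in 45:47) {
    moms <- sim_cfa_moments(seed, n = c(145, 91), lambda2 = rep(0.7, 7) * runif(7, 0.7, 1.3),
                            tau2 = rep(4, 7) + rnorm(7, 0, 0.2))
    rep <- invariance_sequence(cfa_model(paste0("y", 1:7)), moms, modify = FALSE)
    expect_true(all(diff(rep$table$chisq) >= -1e-8))
  }
})

test_that("zero covariate paths reduce to the plain model plus saturation", {
  lam <- c(0.7, 0.8, 0.6, 0.75, 0.66, 0.7, 0.72)
  # doctor joint moments so the indicator/covariate cross-block is exactly 0
  mk <- function(n, label, lamg) {
    e <- implied_moments(lamg, rep(4, 7), rep(0.5, 7), n = n, label = label)
    Sx <- matrix(c(1, 0.3, 0.3, 1), 2)
    S <- rbind(cbind(e$cov + 0.02 * diag(7), matrix(0, 7, 2)),
               cbind(matrix(0, 2, 7), Sx))
    list(label = label, n = n, mean = c(e$mean, 0.2, -0.1), cov = S,
         logdet = determinant(S)$modulus[1])
  }
  moms <- as_group_moments(list(g1 = mk(150, "g1", lam), g2 = mk(100, "g2", lam * 0.9)),
                           7, q = 2)
  momp <- as_group_moments(lapply(moms, function(m) {
    list(label = m$label, n = m$n, mean = m$mean[1:7],
         cov = m$cov[1:7, 1:7],
         logdet = determinant(m$cov[1:7, 1:7])$modulus[1])
  }), 7)
  no_paths <- data.frame(covariate = character(), indicator = character())
  mc <- cfa_model(paste0("v", 1:7), covariates = c("x1", "x2"),
                  gamma_paths = no_paths)
  fit_cov <- fit_mgcfa(mc, moms)
  fit_plain <- fit_mgcfa(cfa_model(paste0("v", 1:7)), momp)
  expect_equal(fit_cov$chisq, fit_plain$chisq, tolerance = 1e-5)
  l1 <- paste0("lambda_v", 1:7, "_g1")
  expect_equal(fit_cov$estimates[l1], fit_plain$estimates[l1], tolerance = 1e-5)
})

test_that("covariate regressions are recovered within three standard errors", {
  set.seed(48)
  n <- 1000
  gamma <- cbind(c(0.4, 0, 0.2, 0, 0.3, 0, 0.1), c(0, -0.3, 0, 0.25, 0, 0, 0))
  mk <- function(label) {
    X <- cbind(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.5))
    Y <- sim_cfa_group(n, rep(0.7, 7), rep(4, 7), rep(0.51, 7),
                       gamma = gamma, X = X)
    d <- data.frame(group = label, Y, X)
    names(d)[2:8] <- paste0("y", 1:7)
    d
  }
  d <- rbind(mk("g1"), mk("g2"))
  fit <- fit_covariate_model(cfa_model(paste0("y", 1:7), covariates = c("x1", "x2")),
                             d, se = TRUE)
  for (i in 1:7) for (j in 1:2) {
    lab <- paste0("gamma_x", j, "_y", i, "_g1")
    expect_lt(abs(fit$estimates[lab] - gamma[i, j]), 3.5 * fit$se[lab])
  }
  d$x3 <- d$x1 + d$x2
  expect_error(fit_covariate_model(cfa_model(paste0("y", 1:7),
                                             covariates = c("x1", "x2", "x3")), d),
               "collinear")
})

test_that("an irrelevant covariate leaves the loadings untouched", {
  lam <- c(0.7, 0.8, 0.6, 0.75, 0.66, 0.7, 0.72)
  e1 <- implied_moments(lam, rep(4, 7), rep(0.5, 7),
                        gamma = matrix(0, 7, 1), sx = matrix(1, 1, 1), mx = 0,
                        n = 500, label = "g1")
  e1$mean <- stats::setNames(e1$mean, c(paste0("v", 1:7), "x1"))
  moms <- as_group_moments(list(g1 = e1), 7, q = 1)
  fit <- fit_mgcfa(cfa_model(paste0("v", 1:7), covariates = "x1"), moms)
  expect_lt(max(abs(fit$estimates[paste0("lambda_v", 1:7, "_g1")] - lam)), 1e-3)
})

test_that("composite reliability follows the standardized closed form", {
  mkfit <- function(lambda, theta) {
    list(groups_est = list(g = list(Lambda = lambda, Theta = diag(theta, length(lambda)))))
  }
  expect_equal(as.numeric(composite_reliability(mkfit(rep(0, 7), rep(1, 7)))), 0)
  expect_equal(as.numeric(composite_reliability(mkfit(rep(1, 7), rep(0, 7)))), 1)
  w <- composite_reliability(mkfit(rep(0.7, 7), rep(0.51, 7)))
  expect_equal(as.numeric(w), 4.9^2 / (4.9^2 + 3.57), tolerance = 1e-12)
  heyw <- composite_reliability(mkfit(c(rep(0.7, 6), 1.1), c(rep(0.51, 6), -0.05)))
  expect_match(attr(heyw, "flag"), "Heywood")
})

test_that("a Heywood solution is flagged, not truncated", {
  lam <- c(0.9, 0.7, 0.6, 0.75)
  e <- implied_moments(lam, rep(4, 4), c(-0.04, 0.5, 0.6, 0.45), n = 300,
                       label = "g1")
  moms <- as_group_moments(list(g1 = e), 4)
  fit <- fit_mgcfa(cfa_model(paste0("v", 1:4)), moms)
  expect_true(fit$heywood)
  expect_lt(abs(fit$estimates["theta_v1_g1"] - (-0.04)), 1e-4)
})

test_that("the decision engine applies the configural and delta rules", {
  stats <- data.frame(level = c("configural", "metric"),
                      chisq = c(40, 50), df = c(28, 35),
                      cfi = c(0.96, 0.957), rmsea = c(0.06, 0.058),
                      delta_chisq = c(NA, 10), delta_df = c(NA, 7),
                      delta_cfi = c(NA, 0.003), delta_rmsea = c(NA, -0.002))
  out <- invariance_decisions(stats)
  expect_equal(out$decision, c("supported", "supported"))
  stats$delta_cfi[2] <- 0.006
  expect_equal(invariance_decisions(stats)$decision[2], "rejected")
  stats$delta_cfi[2] <- 0.003; stats$delta_chisq[2] <- 30
  expect_equal(invariance_decisions(stats)$decision[2], "rejected")
  # disabling the LRT rule changes the verdict
  expect_equal(invariance_decisions(stats, invariance_rules(use = c("cfi", "rmsea")))$decision[2],
               "supported")
  stats$cfi[1] <- 0.90
  expect_equal(invariance_decisions(stats)$decision[1], "rejected")
})
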