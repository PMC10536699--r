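# Independent oracles and small data builders used across the suite.

# Brute-force rescaling oracle: enumerates every candidate position of the
# self value among canonical strictly ordered anchor ranks and checks it
# against the observed relations (inversion-involved anchors carry no
# information; ties with consistently ordered anchors span their rank block).
oracle_rescale <- function(y, z, tol = 1e-9) {
  J <- length(z)
  viol <- rep(FALSE, J)
  if (J > 1) {
    for (j in 1:(J - 1)) for (k in (j + 1):J) {
      if (z[j] > z[k] + tol) viol[j] <- viol[k] <- TRUE
    }
  }
  tied <- which(!viol & abs(y - z) <= tol)
  feasible <- logical(2 * J + 1)
  for (cc in 1:(2 * J + 1)) {
    u <- if (cc %% 2 == 0) cc / 2 else (cc - 1) / 2 + 0.5
    ok <- TRUE
    for (j in 1:J) {
      if (viol[j]) next
      if (abs(y - z[j]) <= tol) {
        if (u < min(tied) || u > max(tied)) ok <- FALSE
      } else if (y > z[j]) {
        if (!(u > j)) ok <- FALSE
      } else {
        if (!(u < j)) ok <- FALSE
      }
    }
    feasible[cc] <- ok
  }
  which(feasible)
}

# Continuous two-group CFA data generator (normal indicators; optional
# correlated errors and covariate effects) for MGCFA-level studies that do
# not need the ordinal survey machinery.
sim_cfa_group <- function(n, lambda, tau, theta_diag, rescov = NULL,
                          gamma = NULL, X = NULL) {
  p <- length(lambda)
  Th <- diag(theta_diag, p)
  if (!is.null(rescov)) {
    for (rc in rescov) {
      Th[rc$i, rc$j] <- Th[rc$j, rc$i] <- rc$value
    }
  }
  eta <- stats::rnorm(n)
  E <- matrix(stats::rnorm(n * p), n, p) %*% chol(Th)
  Y <- matrix(tau, n, p, byrow = TRUE) + outer(eta, lambda) + E
  if (!is.null(gamma)) Y <- Y + X %*% t(gamma)
  Y
}

sim_cfa_moments <- function(seed, n = c(200, 200), lambda = rep(0.7, 7),
                            tau = rep(4, 7), theta_diag = rep(0.51, 7),
                            lambda2 = lambda, tau2 = tau, rescov = NULL,
                            prefix = "y") {
  set.seed(seed)
  p <- length(lambda)
  Y1 <- sim_cfa_group(n[1], lambda, tau, theta_diag, rescov)
  Y2 <- sim_cfa_group(n[2], lambda2, tau2, theta_diag, rescov)
  d <- data.frame(group = rep(c("g1", "g2"), n), rbind(Y1, Y2))
  names(d)[-1] <- paste0(prefix, seq_len(p))
  moments_from_data(d, paste0(prefix, seq_len(p)))
}

# Independent multi-group ML discrepancy (re-derived from the Wishart
# likelihood) + generic optimizer: used to cross-check fit_mgcfa minima.
oracle_discrepancy <- function(par, moms, p, level) {
  G <- length(moms)
  N <- sum(vapply(moms, function(m) m$n, numeric(1)))
  # parameter layout: per group loadings (shared if metric+), intercepts,
  # residual variances
  idx <- 0
  lam <- list(); tau <- list(); th <- list()
  if (level == "configural") {
    for (g in 1:G) { lam[[g]] <- par[idx + 1:p]; idx <- idx + p }
  } else {
    l <- par[idx + 1:p]; idx <- idx + p
    for (g in 1:G) lam[[g]] <- l
  }
  for (g in 1:G) { tau[[g]] <- par[idx + 1:p]; idx <- idx + p }
  for (g in 1:G) { th[[g]] <- par[idx + 1:p]; idx <- idx + p }
  total <- 0
  for (g in 1:G) {
    Sig <- tcrossprod(lam[[g]]) + diag(th[[g]], p)
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) return(1e10)
    Si <- solve(Sig)
    S <- moms[[g]]$cov
    d <- moms[[g]]$mean - tau[[g]]
    total <- total + moms[[g]]$n / N *
      (determinant(Sig)$modulus[1] + sum(diag(S %*% Si)) - moms[[g]]$logdet - p +
         drop(t(d) %*% Si %*% d))
  }
  total
}

oracle_min_chisq <- function(moms, p, level, nstart = 5, seed = 99) {
  set.seed(seed)
  G <- length(moms)
  N <- sum(vapply(moms, function(m) m$n, numeric(1)))
  nlam <- if (level == "configural") G * p else p
  best <- Inf
  for (s in 1:nstart) {
    lam0 <- rep(0.7, nlam) + stats::rnorm(nlam, 0, 0.1 * (s > 1))
    tau0 <- unlist(lapply(moms, function(m) m$mean[1:p]))
    th0 <- unlist(lapply(moms, function(m) pmax(diag(m$cov)[1:p] * 0.5, 0.05)))
    par0 <- c(lam0, tau0, th0)
    f <- function(x) oracle_discrepancy(x, moms, p, level)
    o <- stats::optim(par0, f, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    o <- stats::optim(o$par, f, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  (N - G) * best
}

# group_moments wrapper around implied_moments entries
as_group_moments <- function(entries, p, q = 0) {
  structure(entries, class = "group_moments",
            vars = names(entries[[1]]$mean) %||% paste0("v", seq_len(p + q)),
            p = as.integer(p), q = as.integer(q))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-indicator survey container for CHOPIT-level tests
chopit_frame <- function(X, y = NULL, indicator = "comm") {
  n <- nrow(X)
  dat <- data.frame(id = seq_len(n), group = "pop", X, check.names = FALSE)
  for (s in hsr_indicators()) dat[[paste0("y_", s)]] <- NA_integer_
  if (!is.null(y)) dat[[paste0("y_", indicator)]] <- y
  for (s in hsr_indicators()) for (l in 1:5) dat[[paste0("v_", s, "_", l)]] <- NA_integer_
  attr(dat, "indicators") <- hsr_indicators()
  attr(dat, "groups") <- "pop"
  class(dat) <- c("survey_dataset", "data.frame")
  dat
}
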