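#' Specify a one-factor multi-group CFA model
#'
#' One latent variable measured by `indicators`, identified by fixing the
#' factor mean to 0 and variance to 1 in every group, so that all loadings and
#' intercepts are estimated and can be constrained across groups. Optional
#' correlated errors, and optional manifest covariates regressed on the
#' indicators (covariate model): covariates are exogenous, correlated among
#' themselves, saturated in their own moments and uncorrelated with the
#' factor — no second latent variable stands behind them.
#'
#' @param indicators column names of the indicators.
#' @param covariates column names of manifest covariates (numeric columns).
#' @param rescov list of indicator pairs with correlated errors.
#' @param gamma_paths `"all"` for every covariate-indicator regression, or a
#'   data frame with columns `covariate`, `indicator` restricting the paths.
#' @param level constraint level: `"configural"` (no cross-group equalities),
#'   `"metric"` (equal loadings), `"scalar"` (equal loadings and intercepts).
#' @param rescov_group_equal hold added error covariances equal across groups
#'   (the convention used for modification-guided additions).
#' @param gamma_group_equal hold covariate regressions equal across groups.
#' @return object of class `cfa_model`.
#' @export
cfa_model <- function(indicators, covariates = character(0), rescov = list(),
                      gamma_paths = "all",
                      level = c("configural", "metric", "scalar"),
                      rescov_group_equal = TRUE, gamma_group_equal = FALSE) {
  level <- match.arg(level)
  for (pr in rescov) {
    assert_that(length(pr) == 2 && all(pr %in% indicators),
                "error-covariance pair must name two indicators")
  }
  structure(list(indicators = indicators, covariates = covariates,
                 rescov = rescov, gamma_paths = gamma_paths, level = level,
                 rescov_group_equal = rescov_group_equal,
                 gamma_group_equal = gamma_group_equal),
            class = "cfa_model")
}

#' Per-group sample moments
#'
#' Listwise-complete means and covariances (divisor n) of the indicator and
#' covariate columns, per group — the sufficient statistics of the
#' normal-theory multi-group likelihood.
#'
#' @param data data frame with a group column and numeric indicator/covariate
#'   columns.
#' @param indicators indicator column names.
#' @param covariates optional covariate column names (appended after the
#'   indicators in the moment matrices).
#' @param group_col name of the group column.
#' @return object of class `group_moments`: per group `label`, `n`, `mean`,
#'   `cov`, `logdet`.
#' @export
moments_from_data <- function(data, indicators, covariates = NULL,
                              group_col = "group") {
  vars <- c(indicators, covariates)
  assert_that(all(vars %in% names(data)), "missing columns: ",
              paste(setdiff(vars, names(data)), collapse = ", "))
  out <- list()
  for (g in unique(data[[group_col]])) {
    sub <- data[data[[group_col]] == g, vars, drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    n <- nrow(sub)
    if (n < length(vars) + 1) {
      stop("group ", g, " has too few complete rows (", n, ") for ",
           length(vars), " variables")
    }
    M <- as.matrix(sub)
    mu <- colMeans(M)
    S <- crossprod(sweep(M, 2, mu)) / n
    zv <- which(diag(S) < 1e-12)
    if (length(zv)) stop("zero-variance column in group ", g, ": ",
                         paste(vars[zv], collapse = ", "))
    out[[as.character(g)]] <- list(label = as.character(g), n = n, mean = mu,
                                   cov = S, logdet = determinant(S)$modulus[1])
  }
  structure(out, class = "group_moments", vars = vars,
            p = length(indicators), q = length(covariates %||% character(0)))
}

#' Population moments implied by CFA parameters
#'
#' @param lambda loadings; @param tau intercepts; @param theta residual
#'   covariance matrix (or vector of variances); @param gamma optional p x q
#'   covariate regression matrix; @param sx,mx covariate covariance and mean.
#' @param n pseudo sample size attached to the moments.
#' @param label group label.
#' @return a single-group entry usable inside a `group_moments` list.
#' @export
implied_moments <- function(lambda, tau, theta, gamma = NULL, sx = NULL,
                            mx = NULL, n = 1e6, label = "g1") {
  p <- length(lambda)
  Th <- if (is.matrix(theta)) theta else diag(theta, p)
  Sigma <- tcrossprod(lambda) + Th
  mu <- tau
  if (!is.null(gamma)) {
    Sigma <- Sigma + gamma %*% sx %*% t(gamma)
    Sigma <- rbind(cbind(Sigma, gamma %*% sx), cbind(sx %*% t(gamma), sx))
    mu <- c(tau + drop(gamma %*% mx), mx)
  }
  list(label = label, n = n, mean = mu, cov = Sigma,
       logdet = determinant(Sigma)$modulus[1])
}

# ---- parameter table ------------------------------------------------------

build_partable <- function(model, moms) {
  p <- length(model$indicators); q <- length(model$covariates)
  G <- length(moms)
  inds <- model$indicators; covs <- model$covariates
  rows <- list()
  add <- function(group, type, i, j, label, value, free = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(group = group, type = type,
                                             i = i, j = j, label = label,
                                             value = value, free = free,
                                             stringsAsFactors = FALSE)
  }
  for (g in seq_len(G)) {
    S <- moms[[g]]$cov[seq_len(p), seq_len(p), drop = FALSE]
    m <- moms[[g]]$mean[seq_len(p)]
    lam0 <- rowSums(S) / sqrt(max(sum(S), 1e-8))
    lam0 <- sign(lam0 + 1e-12) * pmax(abs(lam0), 0.1)
    th0 <- pmax(diag(S) - lam0^2, 0.05 * diag(S))
    for (i in seq_len(p)) {
      llab <- if (model$level %in% c("metric", "scalar")) paste0("lambda_", inds[i])
              else paste0("lambda_", inds[i], "_g", g)
      tlab <- if (model$level == "scalar") paste0("tau_", inds[i])
              else paste0("tau_", inds[i], "_g", g)
      add(g, "lambda", i, 0L, llab, lam0[i])
      add(g, "tau", i, 0L, tlab, m[i])
      add(g, "theta", i, 0L, paste0("theta_", inds[i], "_g", g), th0[i])
    }
    for (pr in model$rescov) {
      i <- match(pr[1], inds); j <- match(pr[2], inds)
      lab <- if (model$rescov_group_equal) paste0("thcov_", pr[1], "_", pr[2])
             else paste0("thcov_", pr[1], "_", pr[2], "_g", g)
      add(g, "thcov", i, j, lab, 0)
    }
    if (q > 0) {
      Sx <- moms[[g]]$cov[p + seq_len(q), p + seq_len(q), drop = FALSE]
      mx <- moms[[g]]$mean[p + seq_len(q)]
      paths <- model$gamma_paths
      if (identical(paths, "all")) {
        paths <- expand.grid(covariate = covs, indicator = inds,
                             stringsAsFactors = FALSE)
      }
      for (r in seq_len(nrow(paths))) {
        i <- match(paths$indicator[r], inds); a <- match(paths$covariate[r], covs)
        lab <- if (model$gamma_group_equal)
          paste0("gamma_", paths$covariate[r], "_", paths$indicator[r])
        else paste0("gamma_", paths$covariate[r], "_", paths$indicator[r], "_g", g)
        add(g, "gamma", i, a, lab, 0)
      }
      for (a in seq_len(q)) for (b in a:q) {
        add(g, "xcov", a, b, paste0("xcov_", covs[a], "_", covs[b], "_g", g),
            Sx[a, b])
      }
      for (a in seq_len(q)) {
        add(g, "xmean", a, 0L, paste0("xmean_", covs[a], "_g", g), mx[a])
      }
    }
  }
  pt <- do.call(rbind, rows)
  rownames(pt) <- NULL
  pt
}

partable_start <- function(pt) {
  labs <- unique(pt$label[pt$free])
  sapply(labs, function(l) mean(pt$value[pt$label == l]))
}

# assemble per-group matrices from a parameter vector
assemble_group <- function(par, pt, model, g, p, q) {
  val <- function(rowsel) {
    ifelse(pt$free[rowsel], par[pt$label[rowsel]], pt$value[rowsel])
  }
  sel <- pt$group == g
  Lambda <- numeric(p); tau <- numeric(p); Theta <- matrix(0, p, p)
  Gamma <- if (q) matrix(0, p, q) else NULL
  Sx <- if (q) matrix(0, q, q) else NULL
  mx <- if (q) numeric(q) else NULL
  for (r in which(sel)) {
    v <- if (pt$free[r]) par[[pt$label[r]]] else pt$value[r]
    switch(pt$type[r],
      lambda = { Lambda[pt$i[r]] <- Lambda[pt$i[r]] + v },
      lambda_dev = { Lambda[pt$i[r]] <- Lambda[pt$i[r]] + v },
      tau = { tau[pt$i[r]] <- tau[pt$i[r]] + v },
      tau_dev = { tau[pt$i[r]] <- tau[pt$i[r]] + v },
      theta = { Theta[pt$i[r], pt$i[r]] <- v },
      thcov = { Theta[pt$i[r], pt$j[r]] <- v; Theta[pt$j[r], pt$i[r]] <- v },
      gamma = { Gamma[pt$i[r], pt$j[r]] <- v },
      xcov = { Sx[pt$i[r], pt$j[r]] <- v; Sx[pt$j[r], pt$i[r]] <- v },
      xmean = { mx[pt$i[r]] <- v }
    )
  }
  Sigma <- tcrossprod(Lambda) + Theta
  mu <- tau
  if (q) {
    Sigma <- Sigma + Gamma %*% Sx %*% t(Gamma)
    Sigma <- rbind(cbind(Sigma, Gamma %*% Sx), cbind(Sx %*% t(Gamma), Sx))
    mu <- c(tau + drop(Gamma %*% mx), mx)
  }
  list(Lambda = Lambda, tau = tau, Theta = Theta, Gamma = Gamma,
       Sx = Sx, mx = mx, Sigma = Sigma, mu = mu)
}

# multi-group ML discrepancy and analytic gradient over labeled parameters
mgcfa_objective <- function(par, pt, model, moms, want_grad = FALSE,
                            extra_labels = character(0)) {
  p <- attr(moms, "p"); q <- attr(moms, "q"); G <- length(moms)
  N <- sum(vapply(moms, function(m) m$n, numeric(1)))
  labs <- unique(c(pt$label[pt$free], extra_labels))
  F <- 0
  grad <- if (want_grad) stats::setNames(numeric(length(labs)), labs) else NULL
  for (g in seq_len(G)) {
    ag <- assemble_group(par, pt, model, g, p, q)
    P <- p + q
    ch <- tryCatch(chol(ag$Sigma), error = function(e) NULL)
    if (is.null(ch) || min(diag(ch)) < 1e-6) {
      # outside the admissible region: flat penalty plateau
      F <- 1e10
      if (want_grad) return(structure(F, gradient = 0 * grad))
      return(F)
    }
    Si <- chol2inv(ch)
    S <- moms[[g]]$cov
    d <- moms[[g]]$mean - ag$mu
    w <- moms[[g]]$n / N
    ldS <- 2 * sum(log(diag(ch)))
    SiS <- Si %*% S
    b <- drop(Si %*% d)
    F <- F + w * (ldS + sum(diag(SiS)) - moms[[g]]$logdet - P + sum(d * b))
    if (want_grad) {
      W <- w * (Si - SiS %*% Si - tcrossprod(b))
      v <- w * (-2 * b)
      sel <- which(pt$group == g & (pt$free | pt$label %in% extra_labels))
      for (r in sel) {
        lab <- pt$label[r]
        if (!(lab %in% labs)) next
        ty <- pt$type[r]; i <- pt$i[r]; j <- pt$j[r]
        gcontrib <- switch(ty,
          lambda = 2 * sum(W[i, seq_len(p)] * ag$Lambda),
          lambda_dev = 2 * sum(W[i, seq_len(p)] * ag$Lambda),
          tau = v[i],
          tau_dev = v[i],
          theta = W[i, i],
          thcov = 2 * W[i, j],
          gamma = {
            r1 <- drop(ag$Gamma %*% ag$Sx[, j])
            2 * sum(W[i, seq_len(p)] * r1) + 2 * sum(W[i, p + seq_len(q)] * ag$Sx[j, ]) +
              v[i] * ag$mx[j]
          },
          xcov = {
            a <- i; bb <- j
            GA <- ag$Gamma[, a]; GB <- ag$Gamma[, bb]
            WYY <- W[seq_len(p), seq_len(p), drop = FALSE]
            Wyx <- W[seq_len(p), p + seq_len(q), drop = FALSE]
            Wxx <- W[p + seq_len(q), p + seq_len(q), drop = FALSE]
            if (a == bb) {
              sum(GA * drop(WYY %*% GA)) + 2 * sum(Wyx[, a] * GA) + Wxx[a, a]
            } else {
              2 * sum(GA * drop(WYY %*% GB)) +
                2 * (sum(Wyx[, bb] * GA) + sum(Wyx[, a] * GB)) +
                2 * Wxx[a, bb]
            }
          },
          xmean = {
            sum(v[seq_len(p)] * ag$Gamma[, i]) + v[p + i]
          }
        )
        grad[lab] <- grad[lab] + gcontrib
      }
    }
  }
  if (want_grad) {
    if (any(!is.finite(grad))) {
      F <- 1e10
      grad <- 0 * grad
    }
    attr(F, "gradient") <- grad
  }
  F
}

baseline_stats <- function(moms) {
  P <- attr(moms, "p") + attr(moms, "q")
  N <- sum(vapply(moms, function(m) m$n, numeric(1)))
  G <- length(moms)
  F <- 0
  for (g in seq_len(G)) {
    w <- moms[[g]]$n / N
    F <- F + w * (sum(log(diag(moms[[g]]$cov))) - moms[[g]]$logdet)
  }
  list(chisq = (N - G) * F, df = G * (P * (P + 3) / 2 - 2 * P))
}

#' Fit a multi-group CFA by maximum likelihood
#'
#' Minimizes the multi-group normal-theory discrepancy
#' `F = sum_g (n_g/N) * (log|Sigma_g| + tr(S_g Sigma_g^-1) - log|S_g| - P
#' + (m_g - mu_g)' Sigma_g^-1 (m_g - mu_g))`
#' over the free parameters with the cross-group equality constraints implied
#' by the model's level (metric: equal loadings; scalar: equal loadings and
#' intercepts). The chi-square statistic uses the `(N - G) * F_min`
#' convention; the CFI baseline is the per-group independence model with free
#' means and variances; RMSEA uses the multi-group `sqrt(G)` convention; the
#' sample-size-adjusted BIC penalizes with `log((N + 2) / 24)`. These
#' conventions are recorded in the returned object because SEM software
#' differs on each of them.
#'
#' @param model a [cfa_model()].
#' @param groups a `group_moments` object from [moments_from_data()] or
#'   [implied_moments()] entries.
#' @param tol relative convergence tolerance of the quasi-Newton minimizer.
#' @param se compute standard errors from the numerically differentiated
#'   information (slower; off by default).
#' @return object of class `mgcfa_fit` with the labeled estimates, `chisq`,
#'   `df`, `pvalue`, `cfi`, `rmsea`, `abic`, `logl`, convergence diagnostics
#'   and Heywood flags.
#' @export
fit_mgcfa <- function(model, groups, tol = 1e-8, se = FALSE) {
  moms <- groups
  p <- attr(moms, "p"); q <- attr(moms, "q"); G <- length(moms)
  assert_that(p == length(model$indicators), "moments do not match model indicators")
  assert_that(q == length(model$covariates), "moments do not match model covariates")
  N <- sum(vapply(moms, function(m) m$n, numeric(1)))
  pt <- build_partable(model, moms)
  par0 <- partable_start(pt)
  nmoments <- G * ((p + q) * (p + q + 3) / 2)
  df <- nmoments - length(par0)
  if (df < 0) stop("model not identified: ", length(par0),
                   " free parameters for ", nmoments, " moments")

  obj <- function(x) {
    names(x) <- names(par0)
    as.numeric(mgcfa_objective(x, pt, model, moms))
  }
  grfun <- function(x) {
    names(x) <- names(par0)
    attr(mgcfa_objective(x, pt, model, moms, want_grad = TRUE), "gradient")
  }
  opt <- stats::nlminb(par0, obj, gradient = grfun,
                       control = list(rel.tol = tol, iter.max = 2000,
                                      eval.max = 4000))
  est <- opt$par; names(est) <- names(par0)
  gnorm <- max(abs(grfun(est)))
  Fmin <- opt$objective
  chisq <- max((N - G) * Fmin, 0)
  pvalue <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_

  logl <- 0
  heywood <- FALSE
  groups_est <- list()
  for (g in seq_len(G)) {
    ag <- assemble_group(est, pt, model, g, p, q)
    groups_est[[moms[[g]]$label]] <- ag
    Si <- chol2inv(chol(ag$Sigma))
    d <- moms[[g]]$mean - ag$mu
    logl <- logl - moms[[g]]$n / 2 *
      (determinant(ag$Sigma)$modulus[1] + sum(diag(moms[[g]]$cov %*% Si)) +
         drop(t(d) %*% Si %*% d) + (p + q) * log(2 * pi))
    if (any(diag(ag$Theta) < 0)) heywood <- TRUE
  }
  base <- baseline_stats(moms)
  fit <- structure(list(
    model = model, moments = moms, partable = pt, estimates = est,
    chisq = chisq, df = df, pvalue = pvalue, Fmin = Fmin, logl = as.numeric(logl),
    npar = length(est), N = N, G = G,
    ns = vapply(moms, function(m) m$n, numeric(1)),
    baseline = base, groups_est = groups_est, heywood = heywood,
    convergence = list(converged = opt$convergence == 0 || gnorm < 1e-4,
                      code = opt$convergence, message = opt$message,
                      grad_norm = gnorm),
    conventions = c(chisq = "(N-G)*Fmin", baseline = "per-group independence, free means/variances",
                    rmsea = "sqrt(G)*sqrt(max(chisq-df,0)/(df*N))",
                    abic = "-2logL + npar*log((N+2)/24)")
  ), class = "mgcfa_fit")
  idx <- fit_indices(fit, base)
  fit$cfi <- idx$cfi; fit$rmsea <- idx$rmsea; fit$abic <- idx$abic
  fit$rmsea_flag <- idx$flag
  if (se) {
    qfun <- function(x) (N - G) * grfun(x)
    H <- fd_jacobian(qfun, est)
    H <- (H + t(H)) / 2
    vc <- tryCatch(2 * solve(H), error = function(e) matrix(NA_real_, length(est), length(est)))
    dimnames(vc) <- list(names(est), names(est))
    fit$vcov <- vc
    fit$se <- sqrt(pmax(diag(vc), 0))
  }
  fit
}

#' Fit indices from chi-square statistics
#'
#' `CFI = 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)`;
#' `RMSEA = sqrt(G) * sqrt(max(chisq - df, 0) / (df * N))` (0 with a flag when
#' `df = 0`); `aBIC = -2 logL + npar * log((N + 2) / 24)`.
#'
#' @param fit an `mgcfa_fit` (or list with `chisq`, `df`, `logl`, `npar`,
#'   `N`, `G`).
#' @param baseline the baseline (independence) model's `chisq` and `df`.
#' @return list with `cfi`, `rmsea`, `abic`, `flag`.
#' @export
fit_indices <- function(fit, baseline = fit$baseline) {
  num <- max(fit$chisq - fit$df, 0)
  den <- max(baseline$chisq - baseline$df, fit$chisq - fit$df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  flag <- NULL
  if (fit$df > 0) {
    rmsea <- sqrt(fit$G) * sqrt(num / (fit$df * fit$N))
  } else {
    rmsea <- 0
    flag <- "df = 0: RMSEA undefined, reported as 0"
  }
  abic <- -2 * fit$logl + fit$npar * log((fit$N + 2) / 24)
  list(cfi = cfi, rmsea = rmsea, abic = abic, flag = flag)
}

#' Likelihood-ratio (chi-square difference) test of nested fits
#'
#' @param restricted,free nested `mgcfa_fit`s (restricted has fewer free
#'   parameters).
#' @return list with `delta_chisq` (floored at 0 with a flag when negative,
#'   which plain ML cannot exclude), `delta_df`, `p`.
#' @export
lrt_difference <- function(restricted, free) {
  ddf <- restricted$df - free$df
  if (ddf <= 0) stop("models are not nested: restricted model must have larger df")
  dchi <- restricted$chisq - free$chisq
  flag <- NULL
  if (dchi < 0) {
    if (dchi < -1e-8) {  # numerically negligible negatives floor silently
      flag <- "negative chi-square difference floored at 0"
      warning(flag)
    }
    dchi <- 0
  }
  list(delta_chisq = dchi, delta_df = ddf,
       p = stats::pchisq(dchi, ddf, lower.tail = FALSE), flag = flag)
}

# candidate partable rows for modification indices
candidate_rows <- function(fit, cand) {
  model <- fit$model; p <- length(model$indicators)
  G <- fit$G
  rows <- NULL
  if (cand$type == "thcov") {
    i <- match(cand$pair[1], model$indicators)
    j <- match(cand$pair[2], model$indicators)
    lab <- paste0("cand_thcov_", cand$pair[1], "_", cand$pair[2])
    for (g in seq_len(G)) {
      rows <- rbind(rows, data.frame(group = g, type = "thcov", i = i, j = j,
                                     label = lab, value = 0, free = TRUE))
    }
  } else if (cand$type == "free_loading") {
    i <- match(cand$indicator, model$indicators)
    lab <- paste0("cand_lambda_", cand$indicator, "_g", cand$group)
    rows <- data.frame(group = cand$group, type = "lambda_dev", i = i, j = 0,
                       label = lab, value = 0, free = TRUE)
  } else if (cand$type == "free_intercept") {
    i <- match(cand$indicator, model$indicators)
    lab <- paste0("cand_tau_", cand$indicator, "_g", cand$group)
    rows <- data.frame(group = cand$group, type = "tau_dev", i = i, j = 0,
                       label = lab, value = 0, free = TRUE)
  } else stop("unknown candidate type: ", cand$type)
  list(rows = rows, label = rows$label[1])
}

#' Score-test modification indices
#'
#' For each candidate parameter fixed at zero in the fitted model, the
#' expected drop in chi-square if it were freed, from a univariate Lagrange
#' multiplier statistic: `MI = g_c^2 / (2 s_c)` with `g_c` the gradient of the
#' chi-square-scale discrepancy at the restricted optimum and `s_c` the Schur
#' complement of the candidate in the Hessian; the expected parameter change
#' is `-g_c / s_c`.
#'
#' @param fit an `mgcfa_fit`.
#' @param candidates list of candidates: `list(type = "thcov", pair = c(a, b))`
#'   for an equal-across-groups error covariance, or
#'   `list(type = "free_loading"/"free_intercept", indicator =, group =)` to
#'   release one group's parameter from an equality constraint. Default: all
#'   error covariances absent from the model.
#' @return data frame (label, mi, epc) sorted by decreasing `mi`; candidates
#'   with a singular information contribution are dropped with a flag.
#' @export
modification_indices <- function(fit, candidates = NULL) {
  model <- fit$model
  if (is.null(candidates)) {
    inds <- model$indicators
    have <- vapply(model$rescov, paste, collapse = ".", FUN.VALUE = "")
    candidates <- list()
    for (a in seq_along(inds)) for (b in seq_along(inds)) {
      if (a < b && !(paste(inds[a], inds[b], sep = ".") %in% have)) {
        candidates[[length(candidates) + 1L]] <-
          list(type = "thcov", pair = c(inds[a], inds[b]))
      }
    }
  }
  moms <- fit$moments
  N <- fit$N; G <- fit$G
  pt0 <- fit$partable
  est <- fit$estimates
  crs <- lapply(candidates, function(cc) candidate_rows(fit, cc))
  extra <- vapply(crs, function(x) x$label, "")
  pt <- rbind(pt0, do.call(rbind, lapply(crs, function(x) x$rows)))
  labs <- c(names(est), extra)
  parfull <- c(est, stats::setNames(rep(0, length(extra)), extra))
  gfun <- function(x) {
    names(x) <- labs
    (N - G) * attr(mgcfa_objective(x, pt, model, moms, want_grad = TRUE,
                                   extra_labels = extra), "gradient")
  }
  g <- gfun(parfull)
  H <- fd_jacobian(gfun, parfull, h = 1e-6)
  H <- (H + t(H)) / 2
  nf <- length(est)
  Hff <- H[seq_len(nf), seq_len(nf), drop = FALSE]
  Hffi <- tryCatch(solve(Hff), error = function(e) NULL)
  out <- NULL
  for (ci in seq_along(extra)) {
    cpos <- nf + ci
    if (is.null(Hffi)) { next }
    s <- H[cpos, cpos] - drop(H[cpos, seq_len(nf), drop = FALSE] %*% Hffi %*%
                                H[seq_len(nf), cpos, drop = FALSE])
    if (!is.finite(s) || s <= 1e-10) next
    mi <- g[cpos]^2 / (2 * s)
    cc <- candidates[[ci]]
    out <- rbind(out, data.frame(label = extra[ci], mi = mi,
                                 epc = -g[cpos] / s,
                                 a = if (cc$type == "thcov") cc$pair[1] else cc$indicator %||% NA,
                                 b = if (cc$type == "thcov") cc$pair[2] else NA))
  }
  if (is.null(out)) {
    return(data.frame(label = character(), mi = numeric(), epc = numeric(),
                      a = character(), b = character()))
  }
  out[order(-out$mi), , drop = FALSE]
}

#' Decision rules for the invariance sequence
#'
#' Defaults follow small-unequal-sample practice: the first (configural)
#' level is judged against absolute benchmarks `CFI >= 0.95` and
#' `RMSEA <= 0.08`; each subsequent level is rejected if the chi-square
#' difference is significant at `alpha`, or the CFI drops by at least 0.005,
#' or the RMSEA increases by at least 0.010 (whichever of the enabled rules
#' fires). A sample-size-adjusted BIC change of 6 or more is reported as a
#' significant change but does not enter the default decision.
#'
#' @param cfi_min,rmsea_max configural benchmarks.
#' @param alpha LRT significance level.
#' @param delta_cfi,delta_rmsea,delta_bic change thresholds.
#' @param use which rejection rules to apply (`"lrt"`, `"cfi"`, `"rmsea"`).
#' @param mi_threshold,max_modifications modification-search settings.
#' @return list of rules.
#' @export
invariance_rules <- function(cfi_min = 0.95, rmsea_max = 0.08, alpha = 0.05,
                             delta_cfi = 0.005, delta_rmsea = 0.010,
                             delta_bic = 6, use = c("lrt", "cfi", "rmsea"),
                             mi_threshold = 3.84, max_modifications = 2) {
  list(cfi_min = cfi_min, rmsea_max = rmsea_max, alpha = alpha,
       delta_cfi = delta_cfi, delta_rmsea = delta_rmsea, delta_bic = delta_bic,
       use = use, mi_threshold = mi_threshold,
       max_modifications = max_modifications)
}

#' Apply the invariance decision rules to a table of fit statistics
#'
#' The engine is separated from model fitting so that it can be applied to
#' externally reported statistics as well as to this package's fits. Rows
#' without difference statistics are judged by the absolute benchmarks; rows
#' with `delta_chisq`/`delta_df` (and optionally `delta_cfi`, `delta_rmsea`,
#' with the conventions CFI-decrease and RMSEA-increase positive) by the
#' change rules.
#'
#' @param stats data frame with columns `level`, `chisq`, `df`, `cfi`,
#'   `rmsea` and optionally `delta_chisq`, `delta_df`, `delta_cfi`,
#'   `delta_rmsea`, `delta_abic`.
#' @param rules an [invariance_rules()] list.
#' @return `stats` with added `p_delta` and `decision` columns.
#' @export
invariance_decisions <- function(stats, rules = invariance_rules()) {
  stats$p_delta <- NA_real_
  stats$decision <- NA_character_
  for (r in seq_len(nrow(stats))) {
    if (is.null(stats$delta_chisq) || is.na(stats$delta_chisq[r])) {
      ok <- stats$cfi[r] >= rules$cfi_min && stats$rmsea[r] <= rules$rmsea_max
      stats$decision[r] <- if (ok) "supported" else "rejected"
    } else {
      p <- stats::pchisq(stats$delta_chisq[r], stats$delta_df[r],
                         lower.tail = FALSE)
      stats$p_delta[r] <- p
      rej <- FALSE
      if ("lrt" %in% rules$use && p < rules$alpha) rej <- TRUE
      if ("cfi" %in% rules$use && !is.null(stats$delta_cfi) &&
          !is.na(stats$delta_cfi[r]) && stats$delta_cfi[r] >= rules$delta_cfi) rej <- TRUE
      if ("rmsea" %in% rules$use && !is.null(stats$delta_rmsea) &&
          !is.na(stats$delta_rmsea[r]) && stats$delta_rmsea[r] >= rules$delta_rmsea) rej <- TRUE
      stats$decision[r] <- if (rej) "rejected" else "supported"
    }
  }
  stats
}

#' Configural-metric-scalar invariance sequence
#'
#' Fits the three nested levels in order and applies the decision rules.
#' When the configural model is rejected and `modify = TRUE`, a
#' modification-index-guided search adds equal-across-group error covariances
#' one at a time (largest MI first, only while it exceeds the rules'
#' threshold, capped at `max_modifications`) before proceeding; the higher
#' levels then keep the added covariances. At the metric and scalar levels,
#' constrained parameters whose release would drop the chi-square by more
#' than the MI threshold are flagged by indicator and group.
#'
#' @param model a [cfa_model()] (its `level` field is overridden per step).
#' @param groups a `group_moments` object.
#' @param rules an [invariance_rules()] list.
#' @param modify run the MI-guided modified-configural step when needed.
#' @return object of class `invariance_report`: per-level fits, the decision
#'   table, flagged parameters and the rules used.
#' @export
invariance_sequence <- function(model, groups, rules = invariance_rules(),
                                modify = TRUE) {
  fits <- list(); rows <- list(); flags <- list()
  mk_row <- function(name, fit, ref = NULL) {
    row <- data.frame(level = name, chisq = fit$chisq, df = fit$df,
                      cfi = fit$cfi, rmsea = fit$rmsea, abic = fit$abic,
                      delta_chisq = NA_real_, delta_df = NA_real_,
                      delta_cfi = NA_real_, delta_rmsea = NA_real_,
                      delta_abic = NA_real_)
    if (!is.null(ref)) {
      lt <- lrt_difference(fit, ref)
      row$delta_chisq <- lt$delta_chisq; row$delta_df <- lt$delta_df
      row$delta_cfi <- ref$cfi - fit$cfi
      row$delta_rmsea <- fit$rmsea - ref$rmsea
      row$delta_abic <- fit$abic - ref$abic
    }
    row
  }
  m <- model; m$level <- "configural"
  fit_conf <- fit_mgcfa(m, groups)
  fits$configural <- fit_conf
  rows$configural <- mk_row("configural", fit_conf)
  conf_dec <- invariance_decisions(rows$configural, rules)$decision

  reference <- fit_conf
  if (conf_dec == "rejected" && isTRUE(modify)) {
    added <- 0
    while (added < rules$max_modifications) {
      mi <- modification_indices(reference)
      if (!nrow(mi) || mi$mi[1] <= rules$mi_threshold) break
      m$rescov <- c(m$rescov, list(c(mi$a[1], mi$b[1])))
      flags[[length(flags) + 1L]] <-
        data.frame(step = "configural modification", parameter = mi$label[1],
                   mi = mi$mi[1], epc = mi$epc[1])
      reference <- fit_mgcfa(m, groups)
      added <- added + 1
      if (invariance_decisions(mk_row("configural modified", reference),
                               rules)$decision == "supported") break
    }
    if (added > 0) {
      fits$configural_modified <- reference
      rows$configural_modified <- mk_row("configural modified", reference)
    }
  }

  m$level <- "metric"
  fit_met <- fit_mgcfa(m, groups)
  fits$metric <- fit_met
  rows$metric <- mk_row("metric", fit_met, reference)
  for (g in seq_along(groups)) {
    cand <- lapply(model$indicators, function(s) list(type = "free_loading",
                                                      indicator = s, group = g))
    mi <- modification_indices(fit_met, cand)
    hit <- mi[mi$mi > rules$mi_threshold, , drop = FALSE]
    if (nrow(hit)) {
      flags[[length(flags) + 1L]] <- data.frame(step = "metric",
                                                parameter = hit$label,
                                                mi = hit$mi, epc = hit$epc)
    }
  }

  m$level <- "scalar"
  fit_sca <- fit_mgcfa(m, groups)
  fits$scalar <- fit_sca
  rows$scalar <- mk_row("scalar", fit_sca, fit_met)
  for (g in seq_along(groups)) {
    cand <- lapply(model$indicators, function(s) list(type = "free_intercept",
                                                      indicator = s, group = g))
    mi <- modification_indices(fit_sca, cand)
    hit <- mi[mi$mi > rules$mi_threshold, , drop = FALSE]
    if (nrow(hit)) {
      flags[[length(flags) + 1L]] <- data.frame(step = "scalar",
                                                parameter = hit$label,
                                                mi = hit$mi, epc = hit$epc)
    }
  }

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- invariance_decisions(tab, rules)
  structure(list(fits = fits, table = tab,
                 flags = if (length(flags)) do.call(rbind, flags) else NULL,
                 rules = rules,
                 ns = fit_conf$ns),
            class = "invariance_report")
}

#' @export
print.invariance_report <- function(x, ...) {
  cat("Measurement invariance analysis\n")
  cat("n per group:", paste(names(x$ns), x$ns, sep = " = ", collapse = "; "), "\n\n")
  tab <- x$table
  fmt <- function(v, d = 3) ifelse(is.na(v), "", formatC(v, digits = d, format = "f"))
  fmt_chidf <- function(chi, df) {
    mapply(function(a, b) if (is.na(a)) "" else sprintf("%.2f (%d)", a, as.integer(b)),
           chi, df)
  }
  disp <- data.frame(
    model = tab$level,
    `chisq(df)` = fmt_chidf(tab$chisq, tab$df),
    `dchisq(ddf)` = fmt_chidf(tab$delta_chisq, tab$delta_df),
    p_delta = fmt(tab$p_delta),
    RMSEA = fmt(tab$rmsea), dRMSEA = fmt(tab$delta_rmsea),
    CFI = fmt(tab$cfi), dCFI = fmt(tab$delta_cfi),
    aBIC = fmt(tab$abic, 2), decision = tab$decision,
    check.names = FALSE)
  print(disp, row.names = FALSE)
  if (!is.null(x$flags)) {
    cat("\nFlagged parameters (MI >", x$rules$mi_threshold, "):\n")
    print(x$flags, row.names = FALSE)
  }
  invisible(x)
}

#' Fit a covariate (MIMIC-style) multi-group CFA from raw data
#'
#' Builds per-group moments over the indicators plus manifest covariates and
#' fits the covariate model of [cfa_model()]: covariates regressed on the
#' indicators, correlated among themselves, uncorrelated with the factor.
#' Invariance constraints apply to loadings and intercepts only; the
#' covariate regressions stay group-specific unless the model says otherwise.
#'
#' @param model a [cfa_model()] with a nonempty `covariates` field.
#' @param data data frame holding indicator and covariate columns and a
#'   group column.
#' @param group_col group column name.
#' @param ... passed to [fit_mgcfa()].
#' @return an `mgcfa_fit`.
#' @export
fit_covariate_model <- function(model, data, group_col = "group", ...) {
  assert_that(length(model$covariates) > 0, "model has no covariates")
  for (g in unique(data[[group_col]])) {
    sub <- data[data[[group_col]] == g, model$covariates, drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    X <- cbind(1, as.matrix(sub))
    if (qr(X)$rank < ncol(X)) {
      stop("collinear covariates in group ", g, ": ",
           paste(model$covariates, collapse = ", "))
    }
  }
  moms <- moments_from_data(data, model$indicators, model$covariates, group_col)
  fit_mgcfa(model, moms, ...)
}

#' Composite (factor-analysis-based) reliability
#'
#' `omega = (sum lambda*)^2 / ((sum lambda*)^2 + sum theta*)` on the
#' standardized single-factor solution.
#'
#' @param fit an `mgcfa_fit` (single factor).
#' @param group which group's solution to standardize (default first).
#' @return the reliability; a Heywood case (negative residual variance) is
#'   flagged via the `"flag"` attribute.
#' @export
composite_reliability <- function(fit, group = 1) {
  ag <- fit$groups_est[[group]]
  lam <- ag$Lambda
  th <- diag(ag$Theta)
  tot <- lam^2 + th
  flag <- NULL
  if (any(th < 0)) flag <- "Heywood case: negative residual variance"
  ls <- lam / sqrt(tot)
  ts <- th / tot
  if (sum(ls) == 0 && all(ts == 0)) return(structure(0, flag = flag))
  w <- sum(ls)^2 / (sum(ls)^2 + sum(ts))
  structure(w, flag = flag)
}
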