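#' Parameter container for the compound hierarchical ordered probit
#'
#' The model couples (i) a self-report component: latent value
#' `Y* ~ N(X beta + eta, 1)` with respondent random effect
#' `eta ~ N(0, omega^2)` and residual SD fixed to 1 for identification, and
#' (ii) a vignette component: latent value `Z*_j ~ N(theta_j, sigma_j^2)` per
#' vignette level `j`, with no respondent effect. Both components are
#' discretized by the same respondent-specific thresholds
#' `tau1 = gamma1' V`, `tauk = tau(k-1) + exp(gammak' V)`, which is what ties
#' the two parts together and identifies the scale: the location and scale of
#' the latent metric are absorbed by the threshold intercepts, so `X` carries
#' no intercept.
#'
#' @param beta named covariate effects on the self latent mean (no intercept).
#' @param omega random-effect SD (>= 0).
#' @param gamma threshold coefficient matrix, `(p+1) x (K-1)`, first row the
#'   intercept row.
#' @param theta named vignette locations, one per modeled vignette level.
#' @param sigma vignette SDs (> 0), same length as `theta`.
#' @param covariates covariate names expected in the data.
#' @param levels integer vignette levels corresponding to `theta`.
#' @param K number of response categories (default 5).
#' @return object of class `chopit_params`.
#' @export
chopit_params <- function(beta, omega, gamma, theta, sigma,
                          covariates = names(beta), levels = seq_along(theta),
                          K = 5L) {
  assert_that(omega >= 0, "omega must be non-negative")
  assert_that(all(sigma > 0), "vignette SDs must be positive")
  assert_that(nrow(gamma) == length(beta) + 1L, "gamma rows must be covariates + intercept")
  assert_that(ncol(gamma) == K - 1L, "gamma needs K-1 boundary columns")
  assert_that(length(sigma) == length(theta), "theta/sigma length mismatch")
  structure(list(beta = beta, omega = omega, gamma = gamma,
                 theta = theta, sigma = sigma,
                 covariates = covariates, levels = as.integer(levels), K = K),
            class = "chopit_params")
}

# ---- internal data preparation -------------------------------------------

chopit_prepare <- function(data, covariates, indicator) {
  ycol <- paste0("y_", indicator)
  assert_that(ycol %in% names(data), "indicator not found: ", indicator)
  X <- encode_covariates(data, covariates)
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  dat <- data[ok, , drop = FALSE]
  if (!nrow(dat)) stop("empty data after removing incomplete covariate rows")
  V <- cbind(`(Intercept)` = 1, X)
  y <- dat[[ycol]]
  self_idx <- which(!is.na(y))

  vcols <- grep(paste0("^v_", indicator, "_"), names(dat), value = TRUE)
  vig <- NULL
  for (cl in vcols) {
    l <- as.integer(sub(".*_", "", cl))
    ri <- which(!is.na(dat[[cl]]))
    if (length(ri)) {
      vig <- rbind(vig, data.frame(row = ri, level = l, rating = dat[[cl]][ri]))
    }
  }
  levels <- if (is.null(vig)) integer(0) else sort(unique(vig$level))
  if (!is.null(vig)) vig$j <- match(vig$level, levels)
  list(y = y, X = X, V = V, self_idx = self_idx, vig = vig,
       levels = levels, J = length(levels), p = ncol(X), K = 5L,
       id = dat$id, data = dat)
}

chopit_pack <- function(params, omega_free = TRUE) {
  v <- c(params$beta,
         if (omega_free) log(max(params$omega, 1e-8)),
         as.numeric(params$gamma),
         params$theta, log(params$sigma))
  v
}

chopit_unpack <- function(par, d, omega_free = TRUE) {
  p <- d$p; J <- d$J; K <- d$K
  i <- 0
  beta <- par[seq_len(p)]; i <- p
  if (omega_free) { lw <- par[i + 1]; i <- i + 1 } else lw <- -Inf
  gamma <- matrix(par[i + seq_len((p + 1) * (K - 1))], p + 1, K - 1); i <- i + (p + 1) * (K - 1)
  theta <- par[i + seq_len(J)]; i <- i + J
  ls <- par[i + seq_len(J)]
  list(beta = beta, lw = lw, gamma = gamma, theta = theta, ls = ls)
}

# negative log-likelihood and analytic gradient
chopit_nll <- function(par, d, gh, omega_free = TRUE, want_grad = TRUE) {
  pu <- chopit_unpack(par, d, omega_free)
  if (any(!is.finite(par))) stop("non-finite parameter")
  p <- d$p; K <- d$K; J <- d$J
  V <- d$V
  lin <- V %*% pu$gamma                      # n x (K-1)
  expo <- exp(lin)
  thr <- lin
  for (k in 2:(K - 1)) thr[, k] <- thr[, k - 1] + expo[, k]
  omega <- exp(pu$lw)
  cc <- sqrt(2) * omega
  nll <- 0
  grad <- if (want_grad) numeric(length(par)) else NULL
  gid <- list(beta = seq_len(p),
              lw = if (omega_free) p + 1 else integer(0),
              gamma = (p + omega_free) + seq_len((p + 1) * (K - 1)),
              theta = (p + omega_free) + (p + 1) * (K - 1) + seq_len(J),
              ls = (p + omega_free) + (p + 1) * (K - 1) + J + seq_len(J))

  # ---- self component (Gauss-Hermite over the random effect) ----
  si <- d$self_idx
  if (length(si)) {
    k <- d$y[si]
    Xs <- d$X[si, , drop = FALSE]
    mu <- drop(Xs %*% pu$beta)
    hi <- ifelse(k == K, Inf, thr[cbind(si, pmin(k, K - 1))])
    lo <- ifelse(k == 1, -Inf, thr[cbind(si, pmax(k - 1, 1))])
    P <- numeric(length(si))
    fu <- numeric(length(si)); fv <- numeric(length(si)); xf <- numeric(length(si))
    for (t in seq_along(gh$x)) {
      sh <- mu + cc * gh$x[t]
      u <- hi - sh; v <- lo - sh
      P <- P + gh$w[t] * (stats::pnorm(u) - stats::pnorm(v))
      if (want_grad) {
        du <- ifelse(is.finite(u), stats::dnorm(u), 0)
        dv <- ifelse(is.finite(v), stats::dnorm(v), 0)
        fu <- fu + gh$w[t] * du
        fv <- fv + gh$w[t] * dv
        xf <- xf + gh$w[t] * gh$x[t] * (du - dv)
      }
    }
    sp <- sqrt(pi)
    P <- pmax(P / sp, 1e-300)
    nll <- nll - sum(log(P))
    if (want_grad) {
      fu <- fu / (sp * P); fv <- fv / (sp * P); xf <- xf / (sp * P)
      # beta: dlogP/dbeta = -X (fu - fv)
      grad[gid$beta] <- grad[gid$beta] + drop(crossprod(Xs, fu - fv))
      if (omega_free) grad[gid$lw] <- grad[gid$lw] + cc * sum(xf)
      # gamma: thresholds move with the boundary coefficients
      Gg <- matrix(0, p + 1, K - 1)
      for (b in seq_len(K - 1)) {
        eb <- expo[si, b]
        whi <- if (b == 1) as.numeric(k < K) else as.numeric(k < K & b <= k) * eb
        wlo <- if (b == 1) as.numeric(k > 1) else as.numeric(k > 1 & b <= k - 1) * eb
        cb <- fu * whi - fv * wlo
        Gg[, b] <- -drop(crossprod(V[si, , drop = FALSE], cb))
      }
      grad[gid$gamma] <- grad[gid$gamma] + as.numeric(Gg)
    }
  }

  # ---- vignette component ----
  if (!is.null(d$vig) && nrow(d$vig)) {
    vg <- d$vig
    sj <- exp(pu$ls)[vg$j]
    th <- pu$theta[vg$j]
    kk <- vg$rating
    hi <- ifelse(kk == K, Inf, thr[cbind(vg$row, pmin(kk, K - 1))])
    lo <- ifelse(kk == 1, -Inf, thr[cbind(vg$row, pmax(kk - 1, 1))])
    u <- (hi - th) / sj
    v <- (lo - th) / sj
    P <- pmax(stats::pnorm(u) - stats::pnorm(v), 1e-300)
    nll <- nll - sum(log(P))
    if (want_grad) {
      du <- ifelse(is.finite(u), stats::dnorm(u), 0)
      dv <- ifelse(is.finite(v), stats::dnorm(v), 0)
      a <- (du - dv) / (sj * P)
      # theta_j
      gt <- tapply(a, vg$j, sum)
      grad[gid$theta][as.integer(names(gt))] <- grad[gid$theta][as.integer(names(gt))] + gt
      # log sigma_j: du/dls = -u
      b2 <- (-ifelse(is.finite(u), u * du, 0) + ifelse(is.finite(v), v * dv, 0)) / P
      gs <- tapply(b2, vg$j, sum)
      grad[gid$ls][as.integer(names(gs))] <- grad[gid$ls][as.integer(names(gs))] - gs
      # gamma
      Gg <- matrix(0, p + 1, K - 1)
      Vv <- V[vg$row, , drop = FALSE]
      for (b in seq_len(K - 1)) {
        eb <- expo[vg$row, b]
        whi <- if (b == 1) as.numeric(kk < K) else as.numeric(kk < K & b <= kk) * eb
        wlo <- if (b == 1) as.numeric(kk > 1) else as.numeric(kk > 1 & b <= kk - 1) * eb
        cb <- (du * whi - dv * wlo) / (sj * P)
        Gg[, b] <- -drop(crossprod(Vv, cb))
      }
      grad[gid$gamma] <- grad[gid$gamma] + as.numeric(Gg)
    }
  }
  if (want_grad) attr(nll, "gradient") <- grad
  nll
}

#' Joint log-likelihood of the hierarchical ordered probit
#'
#' Sums, over respondents, the log probability of the observed self-report —
#' the random effect integrated out by Gauss-Hermite quadrature — and, over
#' vignette ratings, the log probability of the observed category given the
#' vignette location and the rating respondent's own thresholds. Categories 1
#' and K use open intervals to minus/plus infinity.
#'
#' @param params a [chopit_params()] object.
#' @param data a `survey_dataset`.
#' @param indicator indicator label to evaluate.
#' @param quadrature_nodes number of Gauss-Hermite nodes (>= 5).
#' @return the log-likelihood (a single number).
#' @export
chopit_loglik <- function(params, data, indicator, quadrature_nodes = 15L) {
  assert_that(quadrature_nodes >= 5, "need at least 5 quadrature nodes")
  if (any(!is.finite(unlist(params[c("beta", "omega", "gamma", "theta", "sigma")])))) {
    stop("non-finite parameter")
  }
  d <- chopit_prepare(data, params$covariates, indicator)
  if (!length(d$self_idx) && (is.null(d$vig) || !nrow(d$vig))) {
    stop("empty data: no self-reports or vignette ratings for ", indicator)
  }
  idx <- match(d$levels, params$levels)
  assert_that(!anyNA(idx), "data contain vignette levels the params do not cover")
  gh <- pracma::gaussHermite(quadrature_nodes)
  par <- c(params$beta, log(max(params$omega, 1e-12)),
           as.numeric(params$gamma), params$theta[idx], log(params$sigma[idx]))
  -as.numeric(chopit_nll(par, d, gh, omega_free = TRUE, want_grad = FALSE))
}

#' Fit the hierarchical ordered probit by maximum likelihood
#'
#' Maximizes the joint self + vignette likelihood by quasi-Newton iterations
#' (analytic gradient, `omega` and the vignette SDs on the log scale) from a
#' deterministic start: marginal ordered-probit thresholds for the intercept
#' row, zeros for all slopes. The covariance matrix of the estimates comes
#' from the numerically differentiated observed information. Respondent rows
#' enter listwise-complete with respect to the covariates; self-reports and
#' vignette ratings each contribute wherever observed.
#'
#' In the per-indicator design each respondent contributes a single
#' self-report, and the vignette SDs are free, so a joint rescaling of all
#' thresholds, locations, SDs and effects can be traded exactly against the
#' random-effect SD: `omega` is structurally unidentified and is therefore
#' fixed at 0 by default (the scale convention is absorbed by the threshold
#' intercepts). `omega = "free"` is available for designs that do identify it
#' (e.g. several self items sharing the effect) but will sit on a likelihood
#' ridge here.
#'
#' @param data a `survey_dataset`.
#' @param covariates covariate names (encoded via the package's one-hot rules;
#'   education is excluded by default because of its nonresponse burden).
#' @param indicator indicator to fit.
#' @param quadrature_nodes Gauss-Hermite nodes for the random-effect integral.
#' @param tol relative convergence tolerance.
#' @param seed unused by the deterministic start; retained so callers can
#'   thread one RNG stream through an analysis.
#' @param omega `"zero"` (default; identified) or `"free"`.
#' @param slopes `"all"` lets every boundary's coefficients depend on the
#'   covariates; `"proportional"` restricts covariate effects to the first
#'   boundary, which shifts all thresholds uniformly — the model then
#'   coincides with a plain ordered probit with mean effects of opposite
#'   sign. Without vignette data `beta` is collinear with the first-boundary
#'   slopes and is pinned at 0 (mean effects are absorbed by the thresholds).
#' @return object of class `chopit_fit`: `params` (natural scale), `se`,
#'   `loglik`, `vcov` (internal parameterization), `convergence`, and
#'   `thresholds`, the predicted respondent-specific thresholds for every
#'   covariate-complete row (with respondent ids).
#' @export
fit_chopit <- function(data, covariates = c("language", "gender", "age", "insurance"),
                       indicator, quadrature_nodes = 15L, tol = 1e-6, seed = NULL,
                       omega = c("zero", "free"), slopes = c("all", "proportional")) {
  omega <- match.arg(omega)
  slopes <- match.arg(slopes)
  d <- chopit_prepare(data, covariates, indicator)
  has_vig <- !is.null(d$vig) && nrow(d$vig) > 0
  omega_free <- omega == "free"
  yobs <- d$y[d$self_idx]
  assert_that(length(unique(yobs)) >= 2, "need at least 2 observed categories")
  qrV <- qr(d$V)
  if (qrV$rank < ncol(d$V)) stop("covariate matrix is rank deficient after encoding")

  K <- d$K; p <- d$p; J <- d$J
  npar <- p + omega_free + (p + 1) * (K - 1) + 2 * J
  if (length(d$self_idx) + (if (has_vig) nrow(d$vig) else 0) <= npar) {
    stop("fewer observations than parameters")
  }

  # deterministic start: marginal ordered probit for the intercept row
  cump <- cumsum(tabulate(yobs, K) / length(yobs))[1:(K - 1)]
  cump <- pmin(pmax(cump, 1e-3), 1 - 1e-3)
  tau0 <- stats::qnorm(cump)
  inc0 <- pmax(diff(tau0), 0.05)
  g0 <- matrix(0, p + 1, K - 1)
  g0[1, ] <- c(tau0[1], log(inc0))
  theta0 <- numeric(J)
  if (has_vig) {
    anchors <- c(tau0[1] - 0.75, (tau0[-(K - 1)] + tau0[-1]) / 2, tau0[K - 1] + 0.75)
    mbar <- tapply(d$vig$rating, d$vig$j, mean)
    theta0 <- stats::approx(seq_len(K), anchors, xout = as.numeric(mbar), rule = 2)$y
  }
  start_params <- chopit_params(beta = stats::setNames(rep(0, p), colnames(d$X)),
                                omega = if (omega_free) 0.5 else 0,
                                gamma = g0, theta = theta0, sigma = rep(1, J),
                                covariates = covariates, levels = d$levels, K = K)
  par0 <- chopit_pack(start_params, omega_free = omega_free)

  # pinned coordinates: beta without vignette data; boundary-2+ slopes under
  # the proportional restriction
  pinned <- integer(0)
  if (!has_vig) pinned <- c(pinned, seq_len(p))
  if (slopes == "proportional" && p > 0) {
    goff <- p + omega_free
    for (b in 2:(K - 1)) pinned <- c(pinned, goff + (b - 1) * (p + 1) + 1 + seq_len(p))
  }
  active <- setdiff(seq_along(par0), pinned)
  par0[pinned] <- 0

  gh <- pracma::gaussHermite(quadrature_nodes)
  full <- function(x) { out <- par0; out[active] <- x; out }
  obj <- function(x) as.numeric(chopit_nll(full(x), d, gh, omega_free, want_grad = FALSE))
  gr <- function(x) attr(chopit_nll(full(x), d, gh, omega_free,
                                    want_grad = TRUE), "gradient")[active]
  opt <- stats::nlminb(par0[active], obj, gradient = gr,
                       control = list(rel.tol = min(tol, 1e-8), iter.max = 1000,
                                      eval.max = 2000))
  par <- full(opt$par)
  gnorm <- max(abs(gr(opt$par)))
  converged <- opt$convergence == 0 || gnorm < 1e-3

  Ha <- fd_jacobian(gr, opt$par)
  Ha <- (Ha + t(Ha)) / 2
  vca <- tryCatch(solve(Ha), error = function(e) matrix(NA_real_, length(active), length(active)))
  vc <- matrix(0, length(par), length(par))
  vc[active, active] <- vca

  pu <- chopit_unpack(par, d, omega_free)
  gamma_hat <- pu$gamma
  dimnames(gamma_hat) <- list(c("(Intercept)", colnames(d$X)), paste0("k", 1:(K - 1)))
  lvl_names <- paste0("lvl", d$levels, recycle0 = TRUE)
  params <- chopit_params(beta = stats::setNames(pu$beta, colnames(d$X)),
                          omega = exp(pu$lw), gamma = gamma_hat,
                          theta = stats::setNames(pu$theta, lvl_names),
                          sigma = stats::setNames(exp(pu$ls), lvl_names),
                          covariates = covariates, levels = d$levels, K = K)
  se_int <- sqrt(pmax(diag(vc), 0))
  gid_names <- c(paste0("beta_", colnames(d$X)),
                 if (omega_free) "log_omega",
                 paste0("gamma_", rep(rownames(gamma_hat), K - 1), "_k",
                        rep(1:(K - 1), each = p + 1)),
                 paste0("theta_lvl", d$levels, recycle0 = TRUE),
                 paste0("log_sigma_lvl", d$levels, recycle0 = TRUE))
  names(se_int) <- gid_names
  dimnames(vc) <- list(gid_names, gid_names)

  thr_all <- thresholds_from_gamma(d$V, gamma_hat)
  fit <- structure(list(
    params = params,
    se = se_int,
    vcov = vc,
    loglik = -opt$objective,
    convergence = list(converged = converged, code = opt$convergence,
                       message = opt$message, grad_norm = gnorm,
                       iterations = opt$iterations),
    thresholds = cbind(id = d$id, as.data.frame(thr_all)),
    indicator = indicator, covariates = covariates,
    n_self = length(d$self_idx),
    n_vignette = if (has_vig) nrow(d$vig) else 0L,
    omega_free = omega_free
  ), class = "chopit_fit")
  assert_that(all(apply(thr_all, 1, function(r) all(diff(r) > 0))),
              "internal error: non-monotone predicted thresholds")
  fit
}

#' Predict respondent-specific thresholds from a fitted model
#'
#' @param fit a `chopit_fit`.
#' @param V new covariate values: either a data frame (re-encoded with the
#'   fit's covariate rules) or a numeric matrix whose columns match the fit's
#'   encoded covariates (an intercept column is added).
#' @return matrix of K-1 strictly increasing thresholds per row.
#' @export
predict_thresholds <- function(fit, V) {
  gamma <- fit$params$gamma
  if (is.data.frame(V) && !is.null(V$group)) {
    X <- encode_covariates(V, fit$covariates)
    V <- cbind(`(Intercept)` = 1, X)
  } else {
    V <- as.matrix(V)
    if (ncol(V) == nrow(gamma) - 1L) V <- cbind(`(Intercept)` = 1, V)
  }
  if (ncol(V) != nrow(gamma)) {
    stop("covariate columns do not match the fitted model (need ",
         nrow(gamma) - 1L, " covariate columns)")
  }
  thresholds_from_gamma(V, gamma)
}

#' Collect predicted thresholds from several fits into a long table
#'
#' @param fits list of `chopit_fit` objects (typically one per indicator).
#' @return data frame with columns id, indicator, k, value.
#' @export
thresholds_long <- function(fits) {
  out <- list()
  for (f in fits) {
    th <- f$thresholds
    for (k in 1:(ncol(th) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(id = th$id, indicator = f$indicator,
                                            k = k, value = th[[k + 1L]])
    }
  }
  do.call(rbind, out)
}

#' Screen predicted thresholds for association with the self-reports
#'
#' For each predicted threshold variable, regresses every indicator's
#' self-report on it within each group (a simple linear path, matching the
#' covariate-model role the thresholds will play) and keeps the threshold if
#' any path is significant at `alpha`. Constant threshold variables have no
#' defined slope and are never selected.
#'
#' @param thresholds long table (id, indicator, k, value), e.g. from
#'   [thresholds_long()].
#' @param data a `survey_dataset` providing the self-reports and groups.
#' @param alpha significance level for a qualifying path.
#' @return list with `selected` (threshold variables kept) and `paths`
#'   (per threshold/indicator/group estimates and p-values for kept paths).
#' @export
screen_threshold_covariates <- function(thresholds, data, alpha = 0.05) {
  inds <- attr(data, "indicators") %||% hsr_indicators()
  vars <- unique(thresholds[, c("indicator", "k")])
  sel <- list(); paths <- list()
  any_rows <- FALSE
  for (r in seq_len(nrow(vars))) {
    s <- vars$indicator[r]; k <- vars$k[r]
    vname <- paste0("thr_", s, "_k", k)
    tv <- thresholds[thresholds$indicator == s & thresholds$k == k, c("id", "value")]
    m <- merge(data.frame(id = data$id, group = data$group,
                          data[, paste0("y_", inds), drop = FALSE]), tv, by = "id")
    if (nrow(m)) any_rows <- TRUE
    if (stats::sd(m$value, na.rm = TRUE) < 1e-10) next
    qual <- NULL
    for (t in inds) for (g in unique(m$group)) {
      sub <- m[m$group == g & !is.na(m[[paste0("y_", t)]]) & !is.na(m$value), ]
      if (nrow(sub) < 4 || stats::sd(sub$value) < 1e-10) next
      fm <- stats::lm(sub[[paste0("y_", t)]] ~ sub$value)
      cf <- summary(fm)$coefficients
      if (nrow(cf) < 2) next
      pv <- cf[2, 4]
      if (is.finite(pv) && pv < alpha) {
        qual <- rbind(qual, data.frame(threshold = vname, target = t, group = g,
                                       estimate = cf[2, 1], p = pv))
      }
    }
    if (!is.null(qual)) {
      sel[[length(sel) + 1L]] <- data.frame(threshold = vname, indicator = s, k = k)
      paths[[length(paths) + 1L]] <- qual
    }
  }
  if (!any_rows) stop("no complete rows shared by thresholds and data")
  list(selected = if (length(sel)) do.call(rbind, sel) else
         data.frame(threshold = character(), indicator = character(), k = integer()),
       paths = if (length(paths)) do.call(rbind, paths) else
         data.frame(threshold = character(), target = character(),
                    group = character(), estimate = numeric(), p = numeric()))
}

#' Simulate data directly from the hierarchical ordered probit
#'
#' A single-indicator generator used for likelihood and recovery studies:
#' every respondent gives a self-report and rates all modeled vignette
#' levels.
#'
#' @param params a [chopit_params()] object.
#' @param X covariate matrix (no intercept), columns named like
#'   `params$covariates`.
#' @param indicator indicator label for the generated columns.
#' @param seed integer seed.
#' @return a `survey_dataset`-shaped data frame with one populated indicator.
#' @export
simulate_chopit <- function(params, X, indicator = "comm", seed = 1L) {
  set.seed(seed)
  X <- as.matrix(X)
  n <- nrow(X)
  V <- cbind(`(Intercept)` = 1, X)
  thr <- thresholds_from_gamma(V, params$gamma)
  eta <- stats::rnorm(n, 0, params$omega)
  ystar <- drop(X %*% params$beta) + eta + stats::rnorm(n)
  dat <- data.frame(id = seq_len(n), group = "pop", X, check.names = FALSE)
  for (s in hsr_indicators()) dat[[paste0("y_", s)]] <- NA_integer_
  dat[[paste0("y_", indicator)]] <- categorize_latent(ystar, thr)
  dat$vset <- 1L
  for (s in hsr_indicators()) for (l in 1:5) dat[[paste0("v_", s, "_", l)]] <- NA_integer_
  for (jj in seq_along(params$levels)) {
    l <- params$levels[jj]
    zstar <- stats::rnorm(n, params$theta[jj], params$sigma[jj])
    dat[[paste0("v_", indicator, "_", l)]] <- categorize_latent(zstar, thr)
  }
  structure(dat, class = c("survey_dataset", "data.frame"),
            groups = "pop", indicators = hsr_indicators(), seed = seed)
}
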