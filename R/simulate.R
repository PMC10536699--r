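#' Compute respondent-specific thresholds from boundary coefficients
#'
#' The first boundary is linear in the covariates, `tau1 = gamma1' V`; each
#' subsequent boundary adds a strictly positive exponential increment,
#' `tauk = tau(k-1) + exp(gammak' V)`, so the thresholds are ordered for any
#' covariate values.
#'
#' @param V numeric matrix of covariate rows (first column the intercept).
#' @param gamma coefficient matrix, rows = covariates incl. intercept,
#'   columns = the K-1 boundaries.
#' @return matrix of thresholds, one row per row of `V`.
#' @export
thresholds_from_gamma <- function(V, gamma) {
  V <- as.matrix(V)
  assert_that(ncol(V) == nrow(gamma), "covariate columns do not match gamma rows")
  lin <- V %*% gamma
  out <- lin
  for (k in 2:ncol(gamma)) out[, k] <- out[, k - 1] + exp(lin[, k])
  colnames(out) <- paste0("k", seq_len(ncol(gamma)))
  out
}

#' Simulate a multi-group vignette survey
#'
#' Draws respondents with socio-demographic covariates, a factor score, an
#' optional respondent random effect and unique errors; forms the latent self
#' value per indicator; derives each respondent's thresholds from the group's
#' boundary coefficients and the respondent's covariates; and discretizes both
#' the self values and the latent vignette values (drawn around the specified
#' vignette locations) with those same thresholds, so vignette ratings inherit
#' the respondent's scale use (response consistency). No entries are missing;
#' use [apply_missingness()] to emulate item nonresponse.
#'
#' @param spec a [hsr_population()] specification.
#' @param design a [vignette_design()].
#' @param n_per_group named (or positionally matched) positive integers.
#' @param seed integer seed; the draw is fully reproducible given the seed,
#'   which is recorded in the output attributes.
#' @return a `survey_dataset` data frame: id, group, covariates, 7 self-report
#'   columns `y_*` (1..5), the assigned vignette set `vset`, and vignette
#'   rating columns `v_<indicator>_<level>` (1..5, NA outside the assigned set).
#' @export
simulate_survey <- function(spec, design = vignette_design(),
                            n_per_group = c(english = 145, arabic = 91),
                            seed = 1L) {
  validate_population(spec)
  validate_vignette_design(design)
  assert_that(all(n_per_group > 0) && all(n_per_group == round(n_per_group)),
              "n_per_group must be positive integers")
  assert_that(length(n_per_group) == length(spec$groups),
              "n_per_group must give one size per group")
  set.seed(seed)

  groups <- spec$groups
  inds <- spec$indicators
  n <- sum(n_per_group)
  group <- rep(groups, times = n_per_group)
  cd <- spec$covariate_dist

  dat <- data.frame(
    id = seq_len(n),
    group = group,
    gender = stats::rbinom(n, 1, cd$gender),
    age = sample(names(cd$age), n, replace = TRUE, prob = cd$age),
    education = sample(names(cd$education), n, replace = TRUE, prob = cd$education),
    insurance = stats::rbinom(n, 1, cd$insurance),
    stringsAsFactors = FALSE
  )
  attr(dat, "groups") <- groups

  X <- encode_covariates(dat, c("gender", "age", "insurance"))
  X <- X[, spec$threshold_covariates, drop = FALSE]
  V <- cbind(`(Intercept)` = 1, X)

  fmean <- spec$factor_mean[group] + drop(X %*% t(spec$factor_reg))[cbind(seq_len(n), match(group, groups))]
  fscore <- fmean + sqrt(spec$factor_var[group]) * stats::rnorm(n)
  reffect <- if (spec$omega > 0) stats::rnorm(n, 0, spec$omega) else numeric(n)

  # respondent thresholds per indicator (list of n x 4 matrices)
  thr <- vector("list", length(inds))
  names(thr) <- inds
  for (s in inds) {
    tm <- matrix(NA_real_, n, 4)
    for (g in groups) {
      gi <- which(group == g)
      tm[gi, ] <- thresholds_from_gamma(V[gi, , drop = FALSE], spec$gamma[[g]][[s]])
    }
    thr[[s]] <- tm
  }

  for (s in inds) {
    lam <- spec$lambda[group, s]
    ts <- spec$tau[group, s]
    sds <- spec$resid_sd[group, s]
    latent <- ts + lam * fscore + reffect + stats::rnorm(n, 0, sds)
    dat[[paste0("y_", s)]] <- categorize_latent(latent, thr[[s]])
  }

  dat$vset <- sample(seq_along(design$sets), n, replace = TRUE,
                     prob = design$assignment)
  for (s in inds) for (l in 1:5) dat[[paste0("v_", s, "_", l)]] <- NA_integer_
  for (set_id in seq_along(design$sets)) {
    st <- design$sets[[set_id]]
    ri <- which(dat$vset == set_id)
    if (!length(ri)) next
    for (s in st$indicators) for (l in st$levels) {
      zlat <- stats::rnorm(length(ri), spec$theta[s, l], spec$sigma_v[s, l])
      dat[ri, paste0("v_", s, "_", l)] <-
        categorize_latent(zlat, thr[[s]][ri, , drop = FALSE])
    }
  }

  structure(dat, class = c("survey_dataset", "data.frame"),
            groups = groups, indicators = inds, seed = as.integer(seed))
}

#' Mask survey entries at given rates
#'
#' Independently sets entries to missing, emulating "cannot say" responses and
#' item nonresponse. Non-masked entries are returned unchanged; the draw is
#' deterministic given the seed.
#'
#' @param data a `survey_dataset`.
#' @param rates named rates in `[0, 1]`; recognised names are `self` (all
#'   self-report columns), `vignette` (all vignette columns), and the covariate
#'   columns `education`, `insurance`, `gender`, `age`. A `survey_dataset`'s
#'   `missing` defaults from its generating spec can be passed directly.
#' @param seed integer seed.
#' @return the masked `survey_dataset`.
#' @export
apply_missingness <- function(data, rates, seed = 1L) {
  rates <- unlist(rates)
  assert_that(all(rates >= 0 & rates <= 1), "rates must lie in [0,1]")
  set.seed(seed)
  n <- nrow(data)
  mask_cols <- function(cols, rate) {
    for (cl in cols) {
      hit <- stats::runif(n) < rate
      data[[cl]][hit] <<- NA
    }
  }
  for (nm in names(rates)) {
    if (nm == "self") {
      mask_cols(grep("^y_", names(data), value = TRUE), rates[[nm]])
    } else if (nm == "vignette") {
      vcols <- grep("^v_", names(data), value = TRUE)
      for (cl in vcols) {
        hit <- stats::runif(n) < rates[[nm]]
        data[[cl]][hit] <- NA
      }
    } else if (nm %in% names(data)) {
      mask_cols(nm, rates[[nm]])
    } else {
      stop("unknown field in rates: ", nm)
    }
  }
  data
}
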