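#' Construct a population specification for the vignette-survey generator
#'
#' Defines the data-generating process the downstream analyses assume: a
#' one-factor measurement model for 7 rating indicators observed on a
#' 5-category scale, covariate-driven response-category thresholds (the
#' mechanism behind response-category differential item functioning, RC-DIF),
#' and vignette locations on the same latent metric rated through each
#' respondent's own thresholds (response consistency).
#'
#' The latent scale is set so that, given covariates, each indicator's latent
#' self value has unit variance (loadings 0.70, unique SD sqrt(0.51), factor
#' variance 1). With seven indicators this yields a composite reliability of
#' about 0.87 and keeps the generator's self-report component identical to the
#' CHOPIT measurement model with its residual SD fixed at 1.
#'
#' @param groups character vector of group labels (default English/Arabic
#'   language groups).
#' @param lambda numeric length-7 loadings, recycled per group.
#' @param tau numeric length-7 latent intercepts.
#' @param resid_sd numeric length-7 unique (residual) SDs.
#' @param factor_mean,factor_var per-group factor mean and variance.
#' @param omega SD of the respondent-level random effect shared by all of a
#'   respondent's self-reports (0 disables it; nonzero values add a uniform
#'   residual covariance that a strict one-factor analysis model does not
#'   capture).
#' @param gamma_intercepts baseline category-boundary parameters: the first
#'   element is the first threshold, the rest are log-increments.
#' @param gamma_slopes optional matrix (threshold covariates x 4 boundaries)
#'   of covariate effects on the boundary parameters, shared by both groups.
#' @param factor_reg named numeric vector of covariate effects on the factor
#'   mean (same encoded covariate columns as the thresholds), shared by groups.
#' @param theta matrix 7 x 5 of vignette locations per indicator and level
#'   (strictly increasing within a row).
#' @param sigma_v matrix 7 x 5 of vignette latent SDs.
#' @param covariate_dist list with elements `gender` (P(female)), `age`
#'   (named probabilities over the five bands), `education` (3 levels),
#'   `insurance` (P(card)).
#' @param missing default masking rates used by [apply_missingness()].
#' @return an object of class `population_spec`.
#' @seealso [simulate_survey()], [inject_noninvariance()]
#' @export
hsr_population <- function(groups = c("english", "arabic"),
                           lambda = rep(0.70, 7),
                           tau = rep(0, 7),
                           resid_sd = rep(sqrt(0.51), 7),
                           factor_mean = c(0, 0),
                           factor_var = c(1, 1),
                           omega = 0,
                           gamma_intercepts = c(-2.2, log(0.8), log(0.8), log(0.8)),
                           gamma_slopes = NULL,
                           factor_reg = NULL,
                           theta = NULL,
                           sigma_v = NULL,
                           covariate_dist = NULL,
                           missing = list(self = 0.04, vignette = 0.05,
                                          education = 0.12, insurance = 0.06)) {
  indicators <- hsr_indicators()
  thr_cov <- threshold_covariate_names()

  if (is.null(gamma_slopes)) {
    gamma_slopes <- matrix(0, length(thr_cov), 4,
                           dimnames = list(thr_cov, paste0("k", 1:4)))
    # mild, realistic covariate effects on scale use: women shift the first
    # boundary up a little; older bands shift all boundaries down slightly;
    # respondents with an insurance card place the top boundary higher
    gamma_slopes["gender", 1] <- 0.10
    gamma_slopes[paste0("age", 2:5), 1] <- c(-0.03, -0.06, -0.09, -0.12)
    gamma_slopes["insurance", 4] <- 0.15
  }
  if (is.null(factor_reg)) {
    factor_reg <- stats::setNames(rep(0, length(thr_cov)), thr_cov)
    factor_reg["insurance"] <- 0.30
    factor_reg[paste0("age", 2:5)] <- c(-0.05, -0.10, -0.15, -0.20)
  }
  if (is.null(theta)) {
    theta <- matrix(rep(c(-1.6, -0.8, 0, 0.8, 1.6), each = 7), 7, 5,
                    dimnames = list(indicators, paste0("lvl", 1:5)))
  }
  if (is.null(sigma_v)) {
    sigma_v <- matrix(1, 7, 5, dimnames = dimnames(theta))
  }
  if (is.null(covariate_dist)) {
    covariate_dist <- list(
      gender = 0.23,
      age = c(`18-25` = 0.46, `26-30` = 0.19, `31-35` = 0.15,
              `36-40` = 0.09, `41+` = 0.11),
      education = c(none = 0.31, mandatory = 0.25, high = 0.44),
      insurance = 0.40
    )
  }

  G <- length(groups)
  as_gmat <- function(x, what) {
    m <- matrix(rep(x, length.out = G * 7), G, 7, byrow = TRUE,
                dimnames = list(groups, indicators))
    m
  }
  gamma <- vector("list", G)
  names(gamma) <- groups
  for (g in groups) {
    gamma[[g]] <- lapply(stats::setNames(indicators, indicators), function(s) {
      rbind(`(Intercept)` = gamma_intercepts, gamma_slopes)
    })
  }

  spec <- structure(list(
    groups = groups,
    indicators = indicators,
    threshold_covariates = thr_cov,
    lambda = as_gmat(lambda), tau = as_gmat(tau), resid_sd = as_gmat(resid_sd),
    factor_mean = stats::setNames(rep(factor_mean, length.out = G), groups),
    factor_var = stats::setNames(rep(factor_var, length.out = G), groups),
    factor_reg = do.call(rbind, stats::setNames(rep(list(factor_reg), G), groups)),
    omega = omega,
    gamma = gamma,
    theta = theta, sigma_v = sigma_v,
    covariate_dist = covariate_dist,
    missing = missing
  ), class = "population_spec")
  validate_population(spec)
  spec
}

#' The default study condition: language-driven RC-DIF
#'
#' Returns the default population with response-category DIF injected for the
#' second (Arabic) group: the intercept row of every indicator's threshold
#' matrix is shifted by a common magnitude, emulating a language-level
#' difference in how the response labels are understood (scale use is a
#' property of the respondent, so it shifts all items alike). The groups'
#' latent distributions, loadings and intercepts stay identical: any
#' non-invariance an unadjusted analysis finds under this condition is purely
#' an artifact of scale use, which the vignette-based adjustments are
#' designed to remove.
#'
#' @param magnitude shift of the intercept boundary row on the latent probit
#'   scale (the first threshold moves by the magnitude and every increment is
#'   scaled by its exponential).
#' @param target_group group receiving the shift.
#' @return a `population_spec` with DIF.
#' @export
hsr_study_spec <- function(magnitude = 0.5, target_group = "arabic") {
  inject_noninvariance(hsr_population(), "rcdif", hsr_indicators(),
                       magnitude, target_group)
}

#' The seven rating indicators
#'
#' Short labels for the health system responsiveness items: waiting time,
#' respectful treatment, clarity of communication, autonomy in decisions,
#' confidentiality, choice of provider, and quality/cleanliness of amenities.
#' @return character vector of length 7.
#' @export
hsr_indicators <- function() {
  c("time", "resp", "comm", "aut", "conf", "choice", "clean")
}

threshold_covariate_names <- function() {
  c("gender", paste0("age", 2:5), "insurance")
}

#' Validate a population specification
#'
#' Checks the structural invariants: positive residual and vignette SDs,
#' non-negative random-effect SD, strictly increasing vignette locations per
#' indicator, and covariate probabilities in `[0, 1]` summing to one.
#'
#' @param spec a `population_spec`.
#' @return `spec`, invisibly; otherwise an error naming the violated invariant.
#' @export
validate_population <- function(spec) {
  assert_that(inherits(spec, "population_spec"), "not a population_spec")
  assert_that(all(spec$resid_sd > 0), "residual SDs must be positive")
  assert_that(all(spec$sigma_v > 0), "vignette SDs must be positive")
  assert_that(spec$omega >= 0, "omega must be non-negative")
  assert_that(all(spec$factor_var > 0), "factor variances must be positive")
  for (s in spec$indicators) {
    assert_that(all(diff(spec$theta[s, ]) > 0),
                "vignette locations must be strictly increasing for indicator ", s)
  }
  cd <- spec$covariate_dist
  assert_that(cd$gender >= 0 && cd$gender <= 1, "gender proportion outside [0,1]")
  assert_that(cd$insurance >= 0 && cd$insurance <= 1, "insurance proportion outside [0,1]")
  for (nm in c("age", "education")) {
    p <- cd[[nm]]
    assert_that(all(p >= 0 & p <= 1), nm, " probabilities outside [0,1]")
    assert_that(abs(sum(p) - 1) < 1e-8, nm, " probabilities must sum to 1")
  }
  for (g in spec$groups) {
    assert_that(all(spec$indicators %in% names(spec$gamma[[g]])),
                "gamma matrices missing for group ", g)
    for (s in spec$indicators) {
      gm <- spec$gamma[[g]][[s]]
      assert_that(is.matrix(gm) && ncol(gm) == 4 &&
                    nrow(gm) == length(spec$threshold_covariates) + 1L,
                  "gamma matrix for ", g, "/", s, " has wrong shape")
    }
  }
  invisible(spec)
}

#' Construct a vignette-set design
#'
#' The default mirrors the study layout: set 1 presents the bottom, middle and
#' top vignette for all seven indicators; sets 2-5 present the full five
#' vignettes for one or two indicators (attention+respect,
#' communication+amenities, confidentiality+choice, autonomy), each set
#' randomly assigned with equal probability.
#'
#' @param sets list of `list(indicators=, levels=)` per set.
#' @param assignment probability of each set (sums to 1).
#' @return an object of class `vignette_design`.
#' @export
vignette_design <- function(sets = NULL, assignment = NULL) {
  if (is.null(sets)) {
    sets <- list(
      list(indicators = hsr_indicators(), levels = c(1L, 3L, 5L)),
      list(indicators = c("time", "resp"), levels = 1:5),
      list(indicators = c("comm", "clean"), levels = 1:5),
      list(indicators = c("conf", "choice"), levels = 1:5),
      list(indicators = "aut", levels = 1:5)
    )
  }
  if (is.null(assignment)) assignment <- rep(1 / length(sets), length(sets))
  des <- structure(list(sets = sets, assignment = assignment),
                   class = "vignette_design")
  validate_vignette_design(des)
  des
}

#' @rdname vignette_design
#' @param design a `vignette_design` to validate.
#' @export
validate_vignette_design <- function(design) {
  assert_that(inherits(design, "vignette_design"), "not a vignette_design")
  assert_that(length(design$assignment) == length(design$sets),
              "assignment length must match number of sets")
  assert_that(all(design$assignment >= 0) && abs(sum(design$assignment) - 1) < 1e-8,
              "assignment probabilities must sum to 1")
  for (i in seq_along(design$sets)) {
    st <- design$sets[[i]]
    assert_that(all(st$indicators %in% hsr_indicators()),
                "unknown indicator in set ", i)
    assert_that(all(st$levels %in% 1:5), "vignette levels must be in 1..5 in set ", i)
  }
  invisible(design)
}

#' Shift a single parameter to create cross-group non-invariance
#'
#' Returns a modified copy of the population specification in which one
#' parameter block differs between groups: a factor loading (`loading`), a
#' latent intercept (`intercept`), or a covariate row of the threshold
#' coefficient matrix (`rcdif`, shifting that covariate's effect on every
#' category boundary of the indicator). Everything else is untouched, so the
#' copy is suitable for controlled power/calibration contrasts.
#'
#' @param spec a `population_spec`.
#' @param kind one of `"loading"`, `"intercept"`, `"rcdif"`.
#' @param indicator indicator label(s) to modify.
#' @param magnitude finite shift added to the parameter.
#' @param target_group group label receiving the shift.
#' @param covariate for `kind = "rcdif"`: which covariate row of the gamma
#'   matrix to shift (default the intercept row, i.e. a uniform scale shift).
#' @return the modified `population_spec`.
#' @export
inject_noninvariance <- function(spec, kind = c("loading", "intercept", "rcdif"),
                                 indicator, magnitude, target_group,
                                 covariate = "(Intercept)") {
  kind <- match.arg(kind)
  validate_population(spec)
  assert_that(is.finite(magnitude), "magnitude must be finite")
  assert_that(target_group %in% spec$groups, "unknown group: ", target_group)
  assert_that(all(indicator %in% spec$indicators),
              "unknown indicator: ", paste(setdiff(indicator, spec$indicators), collapse = ", "))
  for (s in indicator) {
    if (kind == "loading") {
      spec$lambda[target_group, s] <- spec$lambda[target_group, s] + magnitude
    } else if (kind == "intercept") {
      spec$tau[target_group, s] <- spec$tau[target_group, s] + magnitude
    } else {
      gm <- spec$gamma[[target_group]][[s]]
      assert_that(covariate %in% rownames(gm), "unknown covariate row: ", covariate)
      gm[covariate, ] <- gm[covariate, ] + magnitude
      spec$gamma[[target_group]][[s]] <- gm
    }
  }
  spec
}
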