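#' @keywords internal
"_PACKAGE"

# shared small helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invariant <- function(...) {
  stop(structure(class = c("anchormi_invariant_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_invariant(...)
}

#' Internal: category from latent value and ordered thresholds
#'
#' Applies the ordered-probit observation rule: category k is observed when
#' the latent value falls in `[thr[k-1], thr[k])`, with open outer intervals.
#'
#' @param latent numeric vector of latent values.
#' @param thr matrix with one row per element of `latent` and K-1 ordered
#'   threshold columns.
#' @return integer vector of categories in 1..K.
#' @keywords internal
categorize_latent <- function(latent, thr) {
  thr <- as.matrix(thr)
  assert_that(length(latent) == nrow(thr), "latent/threshold row mismatch")
  1L + as.integer(rowSums(latent >= thr))
}

#' Category probabilities implied by a latent normal and thresholds
#'
#' @param mu latent mean.
#' @param sd latent standard deviation.
#' @param thr ordered thresholds (length K-1).
#' @return probabilities of the K categories (sums to 1).
#' @export
category_probs <- function(mu, sd, thr) {
  cum <- c(stats::pnorm(thr, mean = mu, sd = sd), 1)
  diff(c(0, cum))
}

# encode categorical covariates: one-hot with first level as reference,
# plus numeric-score variants for ordinal covariates
encode_covariates <- function(data, covariates) {
  cols <- list()
  for (cv in covariates) {
    if (cv == "language") {
      grp <- data$group
      lev <- attr(data, "groups") %||% sort(unique(grp))
      cols[["language"]] <- as.numeric(grp != lev[1L])
    } else if (cv == "gender") {
      cols[["gender"]] <- as.numeric(data$gender)
    } else if (cv == "insurance") {
      cols[["insurance"]] <- as.numeric(data$insurance)
    } else if (cv == "age") {
      f <- factor(data$age, levels = age_bands())
      mm <- stats::model.matrix(~ f - 1)
      mm <- mm[, -1L, drop = FALSE]
      colnames(mm) <- paste0("age", seq_len(ncol(mm)) + 1L)
      # preserve NA rows (model.matrix drops them)
      out <- matrix(NA_real_, nrow(data), ncol(mm), dimnames = list(NULL, colnames(mm)))
      out[!is.na(data$age), ] <- mm
      for (j in colnames(out)) cols[[j]] <- out[, j]
    } else if (cv == "age_score") {
      cols[["age_score"]] <- as.numeric(factor(data$age, levels = age_bands())) - 1
    } else if (cv == "education") {
      f <- factor(data$education, levels = education_levels())
      for (j in 2:3) {
        cols[[paste0("edu_", education_levels()[j])]] <-
          ifelse(is.na(f), NA_real_, as.numeric(f == education_levels()[j]))
      }
    } else if (cv == "education_score") {
      cols[["education_score"]] <- as.numeric(factor(data$education, levels = education_levels())) - 1
    } else if (cv %in% names(data)) {
      cols[[cv]] <- as.numeric(data[[cv]])
    } else {
      stop("unknown covariate: ", cv)
    }
  }
  do.call(cbind, cols)
}

age_bands <- function() c("18-25", "26-30", "31-35", "36-40", "41+")
education_levels <- function() c("none", "mandatory", "high")

# finite-difference gradient (central); used for Hessians of analytic gradients
fd_jacobian <- function(fn, x, h = 1e-5) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), n)
  for (i in seq_len(n)) {
    hp <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hp
    xm <- x; xm[i] <- x[i] - hp
    J[, i] <- (fn(xp) - fn(xm)) / (2 * hp)
  }
  J
}
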