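#' Anchor set for non-parametric rescaling
#'
#' @param indicator indicator label the anchors refer to.
#' @param z numeric anchor values in intended bottom-to-top order.
#' @param source `"per-respondent"` or `"pooled-mean"`.
#' @return object of class `anchor_set`.
#' @export
anchor_set <- function(indicator, z, source = c("per-respondent", "pooled-mean")) {
  source <- match.arg(source)
  assert_that(length(z) >= 1, "anchor set needs at least one vignette value")
  structure(list(indicator = indicator, z = as.numeric(z), source = source),
            class = "anchor_set")
}

#' Rescale one self-report against vignette anchors
#'
#' Places a self-report `y` on the `2J+1`-point scale defined by `J` anchor
#' values: odd values are the gaps below, between and above the anchors, even
#' values are ties with an anchor. For strictly ordered anchors the result is
#' a single value (`Cs = Ce`). When anchors are tied with `y` or strictly
#' misordered among themselves, the rescaled score is ambiguous and the
#' function returns the interval of all attainable values: an anchor involved
#' in a strict inversion carries no usable information about `y`'s position,
#' and a tie between `y` and a block of equal, consistently ordered anchors
#' lets `y` sit anywhere between the lowest and highest rank of that block
#' (so, with two vignettes and `y = z1 = z2`, the admissible values are 2, 3
#' and 4).
#'
#' @param y a non-missing rating.
#' @param z an [anchor_set()] or numeric vector of non-missing anchor values
#'   in intended order.
#' @param tol equality tolerance; integer ratings compare exactly, real-valued
#'   (mean) anchors within `1e-9`.
#' @return list of class `c_interval` with elements `Cs`, `Ce`, `J`.
#' @export
rescale_one <- function(y, z, tol = 1e-9) {
  if (inherits(z, "anchor_set")) z <- z$z
  if (length(y) != 1L || !is.numeric(c(y, z))) {
    stop("invalid input: y must be a single numeric rating and z numeric")
  }
  if (is.na(y) || anyNA(z)) {
    stop(structure(class = c("anchormi_not_rescalable", "error", "condition"),
                   list(message = "not rescalable: missing self-report or anchor value",
                        call = sys.call())))
  }
  J <- length(z)

  # anchors taking part in a strict inversion are unreliable
  violating <- rep(FALSE, J)
  if (J > 1) {
    for (j in seq_len(J - 1)) for (k in (j + 1):J) {
      if (z[j] > z[k] + tol) violating[c(j, k)] <- TRUE
    }
  }
  rel <- ifelse(abs(y - z) <= tol, 0L, ifelse(y > z, 1L, -1L))

  lo <- 1L
  hi <- 2L * J + 1L
  reliable <- which(!violating)
  above <- reliable[rel[reliable] == 1L]   # y strictly above anchor j: C >= 2j+1
  below <- reliable[rel[reliable] == -1L]  # y strictly below anchor j: C <= 2j-1
  tied  <- reliable[rel[reliable] == 0L]   # y within the tie block: 2*min..2*max
  if (length(above)) lo <- max(lo, 2L * max(above) + 1L)
  if (length(below)) hi <- min(hi, 2L * min(below) - 1L)
  if (length(tied)) {
    lo <- max(lo, 2L * min(tied))
    hi <- min(hi, 2L * max(tied))
  }
  if (hi < lo) { # unreachable for rating data; guard against tolerance chains
    rng <- range(lo, hi)
    lo <- rng[1]; hi <- rng[2]
  }
  structure(list(Cs = lo, Ce = hi, J = J), class = "c_interval")
}

#' Pooled anchor means per indicator
#'
#' Mean rating of each requested vignette level, pooled over every respondent
#' (in all groups) who rated it; one anchor set per indicator, in
#' bottom-to-top order.
#'
#' @param data a `survey_dataset`.
#' @param levels vignette levels to use (default bottom/middle/top = 1, 3, 5).
#' @return named list of `anchor_set` objects, one per indicator.
#' @export
pooled_anchor_means <- function(data, levels = c(1L, 3L, 5L)) {
  inds <- attr(data, "indicators") %||% hsr_indicators()
  out <- list()
  for (s in inds) {
    zs <- vapply(levels, function(l) {
      v <- data[[paste0("v_", s, "_", l)]]
      if (is.null(v) || all(is.na(v))) {
        stop("no ratings for indicator-level ", s, "/", l)
      }
      mean(v, na.rm = TRUE)
    }, numeric(1))
    out[[s]] <- anchor_set(s, zs, source = "pooled-mean")
  }
  out
}

#' Per-respondent anchor means
#'
#' For each respondent, the mean of their own ratings of the bottom, middle
#' and top vignettes across whatever indicators their assigned set covered.
#' These anchors carry the respondent's personal scale use, which is what a
#' rescaling must remove to correct response-category DIF; respondents who
#' rated no vignette at a level get `NA` there.
#'
#' @param data a `survey_dataset`.
#' @param levels vignette levels to average (default 1, 3, 5).
#' @return data frame with `id` and one column per level, `z1 < ... < zJ`
#'   intended order.
#' @export
respondent_anchor_means <- function(data, levels = c(1L, 3L, 5L)) {
  inds <- attr(data, "indicators") %||% hsr_indicators()
  out <- data.frame(id = data$id)
  for (i in seq_along(levels)) {
    cols <- paste0("v_", inds, "_", levels[i])
    cols <- cols[cols %in% names(data)]
    m <- as.matrix(data[, cols, drop = FALSE])
    out[[paste0("z", i)]] <- rowMeans(m, na.rm = TRUE)
  }
  out[is.na(out)] <- NA  # rowMeans over all-NA gives NaN
  out
}

#' Rescale all self-reports of a dataset
#'
#' Applies [rescale_one()] per respondent and indicator and keeps the lowest
#' (`Cs`) or highest (`Ce`) admissible rescaled value. Anchors may be common
#' per indicator (a list of [anchor_set()]s, e.g. from
#' [pooled_anchor_means()]) or respondent-specific (a data frame from
#' [respondent_anchor_means()], applied to every indicator). Missing
#' self-reports, and respondents without anchors, stay missing.
#'
#' @param data a `survey_dataset`.
#' @param anchors per-indicator anchor list or per-respondent anchor table.
#' @param mode `"lowest"` or `"highest"`.
#' @return data frame with `id`, `group` and rescaled columns `c_<indicator>`
#'   on the scale `1..2J+1`; attributes record `J`, the mode and the anchors.
#' @export
rescale_dataset <- function(data, anchors, mode = c("lowest", "highest")) {
  mode <- match.arg(mode)
  inds <- attr(data, "indicators") %||% hsr_indicators()
  per_resp <- is.data.frame(anchors)
  if (!per_resp) {
    assert_that(all(inds %in% names(anchors)),
                "anchors required for every indicator")
  }
  out <- data.frame(id = data$id, group = data$group)
  J <- if (per_resp) ncol(anchors) - 1L else length(anchors[[inds[1]]]$z)
  for (s in inds) {
    cc <- rep(NA_real_, nrow(data))
    y <- data[[paste0("y_", s)]]
    for (i in seq_len(nrow(data))) {
      if (is.na(y[i])) next
      z <- if (per_resp) {
        as.numeric(anchors[match(data$id[i], anchors$id), -1L])
      } else {
        anchors[[s]]$z
      }
      if (anyNA(z)) next
      ci <- rescale_one(y[i], z)
      cc[i] <- if (mode == "lowest") ci$Cs else ci$Ce
    }
    out[[paste0("c_", s)]] <- cc
  }
  structure(out, J = J, mode = mode, anchors = anchors,
            indicators = inds, groups = attr(data, "groups"))
}

#' Vignette ordering accuracy
#'
#' A respondent-indicator pair is accurately ordered when the rated vignette
#' levels are (weakly, by default) increasing in their intended level.
#' Respondents rating fewer than two levels of an indicator contribute
#' nothing for that indicator.
#'
#' @param data a `survey_dataset`.
#' @param strict require strictly increasing ratings.
#' @return list with `overall` proportion, `by_group` proportions, and a
#'   `flags` data frame (id, group, indicator, accurate).
#' @export
ordering_accuracy <- function(data, strict = FALSE) {
  inds <- attr(data, "indicators") %||% hsr_indicators()
  rows <- list()
  for (s in inds) {
    cols <- paste0("v_", s, "_", 1:5)
    cols <- cols[cols %in% names(data)]
    m <- as.matrix(data[, cols, drop = FALSE])
    nrated <- rowSums(!is.na(m))
    keep <- which(nrated >= 2)
    if (!length(keep)) next
    acc <- vapply(keep, function(i) {
      v <- m[i, !is.na(m[i, ])]
      d <- diff(v)
      if (strict) all(d > 0) else all(d >= 0)
    }, logical(1))
    rows[[s]] <- data.frame(id = data$id[keep], group = data$group[keep],
                            indicator = s, accurate = acc,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no respondent-indicator pairs with >= 2 rated vignette levels")
  flags <- do.call(rbind, rows)
  rownames(flags) <- NULL
  list(overall = mean(flags$accurate),
       by_group = tapply(flags$accurate, flags$group, mean),
       flags = flags)
}
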