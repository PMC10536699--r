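test_that("strictly ordered anchors reproduce the piecewise rescaling rule", {
  # J = 3, anchors 2 < 3 < 4: every line of the rule, bottom to top
  z <- c(2, 3, 4)
  cases <- list(list(y = 1, c = 1), list(y = 2, c = 2), list(y = 2.5, c = 3),
                list(y = 3, c = 4), list(y = 3.5, c = 5), list(y = 4, c = 6),
                list(y = 5, c = 7))
  for (cs in cases) {
    r <- rescale_one(cs$y, z)
    expect_equal(r$Cs, cs$c)
    expect_equal(r$Ce, cs$c)
  }
  # J = 2 interior band
  expect_equal(unclass(rescale_one(2.5, c(2, 3)))[c("Cs", "Ce")],
               list(Cs = 3, Ce = 3))
})

test_that("a self-report tied with two tied anchors spans ranks 2..4", {
  r <- rescale_one(3, c(3, 3))
  expect_equal(r$Cs, 2)
  expect_equal(r$Ce, 4)
})

test_that("missing inputs are distinguished from invalid inputs", {
  expect_error(rescale_one(NA, c(1, 2)), class = "anchormi_not_rescalable")
  expect_error(rescale_one(3, c(1, NA)), class = "anchormi_not_rescalable")
  expect_error(rescale_one("a", c(1, 2)), "invalid input")
})

test_that("constructive interval equals brute-force enumeration on the full grid", {
  for (J in 1:3) {
    grid <- as.matrix(expand.grid(rep(list(1:5), J + 1)))
    for (r in seq_len(nrow(grid))) {
      y <- grid[r, 1]
      z <- grid[r, -1]
      got <- rescale_one(y, z)
      want <- oracle_rescale(y, z)
      expect_equal(got$Cs, min(want),
                   info = paste("y =", y, "z =", paste(z, collapse = ",")))
      expect_equal(got$Ce, max(want),
                   info = paste("y =", y, "z =", paste(z, collapse = ",")))
      # interval convention is exact: the feasible set is contiguous
      expect_equal(want, seq(min(want), max(want)))
    }
  }
})

test_that("rescaled value is monotone in y, in range, and order-isomorphic", {
  set.seed(1)
  for (rep in 1:30) {
    J <- sample(1:3, 1)
    z <- sort(stats::runif(J, 1, 5)) + cumsum(rep(0.05, J))  # strictly ordered
    ys <- seq(0.5, 5.5, by = 0.25)
    cs <- vapply(ys, function(y) rescale_one(y, z)$Cs, numeric(1))
    expect_true(all(diff(cs) >= 0))
    expect_true(all(cs >= 1 & cs <= 2 * J + 1))
    # joint strictly increasing transform leaves C unchanged
    tr <- function(x) x^3 + 2 * x
    for (y in c(1, 2.7, 4, 5)) {
      a <- rescale_one(y, z)
      b <- rescale_one(tr(y), tr(z))
      expect_equal(unclass(a), unclass(b))
    }
  }
})

test_that("pooled anchor means match an independent aggregation", {
  dat <- simulate_survey(hsr_population(), seed = 21)
  anch <- pooled_anchor_means(dat)
  for (s in c("time", "aut", "clean")) {
    for (i in 1:3) {
      lvl <- c(1, 3, 5)[i]
      v <- dat[[paste0("v_", s, "_", lvl)]]
      expect_equal(anch[[s]]$z[i], mean(v[!is.na(v)]))
    }
  }
  expect_equal(anch$time$source, "pooled-mean")
  # constant ratings give that constant as the mean
  d2 <- dat
  d2$v_time_1[!is.na(d2$v_time_1)] <- 4L
  expect_equal(pooled_anchor_means(d2)$time$z[1], 4)
  # a level nobody rated is an error naming the indicator/level
  d3 <- dat
  d3$v_time_1 <- NA_integer_
  expect_error(pooled_anchor_means(d3), "time/1")
})

test_that("dataset rescaling keeps the lowest/highest bound and missingness", {
  dat <- simulate_survey(hsr_study_spec(), seed = 22)
  dat$y_time[1:5] <- NA
  anch <- respondent_anchor_means(dat)
  lo <- rescale_dataset(dat, anch, "lowest")
  hi <- rescale_dataset(dat, anch, "highest")
  expect_true(all(is.na(lo$c_time[1:5])))
  expect_true(all(lo$c_time <= hi$c_time, na.rm = TRUE))
  # they differ only where the interval is non-degenerate
  for (s in hsr_indicators()) {
    cl <- paste0("c_", s)
    dif <- which(!is.na(lo[[cl]]) & lo[[cl]] != hi[[cl]])
    for (i in head(dif, 10)) {
      z <- as.numeric(anch[match(dat$id[i], anch$id), -1])
      ci <- rescale_one(dat[[paste0("y_", s)]][i], z)
      expect_true(ci$Cs < ci$Ce)
    }
  }
  # pooled non-integer anchors: ties are impossible, so only odd values occur
  pa <- pooled_anchor_means(dat)
  expect_true(all(vapply(pa, function(a) all(abs(a$z - round(a$z)) > 1e-9), TRUE)))
  po <- rescale_dataset(dat, pa, "lowest")
  ph <- rescale_dataset(dat, pa, "highest")
  vals <- unlist(po[paste0("c_", hsr_indicators())])
  expect_true(all(vals[!is.na(vals)] %% 2 == 1))
  expect_equal(po[paste0("c_", hsr_indicators())], ph[paste0("c_", hsr_indicators())])
})

test_that("ordering accuracy matches an all-pairs oracle and its limits", {
  dat <- simulate_survey(hsr_population(), seed = 23)
  oa <- ordering_accuracy(dat)
  # independent all-pairs comparison over the raw table
  flags <- NULL
  for (s in hsr_indicators()) {
    m <- as.matrix(dat[paste0("v_", s, "_", 1:5)])
    for (i in seq_len(nrow(m))) {
      r <- m[i, !is.na(m[i, ])]
      if (length(r) < 2) next
      ok <- TRUE
      for (a in 1:(length(r) - 1)) for (b in (a + 1):length(r)) {
        if (r[a] > r[b]) ok <- FALSE
      }
      flags <- c(flags, ok)
    }
  }
  expect_equal(oa$overall, mean(flags))
  # a respondent rating bottom 5 and top 1 is flagged inaccurate
  d2 <- dat[1, ]
  d2$vset <- 1L
  d2[paste0("v_time_", c(1, 3, 5))] <- c(5L, 3L, 1L)
  expect_false(ordering_accuracy(d2)$flags$accurate[
    ordering_accuracy(d2)$flags$indicator == "time"])
  # noise-free, well-separated vignettes are always ordered correctly
  spec <- hsr_population()
  spec$sigma_v[] <- 1e-6
  nf <- simulate_survey(spec, seed = 24)
  expect_equal(ordering_accuracy(nf)$overall, 1.0)
})
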