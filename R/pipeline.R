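#' Run one of the five comparability workflows end to end
#'
#' The workflows mirror the study design:
#' \describe{
#'   \item{initial}{invariance sequence on the raw self-reports, with the
#'     capped modification-index step when the configural model fails.}
#'   \item{rescaled_lowest / rescaled_highest}{non-parametric vignette
#'     adjustment: anchors (per-respondent means by default), rescaling to
#'     the lowest (`Cs`) or highest (`Ce`) admissible value, then the
#'     invariance sequence on the rescaled scores.}
#'   \item{chopit_covariate}{per-indicator CHOPIT fits, respondent-specific
#'     threshold prediction, covariate screening, then the invariance
#'     sequence with the selected thresholds as manifest covariates.}
#'   \item{sociodemographic_covariate}{the invariance sequence with
#'     socio-demographic covariates: variant 1 uses gender, age and
#'     insurance; variant 2 uses gender and education.}
#' }
#'
#' @param config list with elements: `workflow` (one of the names above);
#'   `data` (a `survey_dataset`) or `input` (path for [read_survey()]);
#'   `rules` (an [invariance_rules()] list); `seed`; `anchor_mode`
#'   (`"respondent"` or `"pooled"`); `variant` (1 or 2, socio-demographic
#'   workflow); `covariates` (CHOPIT covariates); `alpha` (screening level);
#'   `output_dir` (optional; report written there as JSON + text).
#' @return object of class `analysis_report`: workflow id, retained group
#'   sizes, the `invariance_report`, diagnostics (ordering accuracy,
#'   composite reliability, anchors, screened covariates) and provenance
#'   (seed, config echo, statistic conventions). Stage failures are recorded
#'   by stage name in `$error` and a partial report is returned.
#' @export
run_workflow <- function(config) {
  wf <- match.arg(config$workflow,
                  c("initial", "rescaled_lowest", "rescaled_highest",
                    "chopit_covariate", "sociodemographic_covariate"))
  rules <- config$rules %||% invariance_rules()
  seed <- config$seed %||% 1L
  data <- config$data %||% read_survey(config$input)
  inds <- attr(data, "indicators") %||% hsr_indicators()
  stage <- "setup"
  report <- list(workflow = wf, diagnostics = list(),
                 provenance = list(seed = seed,
                                   anchor_mode = config$anchor_mode %||% "respondent",
                                   rules = rules))
  log <- character()
  res <- tryCatch({
    if (wf == "initial") {
      stage <- "moments"
      ycols <- paste0("y_", inds)
      moms <- moments_from_data(data, ycols)
      stage <- "invariance"
      rep <- invariance_sequence(cfa_model(ycols), moms, rules)
    } else if (wf %in% c("rescaled_lowest", "rescaled_highest")) {
      stage <- "anchors"
      mode <- sub("rescaled_", "", wf)
      anchors <- if (identical(config$anchor_mode, "pooled")) {
        pooled_anchor_means(data)
      } else {
        respondent_anchor_means(data)
      }
      stage <- "rescale"
      cdat <- rescale_dataset(data, anchors, mode = mode)
      report$diagnostics$anchors <- if (is.data.frame(anchors)) {
        summary(anchors[, -1])
      } else {
        lapply(anchors, function(a) a$z)
      }
      stage <- "moments"
      ccols <- paste0("c_", inds)
      moms <- moments_from_data(cdat, ccols)
      stage <- "invariance"
      rep <- invariance_sequence(cfa_model(ccols), moms, rules)
    } else if (wf == "chopit_covariate") {
      stage <- "chopit"
      covs <- config$covariates %||% c("language", "gender", "age", "insurance")
      fits <- lapply(inds, function(s) {
        fit_chopit(data, covariates = covs, indicator = s)
      })
      log <- c(log, paste0("chopit converged: ",
                           sum(vapply(fits, function(f) f$convergence$converged, TRUE)),
                           "/", length(fits)))
      stage <- "screen"
      thl <- thresholds_long(fits)
      scr <- screen_threshold_covariates(thl, data, alpha = config$alpha %||% 0.05)
      report$diagnostics$screened <- scr
      if (!nrow(scr$selected)) stop("no threshold covariate passed screening")
      stage <- "covariate model"
      wide <- data.frame(id = data$id, group = data$group,
                         data[, paste0("y_", inds)])
      for (r in seq_len(nrow(scr$selected))) {
        s <- scr$selected$indicator[r]; k <- scr$selected$k[r]
        tv <- thl[thl$indicator == s & thl$k == k, c("id", "value")]
        names(tv)[2] <- scr$selected$threshold[r]
        wide <- merge(wide, tv, by = "id")
      }
      # every predicted threshold is (nearly) a linear function of the same
      # few covariates, so the selected set is typically rank deficient;
      # greedily keep the strongest thresholds that still add independent
      # variation (residual share >= 1% given those already kept)
      strength <- vapply(scr$selected$threshold, function(v) {
        min(scr$paths$p[scr$paths$threshold == v])
      }, numeric(1))
      ord <- order(strength)
      kept <- character(0)
      for (v in scr$selected$threshold[ord]) {
        if (!length(kept)) { kept <- v; next }
        cc <- stats::complete.cases(wide[c(v, kept)])
        r2 <- summary(stats::lm(wide[[v]][cc] ~ as.matrix(wide[kept])[cc, ]))$r.squared
        if (is.finite(r2) && r2 < 0.99) kept <- c(kept, v)
      }
      report$diagnostics$screened$kept <- kept
      paths <- unique(data.frame(covariate = scr$paths$threshold,
                                 indicator = paste0("y_", scr$paths$target)))
      paths <- paths[paths$covariate %in% kept, ]
      model <- cfa_model(paste0("y_", inds), covariates = kept,
                         gamma_paths = paths)
      stage <- "invariance"
      moms <- moments_from_data(wide, model$indicators, model$covariates)
      rep <- invariance_sequence(model, moms, rules)
    } else {
      stage <- "encode covariates"
      variant <- config$variant %||% 1
      covs <- if (variant == 1) c("gender", "age", "insurance") else c("gender", "education")
      X <- encode_covariates(data, covs)
      wide <- data.frame(group = data$group, data[, paste0("y_", inds)], X,
                         check.names = FALSE)
      model <- cfa_model(paste0("y_", inds), covariates = colnames(X))
      stage <- "invariance"
      for (g in unique(wide$group)) {
        sub <- wide[wide$group == g, model$covariates, drop = FALSE]
        sub <- sub[stats::complete.cases(sub), , drop = FALSE]
        if (qr(cbind(1, as.matrix(sub)))$rank < ncol(sub) + 1) {
          stop("collinear covariates in group ", g, ": ",
               paste(model$covariates, collapse = ", "))
        }
      }
      moms <- moments_from_data(wide, model$indicators, model$covariates)
      rep <- invariance_sequence(model, moms, rules)
    }
    rep
  }, error = function(e) {
    report$error <<- list(stage = stage, message = conditionMessage(e))
    NULL
  })
  if (!is.null(res)) {
    report$invariance <- res
    report$ns <- res$ns
  }

  # shared diagnostics: vignette ordering accuracy, composite reliability
  report$diagnostics$ordering_accuracy <- tryCatch({
    oa <- ordering_accuracy(data)
    list(overall = oa$overall, by_group = as.list(oa$by_group))
  }, error = function(e) NULL)
  report$diagnostics$reliability <- tryCatch({
    ycols <- paste0("y_", inds)
    pooled <- data
    pooled$group <- "all"
    moms1 <- moments_from_data(pooled, ycols)
    as.numeric(composite_reliability(fit_mgcfa(cfa_model(ycols), moms1)))
  }, error = function(e) NA_real_)
  report$log <- log
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Workflow:", x$workflow, "\n")
  if (!is.null(x$error)) {
    cat("FAILED at stage:", x$error$stage, "-", x$error$message, "\n")
  }
  if (!is.null(x$ns)) {
    cat("Retained n:", paste(names(x$ns), x$ns, sep = " = ", collapse = "; "), "\n")
  }
  oa <- x$diagnostics$ordering_accuracy
  if (!is.null(oa)) {
    cat(sprintf("Vignette ordering accuracy: %.0f%% overall (%s)\n",
                100 * oa$overall,
                paste(sprintf("%s %.0f%%", names(oa$by_group),
                              100 * unlist(oa$by_group)), collapse = ", ")))
  }
  if (!is.null(x$diagnostics$reliability) && is.finite(x$diagnostics$reliability)) {
    cat(sprintf("Composite reliability (pooled): %.2f\n", x$diagnostics$reliability))
  }
  if (!is.null(x$invariance)) {
    cat("\n")
    print(x$invariance)
  }
  invisible(x)
}

#' Write an analysis report to JSON (and a readable text rendering)
#'
#' @param report an `analysis_report`.
#' @param path output path for the JSON file; a `.txt` rendering is written
#'   alongside when `text = TRUE`.
#' @param text also write the plain-text rendering.
#' @export
write_report <- function(report, path, text = TRUE) {
  obj <- list(workflow = report$workflow,
              ns = as.list(report$ns),
              table = report$invariance$table,
              flags = report$invariance$flags,
              diagnostics = report$diagnostics[setdiff(names(report$diagnostics), "screened")],
              screened = report$diagnostics$screened$selected,
              provenance = report$provenance[c("seed", "anchor_mode")],
              error = report$error)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  if (text) {
    txt <- sub("\\.json$", ".txt", path)
    if (identical(txt, path)) txt <- paste0(path, ".txt")
    sink(txt)
    on.exit(sink())
    print(report)
  }
  invisible(path)
}
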