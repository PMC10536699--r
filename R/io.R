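#' Write / read a survey dataset as delimited text
#'
#' One row per respondent; empty cells are missing. A single comment line
#' records the group labels and the generating seed so that a round trip
#' restores the dataset's metadata; `write_survey()` then `read_survey()` is
#' the identity on values and missingness.
#'
#' @param data a `survey_dataset`.
#' @param path file path.
#' @return `read_survey()` returns a validated `survey_dataset`.
#' @export
write_survey <- function(data, path) {
  meta <- paste0("# anchormi survey; groups=",
                 paste(attr(data, "groups") %||% unique(data$group), collapse = ","),
                 "; seed=", attr(data, "seed") %||% "NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(data, con, sep = ",", row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  first <- readLines(path, n = 1L)
  groups <- NULL; seed <- NA
  if (startsWith(first, "#")) {
    gm <- regmatches(first, regexec("groups=([^;]+)", first))[[1]]
    if (length(gm) == 2) groups <- strsplit(gm[2], ",")[[1]]
    sm <- regmatches(first, regexec("seed=([0-9]+)", first))[[1]]
    if (length(sm) == 2) seed <- as.integer(sm[2])
  }
  dat <- utils::read.csv(path, comment.char = "#", na.strings = "",
                         stringsAsFactors = FALSE)
  req <- c("id", "group", "gender", "age", "education", "insurance")
  miss <- setdiff(req, names(dat))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  known <- c(req, "vset", paste0("y_", hsr_indicators()),
             as.vector(outer(paste0("v_", hsr_indicators(), "_"), 1:5, paste0)))
  unk <- setdiff(names(dat), known)
  if (length(unk)) stop("unknown columns: ", paste(unk, collapse = ", "))
  rcols <- grep("^(y|v)_", names(dat), value = TRUE)
  for (cl in rcols) {
    v <- dat[[cl]]
    bad <- which(!is.na(v) & !(v %in% 1:5))
    if (length(bad)) {
      stop("rating outside 1..5 at row ", bad[1], ", column ", cl,
           " (value ", v[bad[1]], ")")
    }
  }
  if (is.null(groups)) groups <- unique(dat$group)
  structure(dat, class = c("survey_dataset", "data.frame"),
            groups = groups, indicators = hsr_indicators(), seed = seed)
}

#' Serialize a population spec or vignette design to a config file
#'
#' Plain YAML key/value files; matrices are stored with their dimnames so a
#' round trip reproduces the object exactly.
#'
#' @param spec a `population_spec` or `vignette_design`.
#' @param path file path.
#' @export
write_config <- function(spec, path) {
  enc <- function(x) {
    if (is.matrix(x)) {
      list(.matrix = TRUE, dimnames = dimnames(x), nrow = nrow(x),
           data = as.numeric(x))
    } else if (is.list(x)) {
      lapply(x, enc)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)   # keep names: emitted as a YAML map
    } else x
  }
  obj <- list(class = class(spec)[1], fields = lapply(unclass(spec), enc))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  dec <- function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      matrix(unlist(x$data), nrow = x$nrow, dimnames = x$dimnames)
    } else if (is.list(x)) lapply(x, dec) else x
  }
  fields <- lapply(obj$fields, dec)
  out <- structure(fields, class = obj$class)
  # numeric vectors with names survive YAML as lists; restore common fields
  if (obj$class == "population_spec") {
    for (nm in c("factor_mean", "factor_var")) out[[nm]] <- unlist(out[[nm]])
    out$covariate_dist <- lapply(out$covariate_dist, unlist)
    out$missing <- lapply(out$missing, function(x) unlist(x))
    out$groups <- unlist(out$groups)
    out$indicators <- unlist(out$indicators)
    out$threshold_covariates <- unlist(out$threshold_covariates)
    out$omega <- unlist(out$omega)
    validate_population(out)
  } else if (obj$class == "vignette_design") {
    out$sets <- lapply(out$sets, function(s) list(indicators = unlist(s$indicators),
                                                  levels = as.integer(unlist(s$levels))))
    out$assignment <- unlist(out$assignment)
    validate_vignette_design(out)
  }
  out
}
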