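#' Read long-format repeated-measures phenotypes
#'
#' One row per subject-by-visit observation: subject id, age at observation
#' (years, continuous), outcome value, and covariates that must be constant
#' within subject (time-invariant). Rows with a missing age or outcome are
#' rejected with a warning giving the count; a covariate that varies within a
#' subject is an error naming that subject.
#'
#' @param path CSV/TSV with a header.
#' @param column_map Named character vector with entries `subject_id`, `age`,
#'   `phenotype`; remaining columns (or those named in `covariates`) are
#'   treated as covariates.
#' @param covariates Optional character vector restricting which file columns
#'   are kept as covariates; default: all columns not otherwise mapped.
#' @return A `data.frame` with columns `subject_id`, `age`, `phenotype`, then
#'   the covariate columns. Attribute `n_rejected` counts dropped rows.
#' @export
read_long_phenotypes <- function(path,
                                 column_map = c(subject_id = "subject_id",
                                                age = "age", phenotype = "phenotype"),
                                 covariates = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  for (fld in c("subject_id", "age", "phenotype")) {
    if (is.na(column_map[fld]) || !(column_map[fld] %in% names(dt)))
      stop("format error: column '", column_map[fld], "' (", fld, ") missing from ", path)
  }
  if (is.null(covariates))
    covariates <- setdiff(names(dt), unname(column_map))
  out <- data.frame(subject_id = as.character(dt[[column_map["subject_id"]]]),
                    age = suppressWarnings(as.numeric(dt[[column_map["age"]]])),
                    phenotype = suppressWarnings(as.numeric(dt[[column_map["phenotype"]]])),
                    stringsAsFactors = FALSE)
  for (cv in covariates) out[[cv]] <- dt[[cv]]
  bad <- is.na(out$age) | is.na(out$phenotype)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected: missing age or phenotype")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no valid phenotype rows in ", path)
  check_time_invariant(out, covariates)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

check_time_invariant <- function(df, covariates) {
  for (cv in covariates) {
    nvals <- tapply(df[[cv]], df$subject_id, function(v) length(unique(v)))
    varying <- names(nvals)[nvals > 1L]
    if (length(varying))
      stop("covariate '", cv, "' varies within subject(s): ",
           paste(utils::head(varying, 5), collapse = ", "))
  }
  invisible(TRUE)
}
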