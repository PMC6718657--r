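#' Read GWAS summary statistics
#'
#' Reads a delimited file of per-SNP association results into a validated
#' summary-statistics table. The minimum input is a SNP identifier and a
#' p-value; chromosome, position, alleles and an effect direction are carried
#' through when present. Rows with a p-value outside (0, 1] are rejected (with
#' a warning giving the count), and duplicate SNP ids are resolved by keeping
#' the record with the smallest p-value.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param column_map Named character vector mapping internal field names to
#'   column names in the file. Required entries: `snp_id`, `pvalue`. Optional:
#'   `chrom`, `pos`, `allele_effect`, `allele_other`, `direction`.
#' @param sep Field separator; `"auto"` (default) infers TSV vs CSV from the
#'   header line.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `allele_effect`, `allele_other`, `pvalue`, `direction` (missing optional
#'   fields are `NA`), one row per retained SNP, in file order after
#'   deduplication. Attribute `n_rejected` records the number of dropped
#'   invalid-p rows.
#' @export
read_summary_stats <- function(path, column_map = c(snp_id = "snp_id", pvalue = "pvalue"),
                               sep = "auto") {
  if (!file.exists(path)) stop("summary statistics file not found: ", path)
  sep <- infer_sep(path, sep)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = TRUE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L) stop("summary statistics file is empty: ", path)
  for (fld in c("snp_id", "pvalue")) {
    if (is.na(column_map[fld]) || !(column_map[fld] %in% names(dt)))
      stop("format error: mandatory column '", fld, "' (file column '",
           column_map[fld], "') missing from ", path)
  }
  get_col <- function(fld, default = NA) {
    cn <- column_map[fld]
    if (!is.na(cn) && cn %in% names(dt)) dt[[cn]] else rep(default, nrow(dt))
  }
  out <- data.frame(
    snp_id        = as.character(get_col("snp_id")),
    chrom         = as.character(get_col("chrom")),
    pos           = suppressWarnings(as.integer(get_col("pos"))),
    allele_effect = as.character(get_col("allele_effect")),
    allele_other  = as.character(get_col("allele_other")),
    pvalue        = suppressWarnings(as.numeric(get_col("pvalue"))),
    direction     = parse_direction(get_col("direction")),
    stringsAsFactors = FALSE
  )
  bad <- is.na(out$pvalue) | out$pvalue <= 0 | out$pvalue > 1
  n_rejected <- sum(bad)
  if (n_rejected > 0L) {
    warning(n_rejected, " row(s) rejected: p-value missing or outside (0,1]")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no valid summary-statistic rows in ", path)
  if (anyDuplicated(out$snp_id)) {
    # dedup policy: keep the smallest p-value per snp_id, stable order
    o <- order(out$pvalue)
    keep <- o[!duplicated(out$snp_id[o])]
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

# direction may be "+"/"-", or a signed numeric effect size
parse_direction <- function(x) {
  if (all(is.na(x))) return(rep(NA_real_, length(x)))
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  sgn <- ifelse(x %in% c("+", "plus"), 1,
         ifelse(x %in% c("-", "−", "minus"), -1, num))
  as.numeric(sgn)
}

infer_sep <- function(path, sep) {
  if (sep != "auto") return(sep)
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}
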