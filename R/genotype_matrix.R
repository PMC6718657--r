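#' Construct a genotype matrix object
#'
#' The pipeline's genotype container: hard-call additive dosages (0/1/2 copies
#' of the counted allele, `NA` for missing) for samples x variants, plus
#' variant metadata. Only biallelic variants are supported, since additive
#' 0/1/2 coding is defined for two alleles.
#'
#' @param dosage Integer/numeric matrix, samples in rows, variants in columns;
#'   values in \{0, 1, 2, NA\}.
#' @param sample_ids Character vector, one per row.
#' @param variants `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `allele_counted`, `allele_other`, one row per column of `dosage`.
#' @return An object of class `genotype_matrix` (a list with elements
#'   `dosage`, `sample_ids`, `variants`).
#' @export
genotype_matrix <- function(dosage, sample_ids, variants) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(sample_ids))
    stop("dosage rows (", nrow(dosage), ") != number of sample ids (", length(sample_ids), ")")
  if (ncol(dosage) != nrow(variants))
    stop("dosage columns (", ncol(dosage), ") != number of variants (", nrow(variants), ")")
  need <- c("snp_id", "chrom", "pos", "allele_counted", "allele_other")
  if (!all(need %in% names(variants)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(variants$snp_id)) stop("duplicate variant ids")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosage values must be 0, 1, 2 or NA")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- variants$snp_id
  rownames(variants) <- NULL
  structure(list(dosage = dosage,
                 sample_ids = as.character(sample_ids),
                 variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  nm <- sum(is.na(x$dosage))
  cat("  missing calls:", nm,
      sprintf("(%.2f%%)\n", 100 * nm / length(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param samples Row index (ids, logical or integer); default all.
#' @param variants Column index; default all.
#' @return A `genotype_matrix` restricted to the requested samples/variants.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  if (is.character(si)) si <- match(si, x$sample_ids)
  if (is.character(vi)) vi <- match(vi, x$variants$snp_id)
  genotype_matrix(x$dosage[si, vi, drop = FALSE],
                  x$sample_ids[si],
                  x$variants[vi, , drop = FALSE])
}
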