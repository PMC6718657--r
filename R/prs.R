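#' Select SNPs for a polygenic risk score tier
#'
#' Retains SNPs with `p < threshold` (strict), intersected with the tier's
#' SNP list (`NULL` for the all-SNP tier). The risk allele is the effect
#' allele when the direction is positive, and the other allele when negative;
#' every retained SNP must carry direction information, since a unit-weighted
#' risk score is undefined without allele orientation.
#'
#' @param stats Summary statistics (see [read_summary_stats()]).
#' @param tier_list Character vector of SNP ids restricting the tier, or
#'   `NULL` for all SNPs.
#' @param threshold P-value inclusion threshold (default 0.05, strict `<`).
#' @return `data.frame` of scoring SNPs: `snp_id`, `risk_allele`, `weight`
#'   (always 1).
#' @export
select_scoring_snps <- function(stats, tier_list = NULL, threshold = 0.05) {
  sel <- stats$pvalue < threshold
  if (!is.null(tier_list)) sel <- sel & (stats$snp_id %in% tier_list)
  s <- stats[sel, , drop = FALSE]
  if (nrow(s) == 0L) stop("no SNPs pass p < ", threshold, " in this tier")
  nodir <- is.na(s$direction) | s$direction == 0
  if (any(nodir))
    stop("orientation error: no effect direction for SNP(s): ",
         paste(utils::head(s$snp_id[nodir], 5), collapse = ", "))
  if (any(is.na(s$allele_effect)) || any(is.na(s$allele_other)))
    stop("orientation error: alleles missing for selected SNPs")
  data.frame(snp_id = s$snp_id,
             risk_allele = ifelse(s$direction > 0, s$allele_effect, s$allele_other),
             weight = 1,
             stringsAsFactors = FALSE)
}

#' Compute raw unit-weighted polygenic risk scores
#'
#' Per sample, the sum over scoring SNPs of the number of risk alleles
#' carried (0/1/2). When a variant's counted allele is not the risk allele
#' the dosage is flipped (`2 - d`). Alleles are matched literally: a scoring
#' SNP whose risk allele matches neither recorded allele is an ambiguity
#' error (never a silent strand flip). A missing genotype contributes twice
#' the sample-set risk-allele frequency at that SNP (`mean_impute`, the
#' PLINK default) or is omitted with per-sample rescaling to the full SNP
#' count (`omit`).
#'
#' @param geno A [genotype_matrix()].
#' @param scoring_snps Output of [select_scoring_snps()].
#' @param missing_policy `"mean_impute"` (default) or `"omit"`.
#' @return List: `raw` (named numeric vector per sample), `n_snps_used`,
#'   `n_snps_missing_from_genotypes`.
#' @export
compute_prs <- function(geno, scoring_snps, missing_policy = c("mean_impute", "omit")) {
  missing_policy <- match.arg(missing_policy)
  vi <- match(scoring_snps$snp_id, geno$variants$snp_id)
  absent <- is.na(vi)
  n_absent <- sum(absent)
  use <- scoring_snps[!absent, , drop = FALSE]
  vi <- vi[!absent]
  if (length(vi) == 0L) stop("input error: no scoring SNP present in the genotypes")
  v <- geno$variants[vi, , drop = FALSE]
  is_counted <- use$risk_allele == v$allele_counted
  is_other <- use$risk_allele == v$allele_other
  bad <- !is_counted & !is_other
  if (any(bad))
    stop("ambiguity error: risk allele matches neither recorded allele for: ",
         paste(utils::head(use$snp_id[bad], 5), collapse = ", "))
  d <- geno$dosage[, vi, drop = FALSE]
  storage.mode(d) <- "double"
  d[, is_other] <- 2 - d[, is_other, drop = FALSE]
  if (missing_policy == "mean_impute") {
    rf <- colMeans(d, na.rm = TRUE)           # risk-allele dosage mean = 2*freq
    for (j in which(colSums(is.na(d)) > 0L)) d[is.na(d[, j]), j] <- rf[j]
    raw <- rowSums(d)
  } else {
    m <- ncol(d)
    nonmiss <- rowSums(!is.na(d))
    if (any(nonmiss == 0L)) stop("sample(s) with no scored genotype under omit policy")
    raw <- rowSums(d, na.rm = TRUE) * m / nonmiss
  }
  names(raw) <- geno$sample_ids
  list(raw = raw, n_snps_used = length(vi),
       n_snps_missing_from_genotypes = n_absent)
}

#' Z-standardize scores
#'
#' `(x - mean) / sd` with the `n - 1` denominator, as for interpretable
#' standardized polygenic scores.
#'
#' @param raw Numeric vector (length >= 2, nonzero variance).
#' @return Standardized vector (mean 0, sd 1).
#' @export
z_transform <- function(raw) {
  if (length(raw) < 2L) stop("need >= 2 samples to standardize")
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) stop("zero variance: scores cannot be standardized")
  (raw - mean(raw)) / s
}

#' Build one PRS tier end to end
#'
#' Convenience wrapper: select scoring SNPs for a tier, score the genotypes,
#' and Z-standardize.
#'
#' @inheritParams select_scoring_snps
#' @inheritParams compute_prs
#' @param tier Label stored with the result (`"all"`, `"mapped"`,
#'   `"functional"`, or free text).
#' @return List of class `prs_result`: `tier`, `threshold`, `raw`, `z`,
#'   `n_snps_used`, `n_snps_missing_from_genotypes`.
#' @export
build_prs <- function(geno, stats, tier = "all", tier_list = NULL,
                      threshold = 0.05, missing_policy = "mean_impute") {
  sc <- select_scoring_snps(stats, tier_list, threshold)
  pr <- compute_prs(geno, sc, missing_policy)
  structure(list(tier = tier, threshold = threshold,
                 raw = pr$raw, z = z_transform(pr$raw),
                 n_snps_used = pr$n_snps_used,
                 n_snps_missing_from_genotypes = pr$n_snps_missing_from_genotypes),
            class = "prs_result")
}

#' Correlations, means and SDs among scores (and other per-sample columns)
#'
#' Builds the familiar score-summary layout: Pearson correlation matrix of
#' the supplied per-sample vectors plus their means and standard deviations
#' (of the unstandardized values).
#'
#' @param score_list Named list of numeric vectors, all named by the same
#'   sample ids (e.g. `raw` elements of [build_prs()] results, phenotype
#'   means, PCs).
#' @return `data.frame`: correlation matrix columns, then `mean` and `sd`.
#' @export
prs_summary <- function(score_list) {
  ids <- names(score_list[[1]])
  for (v in score_list) {
    if (is.null(names(v)) || !identical(sort(names(v)), sort(ids)))
      stop("alignment error: score vectors are not on the same sample ids")
  }
  m <- vapply(score_list, function(v) v[ids], numeric(length(ids)))
  cm <- stats::cor(m)
  out <- as.data.frame(cm)
  out$mean <- colMeans(m)
  out$sd <- apply(m, 2, stats::sd)
  cbind(data.frame(score = colnames(m), stringsAsFactors = FALSE), out,
        row.names = NULL)
}
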