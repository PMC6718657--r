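#' Per-variant and per-sample QC statistics
#'
#' Computes, from non-missing dosages: counted-allele frequency and minor
#' allele frequency per variant, HWE exact p per variant, and call rates per
#' variant and per sample. A variant with no non-missing calls gets
#' `maf = 0` and is flagged in `all_missing`.
#'
#' @param geno A [genotype_matrix()].
#' @return A list of class `qc_report` with `variant` (`data.frame`: `snp_id`,
#'   `freq_counted`, `maf`, `call_rate`, `hwe_p`, `all_missing`) and `sample`
#'   (`data.frame`: `sample_id`, `call_rate`).
#' @export
variant_stats <- function(geno) {
  d <- geno$dosage
  if (length(d) == 0L) stop("empty genotype matrix")
  n_obs <- colSums(!is.na(d))
  freq <- ifelse(n_obs > 0, colMeans(d, na.rm = TRUE) / 2, NA_real_)
  all_missing <- n_obs == 0L
  freq[all_missing] <- 0
  maf <- pmin(freq, 1 - freq)
  maf[all_missing] <- 0
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  hwe <- rep(1.0, ncol(d))
  nz <- n_obs > 0L
  # major homozygote first; the exact test is label-symmetric anyway
  hwe[nz] <- hwe_exact_p(pmax(n0, n2)[nz], n1[nz], pmin(n0, n2)[nz])
  variant <- data.frame(snp_id = geno$variants$snp_id,
                        freq_counted = freq,
                        maf = maf,
                        call_rate = n_obs / nrow(d),
                        hwe_p = hwe,
                        all_missing = all_missing,
                        stringsAsFactors = FALSE)
  sample <- data.frame(sample_id = geno$sample_ids,
                       call_rate = rowMeans(!is.na(d)),
                       stringsAsFactors = FALSE)
  structure(list(variant = variant, sample = sample), class = "qc_report")
}

#' Apply the standard genotype QC filters
#'
#' Removal order is fixed so reason codes are unambiguous:
#' (1) variants with missingness at or above `miss_max`;
#' (2) samples with missingness at or above `miss_max`;
#' (3) variants with minor allele frequency below `maf_min`;
#' (4) variants failing the Hardy-Weinberg exact test at `hwe_thresh`.
#' MAF and HWE are recomputed on the retained samples.
#'
#' @param geno A [genotype_matrix()].
#' @param hwe_thresh Remove variants with HWE exact p below this (default 1e-6).
#' @param maf_min Remove variants with MAF below this (default 0.01).
#' @param miss_max Remove variants/samples with missing rate `>=` this
#'   (default 0.05; note the boundary is inclusive).
#' @return A list: `geno` (filtered [genotype_matrix()]), `report`
#'   (`data.frame` of removals: `id`, `type`, `reason`), `stats`
#'   (the post-filter `qc_report`).
#' @export
apply_variant_filters <- function(geno, hwe_thresh = 1e-6, maf_min = 0.01,
                                  miss_max = 0.05) {
  stopifnot(hwe_thresh > 0, hwe_thresh < 1, maf_min >= 0, maf_min <= 0.5,
            miss_max > 0, miss_max <= 1)
  removals <- list()
  st <- variant_stats(geno)
  # (1) variant missingness
  drop_v <- st$variant$snp_id[(1 - st$variant$call_rate) >= miss_max]
  if (length(drop_v)) {
    removals[[length(removals) + 1L]] <-
      data.frame(id = drop_v, type = "variant", reason = "missingness")
    geno <- subset_genotypes(geno, variants = !(geno$variants$snp_id %in% drop_v))
  }
  if (nrow(geno$variants) == 0L) stop("all variants filtered (missingness)")
  # (2) sample missingness
  miss_s <- rowMeans(is.na(geno$dosage))
  drop_s <- geno$sample_ids[miss_s >= miss_max]
  if (length(drop_s)) {
    removals[[length(removals) + 1L]] <-
      data.frame(id = drop_s, type = "sample", reason = "missingness")
    geno <- subset_genotypes(geno, samples = !(geno$sample_ids %in% drop_s))
  }
  if (length(geno$sample_ids) == 0L) stop("all samples filtered (missingness)")
  # (3) MAF, recomputed on retained samples
  st <- variant_stats(geno)
  drop_v <- st$variant$snp_id[st$variant$maf < maf_min]
  if (length(drop_v)) {
    removals[[length(removals) + 1L]] <-
      data.frame(id = drop_v, type = "variant", reason = "maf")
    geno <- subset_genotypes(geno, variants = !(geno$variants$snp_id %in% drop_v))
  }
  if (nrow(geno$variants) == 0L) stop("all variants filtered (maf)")
  # (4) HWE
  st <- variant_stats(geno)
  drop_v <- st$variant$snp_id[st$variant$hwe_p < hwe_thresh]
  if (length(drop_v)) {
    removals[[length(removals) + 1L]] <-
      data.frame(id = drop_v, type = "variant", reason = "hwe")
    geno <- subset_genotypes(geno, variants = !(geno$variants$snp_id %in% drop_v))
  }
  if (nrow(geno$variants) == 0L) stop("all variants filtered (hwe)")
  report <- if (length(removals)) do.call(rbind, removals) else
    data.frame(id = character(), type = character(), reason = character())
  list(geno = geno, report = report, stats = variant_stats(geno))
}
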