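#' Sliding-window LD pruning
#'
#' Screens out local linkage disequilibrium with a PLINK-style sliding window:
#' within each physical window, while any retained pair of variants has
#' squared Pearson dosage correlation above `r2_max`, one member of the
#' highest-r^2 offending pair is removed — the lower-MAF variant, ties broken
#' by removing the variant at the later position. The window slides forward by
#' `step_snps` variants; a final verification pass enforces the guarantee that
#' no retained pair within `window_kb` of each other exceeds `r2_max`.
#'
#' r^2 is computed over pairwise-complete samples. Variants must be sorted by
#' (chromosome, position).
#'
#' @param geno A [genotype_matrix()].
#' @param window_kb Physical window size in kilobases (default 50).
#' @param step_snps Variants to advance the window start by (default 5).
#' @param r2_max Maximum tolerated r^2 (default 0.5, exclusive).
#' @param exclude_regions Optional `data.frame` (`chrom`, `start`, `end`,
#'   1-based inclusive) of long-range-LD regions whose variants are dropped
#'   before pruning (e.g. the MHC); none by default.
#' @return Character vector of retained `snp_id`s, in map order.
#' @export
ld_prune <- function(geno, window_kb = 50, step_snps = 5, r2_max = 0.5,
                     exclude_regions = NULL) {
  v <- geno$variants
  o <- order(v$chrom, v$pos)
  if (!identical(o, seq_len(nrow(v))))
    stop("input error: variants must be sorted by (chrom, pos)")
  keep_mask <- rep(TRUE, nrow(v))
  if (!is.null(exclude_regions)) {
    for (i in seq_len(nrow(exclude_regions))) {
      hit <- v$chrom == exclude_regions$chrom[i] &
        v$pos >= exclude_regions$start[i] & v$pos <= exclude_regions$end[i]
      keep_mask[hit] <- FALSE
    }
  }
  window_bp <- window_kb * 1000
  maf <- variant_stats(geno)$variant$maf
  d <- geno$dosage
  r2_pair <- function(i, j) {
    r <- suppressWarnings(stats::cor(d[, i], d[, j], use = "pairwise.complete.obs"))
    if (is.na(r)) 0 else r * r
  }
  # remove per tie rule until no within-window pair among `idx` exceeds r2_max
  resolve <- function(idx) {
    repeat {
      live <- idx[keep_mask[idx]]
      if (length(live) < 2L) return(invisible())
      best <- NULL; best_r2 <- r2_max
      for (a in seq_len(length(live) - 1L)) {
        for (b in (a + 1L):length(live)) {
          i <- live[a]; j <- live[b]
          if (v$chrom[i] != v$chrom[j]) break
          if (v$pos[j] - v$pos[i] > window_bp) break  # positions sorted
          r2 <- r2_pair(i, j)
          if (r2 > best_r2) { best_r2 <- r2; best <- c(i, j) }
        }
      }
      if (is.null(best)) return(invisible())
      i <- best[1]; j <- best[2]
      drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j
              else if (v$pos[i] > v$pos[j]) i else j
      keep_mask[drop] <<- FALSE
    }
  }
  for (chr in unique(v$chrom)) {
    cidx <- which(v$chrom == chr)
    for (s in seq(1L, length(cidx), by = step_snps)) {
      start_pos <- v$pos[cidx[s]]
      widx <- cidx[v$pos[cidx] >= start_pos & v$pos[cidx] <= start_pos + window_bp]
      resolve(widx)
    }
    # guarantee pass: catch pairs no window started on
    resolve(cidx)
  }
  v$snp_id[keep_mask]
}
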