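#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list accumulating a running sum: a gene in the set
#' ("hit") increments by its score divided by the summed scores of all set
#' members; a gene outside the set ("miss") decrements by `1/(N - n)` where
#' `N` is the universe size and `n` the set size. The enrichment score is the
#' running-sum extremum of largest magnitude (ties resolved toward the
#' positive extremum). If every set member has score zero the hits contribute
#' nothing and the score is negative.
#'
#' @param ranked_scores Numeric vector of gene scores sorted in decreasing
#'   order, named by `gene_id` (ties must already be broken deterministically,
#'   as by [compute_gene_scores()]).
#' @param set_members Character vector of gene ids; must be a nonempty strict
#'   subset of the universe.
#' @return The enrichment score, in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked_scores, set_members) {
  genes <- names(ranked_scores)
  inset <- genes %in% set_members
  n <- sum(inset); N <- length(genes)
  if (n == 0L) stop("undefined statistic: set has no gene in the universe")
  if (n == N) stop("undefined statistic: set equals the universe")
  es_from_positions(which(inset), ranked_scores[inset], N)
}

# Running-sum extremum from hit positions. `pos` sorted increasing, `hit_scores`
# aligned with pos. O(n) in the set size.
es_from_positions <- function(pos, hit_scores, N) {
  n <- length(pos)
  nr <- sum(hit_scores)
  inc <- if (nr > 0) hit_scores / nr else rep(0, n)
  dec <- 1 / (N - n)
  k <- seq_len(n)
  cum_at_hit <- cumsum(inc) - (pos - k) * dec      # value just after each hit
  cum_before <- cum_at_hit - inc                   # value just before each hit
  hi <- max(0, cum_at_hit)
  lo <- min(0, cum_before, cumsum(inc)[n] - (N - n) * dec)  # end of walk
  # extremum of largest magnitude; ties (to fp tolerance) resolve positive
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo
}

#' Significance-proportion correction of an enrichment score
#'
#' The competitive correction compares the proportion of "significant" genes
#' inside the set (`k`) with the proportion in the whole universe (`K`), and
#' rescales the enrichment score by `k/K`. A gene is significant when its best
#' SNP lies in the top fraction of all SNP p-values (see
#' [significant_gene_threshold()]). When `K = 0` the corrected score is 0.
#'
#' @param es Enrichment score for the set.
#' @param set_members Character vector of the set's gene ids (within the
#'   universe).
#' @param significant_genes Character vector of significant gene ids.
#' @param universe Character vector of all genes in the universe.
#' @return List with `spes` (corrected score), `k`, `K`.
#' @export
significance_proportion_correction <- function(es, set_members,
                                               significant_genes, universe) {
  k <- length(intersect(significant_genes, set_members)) / length(set_members)
  K <- length(intersect(significant_genes, universe)) / length(universe)
  spes <- if (K == 0) 0 else es * (k / K)
  list(spes = spes, k = k, K = K)
}

#' P-value threshold defining "significant" SNPs
#'
#' Returns the empirical `top_frac` quantile of the SNP p-values; a gene
#' counts as significant when its best mapped SNP p-value is at or below this
#' threshold, i.e. lies in the top `top_frac` of all SNP p-values.
#'
#' @param pvalues All SNP p-values.
#' @param top_frac Fraction defining the top of the p-value distribution
#'   (default 0.05).
#' @return The threshold p-value.
#' @export
significant_gene_threshold <- function(pvalues, top_frac = 0.05) {
  stats::quantile(pvalues, top_frac, type = 1, names = FALSE)
}
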