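#' Hardy-Weinberg exact test
#'
#' Exact conditional (Levene-Haldane) test of Hardy-Weinberg equilibrium from
#' genotype counts. Conditioning on the observed allele counts, every
#' heterozygote count of matching parity is enumerated; the p-value is the
#' total probability of configurations no more probable than the observed one.
#' Probabilities are computed in log space via the closed-form expression, so
#' the test is stable for large counts. A monomorphic variant returns 1.
#'
#' @param n_AA,n_Aa,n_aa Nonnegative genotype counts (major homozygote,
#'   heterozygote, minor homozygote). Vectorized.
#' @return Exact p-value(s) in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (length(n_Aa) != length(n_AA) || length(n_aa) != length(n_AA))
    stop("count vectors must have equal length")
  mapply(hwe_exact_p_one, n_AA, n_Aa, n_aa)
}

hwe_exact_p_one <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("total genotype count must be >= 1")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  nmin <- min(nA, na)
  if (nmin == 0L) return(1.0)                     # monomorphic
  h <- seq.int(nmin %% 2L, nmin, by = 2L)         # attainable het counts (parity)
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  # include configurations at most as probable as observed (fp-tolerant)
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}
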