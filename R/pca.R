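#' Standardize genotypes for PCA
#'
#' Per variant: subtract `2*p` and divide by `sqrt(2*p*(1-p))`, with `p` the
#' counted-allele frequency estimated from non-missing calls (the usual
#' unit-variance scaling of population-genetics PCA). Missing entries are set
#' to 0 after centering (mean imputation). Monomorphic variants (zero
#' variance) are dropped and reported via the `dropped` attribute.
#'
#' @param geno A [genotype_matrix()], QC'd and autosomal.
#' @return Numeric matrix (samples x variants) with attribute `dropped`
#'   listing removed monomorphic variant ids.
#' @export
standardize_genotypes <- function(geno) {
  d <- geno$dosage
  storage.mode(d) <- "double"
  p <- colMeans(d, na.rm = TRUE) / 2
  mono <- !is.finite(p) | p <= 0 | p >= 1
  x <- sweep(d[, !mono, drop = FALSE], 2, 2 * p[!mono], "-")
  x <- sweep(x, 2, sqrt(2 * p[!mono] * (1 - p[!mono])), "/")
  x[is.na(x)] <- 0
  colnames(x) <- geno$variants$snp_id[!mono]
  rownames(x) <- geno$sample_ids
  attr(x, "dropped") <- geno$variants$snp_id[mono]
  x
}

#' Principal components of standardized genotypes
#'
#' Top-k eigendecomposition, via SVD, of the sample-by-sample covariance of
#' the variant-standardized genotype matrix divided by the variant count —
#' the population-genetics convention, under which strong structure yields
#' leading eigenvalues well above 1 while the bulk sits near 1. Eigenvector
#' sign is fixed deterministically: the loading of largest magnitude is
#' positive.
#'
#' @param x Standardized matrix from [standardize_genotypes()].
#' @param n_components Components to return (default 20; reduced with a
#'   warning if the matrix rank is lower).
#' @return List of class `pca_result`: `eigenvalues` (nonincreasing),
#'   `scores` (samples x k), `loadings` (variants x k), `n_components`.
#' @export
genotype_pca <- function(x, n_components = 20) {
  n <- nrow(x); m <- ncol(x)
  if (n < n_components) {
    warning("fewer samples than requested components; returning ", n)
    n_components <- n
  }
  xc <- sweep(x, 2, colMeans(x), "-")       # column-center for covariance PCA
  sv <- svd(xc)
  eig <- sv$d^2 / m                          # eigenvalues of xc %*% t(xc) / m
  pos <- sum(sv$d > sv$d[1] * 1e-12)
  k <- min(n_components, pos)
  if (k < n_components)
    warning("rank-deficient input: returning ", k, " components")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- colnames(scores)
  structure(list(eigenvalues = eig[seq_len(k)], scores = scores,
                 loadings = loadings, n_components = k),
            class = "pca_result")
}

#' Shifted square-root transform for covariates
#'
#' Utility for skewed covariates (e.g. an ancestry PC): shifts the vector to
#' be positive (recording the shift) and takes the square root. Applying it
#' is the caller's choice; no model function transforms silently.
#'
#' @param x Numeric vector.
#' @param eps Margin added above the minimum (default 1e-8).
#' @return Transformed vector with attribute `shift`.
#' @export
sqrt_shift_transform <- function(x, eps = 1e-8) {
  shift <- if (min(x) <= 0) -min(x) + eps else 0
  out <- sqrt(x + shift)
  attr(out, "shift") <- shift
  out
}
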