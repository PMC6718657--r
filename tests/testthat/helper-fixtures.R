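# Shared fixture builders; everything is generated in code at test time.

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small genotype matrix with explicit dosages (rows = samples)
toy_geno <- function(dosage, pos = NULL, chrom = NULL,
                     counted = NULL, other = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(counted)) counted <- rep("A", m)
  if (is.null(other)) other <- rep("G", m)
  genotype_matrix(dosage,
                  sprintf("S%02d", seq_len(nrow(dosage))),
                  data.frame(snp_id = sprintf("rs%03d", seq_len(m)),
                             chrom = chrom, pos = pos,
                             allele_counted = counted, allele_other = other,
                             stringsAsFactors = FALSE))
}

# random HWE genotypes at given mafs
random_geno <- function(n, mafs, seed = 1) {
  set.seed(seed)
  d <- vapply(mafs, function(p) stats::rbinom(n, 2, p), numeric(n))
  toy_geno(matrix(as.integer(d), nrow = n))
}

# independent exact-test oracle: direct factorial-formula enumeration,
# no recurrence, no log-space normalization trick shared with the package
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (min(nA, na) == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  prob_of <- function(h) {
    exp(lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
          lgamma((na - h) / 2 + 1) + h * log(2) +
          lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1))
  }
  probs <- vapply(hs, prob_of, numeric(1))
  obs <- prob_of(nAa)
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# hand-rolled de Boor recursion for the B-spline basis test oracle
deboor_basis <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1
  B <- sapply(seq_len(length(knots) - 1), function(i) {
    as.numeric(x >= knots[i] & x < knots[i + 1])
  })
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  # clamp: include right boundary in the last nonzero-width interval
  right <- max(knots)
  last_int <- max(which(knots < right))
  B[x == right, last_int] <- 1
  for (d in seq_len(degree)) {
    Bn <- matrix(0, length(x), length(knots) - d - 1)
    for (i in seq_len(ncol(Bn))) {
      den1 <- knots[i + d] - knots[i]
      den2 <- knots[i + d + 1] - knots[i + 1]
      t1 <- if (den1 > 0) (x - knots[i]) / den1 * B[, i] else 0
      t2 <- if (den2 > 0) (knots[i + d + 1] - x) / den2 * B[, i + 1] else 0
      Bn[, i] <- t1 + t2
    }
    B <- Bn
  }
  B[, seq_len(n_basis), drop = FALSE]
}

# independent brute-force check for LD pruning: a kept set is valid when no
# within-window pair exceeds r2_max, and maximal when adding back any removed
# variant creates a violation
prune_valid_and_maximal <- function(geno, kept, window_kb = 50, r2_max = 0.5) {
  v <- geno$variants
  d <- geno$dosage
  r2 <- function(i, j) {
    r <- suppressWarnings(cor(d[, i], d[, j], use = "pairwise.complete.obs"))
    if (is.na(r)) 0 else r^2
  }
  ki <- match(kept, v$snp_id)
  pair_ok <- function(i, j) {
    v$chrom[i] != v$chrom[j] ||
      abs(v$pos[i] - v$pos[j]) > window_kb * 1000 ||
      r2(i, j) <= r2_max
  }
  for (a in seq_along(ki)) for (b in seq_along(ki)) {
    if (a < b && !pair_ok(ki[a], ki[b])) return("violation")
  }
  for (r in setdiff(seq_len(nrow(v)), ki)) {
    if (all(vapply(ki, function(k) pair_ok(r, k), logical(1)))) return("not maximal")
  }
  "ok"
}

# long-format phenotype generator for quick TVEM fixtures
quick_long <- function(n_subj, obs_per, beta_fun, noise_sd = 0, seed = 1,
                       age_range = c(2, 5), x_sd = 1, subject_sd = 0) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subj), function(i) {
    t <- sort(runif(obs_per, age_range[1], age_range[2]))
    x <- rnorm(1, 0, x_sd)
    u <- rnorm(1, 0, subject_sd)
    data.frame(subject_id = sprintf("P%04d", i), age = t,
               phenotype = beta_fun(t) * x + u + rnorm(obs_per, 0, noise_sd),
               x = x, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
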