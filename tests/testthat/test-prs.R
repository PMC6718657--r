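two_snp_stats <- function() {
  data.frame(snp_id = c("rs001", "rs002", "rs003"),
             chrom = "chr1", pos = c(1000L, 2000L, 3000L),
             allele_effect = c("A", "A", "A"), allele_other = c("G", "G", "G"),
             pvalue = c(0.01, 0.04, 0.05), direction = c(1, -1, 1),
             stringsAsFactors = FALSE)
}

test_that("scoring-SNP selection is strict in p and oriented by direction", {
  st <- two_snp_stats()
  sc <- select_scoring_snps(st, threshold = 0.05)
  expect_equal(sc$snp_id, c("rs001", "rs002"))   # p = 0.05 excluded
  expect_equal(sc$risk_allele, c("A", "G"))      # negative direction flips
  expect_true(all(sc$weight == 1))

  sc <- select_scoring_snps(st, tier_list = "rs001")
  expect_equal(sc$snp_id, "rs001")

  st$direction[1] <- NA
  expect_error(select_scoring_snps(st), "rs001")
})

test_that("raw scores match a hand-summed oracle with flips and imputation", {
  # risk = counted at rs001; risk = other at rs002 (direction -1)
  st <- two_snp_stats()
  sc <- select_scoring_snps(st)
  d <- rbind(c(0L, 2L),        # risk counts: 0 + (2-2)=0
             c(2L, 0L),        # 2 + 2 = 4
             c(1L, NA))        # 1 + imputed
  g <- toy_geno(d, pos = c(1000L, 2000L))
  g$variants$snp_id <- c("rs001", "rs002")
  pr <- compute_prs(g, sc)
  # rs002 risk dosages observed: (2-2)=0 and (2-0)=2 -> mean 1 imputed
  expect_equal(unname(pr$raw), c(0, 4, 1 + 1))
  expect_equal(pr$n_snps_used, 2L)
  expect_equal(pr$n_snps_missing_from_genotypes, 0L)

  pr_omit <- compute_prs(g, sc, missing_policy = "omit")
  expect_equal(unname(pr_omit$raw)[3], 1 * 2 / 1)  # rescaled to 2 SNPs

  # extremes: all non-risk -> 0; all risk -> 2m
  g0 <- toy_geno(rbind(c(0L, 2L), c(2L, 0L)), pos = c(1000L, 2000L))
  pr0 <- compute_prs(g0, sc)
  expect_equal(unname(pr0$raw), c(0, 4))

  # a scoring SNP absent from the genotypes is counted, not an error
  sc3 <- rbind(sc, data.frame(snp_id = "rs_absent", risk_allele = "A", weight = 1))
  pr3 <- compute_prs(g, sc3)
  expect_equal(pr3$n_snps_missing_from_genotypes, 1L)

  # irreconcilable allele -> loud ambiguity error
  sc_bad <- sc; sc_bad$risk_allele[1] <- "T"
  expect_error(compute_prs(g, sc_bad), "ambiguity")
})

test_that("scores are invariant to SNP order and to allele-coding flips", {
  set.seed(71)
  st <- data.frame(snp_id = sprintf("rs%03d", 1:20), chrom = "chr1",
                   pos = seq(1000L, by = 1000L, length.out = 20),
                   allele_effect = "A", allele_other = "G",
                   pvalue = runif(20, 0.001, 0.049),
                   direction = sample(c(1, -1), 20, TRUE),
                   stringsAsFactors = FALSE)
  g <- random_geno(50, runif(20, 0.1, 0.5), seed = 71)
  sc <- select_scoring_snps(st)
  base <- compute_prs(g, sc)$raw

  perm <- sample(nrow(sc))
  expect_equal(compute_prs(g, sc[perm, ])$raw, base)

  # flip which allele the file counts at some variants
  gf <- g
  flip <- sample(20, 7)
  gf$dosage[, flip] <- 2L - gf$dosage[, flip]
  tmp <- gf$variants$allele_counted[flip]
  gf$variants$allele_counted[flip] <- gf$variants$allele_other[flip]
  gf$variants$allele_other[flip] <- tmp
  expect_equal(compute_prs(gf, sc)$raw, base)
})

test_that("mean imputation equates each SNP's scored mean to its observed mean", {
  set.seed(72)
  g <- random_geno(200, runif(10, 0.2, 0.5), seed = 72)
  st <- data.frame(snp_id = g$variants$snp_id, chrom = "chr1",
                   pos = g$variants$pos, allele_effect = "A",
                   allele_other = "G", pvalue = 0.01, direction = 1,
                   stringsAsFactors = FALSE)
  sc <- select_scoring_snps(st)
  mask <- matrix(runif(length(g$dosage)) < 0.05, nrow = nrow(g$dosage))
  gm <- g; gm$dosage[mask] <- NA
  pr <- compute_prs(gm, sc)
  obs_means <- colMeans(gm$dosage, na.rm = TRUE)
  expect_equal(mean(pr$raw), sum(obs_means), tolerance = 1e-9)
})

test_that("z-transform standardizes with the n-1 denominator", {
  expect_equal(z_transform(c(0, 1, 2)), c(-1, 0, 1))
  set.seed(73)
  x <- rnorm(40, 5, 3)
  z <- z_transform(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_error(z_transform(rep(2, 5)), "zero variance")
  expect_error(z_transform(3), ">= 2 samples")
})

test_that("tier nesting: functional score uses a subset of mapped SNPs", {
  set.seed(74)
  g <- random_geno(100, runif(30, 0.1, 0.5), seed = 74)
  st <- data.frame(snp_id = g$variants$snp_id, chrom = "chr1",
                   pos = g$variants$pos, allele_effect = "A",
                   allele_other = "G", pvalue = runif(30, 0.001, 0.049),
                   direction = sample(c(1, -1), 30, TRUE),
                   stringsAsFactors = FALSE)
  mapped <- g$variants$snp_id[1:15]
  functional <- mapped[1:5]
  p_all <- build_prs(g, st, "all")
  p_map <- build_prs(g, st, "mapped", mapped)
  p_fun <- build_prs(g, st, "functional", functional)
  expect_gte(p_map$n_snps_used, p_fun$n_snps_used)
  expect_gte(p_all$n_snps_used, p_map$n_snps_used)
  # nested tiers share variance: correlation strictly positive
  expect_gt(cor(p_map$raw, p_fun$raw), 0)
})

test_that("score summaries align samples and flag mismatches", {
  set.seed(75)
  a <- setNames(rnorm(500), sprintf("S%03d", 1:500))
  b <- setNames(rnorm(500), sprintf("S%03d", 1:500))
  sm <- prs_summary(list(a = a, b = b))
  expect_equal(sm$a[1], 1)                        # self-correlation
  expect_lt(abs(sm$b[1]), 0.15)                   # independent vectors
  expect_equal(sm$mean, c(mean(a), mean(b)))
  expect_equal(sm$sd, c(sd(a), sd(b)))
  names(b)[1] <- "WRONG"
  expect_error(prs_summary(list(a = a, b = b)), "alignment")
})
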