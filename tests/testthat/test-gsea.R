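three_gene_annotation <- function() {
  data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
             start = c(100000L, 150000L, 400000L),
             end = c(110000L, 160000L, 410000L),
             strand = "+", stringsAsFactors = FALSE)
}

stats_at <- function(pos, p = rep(0.5, length(pos)), chrom = "chr1") {
  data.frame(snp_id = sprintf("rs%d", seq_along(pos)), chrom = chrom, pos = pos,
             allele_effect = "A", allele_other = "G", pvalue = p,
             direction = 1, stringsAsFactors = FALSE)
}

test_that("SNP-gene mapping respects the 20 kb flank boundary exactly", {
  ann <- three_gene_annotation()
  st <- stats_at(c(80000L, 79999L, 105000L, 130000L, 430000L, 430001L))
  map <- map_snps_to_genes(st, ann, flank_bp = 20000)
  expect_true(any(map$snp_id == "rs1" & map$gene_id == "G1"))  # start - 20000
  expect_false("rs2" %in% map$snp_id)                          # start - 20001
  expect_true(any(map$snp_id == "rs3" & map$gene_id == "G1"))  # gene body
  # rs4 at 130000 sits in both G1's and G2's flanks
  expect_equal(sort(map$gene_id[map$snp_id == "rs4"]), c("G1", "G2"))
  expect_true(any(map$snp_id == "rs5" & map$gene_id == "G3"))  # end + 20000
  expect_false("rs6" %in% map$snp_id)                          # end + 20001
})

test_that("chromosome-name mismatch warns instead of silently mapping nothing", {
  ann <- three_gene_annotation()
  st <- stats_at(105000L, chrom = "1")
  expect_warning(map_snps_to_genes(st, ann), "chromosome")
})

test_that("gene scores take -log10 of the best SNP and sort deterministically", {
  ann <- three_gene_annotation()
  st <- stats_at(c(105000L, 106000L, 155000L, 405000L),
                 p = c(0.01, 0.5, 1, 0.001))
  map <- map_snps_to_genes(st, ann)
  gs <- compute_gene_scores(map, st)
  expect_equal(gs$gene_id, c("G3", "G1", "G2"))   # descending score
  expect_equal(gs$score[gs$gene_id == "G1"], 2)
  expect_equal(gs$best_snp[gs$gene_id == "G1"], "rs1")
  expect_equal(gs$n_snps[gs$gene_id == "G1"], 2L)
  expect_equal(gs$score[gs$gene_id == "G2"], 0)   # p = 1

  # order invariance and monotonicity in added SNPs
  gs2 <- compute_gene_scores(map[rev(seq_len(nrow(map))), ], st)
  expect_equal(gs2, gs)
  st_extra <- rbind(st, stats_at(107000L, p = 0.9)[1, ])
  st_extra$snp_id[5] <- "rs_extra"
  map2 <- map_snps_to_genes(st_extra, ann)
  gs3 <- compute_gene_scores(map2, st_extra)
  expect_equal(gs3$score[gs3$gene_id == "G1"], 2)  # larger p cannot change max

  expect_error(compute_gene_scores(map, st[-1, ]), "absent from summary")
})

test_that("enrichment score matches a step-by-step running-sum oracle", {
  # independent oracle: literal walk over the ranked list
  es_oracle <- function(scores, members) {
    inset <- names(scores) %in% members
    nr <- sum(scores[inset])
    run <- 0; best <- 0
    for (i in seq_along(scores)) {
      run <- run + if (inset[i]) {
        if (nr > 0) scores[i] / nr else 0
      } else -1 / (length(scores) - sum(inset))
      if (abs(run) > abs(best) + 1e-12 ||
          (abs(run) > abs(best) - 1e-12 && run > best)) best <- run
    }
    unname(best)
  }
  sc <- c(A = 5, B = 3, C = 2.5, D = 1, E = 0.5, F = 0)
  expect_equal(enrichment_score(sc, "A"), 1)          # top gene alone
  expect_equal(enrichment_score(sc, c("A", "C")), es_oracle(sc, c("A", "C")))
  expect_lt(enrichment_score(sc, c("E", "F")), 0)     # bottom zero-score set

  set.seed(41)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    sc <- sort(runif(n, 0, 5), decreasing = TRUE)
    names(sc) <- paste0("g", seq_len(n))
    members <- sample(names(sc), sample(seq_len(n - 1), 1))
    expect_equal(enrichment_score(sc, members), es_oracle(sc, members),
                 tolerance = 1e-12)
  }

  expect_error(enrichment_score(sc, names(sc)), "equals the universe")
  expect_error(enrichment_score(sc, "nowhere"), "no gene in the universe")
})

test_that("enrichment score agrees with fgsea's weighted-KS statistic", {
  skip_if_not_installed("fgsea")
  set.seed(42)
  for (i in 1:20) {
    n <- 50
    sc <- sort(runif(n, 0.01, 6), decreasing = TRUE)
    names(sc) <- paste0("g", seq_len(n))
    members <- sample(names(sc), 8)
    ours <- enrichment_score(sc, members)
    ref <- fgsea::calcGseaStat(sc, selectedStats = which(names(sc) %in% members),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("significance-proportion correction scales es by k/K", {
  r <- significance_proportion_correction(0.5, c("A", "B"), c("A", "C"),
                                          c("A", "B", "C", "D"))
  expect_equal(r$k, 0.5)
  expect_equal(r$K, 0.5)
  expect_equal(r$spes, 0.5)                       # k = K -> identity
  r <- significance_proportion_correction(0.5, c("B", "D"), c("A", "C"),
                                          c("A", "B", "C", "D"))
  expect_equal(r$spes, 0)                         # k = 0
  r <- significance_proportion_correction(0.4, c("A", "C"),
                                          c("A", "C"), c("A", "B", "C", "D"))
  expect_equal(r$k, 2 * r$K)
  expect_equal(r$spes, 2 * 0.4)                   # k = 2K doubles es
  r <- significance_proportion_correction(0.4, c("A"), character(),
                                          c("A", "B"))
  expect_equal(r$spes, 0)                         # K = 0 flagged as 0
})

test_that("permutation FDR is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 17, n_snps = 1500, n_genes = 150, n_sets = 12,
                    genes_per_set = 12, n_planted_sets = 1, planted_effect = 3)
  lay <- gen_gene_universe(cfg)
  st <- gen_gwas_summary(cfg, lay)
  map <- map_snps_to_genes(st, lay$annotations)
  r1 <- permutation_fdr(st, map, lay$sets, n_perm = 120, seed = 9, size_min = 5)
  r2 <- permutation_fdr(st, map, lay$sets, n_perm = 120, seed = 9, size_min = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$q_fdr >= 0 & r1$q_fdr <= 1))
  expect_true(all(r1$es >= -1 & r1$es <= 1))
  expect_error(permutation_fdr(st, map, lay$sets, n_perm = 50, seed = 1),
               "n_perm")
})

test_that("permutation p-values are uniform for a fixed null set", {
  # exchangeable p-values: p_perm over replicate draws should be uniform on
  # the achievable grid; Kolmogorov band at n = 200 draws
  cfg <- sim_config(seed = 50, n_snps = 400, n_genes = 60, n_sets = 1,
                    genes_per_set = 15, n_planted_sets = 0, planted_effect = 0)
  lay <- gen_gene_universe(cfg)
  map <- map_snps_to_genes(gen_gwas_summary(cfg, lay), lay$annotations)
  draws <- vapply(1:200, function(i) {
    cfg_i <- sim_config(seed = 1000 + i, n_snps = 400, n_genes = 60, n_sets = 1,
                        genes_per_set = 15, n_planted_sets = 0, planted_effect = 0)
    st <- gen_gwas_summary(cfg_i, lay)
    permutation_fdr(st, map, lay$sets, n_perm = 100, seed = i,
                    size_min = 5)$p_perm[1]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(draws, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("set selection applies strict FDR and size bounds", {
  res <- data.frame(set_id = c("a", "b", "c", "d"),
                    n_genes_in_universe = c(10L, 10L, 201L, 9L),
                    es = 0.5, spes = 0.5, k = 0.2, K = 0.1,
                    p_perm = 0.01, q_fdr = c(0.05, 0.049, 0.001, 0.001))
  expect_equal(select_gene_sets(res), "b")   # q=0.05 excluded; size 201 and 9 excluded
})

test_that("tier extraction nests functional within mapped, with proxies", {
  map <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                    gene_id = c("G1", "G1", "G2"), stringsAsFactors = FALSE)
  sets <- list(S1 = "G1", S2 = "G2")
  fi <- functional_index(data.frame(snp_id = "rs1", functional_class = "eqtl"),
                         proxies = data.frame(snp_a = "rs2", snp_b = "rs9",
                                              r2 = 0.9))
  t1 <- extract_tier_snps("S1", sets, map, fi)
  expect_equal(t1$mapped, c("rs1", "rs2"))
  expect_equal(t1$functional, "rs1")          # rs9 proxy target unannotated
  fi2 <- functional_index(data.frame(snp_id = c("rs1", "rs9"),
                                     functional_class = c("eqtl", "coding")),
                          proxies = data.frame(snp_a = "rs2", snp_b = "rs9",
                                               r2 = 0.9))
  t2 <- extract_tier_snps("S1", sets, map, fi2, r2_proxy = 0.8)
  expect_equal(t2$functional, c("rs1", "rs2"))  # functionality via proxy
  t3 <- extract_tier_snps("S1", sets, map, fi2, r2_proxy = 0.95)
  expect_equal(t3$functional, "rs1")            # threshold above the pair
  expect_warning(t0 <- extract_tier_snps(character(), sets, map, fi), "empty")
  expect_length(t0$mapped, 0)
  expect_length(t0$functional, 0)
})

test_that("engine q-values match an oracle that replays stored permutations", {
  # tiny instance: universe of <= 8 genes, 3 sets; the oracle recomputes
  # gene scores / ES / SPES / p / q from the same permutation stream using
  # plain loops, independent of the engine's vectorized internals
  ann <- data.frame(gene_id = paste0("G", 1:8), chrom = "chr1",
                    start = seq(1e5, 8e5, by = 1e5),
                    end = seq(1e5, 8e5, by = 1e5) + 1e4,
                    strand = "+", stringsAsFactors = FALSE)
  set.seed(60)
  pos <- as.integer(rep(ann$start, each = 3) + sample.int(9000, 24))
  st <- stats_at(pos, p = runif(24))
  map <- map_snps_to_genes(st, ann)
  sets <- list(SA = c("G1", "G2", "G3"), SB = c("G4", "G5"),
               SC = c("G2", "G6", "G7", "G8"))
  n_perm <- 2000
  res <- permutation_fdr(st, map, sets, n_perm = n_perm, seed = 3,
                         top_frac = 0.25, size_min = 2, size_max = 8)

  # oracle
  slog <- -log10(quantile(st$pvalue, 0.25, type = 1, names = FALSE))
  spes_all <- function(v) {                       # v = -log10 p per SNP
    sc <- sapply(ann$gene_id, function(g) {
      snps <- map$snp_id[map$gene_id == g]
      max(v[match(snps, st$snp_id)])
    })
    ord <- order(-sc, names(sc))
    ranked <- sc[ord]
    sig <- names(sc)[sc >= slog - 1e-12]
    K <- length(sig) / 8
    sapply(sets, function(s) {
      es <- enrichment_score(ranked, s)
      k <- length(intersect(sig, s)) / length(s)
      if (K == 0) 0 else es * k / K
    })
  }
  obs <- spes_all(-log10(st$pvalue))
  set.seed(3)
  perm <- matrix(NA_real_, 3, n_perm)
  for (b in seq_len(n_perm)) {
    perm[, b] <- spes_all(sample(-log10(st$pvalue)))
  }
  p_or <- (1 + rowSums(perm >= obs)) / (1 + n_perm)
  q_raw <- sapply(obs, function(t) min(1, mean(colSums(perm >= t)) / sum(obs >= t)))
  o <- order(obs)
  q_or <- q_raw; q_or[o] <- cummin(q_raw[o])
  expect_equal(res$spes, unname(obs), tolerance = 1e-12)
  expect_equal(res$p_perm, unname(p_or), tolerance = 1e-12)
  expect_equal(res$q_fdr, unname(q_or), tolerance = 1e-12)
})
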