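test_that("gene layout: gaps exceed twice the flank unless overlap is requested", {
  cfg <- sim_config(seed = 101, n_snps = 500, n_genes = 60, n_sets = 6,
                    genes_per_set = 10)
  lay <- gen_gene_universe(cfg)
  st <- gen_gwas_summary(cfg, lay)
  map <- map_snps_to_genes(st, lay$annotations, cfg$flank_bp)
  expect_equal(anyDuplicated(map$snp_id), 0L)    # single-valued map

  cfg_ov <- sim_config(seed = 101, n_snps = 500, n_genes = 60, n_sets = 6,
                       genes_per_set = 10, overlapping_genes = TRUE)
  lay_ov <- gen_gene_universe(cfg_ov)
  st_ov <- gen_gwas_summary(cfg_ov, lay_ov)
  map_ov <- map_snps_to_genes(st_ov, lay_ov$annotations, cfg_ov$flank_bp)
  expect_gt(anyDuplicated(map_ov$snp_id), 0L)    # some SNP maps to 2 genes
})

test_that("same seed gives byte-identical bundles; different seed differs", {
  cfg <- sim_config(seed = 102, n_snps = 300, n_genes = 40, n_sets = 5,
                    genes_per_set = 8, n_planted_sets = 2, n_samples = 30)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  p1 <- write_sim_bundle(cfg, d1)
  p2 <- write_sim_bundle(cfg, d2)
  for (f in c("summary", "gmt", "genes_bed", "functional", "phenotypes")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), label = f)
  }
  expect_identical(readBin(paste0(p1$geno_prefix, ".bed"), "raw", 1e6),
                   readBin(paste0(p2$geno_prefix, ".bed"), "raw", 1e6))
  cfg3 <- sim_config(seed = 103, n_snps = 300, n_genes = 40, n_sets = 5,
                     genes_per_set = 8, n_planted_sets = 2, n_samples = 30)
  d3 <- file.path(tempdir(), "simC")
  p3 <- write_sim_bundle(cfg3, d3)
  expect_false(identical(readLines(p1$summary), readLines(p3$summary)))
})

test_that("null summary statistics are uniform; planted genes separate", {
  rejections <- vapply(1:20, function(i) {
    cfg <- sim_config(seed = 200 + i, n_snps = 1000, n_genes = 100, n_sets = 10,
                      genes_per_set = 10, planted_effect = 0)
    lay <- gen_gene_universe(cfg)
    st <- gen_gwas_summary(cfg, lay)
    suppressWarnings(ks.test(st$pvalue, "punif")$p.value) < 0.01
  }, logical(1))
  expect_lte(sum(rejections), 1L)                 # 19/20 seeds non-significant

  cfg <- sim_config(seed = 104, n_snps = 4000, n_genes = 200, n_sets = 20,
                    genes_per_set = 15, n_planted_sets = 2, planted_effect = 3)
  lay <- gen_gene_universe(cfg)
  st <- gen_gwas_summary(cfg, lay)
  map <- map_snps_to_genes(st, lay$annotations, cfg$flank_bp)
  gs <- compute_gene_scores(map, st)
  planted_genes <- intersect(unique(unlist(lay$sets[lay$planted_sets])),
                             gs$gene_id)
  null_med <- median(gs$score[!gs$gene_id %in% planted_genes])
  frac_sep <- mean(gs$score[gs$gene_id %in% planted_genes] > null_med)
  expect_gt(frac_sep, 0.99)
})

test_that("generated genotype frequencies track the drawn MAFs under HWE", {
  cfg <- sim_config(seed = 105, n_snps = 600, n_genes = 60, n_sets = 6,
                    genes_per_set = 10, n_samples = 500)
  lay <- gen_gene_universe(cfg)
  gt <- gen_genotypes(cfg, lay)
  emp <- colMeans(gt$geno$dosage) / 2
  se <- sqrt(gt$maf * (1 - gt$maf) / (2 * cfg$n_samples))
  expect_gte(mean(abs(emp - gt$maf) <= 3 * se), 0.95)
  st <- variant_stats(gt$geno)$variant
  expect_lte(mean(st$hwe_p < 1e-6), 0.01)         # HWE filter removes <=1%
})

test_that("functional fraction 0 and 1 collapse the functional tier", {
  cfg <- sim_config(seed = 106, n_snps = 400, n_genes = 40, n_sets = 5,
                    genes_per_set = 8, n_planted_sets = 2)
  lay <- gen_gene_universe(cfg)
  st <- gen_gwas_summary(cfg, lay)
  map <- map_snps_to_genes(st, lay$annotations, cfg$flank_bp)
  mapped <- unique(map$snp_id)

  cfg0 <- sim_config(seed = 106, frac_functional = 0)
  fa0 <- gen_functional_annotations(cfg0, mapped)
  expect_equal(nrow(fa0$annotations), 0L)
  cfg1 <- sim_config(seed = 106, frac_functional = 1)
  fa1 <- gen_functional_annotations(cfg1, mapped)
  fi <- functional_index(fa1$annotations)
  expect_true(all(is_functional(fi, mapped)))
  # fixed seed -> identical assignment
  fa1b <- gen_functional_annotations(cfg1, mapped)
  expect_identical(fa1, fa1b)
})

test_that("noise-free longitudinal generator is recovered by the model exactly", {
  cfg <- sim_config(seed = 107, beta_profile = list(type = "constant", c = 0.7),
                    noise_sd = 0, subject_sd = 0, n_samples = 60,
                    covariate_effects = c())
  prs_z <- setNames(rnorm(60), sprintf("S%04d", 1:60))
  sim <- gen_longitudinal(cfg, z_transform(prs_z))
  fit <- fit_tvem(sim$records, tvem_spec(time_varying = "prs"))
  cv <- fit$curves[fit$curves$predictor == "prs", ]
  expect_lt(max(abs(cv$beta - 0.7)), 1e-6)
  # truth sidecar carries the generating profile
  expect_equal(sim$truth$beta_profile$c, 0.7)
  # regeneration with the stored seed reproduces the records exactly
  sim2 <- gen_longitudinal(cfg, z_transform(prs_z))
  expect_identical(sim$records, sim2$records)
})

test_that("beta profiles evaluate their stated functional forms", {
  t <- c(2, 3.5, 5)
  expect_equal(beta_profile_fun(list(type = "constant", c = 2), t), rep(2, 3))
  expect_equal(beta_profile_fun(list(type = "linear", a = 1, b = 2), t),
               1 + 2 * t)
  expect_equal(beta_profile_fun(list(type = "bump", center = 3.5, width = 0.5,
                                     height = 2), 3.5), 2)
  expect_lt(beta_profile_fun(list(type = "bump", center = 3.5, width = 0.3,
                                  height = 2), 5), 1e-4)
  expect_error(beta_profile_fun(list(type = "sawtooth"), t), "unknown")
})
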