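#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with defaults sized so
#' the full pipeline exercises in minutes: a 20,000-SNP / 1,000-gene genome
#' on simulated chromosomes, 100 gene sets of which 5 carry planted signal,
#' 500 genotyped samples, and 4-8 phenotype observations per subject over a
#' continuous age range.
#'
#' @param seed Master seed; fixes every generated file.
#' @param n_snps,n_genes,n_sets,genes_per_set,n_planted_sets Genome and
#'   gene-set dimensions.
#' @param planted_effect Mean `-log10 p` uplift for SNPs in planted-set genes
#'   (0 = null).
#' @param flank_bp Flank used when laying out genes (gaps exceed `2*flank_bp`
#'   unless `overlapping_genes`).
#' @param overlapping_genes If `TRUE`, genes are packed so some flanks
#'   overlap and SNPs can map to two genes.
#' @param maf_range Range minor allele frequencies are drawn from.
#' @param n_samples Genotyped sample count.
#' @param n_populations,freq_divergence Optional population structure:
#'   number of populations and the scale of their allele-frequency
#'   divergence.
#' @param missing_rate Genotype missingness rate (default 0).
#' @param frac_functional Fraction of mapped SNPs given a functional
#'   annotation.
#' @param beta_profile Age-varying PRS effect for the phenotype generator:
#'   `list(type = "constant", c =)`, `list(type = "linear", a =, b =)`,
#'   `list(type = "sine", amplitude =, period =)`, or
#'   `list(type = "bump", center =, width =, height =)`.
#' @param ages_per_subject Integer range `c(lo, hi)` of observations per
#'   subject.
#' @param age_range Observation ages are uniform over this range (years).
#' @param noise_sd Residual SD of the phenotype.
#' @param subject_sd SD of the subject random intercept (within-subject
#'   correlation; default 0.5).
#' @param covariate_effects Named numeric vector of time-invariant covariate
#'   effects (covariates are generated standard normal / Bernoulli(0.5) for
#'   names ending in `_bin`).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_snps = 20000, n_genes = 1000, n_sets = 100,
                       genes_per_set = 30, n_planted_sets = 5,
                       planted_effect = 3, flank_bp = 20000,
                       overlapping_genes = FALSE,
                       maf_range = c(0.05, 0.5),
                       n_samples = 500, n_populations = 1,
                       freq_divergence = 0, missing_rate = 0,
                       frac_functional = 0.3,
                       beta_profile = list(type = "constant", c = 0.3),
                       ages_per_subject = c(4, 8), age_range = c(2, 5),
                       noise_sd = 1, subject_sd = 0.5,
                       covariate_effects = c(sex_bin = 0.2)) {
  cfg <- as.list(environment())
  stopifnot(n_planted_sets <= n_sets, frac_functional >= 0, frac_functional <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, n_populations >= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(cfg, class = "sim_config")
}

#' Generate the simulated gene universe
#'
#' Lays out non-overlapping genes along simulated chromosomes with
#' inter-gene gaps exceeding `2*flank_bp` (so each SNP maps to at most one
#' gene), or overlapping flanks when `overlapping_genes`. SNPs are placed
#' inside genes, in flanks, and intergenically; gene-set membership is
#' sampled without replacement, with the planted sets recorded.
#'
#' @param config A [sim_config()].
#' @return List: `annotations` (gene `data.frame`), `sets`
#'   (named list of gene ids), `planted_sets` (set ids), `snp_layout`
#'   (`data.frame`: `snp_id`, `chrom`, `pos`).
#' @export
gen_gene_universe <- function(config) {
  set.seed(config$seed)
  ng <- config$n_genes
  gene_len <- 10000L
  gap <- if (config$overlapping_genes) as.integer(config$flank_bp)
         else as.integer(2L * config$flank_bp + 10000L)
  genes_per_chrom <- ceiling(ng / 20)
  chrom <- paste0("chr", rep(seq_len(20), each = genes_per_chrom))[seq_len(ng)]
  idx_on_chrom <- stats::ave(seq_len(ng), chrom, FUN = seq_along)
  start <- 1L + (idx_on_chrom - 1L) * (gene_len + gap)
  annotations <- data.frame(gene_id = sprintf("G%04d", seq_len(ng)),
                            chrom = chrom, start = start,
                            end = start + gene_len - 1L,
                            strand = sample(c("+", "-"), ng, replace = TRUE),
                            stringsAsFactors = FALSE)
  # planted sets take disjoint genes from a reserved pool so that the
  # remaining ("null") sets carry no planted signal: the planted/null labels
  # then mean what power and FDR calibration require
  n_pl <- config$n_planted_sets
  pool <- sample(annotations$gene_id, n_pl * config$genes_per_set)
  rest <- setdiff(annotations$gene_id, pool)
  if (length(rest) < config$genes_per_set)
    stop("config error: not enough genes outside the planted pool")
  sets <- lapply(seq_len(config$n_sets), function(i) {
    if (i <= n_pl)
      sort(pool[(i - 1L) * config$genes_per_set + seq_len(config$genes_per_set)])
    else sort(sample(rest, config$genes_per_set))
  })
  names(sets) <- sprintf("SET%03d", seq_len(config$n_sets))
  planted <- names(sets)[seq_len(n_pl)]

  # SNPs: ~60% inside gene bodies, 20% in flanks, 20% intergenic
  n_snps <- config$n_snps
  kind <- sample(c("body", "flank", "inter"), n_snps, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  gi <- sample.int(ng, n_snps, replace = TRUE)
  pos <- integer(n_snps)
  b <- kind == "body"
  pos[b] <- annotations$start[gi[b]] +
    sample.int(gene_len, sum(b), replace = TRUE) - 1L
  f <- kind == "flank"
  off <- sample.int(config$flank_bp, sum(f), replace = TRUE)
  side <- sample(c(-1L, 1L), sum(f), replace = TRUE)
  pos[f] <- ifelse(side < 0, annotations$start[gi[f]] - off,
                   annotations$end[gi[f]] + off)
  it <- kind == "inter"
  # beyond the flank, in the gap after the gene (exists by construction)
  pos[it] <- annotations$end[gi[it]] + config$flank_bp +
    sample.int(5000L, sum(it), replace = TRUE)
  pos <- pmax(pos, 1L)
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, n_snps, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(bases, a), 1L), character(1))
  snp_layout <- data.frame(snp_id = sprintf("rs%06d", seq_len(n_snps)),
                           chrom = annotations$chrom[gi], pos = pos,
                           allele_a = a1, allele_b = unname(a2),
                           stringsAsFactors = FALSE)
  o <- order(snp_layout$chrom, snp_layout$pos)
  snp_layout <- snp_layout[o, , drop = FALSE]
  rownames(snp_layout) <- NULL
  list(annotations = annotations, sets = sets, planted_sets = planted,
       snp_layout = snp_layout)
}

#' Generate GWAS summary statistics with planted enrichment
#'
#' Null SNPs draw p-values uniform on (0, 1); SNPs mapping to a gene of a
#' planted set draw `p = 10^(-e)` with `e ~ planted_effect + Exponential(1)`
#' (truncated to (0, 1]). Effect directions are random signs; alleles are
#' random distinct bases.
#'
#' @param config A [sim_config()].
#' @param layout Output of [gen_gene_universe()].
#' @return Summary-statistics `data.frame` in the layout's SNP order.
#' @export
gen_gwas_summary <- function(config, layout) {
  set.seed(config$seed + 1L)
  snp <- layout$snp_layout
  n <- nrow(snp)
  p <- stats::runif(n)
  if (config$planted_effect > 0 && length(layout$planted_sets)) {
    planted_genes <- unique(unlist(layout$sets[layout$planted_sets]))
    map <- map_snps_to_genes(
      data.frame(snp_id = snp$snp_id, chrom = snp$chrom, pos = snp$pos,
                 stringsAsFactors = FALSE),
      layout$annotations, config$flank_bp)
    hit <- snp$snp_id %in% map$snp_id[map$gene_id %in% planted_genes]
    e <- config$planted_effect + stats::rexp(sum(hit))
    p[hit] <- pmin(1, 10^(-e))
  }
  data.frame(snp_id = snp$snp_id, chrom = snp$chrom, pos = snp$pos,
             allele_effect = snp$allele_a, allele_other = snp$allele_b,
             pvalue = p,
             direction = sample(c(1, -1), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate diploid genotypes under Hardy-Weinberg sampling
#'
#' Per variant, a MAF is drawn from `maf_range` and genotypes are binomial
#' (2, maf) draws — Hardy-Weinberg by construction. With `n_populations > 1`
#' population allele frequencies diverge by logit-scale normal offsets of SD
#' `sqrt(freq_divergence)` around the ancestral frequency, and sample
#' population labels are recorded. Optional missingness is
#' missing-completely-at-random.
#'
#' @param config A [sim_config()].
#' @param layout Output of [gen_gene_universe()].
#' @return List: `geno` (a [genotype_matrix()]), `maf` (generating
#'   frequencies, ancestral), `population` (per-sample labels).
#' @export
gen_genotypes <- function(config, layout) {
  set.seed(config$seed + 2L)
  snp <- layout$snp_layout
  m <- nrow(snp); n <- config$n_samples
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pop <- sort(rep_len(seq_len(config$n_populations), n))
  if (config$n_populations > 1L && config$freq_divergence > 0) {
    logit <- function(x) log(x / (1 - x))
    inv <- function(x) 1 / (1 + exp(-x))
    freq_pop <- vapply(seq_len(config$n_populations), function(k)
      inv(logit(maf) + stats::rnorm(m, 0, sqrt(config$freq_divergence))),
      numeric(m))
    d <- matrix(stats::rbinom(n * m, 2L, t(freq_pop[, pop])), nrow = n,
                ncol = m, byrow = FALSE)
  } else {
    d <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(n * m) < config$missing_rate
    d[miss] <- NA_integer_
  }
  # genotypes count the same allele the summary stats call the effect allele
  variants <- data.frame(snp_id = snp$snp_id, chrom = snp$chrom, pos = snp$pos,
                         allele_counted = snp$allele_a, allele_other = snp$allele_b,
                         stringsAsFactors = FALSE)
  geno <- genotype_matrix(d, sprintf("S%04d", seq_len(n)), variants)
  list(geno = geno, maf = maf, population = pop)
}

#' Evaluate a beta profile at given ages
#'
#' @param profile A `beta_profile` list (see [sim_config()]).
#' @param t Ages.
#' @return Numeric vector of effects.
#' @export
beta_profile_fun <- function(profile, t) {
  switch(profile$type,
         constant = rep(profile$c, length(t)),
         linear = profile$a + profile$b * t,
         sine = {
           amp <- if (is.null(profile$amplitude)) 1 else profile$amplitude
           per <- if (is.null(profile$period)) 2 * pi else profile$period
           amp * sin(2 * pi * t / per)
         },
         bump = profile$height *
           exp(-0.5 * ((t - profile$center) / profile$width)^2),
         stop("unknown beta profile type: ", profile$type))
}

#' Generate longitudinal phenotypes with a known time-varying PRS effect
#'
#' `y = beta0(t) + beta_profile(t) * prs_z + gamma' z + u_subject + noise`,
#' with `beta0(t) = 1 + 0.2 t`, a subject random intercept of SD
#' `subject_sd` (so the cluster-robust machinery is actually exercised), and
#' Gaussian noise of SD `noise_sd`. All generating values are returned in a
#' `truth` element suitable for a sidecar.
#'
#' @param config A [sim_config()].
#' @param prs_z Named per-sample standardized score vector driving the
#'   time-varying effect.
#' @return List: `records` (long `data.frame`), `truth` (list of generator
#'   parameters incl. per-subject random intercepts).
#' @export
gen_longitudinal <- function(config, prs_z) {
  set.seed(config$seed + 3L)
  ids <- names(prs_z)
  if (is.null(ids)) {
    ids <- sprintf("S%04d", seq_along(prs_z))
    names(prs_z) <- ids
  }
  n <- length(prs_z)
  obs_choices <- seq(config$ages_per_subject[1], config$ages_per_subject[2])
  nobs <- obs_choices[sample.int(length(obs_choices), n, replace = TRUE)]
  covs <- names(config$covariate_effects)
  zmat <- vapply(covs, function(cv) {
    if (grepl("_bin$", cv)) stats::rbinom(n, 1, 0.5) else stats::rnorm(n)
  }, numeric(n))
  if (length(covs) == 0L) zmat <- matrix(0, n, 0)
  u <- stats::rnorm(n, 0, config$subject_sd)
  rows <- lapply(seq_len(n), function(i) {
    t <- sort(stats::runif(nobs[i], config$age_range[1], config$age_range[2]))
    beta0 <- 1 + 0.2 * t
    bt <- beta_profile_fun(config$beta_profile, t)
    zeff <- if (length(covs)) sum(zmat[i, ] * config$covariate_effects) else 0
    y <- beta0 + bt * prs_z[i] + zeff + u[i] +
      stats::rnorm(nobs[i], 0, config$noise_sd)
    df <- data.frame(subject_id = ids[i], age = t, phenotype = y,
                     prs = unname(prs_z[i]), stringsAsFactors = FALSE)
    for (k in seq_along(covs)) df[[covs[k]]] <- zmat[i, k]
    df
  })
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  truth <- list(seed = config$seed, beta_profile = config$beta_profile,
                beta0 = "1 + 0.2*t", covariate_effects = config$covariate_effects,
                noise_sd = config$noise_sd, subject_sd = config$subject_sd,
                subject_intercepts = stats::setNames(u, ids))
  list(records = records, truth = truth)
}

#' Generate functional annotations for mapped SNPs
#'
#' Assigns a random class from \{coding, regulatory, eqtl\} to
#' `frac_functional` of the mapped SNPs; optionally emits proxy pairs pairing
#' some unannotated mapped SNPs to annotated ones with r^2 drawn uniform in
#' `[0.5, 1]`.
#'
#' @param config A [sim_config()].
#' @param mapped_snp_ids Character vector of mapped SNP ids.
#' @param n_proxies Number of proxy pairs to generate (default 0).
#' @return List: `annotations` (`data.frame`: `snp_id`, `functional_class`),
#'   `proxies` (`data.frame`, possibly empty).
#' @export
gen_functional_annotations <- function(config, mapped_snp_ids, n_proxies = 0) {
  set.seed(config$seed + 4L)
  n_fun <- round(config$frac_functional * length(mapped_snp_ids))
  fun_ids <- if (n_fun > 0) sort(sample(mapped_snp_ids, n_fun)) else character()
  annotations <- data.frame(
    snp_id = fun_ids,
    functional_class = if (n_fun > 0)
      sample(c("coding", "regulatory", "eqtl"), n_fun, replace = TRUE)
      else character(),
    stringsAsFactors = FALSE)
  proxies <- data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  unann <- setdiff(mapped_snp_ids, fun_ids)
  if (n_proxies > 0 && length(unann) && length(fun_ids)) {
    k <- min(n_proxies, length(unann))
    proxies <- data.frame(snp_a = sample(unann, k),
                          snp_b = sample(fun_ids, k, replace = TRUE),
                          r2 = stats::runif(k, 0.5, 1),
                          stringsAsFactors = FALSE)
  }
  list(annotations = annotations, proxies = proxies)
}

#' Write a full synthetic input bundle to disk
#'
#' Materializes every input format the pipeline reads — summary TSV, GMT,
#' gene BED, PLINK triplet, functional/proxy TSVs, long-format phenotype CSV
#' — plus `truth.json` recording the generating parameters.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param genotype_format `"plink"` or `"vcf"`.
#' @return Invisibly, the named list of written paths.
#' @export
write_sim_bundle <- function(config, out_dir, genotype_format = c("plink", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- gen_gene_universe(config)
  stats <- gen_gwas_summary(config, layout)
  gt <- gen_genotypes(config, layout)
  map <- map_snps_to_genes(stats, layout$annotations, config$flank_bp)
  fun <- gen_functional_annotations(config, unique(map$snp_id))
  # direction-oriented risk scoring on the all-SNP tier drives the phenotype
  prs <- build_prs(gt$geno, stats, tier = "all", threshold = 0.05)
  ph <- gen_longitudinal(config, prs$z)

  paths <- list(
    summary = file.path(out_dir, "summary_stats.tsv"),
    gmt = file.path(out_dir, "gene_sets.gmt"),
    genes_bed = file.path(out_dir, "genes.bed"),
    functional = file.path(out_dir, "functional.tsv"),
    proxies = file.path(out_dir, "proxies.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    geno_prefix = file.path(out_dir, "genotypes"),
    truth = file.path(out_dir, "truth.json"))
  data.table::fwrite(stats, paths$summary, sep = "\t")
  write_gmt(layout$sets, paths$gmt)
  bed <- data.frame(layout$annotations$chrom, layout$annotations$start - 1L,
                    layout$annotations$end, layout$annotations$gene_id,
                    0L, layout$annotations$strand)
  data.table::fwrite(bed, paths$genes_bed, sep = "\t", col.names = FALSE)
  data.table::fwrite(fun$annotations, paths$functional, sep = "\t")
  data.table::fwrite(fun$proxies, paths$proxies, sep = "\t")
  data.table::fwrite(ph$records, paths$phenotypes)
  if (genotype_format == "plink") write_plink(gt$geno, paths$geno_prefix)
  else write_vcf_genotypes(gt$geno, paste0(paths$geno_prefix, ".vcf"))
  truth <- list(config = unclass(config),
                planted_sets = layout$planted_sets,
                beta0 = ph$truth$beta0,
                subject_sd = config$subject_sd)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(paths)
}
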