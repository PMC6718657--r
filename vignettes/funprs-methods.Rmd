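---
title: "Methods: functionally informed polygenic scores and time-varying genetic effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functionally informed polygenic scores and time-varying genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Standard threshold-based polygenic risk scores (PRS) select every variant
below a p-value cutoff in a discovery GWAS, with no regard to whether those
variants fall in biologically coherent pathways or have any annotated
function, and are usually transported across developmental periods without
asking whether the genetic architecture is stable. `funprs` implements the
alternative this package is built around: filter GWAS summary statistics
through a competitive gene-set enrichment analysis into nested *mapped* and
*functional* SNP tiers, build unit-weighted additive scores from each tier,
and test the scores against a longitudinal phenotype with a time-varying
effect model (TVEM) so that the age profile of the association is estimated
rather than assumed.

The pipeline consumes only standard files — GWAS summary TSV, GMT gene-set
collections, BED/GFF3 gene annotations, PLINK/VCF genotypes, long-format
phenotype CSV — and a synthetic-data module generates all of them with known
ground truth, so every stage is testable without any external download.

# Gene-set enrichment of summary statistics

**SNP-to-gene mapping.** A SNP maps to a gene when its position falls within
a symmetric flank of the gene body, `[start - flank, end + flank]`, default
flank 20 kb, irrespective of strand. A SNP may map to several genes where
flanks overlap.

**Gene statistic.** Each gene is scored by its best mapped SNP:
`score = max(-log10 p)`. A phrase like "ranked by the number of SNPs and
their p-values" is ambiguous; here the SNP count enters only through the
maximum being taken over more SNPs, which is the i-GSEA-style convention.
Genes with at least one mapped SNP form the analysis *universe*. Ranking
ties are broken lexicographically by gene id so runs are bit-reproducible.

**Enrichment score.** Walking the ranked universe, set members ("hits")
increment a running sum by `score / sum(scores of set members)` and
non-members decrement by `1/(N - n)`; the enrichment score (ES) is the
extremum of largest magnitude, with near-ties (within 1e-12) resolved toward
the positive extremum. If all member scores are zero, hits contribute
nothing and the ES is negative. ES lies in `[-1, 1]`.

**Significance-proportion correction.** The competitive correction rescales
ES by `k/K`, where `k` is the proportion of a set's genes whose best SNP
lies in the top fraction (default 5%) of all SNP p-values and `K` is that
proportion in the whole universe. When `K = 0` the corrected score (SPES) is
defined as 0. This sharpens the separation between sets that are enriched in
genuinely significant genes and sets that merely drift upward in the
ranking.

**SNP-label permutation FDR.** The permutation unit is the SNP label:
p-values are shuffled across SNP ids, keeping the SNP-to-gene topology
fixed, which is the only permutation available when the input is summary
statistics rather than subject-level genotypes. Each of `n_perm` (default
1000, minimum 100) permutations recomputes gene scores, ES and SPES for
every set. For a set with observed SPES `s`,
`p_perm = (1 + #{perm SPES >= s}) / (1 + n_perm)`; the FDR at threshold `t`
is the mean permutation count of sets at or above `t` divided by the
observed count, capped at 1, and each set's q-value is the minimum FDR over
all thresholds that include it (which enforces monotonicity in `t`). Sets
are tested only when they have 10–200 genes in the universe, and retained at
`q < 0.05` (both strict bounds, both configurable).

**Tiers.** The *mapped* tier is every SNP mapping to any gene of a retained
set; the *functional* tier is the subset annotated as coding, regulatory or
eQTL — directly or through an LD proxy pair with `r² >= 0.8` (configurable).
By construction `functional ⊆ mapped ⊆ all`.

# Polygenic scores

Scoring SNPs are those with `p < 0.05` (strict; the threshold is exposed so
a stricter `p < 0.01` sensitivity analysis is one flag away), intersected
with the tier. Weights are fixed at 1; the risk allele is the effect allele
when the reported direction is positive and the other allele when negative.
Direction is mandatory at scoring time: a unit-weighted *risk* score is
undefined without allele orientation, so a missing direction is a loud
error, as is a risk allele that matches neither recorded allele (no silent
strand guessing). Missing genotypes are mean-imputed per SNP (PLINK's
scoring default); an omit-and-rescale policy is available. Raw scores are
Z-standardized (`n - 1` denominator) for interpretability.

# Genotype QC and ancestry

The QC sequence is fixed so that removal reason codes are unambiguous:
variant missingness `>= 5%`, then sample missingness `>= 5%` (both
inclusive boundaries), then `MAF < 1%`, then Hardy-Weinberg exact
`p < 1e-6`, with MAF and HWE recomputed after sample removal. The HWE test
is the exact conditional (Levene-Haldane) enumeration over heterozygote
counts, computed in log space; it is label-symmetric and returns 1 for
monomorphic variants.

LD pruning is a PLINK-style sliding window (defaults: 50 kb physical
window, step 5 SNPs, `r² > 0.5` removal; none of these is stated by the
upstream analysis, so all are configurable). Within a window the
highest-r² offending pair is resolved by removing the lower-MAF member,
ties by the later position; a final verification pass guarantees that no
retained pair within the window distance exceeds the bound. An optional BED
of long-range-LD regions (e.g. the MHC) can be excluded up front; none is
shipped. HWE is computed on all samples without ancestry stratification —
a known limitation.

Ancestry PCA standardizes each variant to `(d - 2p) / sqrt(2p(1-p))`,
sets missing entries to 0 after centering, drops monomorphic variants, and
takes the top-k (default 20) eigendecomposition of the sample-by-sample
covariance divided by the variant count. Under this convention the null
bulk of eigenvalues sits near 1 and population structure appears as leading
eigenvalues well above 1; the exact eigenvalue scaling of any particular
external tool is not reproduced, only the subspace, which is what the
covariates need. Eigenvector signs are fixed (largest-magnitude loading
positive) so runs are comparable. A shifted square-root utility is provided
for skewed covariates (the shift is recorded); applying it is always the
caller's decision.

# The time-varying effect model

The model is

`y_ij = Σ_v β_v(t_ij) x_vij + γ' z_i + ε_ij`

with every time-varying coefficient (including the intercept) expanded in a
B-spline basis: cubic, 10 equally spaced interior knots over the observed
age range, clamped boundary knots. Ten knots is deliberately generous — the
difference penalty, not the knot count, controls roughness (the P-spline
principle). Estimation is penalized least squares with penalty
`λ ||D θ_v||²` per coefficient function.

**Penalty construction.** `D` is the order-2 *divided-difference* matrix
over the basis's Greville abscissae rather than the plain difference
matrix. With clamped boundary knots the Greville sites are unequally spaced
near the boundary, so plain second differences do not annihilate linear
functions there; divided differences restore the exact property that
`λ → ∞` shrinks each `β_v(t)` to its best linear-in-age fit (and order-1 to
a constant). On the equally spaced interior the two coincide up to scale.

**Smoothing selection.** One `λ` shared across coefficient functions,
chosen from a log-spaced grid (default `1e-4 … 1e6`, 25 points) by
`AIC = n log(RSS/n) + 2 edf`, `edf = tr[(X'X + λP)^{-1} X'X]`.

**Uncertainty.** Within-subject correlation is handled by working
independence plus a cluster-robust sandwich covariance (clusters =
subjects), to which the Bayesian smoothing-bias term `λ σ̂² P` is added
inside the meat: in the independent-error case this reduces to the familiar
P-spline posterior covariance, whose pointwise bands attain near-nominal
coverage where sandwich-only bands systematically undercover at
high-curvature ages (the Nychka argument). Pointwise 95% bands are
`β(t) ± 1.96 se(t)` on a 101-point age grid; an effect is *significant*
where the band excludes zero, and maximal significant runs are reported as
`[age_start, age_end]` intervals at grid resolution. Subgroup analyses
(e.g. intervention vs control) are independent refits per group; no
cross-model test is offered because the framework does not define one.

The design matrix's condition number is reported: nested-tier scores are
substantially correlated, and entering all three as simultaneous
time-varying predictors is statistically legal but can be ill-conditioned —
the diagnostic informs, the user decides.

Ages are years as reals; month-coded inputs should be converted at
ingestion.

# The synthetic-data generator

The generator emulates the statistical structure each stage assumes, not
any particular cohort:

- **Genome layout:** 1,000 genes of 10 kb on 20 chromosomes, inter-gene gaps
  exceeding twice the 20 kb flank (so SNP-to-gene maps are single-valued
  unless overlap mode is requested); 20,000 SNPs placed ~60% in gene bodies,
  20% in flanks, 20% intergenic.
- **Gene sets:** 100 sets of 30 genes. Planted sets (default 5) draw from a
  reserved, mutually disjoint gene pool and the remaining ("null") sets from
  the other genes; without that reservation, null sets absorb planted genes
  by chance and stop being null, which would make power and FDR calibration
  against the labels meaningless. Null sets may overlap each other, as real
  collections do.
- **Summary statistics:** null SNPs draw `p ~ U(0,1)`; SNPs in planted-set
  genes draw `p = 10^(-e)`, `e ~ effect + Exp(1)` (default effect 3).
  Directions are random signs; alleles are shared with the genotype
  generator so scores orient correctly.
- **Genotypes:** per-variant MAF uniform on [0.05, 0.5], binomial(2, maf)
  sampling (Hardy-Weinberg by construction); optional k populations with
  logit-normal frequency divergence (variance parameter 0.1 in the
  structure-recovery settings) and optional missingness.
- **Phenotypes:** `y = (1 + 0.2t) + β(t)·PRS_z + γ'z + u_i + ε`, with
  subject random intercepts (SD 0.5) so the cluster-robust machinery is
  actually exercised, noise SD 1, 4–8 observations per subject over ages
  2–5. β(t) profiles: constant, linear, sine, Gaussian bump. All generating
  values go to a truth sidecar.

What the generator does *not* emulate: realistic LD (variants are
independent given ancestry), genotyping batch effects, item-level
measurement structure of behavioral instruments, and LD-realistic proxy
patterns. Passing tests therefore demonstrate correctness of the
algorithms under their stated assumptions, not robustness to every
pathology of real array data.

# Verification conditions

The test and acceptance suites run at fixed, stated sizes chosen to
exercise each property at meaningful power: exact-test equivalence is
exhaustive over all genotype triples with total ≤ 50 plus 50 larger triples
against a 10⁶-draw Monte-Carlo pairing oracle; enrichment scores are checked
against a literal running-sum oracle on 100 random universes; FDR null
calibration and planted power use an 8,000-SNP / 600-gene universe, 100 or
60 sets, 500 permutations and 20 replicates; PCA structure recovery uses
500 SNPs × 200 samples over 20 seeds; TVEM coverage uses 500 subjects × 4
observations and 200 replicates (50 in the faster acceptance script), with
coverage averaged over the interior 80% of the age grid; bump detection
uses a height-0.5, width-0.5 bump at age 3.5 — a moderate standardized
effect — over 100 replicates.

# Numerical and degenerate-input policy

- Duplicate summary-statistic ids keep the smallest p; p outside (0,1] is
  rejected with a count, p = 0 included (it would map to an infinite score).
- Only biallelic variants are supported; multiallelic sites are rejected
  with a report, not decomposed.
- An all-missing variant has MAF defined as 0 and is flagged.
- Zero-variance score vectors raise an error rather than returning zeros.
- A set equal to, or disjoint from, the universe has no defined enrichment
  score and errors.
- Every stochastic step takes an explicit seed and the run sidecars record
  it; identical seeds give byte-identical outputs.

# Known limitations

Phenotype-label permutation (which would require subject-level genotypes at
GWAS scale), effect-size-weighted scores, threshold-grid optimization,
imputation, liftover, relatedness filtering, random-effects TVEM variants
and simultaneous (rather than pointwise) confidence bands are out of scope.
The gene statistic is the max-SNP convention only; Fisher-combination
alternatives are not implemented.
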