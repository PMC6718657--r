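Package: funprs
Title: Functionally Informed Polygenic Risk Scores with Time-Varying Effect Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds biologically informed, developmentally targeted polygenic
    risk scores (PRS) from GWAS summary statistics. Competitive gene-set
    enrichment of SNP p-values (weighted Kolmogorov-Smirnov statistic with a
    significance-proportion correction and SNP-label permutation FDR) filters
    variants into nested mapped and functional tiers; unit-weighted additive
    scores are computed from genotypes with PLINK-style semantics; genotype QC
    (Hardy-Weinberg exact test, MAF and missingness filters, sliding-window LD
    pruning) and ancestry principal components are provided; and score-phenotype
    associations across age are estimated with a penalized B-spline
    time-varying effect model (TVEM) with cluster-robust pointwise confidence
    bands. A synthetic-data module generates every input format with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    splines,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
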