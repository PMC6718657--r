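#' Map SNPs to genes with a symmetric flanking window
#'
#' A SNP maps to a gene when its position lies within `flank_bp` of the gene
#' body — i.e. in `[start - flank_bp, end + flank_bp]` on the same chromosome.
#' The flank is symmetric regardless of strand, and a SNP may map to several
#' genes. Implemented as interval overlap via IRanges.
#'
#' @param stats Summary-statistics `data.frame` (needs `snp_id`, `chrom`,
#'   `pos`; see [read_summary_stats()]).
#' @param annotations Gene annotation `data.frame` (see
#'   [read_gene_annotation()]).
#' @param flank_bp Flank in base pairs either side of the gene body
#'   (default 20000, i.e. 20 kb upstream and downstream).
#' @return `data.frame` with columns `snp_id`, `gene_id`, one row per mapped
#'   pair.
#' @export
map_snps_to_genes <- function(stats, annotations, flank_bp = 20000) {
  if (nrow(annotations) == 0L) stop("empty gene annotation")
  if (any(is.na(stats$chrom)) || any(is.na(stats$pos)))
    stop("summary statistics lack chrom/pos; cannot map SNPs to genes")
  if (!any(stats$chrom %in% annotations$chrom))
    warning("no shared chromosome names between summary statistics (",
            paste(utils::head(unique(stats$chrom), 3), collapse = ","),
            ") and annotations (",
            paste(utils::head(unique(annotations$chrom), 3), collapse = ","), ")")
  snp_gr <- GenomicRanges::GRanges(stats$chrom,
                                   IRanges::IRanges(stats$pos, stats$pos))
  gene_gr <- GenomicRanges::GRanges(
    annotations$chrom,
    IRanges::IRanges(pmax(1L, annotations$start - flank_bp),
                     annotations$end + flank_bp))
  # seqlevel-mismatch is already reported above with more context
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(snp_gr, gene_gr, ignore.strand = TRUE))
  out <- data.frame(
    snp_id = stats$snp_id[S4Vectors::queryHits(hits)],
    gene_id = annotations$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-level association scores from mapped SNP p-values
#'
#' The gene statistic is the best mapped SNP: `score = max(-log10 p)` over the
#' gene's SNPs (equivalently `-log10` of the smallest p). Genes with no mapped
#' SNP are absent; the set of returned genes is the analysis universe.
#'
#' @param map SNP-to-gene map from [map_snps_to_genes()].
#' @param stats Summary statistics containing every mapped `snp_id`.
#' @return `data.frame` sorted by descending score (ties broken by `gene_id`):
#'   `gene_id`, `score`, `best_snp`, `n_snps`.
#' @export
compute_gene_scores <- function(map, stats) {
  missing <- setdiff(map$snp_id, stats$snp_id)
  if (length(missing))
    stop("consistency error: mapped SNP(s) absent from summary statistics: ",
         paste(utils::head(missing, 5), collapse = ", "))
  p <- stats$pvalue[match(map$snp_id, stats$snp_id)]
  dt <- data.table::data.table(gene_id = map$gene_id, snp_id = map$snp_id,
                               v = -log10(p))
  gs <- dt[, {
    i <- which.max(v)
    list(score = v[i], best_snp = snp_id[i], n_snps = .N)
  }, by = gene_id]
  gs <- as.data.frame(gs)
  gs <- gs[order(-gs$score, gs$gene_id), , drop = FALSE]
  rownames(gs) <- NULL
  gs
}
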