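#' Read gene annotations from BED or GFF3
#'
#' Loads gene coordinates to serve as the substrate for SNP-to-gene mapping.
#' BED input (0-based, half-open) and GFF3 input (1-based, inclusive; only
#' features of type `gene` are kept) are both normalized to the internal
#' 1-based inclusive convention, so a BED interval `[s, e)` and the GFF3
#' interval `[s+1, e]` yield identical annotations.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`; default inferred from the file extension.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"*"`), coordinates 1-based inclusive.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    type <- as.character(gr$type)
    gr <- gr[type == "gene"]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    ids <- as.character(ids)
  } else {
    ids <- as.character(gr$name)
  }
  if (length(gr) == 0L) stop("no gene features found in ", path)
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop("format error: gene identifiers missing in ", path)
  out <- data.frame(
    gene_id = ids,
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr),   # rtracklayer already 1-based inclusive
    end     = GenomicRanges::end(gr),
    strand  = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop("format error: start > end in ", path)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in ", path)
  rownames(out) <- NULL
  out
}
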