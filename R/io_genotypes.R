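#' Read genotypes from PLINK binary or VCF
#'
#' PLINK input is the classic `.bed`/`.bim`/`.fam` triplet (SNP-major, 2 bits
#' per call); the `.bim` A1 allele is the counted allele. VCF input uses the
#' `GT` field of a plain-text VCF; the ALT allele is counted. Multiallelic
#' sites are rejected with a report. Only hard calls are supported.
#'
#' @param path_or_prefix For PLINK, the path prefix of the triplet (or any of
#'   the three file names); for VCF, the file path.
#' @param format `"plink"`, `"vcf"`, or `"auto"` (default: `.vcf` extension
#'   selects VCF).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path_or_prefix, format = c("auto", "plink", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path_or_prefix)) "vcf" else "plink"
  if (format == "plink") read_plink(path_or_prefix) else read_vcf_genotypes(path_or_prefix)
}

#' @rdname read_genotypes
#' @export
read_plink <- function(path_or_prefix) {
  prefix <- sub("\\.(bed|bim|fam)$", "", path_or_prefix)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("PLINK file missing: ", f)
  bimdt <- data.table::fread(bim, header = FALSE, data.table = FALSE,
                             col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  famdt <- data.table::fread(fam, header = FALSE, data.table = FALSE)
  n <- nrow(famdt); m <- nrow(bimdt)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error: not a PLINK .bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("format error: only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)                       # bytes per variant
  if (length(raw) - 3L != bpv * m)
    stop("format error: .bed payload size inconsistent with .bim/.fam dimensions")
  codes <- plink_decode_bytes(raw[-(1:3)], n, m, bpv)
  variants <- data.frame(snp_id = as.character(bimdt$snp_id),
                         chrom = as.character(bimdt$chrom),
                         pos = as.integer(bimdt$pos),
                         allele_counted = as.character(bimdt$a1),
                         allele_other = as.character(bimdt$a2),
                         stringsAsFactors = FALSE)
  genotype_matrix(codes, as.character(famdt[[2]]), variants)
}

# Expand the 2-bit codes of a SNP-major .bed payload into an n x m dosage
# matrix of A1-allele counts. PLINK1 coding: 00=hom A1 (2), 10=het (1),
# 11=hom A2 (0), 01=missing.
plink_decode_bytes <- function(payload, n, m, bpv) {
  ints <- as.integer(payload)
  # per-byte lookup of the four 2-bit fields, little-endian within byte
  q <- cbind(ints %% 4L, (ints %/% 4L) %% 4L, (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  map <- c(2L, NA_integer_, 1L, 0L)           # indexed by code + 1
  calls <- matrix(map[t(q) + 1L], nrow = 4L * bpv, ncol = m)
  calls[seq_len(n), , drop = FALSE]
}

#' Write genotypes as a PLINK binary triplet
#'
#' @param geno A [genotype_matrix()].
#' @param prefix Output path prefix; writes `prefix.bed`, `.bim`, `.fam`.
#'   The counted allele is written as A1.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  n <- length(geno$sample_ids); m <- nrow(geno$variants)
  v <- geno$variants
  bim <- data.frame(v$chrom, v$snp_id, 0L, v$pos, v$allele_counted, v$allele_other)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  fam <- data.frame(geno$sample_ids, geno$sample_ids, 0L, 0L, 0L, -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  code <- matrix(1L, nrow = 4L * ceiling(n / 4), ncol = m)    # pad = missing code
  d <- geno$dosage
  enc <- c(3L, 2L, 0L)                        # dosage 0,1,2 -> code 11,10,00
  cd <- matrix(1L, nrow = n, ncol = m)
  ok <- !is.na(d)
  cd[ok] <- enc[d[ok] + 1L]
  code[seq_len(n), ] <- cd
  # pack 4 codes per byte, little-endian within byte
  dim(code) <- c(4L, length(code) / 4L)
  bytes <- as.raw(code[1, ] + 4L * code[2, ] + 16L * code[3, ] + 64L * code[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' @rdname read_genotypes
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) rejected")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
    alt <- alt[!multi]
  }
  if (nrow(fix) == 0L) stop("no biallelic variants in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count ALT alleles per call; accept phased or unphased separators
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(fix))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(snp_id = ids,
                         chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         allele_counted = alt,
                         allele_other = fix[, "REF"],
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dos), colnames(gt), variants)
}

#' Write genotypes as a minimal VCF
#'
#' @param geno A [genotype_matrix()]; the counted allele is written as ALT.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(geno, path) {
  v <- geno$variants
  gt_code <- c("0/0", "0/1", "1/1")
  gtm <- matrix("./.", nrow = nrow(v), ncol = length(geno$sample_ids))
  d <- t(geno$dosage)
  ok <- !is.na(d)
  gtm[ok] <- gt_code[d[ok] + 1L]
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", geno$sample_ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$snp_id, v$allele_other, v$allele_counted,
                ".", ".", ".", "GT",
                apply(gtm, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
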