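#' Read per-SNP functional annotations (with optional LD proxies)
#'
#' A SNP is "functional" when it carries a direct annotation — coding,
#' regulatory, or eQTL — or is linked by an LD proxy pair with r^2 at or above
#' a threshold to an annotated SNP. The returned index answers that query.
#'
#' @param path TSV with header and columns `snp_id`, `functional_class`
#'   (one of `coding`, `regulatory`, `eqtl`; a SNP may appear on several rows).
#' @param proxy_path Optional TSV with header and columns `snp_a`, `snp_b`,
#'   `r2` (`r2` in \[0, 1\]).
#' @return An object of class `functional_index` with elements `classes`
#'   (named list: snp_id -> character vector of classes) and `proxies`
#'   (`data.frame` of pairs, possibly empty).
#' @export
read_functional_table <- function(path, proxy_path = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("snp_id", "functional_class")
  if (!all(need %in% names(dt)))
    stop("format error: functional table needs columns ", paste(need, collapse = ", "))
  allowed <- c("coding", "regulatory", "eqtl")
  bad <- setdiff(unique(dt$functional_class), allowed)
  if (length(bad))
    stop("format error: unknown functional class token(s): ", paste(bad, collapse = ", "))
  classes <- lapply(split(dt$functional_class, dt$snp_id), unique)
  proxies <- data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  if (!is.null(proxy_path)) {
    pr <- data.table::fread(proxy_path, sep = "\t", header = TRUE, data.table = FALSE)
    if (!all(c("snp_a", "snp_b", "r2") %in% names(pr)))
      stop("format error: proxy table needs columns snp_a, snp_b, r2")
    if (any(pr$r2 < 0 | pr$r2 > 1)) stop("format error: proxy r2 outside [0,1]")
    proxies <- pr[, c("snp_a", "snp_b", "r2")]
  }
  structure(list(classes = classes, proxies = proxies), class = "functional_index")
}

#' Build a functional index from in-memory tables
#'
#' @param annotations `data.frame` with `snp_id`, `functional_class`.
#' @param proxies Optional `data.frame` with `snp_a`, `snp_b`, `r2`.
#' @return A `functional_index`, as from [read_functional_table()].
#' @export
functional_index <- function(annotations, proxies = NULL) {
  classes <- lapply(split(annotations$functional_class, annotations$snp_id), unique)
  if (is.null(proxies))
    proxies <- data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  structure(list(classes = classes, proxies = proxies), class = "functional_index")
}

#' Query functional status of SNPs
#'
#' @param index A `functional_index`.
#' @param snp_ids Character vector of SNP ids.
#' @param r2_threshold Minimum proxy r^2 for functionality to transfer
#'   (inclusive); default 0.8.
#' @return Logical vector: directly annotated, or in LD (r^2 >= threshold)
#'   with an annotated SNP.
#' @export
is_functional <- function(index, snp_ids, r2_threshold = 0.8) {
  direct <- snp_ids %in% names(index$classes)
  pr <- index$proxies
  if (nrow(pr)) {
    pr <- pr[pr$r2 >= r2_threshold, , drop = FALSE]
    annotated <- names(index$classes)
    # proxy pairs are symmetric
    via <- (snp_ids %in% pr$snp_a[pr$snp_b %in% annotated]) |
           (snp_ids %in% pr$snp_b[pr$snp_a %in% annotated])
    direct <- direct | via
  }
  direct
}
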