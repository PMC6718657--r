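#' Write a result table as TSV with a JSON run-metadata sidecar
#'
#' All pipeline outputs are headered TSVs; each write can be accompanied by a
#' sidecar (`<path>.meta.json`) recording the package version, seed and the
#' parameters that produced the table, for provenance.
#'
#' @param x A `data.frame`.
#' @param path Output TSV path.
#' @param params Named list of parameters to record (may include `seed`).
#' @param sidecar Write the JSON sidecar? Default `TRUE` when `params` given.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, params = NULL, sidecar = !is.null(params)) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  if (sidecar) {
    meta <- list(package = "funprs",
                 version = as.character(utils::packageVersion("funprs")),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 params = params)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a result TSV
#'
#' @param path TSV path written by [write_result_tsv()].
#' @return A `data.frame`.
#' @export
read_result_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
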