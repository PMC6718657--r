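#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT dialect used by MSigDB-style collections
#' (BioCarta, GO, KEGG): one set per line, fields are set name, description,
#' then gene ids. Duplicate gene ids within a line are collapsed.
#'
#' @param path Path to a `.gmt` file.
#' @param source Label recorded for all sets in this file (e.g. the database
#'   name); defaults to the file name.
#' @return A list of class `gene_set_collection`: named list of character
#'   vectors of gene ids, with a `source` attribute; line order preserved.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("format error in ", path, " line ", i, ": fewer than 3 tab-separated fields")
    ids[i] <- f[1]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(ids)) stop("duplicate set ids in ", path)
  names(sets) <- ids
  structure(sets, source = source, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors of gene ids.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
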