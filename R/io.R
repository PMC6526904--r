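## Reading and writing per-family gene trees.

#' Read gene-family trees from a file
#'
#' Accepts either one newick statement per line, or TSV lines
#' `family_id<TAB>newick`.  Plain newick lines receive ids `fam_0001, ...`.
#' Lines starting with `#` are skipped.
#'
#' @param path input file.
#' @param quiet passed to [parse_newick()].
#' @return a list of [gene_family()] records.
#' @export
read_gene_trees <- function(path, quiet = TRUE) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (grepl("\t", lines[i], fixed = TRUE)) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      id <- parts[1L]
      nwk <- parts[2L]
    } else {
      id <- sprintf("fam_%04d", i)
      nwk <- lines[i]
    }
    out[[i]] <- gene_family(id, parse_newick(nwk, quiet = quiet))
  }
  out
}

#' Write gene-family trees to a TSV file
#'
#' One `family_id<TAB>newick` line per record, via the canonical serializer
#' [write_newick()].
#'
#' @param records list of [gene_family()] records.
#' @param path output file.
#' @export
write_gene_trees <- function(records, path) {
  writeLines(vapply(records, function(rec) {
    paste0(rec$family_id, "\t", write_newick(rec$tree))
  }, character(1L)), path)
  invisible(path)
}
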