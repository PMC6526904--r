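## The clan filter: evaluate a set of incontestable clans against every gene
## family and remove families that violate any of them.

#' Construct a clan set
#'
#' An ordered collection of named taxon groups asserted a priori to be
#' monophyletic ("incontestable"), used as the filtering criterion.
#'
#' @param clans named list of character vectors; each clan must contain at
#'   least two taxa and names must be unique.
#' @return an object of class `clan_set`.
#' @export
clan_set <- function(clans) {
  stopifnot(is.list(clans), !is.null(names(clans)),
            all(nzchar(names(clans))))
  if (anyDuplicated(names(clans))) {
    stop("duplicate clan name", call. = FALSE)
  }
  small <- names(clans)[vapply(clans, length, integer(1L)) < 2L]
  if (length(small)) {
    stop("clan(s) with fewer than 2 taxa: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  structure(lapply(clans, as.character), class = "clan_set")
}

#' @export
print.clan_set <- function(x, ...) {
  cat("Clan set with", length(x), "clans:\n")
  for (nm in names(x)) {
    cat("  ", nm, " (", length(x[[nm]]), " taxa)\n", sep = "")
  }
  invisible(x)
}

#' Load a clan set from a config file
#'
#' Format: one clan per line, `clan_name<TAB>taxon1,taxon2,...`; lines
#' starting with `#` are ignored.  Taxa unknown to `species_map` (if given)
#' are retained with a warning -- they simply count as absent at test time.
#'
#' @param path path to the clan TSV.
#' @param species_map optional [species_map()] used to warn about unknown
#'   taxa.
#' @return a [clan_set()].
#' @export
load_clans <- function(path, species_map = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no clans in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1L)) < 2L)
  if (length(bad)) {
    stop("malformed clan line(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  nms <- vapply(parts, `[[`, character(1L), 1L)
  taxa <- lapply(parts, function(p) {
    trimws(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
  })
  cs <- clan_set(setNames(taxa, nms))
  if (!is.null(species_map)) {
    universe <- unique(unname(species_map$leaf_taxon))
    unknown <- setdiff(unique(unlist(cs)), universe)
    if (length(unknown)) {
      warning("clan taxa not in species map universe: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  cs
}

#' Create a gene-family record
#'
#' @param family_id family identifier.
#' @param tree the family's unrooted gene tree (`phylo`).
#' @param alignment optional named character vector of aligned sequences.
#' @return an object of class `gene_family`.
#' @export
gene_family <- function(family_id, tree, alignment = NULL) {
  stopifnot(is.character(family_id), length(family_id) == 1L,
            inherits(tree, "phylo"))
  structure(list(family_id = family_id, tree = tree, alignment = alignment),
            class = "gene_family")
}

## Per-clan status for one tree, computing the split keys only once.
## Returns a character vector (pass/violated/untestable) named by clan.
.clan_statuses <- function(tree, clans, species_map = NULL) {
  taxon_of <- .leaf_taxa(tree, species_map)
  ntip <- length(tree$tip.label)
  keys <- NULL
  out <- character(length(clans))
  for (i in seq_along(clans)) {
    present <- which(taxon_of %in% clans[[i]])
    if (length(present) <= 1L || length(present) == ntip) {
      out[i] <- "untestable"
    } else {
      if (is.null(keys)) keys <- .block_keys(tree)
      out[i] <- if (.block_key(present, ntip) %in% keys) "pass" else "violated"
    }
  }
  setNames(out, names(clans))
}

#' Check one gene family against a clan set
#'
#' Evaluates every clan on the family's tree.  A clan with at most one member
#' present, or whose present members cover the whole leaf set, is untestable
#' and never triggers removal.  The verdict is `"remove"` iff at least one
#' clan is violated.
#'
#' @param record a [gene_family()] record; must be single-copy (prune
#'   duplicates first with [prune_species_duplicates()]).
#' @param clans a [clan_set()].
#' @param species_map optional [species_map()].
#' @return a list with `family_id`, `status` (named character vector over
#'   clans with values pass/violated/untestable) and `verdict`
#'   (`"keep"`/`"remove"`).
#' @export
check_family <- function(record, clans, species_map = NULL) {
  stopifnot(inherits(record, "gene_family"), inherits(clans, "clan_set"))
  if (!is_single_copy(record$tree, species_map)) {
    stop("family ", record$family_id,
         " is multicopy; prune duplicates before clan checking",
         call. = FALSE)
  }
  status <- .clan_statuses(record$tree, clans, species_map)
  list(family_id = record$family_id,
       status = status,
       verdict = if (any(status == "violated")) "remove" else "keep")
}

#' Filter a set of gene families by clan violations
#'
#' Partitions the records into kept and removed sets, preserving input order,
#' and returns the full per-clan status table (also for kept families, so the
#' specific clans violated by each family can be reviewed).
#'
#' @param records list of [gene_family()] records.
#' @param clans a [clan_set()].
#' @param species_map optional [species_map()].
#' @return a list with `kept`, `removed` (record lists) and `report`
#'   (data frame: family_id, one column per clan, verdict).
#' @export
filter_families <- function(records, clans, species_map = NULL) {
  stopifnot(is.list(records), inherits(clans, "clan_set"))
  checks <- lapply(records, check_family, clans = clans,
                   species_map = species_map)
  verdicts <- vapply(checks, `[[`, character(1L), "verdict")
  report <- data.frame(family_id = vapply(checks, `[[`, character(1L),
                                          "family_id"),
                       stringsAsFactors = FALSE)
  if (length(clans) && length(records)) {
    report <- cbind(report, do.call(rbind, lapply(checks, function(ck) {
      as.data.frame(as.list(ck$status), stringsAsFactors = FALSE)
    })))
  }
  report$verdict <- verdicts
  list(kept = records[verdicts == "keep"],
       removed = records[verdicts == "remove"],
       report = report)
}

#' Keep only families informative for a given question
#'
#' Retains records with at least `min_taxa` distinct taxa and at least one
#' taxon from every required group -- e.g. one anuran, one salamander, one
#' caecilian and one outgroup for a family to bear on the root of the
#' Lissamphibia.
#'
#' @param records list of [gene_family()] records.
#' @param species_map a [species_map()] with group assignments (or `NULL`
#'   when leaf labels are group ids).
#' @param required_groups character vector of group ids that must each be
#'   represented.
#' @param min_taxa minimum number of distinct taxa (default 6).
#' @return the kept record list.
#' @export
informativeness_filter <- function(records, species_map, required_groups,
                                   min_taxa = 6L) {
  stopifnot(min_taxa >= 1L)
  if (!is.null(species_map)) {
    known <- unique(unname(species_map$taxon_group))
    bad <- setdiff(required_groups, known)
    if (length(bad)) {
      stop("unknown group id(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  keep <- vapply(records, function(rec) {
    taxa <- unique(.leaf_taxa(rec$tree, species_map))
    if (length(taxa) < min_taxa) return(FALSE)
    groups <- unique(.leaf_groups(rec$tree, species_map))
    all(required_groups %in% groups)
  }, logical(1L))
  records[keep]
}

#' Tally the triplet topology supported by each gene family
#'
#' Classifies every record with [classify_triplet()] and counts the three
#' possible pairings plus unresolved outcomes.  This is a topology
#' classification of the gene trees themselves, not a site-likelihood test.
#'
#' @param records list of [gene_family()] records, each containing at least
#'   one leaf of every ingroup group and one outgroup leaf.
#' @param groups the three ingroup group ids.
#' @param outgroup the outgroup group id.
#' @param species_map optional [species_map()] with group assignments.
#' @return named integer vector over the three pairings and `"unresolved"`;
#'   counts sum to `length(records)`.
#' @export
support_spectrum <- function(records, groups, outgroup, species_map = NULL) {
  stopifnot(length(groups) == 3L)
  cells <- c(paste(groups[c(1L, 2L)], collapse = "+"),
             paste(groups[c(1L, 3L)], collapse = "+"),
             paste(groups[c(2L, 3L)], collapse = "+"),
             "unresolved")
  tally <- setNames(integer(4L), cells)
  for (rec in records) {
    cls <- classify_triplet(rec$tree, groups, outgroup, species_map)
    tally[cls] <- tally[cls] + 1L
  }
  tally
}
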