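## Leaf -> taxon -> group mapping.

#' Construct a species map
#'
#' Translates gene-tree leaf labels to taxon ids and, optionally, taxon ids to
#' group ids (e.g. Anura, Caudata, Gymnophiona, Outgroup).  Leaf matching is
#' exact first; failing that, the longest map entry that is a prefix of the
#' leaf label is used, which accommodates labels like `human_ENSG0001`.
#'
#' @param leaf_taxon named character vector: names are leaf labels (or label
#'   prefixes), values are taxon ids.
#' @param taxon_group optional named character vector: names are taxon ids,
#'   values are group ids.  Group membership must be a partition of taxa.
#' @return an object of class `species_map`.
#' @export
species_map <- function(leaf_taxon, taxon_group = NULL) {
  stopifnot(is.character(leaf_taxon), !is.null(names(leaf_taxon)),
            all(nzchar(names(leaf_taxon))))
  if (anyDuplicated(names(leaf_taxon))) {
    stop("duplicate leaf entries in species map", call. = FALSE)
  }
  if (!is.null(taxon_group)) {
    stopifnot(is.character(taxon_group), !is.null(names(taxon_group)))
    if (anyDuplicated(names(taxon_group))) {
      stop("a taxon may belong to only one group", call. = FALSE)
    }
  }
  structure(list(leaf_taxon = leaf_taxon, taxon_group = taxon_group),
            class = "species_map")
}

#' Map leaf labels to taxon ids
#'
#' @param labels character vector of leaf labels.
#' @param map a [species_map()].
#' @return character vector of taxon ids, same length as `labels`.
#' @export
map_leaves <- function(labels, map) {
  stopifnot(inherits(map, "species_map"))
  lt <- map$leaf_taxon
  out <- unname(lt[labels])
  if (anyNA(out)) {
    keys <- names(lt)[order(-nchar(names(lt)))]
    for (i in which(is.na(out))) {
      hit <- keys[startsWith(labels[i], keys)]
      if (length(hit)) out[i] <- lt[[hit[1L]]]
    }
  }
  if (anyNA(out)) {
    stop("leaves not mapped to any taxon: ",
         paste(labels[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

## taxon of every leaf; identity when no map given
.leaf_taxa <- function(tree, map) {
  if (is.null(map)) tree$tip.label else map_leaves(tree$tip.label, map)
}

## group of every leaf; requires taxon_group unless no map (labels = groups)
.leaf_groups <- function(tree, map) {
  if (is.null(map)) return(tree$tip.label)
  taxa <- map_leaves(tree$tip.label, map)
  if (is.null(map$taxon_group)) {
    stop("species map carries no group assignments", call. = FALSE)
  }
  grp <- unname(map$taxon_group[taxa])
  if (anyNA(grp)) {
    stop("taxa without group assignment: ",
         paste(unique(taxa[is.na(grp)]), collapse = ", "), call. = FALSE)
  }
  grp
}

#' Taxa belonging to a group
#'
#' @param map a [species_map()] with group assignments.
#' @param group a group id.
#' @return character vector of taxon ids.
#' @export
taxa_of_group <- function(map, group) {
  stopifnot(inherits(map, "species_map"))
  if (is.null(map$taxon_group)) {
    stop("species map carries no group assignments", call. = FALSE)
  }
  names(map$taxon_group)[map$taxon_group == group]
}

#' Read a species map from TSV files
#'
#' `species_path` is a two-column TSV (leaf label or prefix, taxon id);
#' `groups_path`, if given, a two-column TSV (taxon id, group id).  Lines
#' starting with `#` are ignored in both files.
#'
#' @param species_path path to the leaf-to-taxon TSV.
#' @param groups_path optional path to the taxon-to-group TSV.
#' @return a [species_map()].
#' @export
read_species_map <- function(species_path, groups_path = NULL) {
  sp <- read.delim(species_path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(sp) < 2L) stop("species map TSV needs two columns", call. = FALSE)
  leaf_taxon <- setNames(as.character(sp[[2L]]), as.character(sp[[1L]]))
  taxon_group <- NULL
  if (!is.null(groups_path)) {
    gr <- read.delim(groups_path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(gr) < 2L) stop("group TSV needs two columns", call. = FALSE)
    taxon_group <- setNames(as.character(gr[[2L]]), as.character(gr[[1L]]))
  }
  species_map(leaf_taxon, taxon_group)
}
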