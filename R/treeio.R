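## Unrooted-tree data model and split/clan primitives.
##
## Trees are plain ape "phylo" objects.  All clan computation is unrooted:
## a set of leaves is a clan iff it is one side of the bipartition induced by
## removing a single edge (a clan, the unrooted analogue of a clade).

#' Parse a single newick string
#'
#' Thin validating wrapper around [ape::read.tree()].  Labels are expected in
#' the usual unquoted `[A-Za-z0-9_.|-]` dialect produced by RAxML and ASTRAL;
#' branch lengths are optional; polytomies are preserved as-is.  Internal node
#' labels (e.g. bootstrap values) are dropped with a warning because they play
#' no role in clan computation.
#'
#' @param text a single newick statement terminated by `";"`.
#' @param quiet suppress the internal-node-label warning.
#' @return an object of class `phylo`.
#' @examples
#' tr <- parse_newick("(A,B,(C,D));")
#' tree_splits(tr)
#' @export
parse_newick <- function(text, quiet = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string", call. = FALSE)
  if (!grepl(";\\s*$", text)) {
    stop("newick string must end with ';'", call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    stop("unbalanced parentheses: unexpected ')' at position ",
         which(depth < 0)[1L], call. = FALSE)
  }
  if (depth[length(depth)] != 0L) {
    stop("unbalanced parentheses: ", sum(chars == "("), " '(' vs ",
         sum(chars == ")"), " ')'", call. = FALSE)
  }
  if (grepl("\\(\\s*,", text) || grepl(",\\s*,", text) || grepl(",\\s*\\)", text)) {
    stop("empty leaf label in newick string", call. = FALSE)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick string", call. = FALSE)
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop("empty leaf label in newick string", call. = FALSE)
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!is.null(tree$node.label)) {
    if (any(nzchar(tree$node.label)) && !quiet) {
      warning("internal node labels ignored", call. = FALSE)
    }
    tree$node.label <- NULL
  }
  tree
}

#' Serialize a tree to canonical newick
#'
#' Children are emitted sorted by their smallest descendant leaf label, so two
#' trees equal as unrooted topologies with the same root node serialize
#' identically regardless of input leaf order.
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a newick string terminated by `";"`.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- NULL
  if (!is.null(tree$edge.length)) {
    elen <- rep(NA_real_, ntip + tree$Nnode)
    elen[tree$edge[, 2L]] <- tree$edge.length
  }
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  rec <- function(v) {
    if (v <= ntip) {
      return(list(str = tree$tip.label[v], key = tree$tip.label[v]))
    }
    ch <- lapply(kids[[as.character(v)]], rec)
    keys <- vapply(ch, `[[`, character(1L), "key")
    ord <- order(keys)
    ids <- kids[[as.character(v)]][ord]
    parts <- vapply(seq_along(ids), function(i) {
      s <- ch[[ord[i]]]$str
      if (!is.null(elen) && !is.na(elen[ids[i]])) {
        s <- paste0(s, ":", fmt(elen[ids[i]]))
      }
      s
    }, character(1L))
    list(str = paste0("(", paste(parts, collapse = ","), ")"),
         key = min(keys))
  }
  root <- ntip + 1L
  paste0(rec(root)$str, ";")
}

## Descendant tip-index set for every edge (one entry per edge, in the order
## of tree$edge).  The complement of each block is the other side of the split.
.edge_blocks <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  e <- po$edge
  for (k in seq_len(nrow(e))) {
    sets[[e[k, 1L]]] <- c(sets[[e[k, 1L]]], sets[[e[k, 2L]]])
  }
  lapply(seq_len(nrow(e)), function(k) sets[[e[k, 2L]]])
}

## Orientation-free canonical key of a bipartition block: always the side
## not containing tip 1.  For trees up to 52 leaves the key is an exact
## double-precision bitmask (fast); larger trees fall back to string keys.
.block_key <- function(idx, ntip) {
  if (ntip <= 52L) {
    m <- sum(2^(idx - 1))
    if (m %% 2 >= 1) sum(2^(seq_len(ntip) - 1)) - m else m
  } else {
    if (1L %in% idx) idx <- setdiff(seq_len(ntip), idx)
    paste(sort(idx), collapse = ".")
  }
}

## Canonical keys of all edge-induced bipartitions (trivial ones included).
.block_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip > 52L) {
    return(unique(vapply(.edge_blocks(tree), .block_key, character(1L),
                         ntip = ntip)))
  }
  mask <- numeric(ntip + tree$Nnode)
  mask[seq_len(ntip)] <- 2^(seq_len(ntip) - 1L)
  po <- ape::reorder.phylo(tree, "postorder")
  e <- po$edge
  for (k in seq_len(nrow(e))) {
    mask[e[k, 1L]] <- mask[e[k, 1L]] + mask[e[k, 2L]]
  }
  m <- mask[e[, 2L]]
  full <- sum(2^(seq_len(ntip) - 1L))
  unique(ifelse(m %% 2 >= 1, full - m, m))
}

#' Nontrivial splits of an unrooted tree
#'
#' Returns one split per internal edge; trivial splits (one leaf versus the
#' rest) are omitted.  Each split is reported as the block not containing the
#' first tip of the tree, as a sorted character vector of leaf labels, so that
#' split sets from differently rooted or ordered newick strings compare equal.
#'
#' @param tree a `phylo` object with at least 3 leaves.
#' @return a list of character vectors, one per nontrivial split.
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("tree must have at least 3 leaves", call. = FALSE)
  blocks <- .edge_blocks(tree)
  out <- list()
  seen <- character(0L)
  for (b in blocks) {
    if (length(b) < 2L || length(b) > ntip - 2L) next
    side <- if (1L %in% b) setdiff(seq_len(ntip), b) else b
    key <- paste(sort(side), collapse = ".")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- sort(tree$tip.label[side])
  }
  out
}

#' Test whether a taxon set forms a clan of a gene tree
#'
#' A taxon set passes iff all leaves mapping to taxa in `taxa` sit together on
#' one side of some split of `tree` (edges incident to leaves count, so a
#' single leaf is always a clan).  Two vacuous cases pass by convention: at
#' most one member present, or the present members covering the whole leaf
#' set -- an untestable clan cannot be violated.  When several leaves map to
#' the same taxon, *all* of them must be inside the block.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of taxon ids; members absent from the tree are
#'   ignored before testing.
#' @param species_map optional [species_map()] translating leaf labels to
#'   taxon ids; by default leaf labels are taken as taxon ids.
#' @return `TRUE` or `FALSE`.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' is_clan(tr, c("A", "B"))   # TRUE
#' is_clan(tr, c("A", "C"))   # FALSE
#' @export
is_clan <- function(tree, taxa, species_map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  taxon_of <- .leaf_taxa(tree, species_map)
  present <- which(taxon_of %in% taxa)
  ntip <- length(tree$tip.label)
  if (length(present) <= 1L || length(present) == ntip) return(TRUE)
  .block_key(present, ntip) %in% .block_keys(tree)
}

#' Classify the rooted triplet topology supported by a gene tree
#'
#' Given three ingroup groups and an outgroup group, reports which pair of
#' ingroup groups jointly forms a clan excluding the third group and all
#' outgroups -- the unrooted reading of the three possible rooted triplet
#' topologies (for the Lissamphibia: Anura+Caudata is Batrachia,
#' Caudata+Gymnophiona is Procera, Anura+Gymnophiona the third topology).
#' At most one pair can form such a clan because two overlapping pair-blocks
#' would be incompatible splits.
#'
#' @param tree a `phylo` object containing at least one leaf of each ingroup
#'   group and at least one outgroup leaf.
#' @param groups character vector of the three ingroup group ids.
#' @param outgroup the outgroup group id.
#' @param species_map a [species_map()] with group assignments (or `NULL` if
#'   leaf labels are group ids themselves).
#' @return a string `"<g1>+<g2>"` naming the supported pair, or
#'   `"unresolved"` when no pair-clan exists.
#' @export
classify_triplet <- function(tree, groups, outgroup, species_map = NULL) {
  stopifnot(inherits(tree, "phylo"), length(groups) == 3L,
            length(outgroup) == 1L)
  group_of <- .leaf_groups(tree, species_map)
  for (g in c(groups, outgroup)) {
    if (!any(group_of == g)) {
      stop("no leaf of required group '", g, "' in tree", call. = FALSE)
    }
  }
  ntip <- length(tree$tip.label)
  keys <- .block_keys(tree)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (p in pairs) {
    block <- which(group_of %in% groups[p])
    if (.block_key(block, ntip) %in% keys) {
      return(paste(groups[p], collapse = "+"))
    }
  }
  "unresolved"
}

#' Collapse species-specific duplicate leaves to a single representative
#'
#' Transcriptome assemblies often yield several sequences per species (isoform
#' or allele redundancy).  Every maximal set of leaves that (i) all map to the
#' same taxon and (ii) form a clan of the tree is reduced to the leaf with the
#' longest sequence (ties broken lexicographically by label).  Same-taxon
#' leaves that do not group together are left untouched -- they are genuine
#' multicopy signal, not redundancy.
#'
#' @param tree a `phylo` object.
#' @param species_map optional [species_map()].
#' @param seq_lengths named numeric vector of sequence lengths, one entry per
#'   leaf label.
#' @return the pruned `phylo` object.
#' @export
prune_species_duplicates <- function(tree, species_map = NULL, seq_lengths) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  missing_len <- setdiff(labs, names(seq_lengths))
  if (length(missing_len)) {
    stop("seq_lengths missing for leaves: ",
         paste(missing_len, collapse = ", "), call. = FALSE)
  }
  taxon_of <- .leaf_taxa(tree, species_map)
  ntip <- length(labs)
  blocks <- .edge_blocks(tree)
  blocks <- c(blocks, lapply(blocks, function(b) setdiff(seq_len(ntip), b)),
              list(seq_len(ntip)))
  drop <- character(0L)
  for (tx in unique(taxon_of[duplicated(taxon_of)])) {
    lx <- which(taxon_of == tx)
    pure <- Filter(function(b) length(b) >= 2L && all(b %in% lx), blocks)
    if (!length(pure)) next
    pure <- unique(lapply(pure, sort))
    maximal <- pure[!vapply(seq_along(pure), function(i) {
      any(vapply(seq_along(pure), function(j) {
        i != j && length(pure[[j]]) > length(pure[[i]]) &&
          all(pure[[i]] %in% pure[[j]])
      }, logical(1L)))
    }, logical(1L))]
    for (b in maximal) {
      cand <- labs[b]
      best <- cand[order(-seq_lengths[cand], cand)][1L]
      drop <- c(drop, setdiff(cand, best))
    }
  }
  if (!length(drop)) return(tree)
  if (ntip - length(drop) < 2L) {
    stop("pruning would leave fewer than 2 leaves", call. = FALSE)
  }
  ape::drop.tip(tree, drop)
}

#' Is a gene family single-copy?
#'
#' `TRUE` iff no taxon labels more than one leaf of the tree.
#'
#' @inheritParams is_clan
#' @export
is_single_copy <- function(tree, species_map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  !anyDuplicated(.leaf_taxa(tree, species_map)) > 0L
}

#' Average branch length of a tree
#'
#' Sum of all branch lengths divided by the number of branches, internal and
#' external alike.
#'
#' @param tree a `phylo` object in which every edge carries a length.
#' @return a single non-negative number.
#' @export
avg_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) seq_len(nrow(tree$edge)) else
      which(is.na(tree$edge.length))
    stop("edges without branch lengths: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sum(tree$edge.length) / length(tree$edge.length)
}
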