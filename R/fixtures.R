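## Default study design: a 33-taxon vertebrate species model (8 anurans,
## 5 salamanders, 5 caecilians, 15 outgroup taxa), seven incontestable clans,
## and a fixture generator emitting synthetic gene-family tree sets with a
## manifest of known per-family truth.

## Build an ultrametric newick from a nested (depth, children) specification;
## depths are node times before present in coalescent units.
.chrono_node <- function(depth, ...) list(depth = depth, children = list(...))

.chrono_newick <- function(spec) {
  rec <- function(x, parent_depth) {
    if (is.character(x)) {
      return(sprintf("%s:%.10g", x, parent_depth))
    }
    parts <- vapply(x$children, rec, character(1L), parent_depth = x$depth)
    sprintf("(%s):%.10g", paste(parts, collapse = ","),
            parent_depth - x$depth)
  }
  top <- rec(spec, spec$depth)
  paste0(sub(":[0-9.eE+-]+$", "", top), ";")
}

#' The default 33-taxon vertebrate species model
#'
#' A rooted, ultrametric species tree in coalescent units mirroring a
#' vertebrate phylogenomic study design: 18 ingroup amphibians (8 Anura, 5
#' Caudata, 5 Gymnophiona, with the Batrachia topology) and 15 outgroups (6
#' fishes, 5 sauropsids, 4 mammals).  Internodes separating the incontestable
#' groups are deep (4-10 coalescent units) while within-group internodes are
#' short (1-2 units), so coalescent simulation shows realistic within-group
#' discordance yet rarely breaks the deep groups.
#'
#' @param theta per-branch effective-size scaling (default 1).
#' @return a [species_model()].
#' @export
default_species_model <- function(theta = 1) {
  n <- .chrono_node
  spec <- n(40, "lamprey",
    n(36, "elephant_shark",
      n(32,
        n(12, "zebrafish", "pufferfish"),
        n(28, "coelacanth",
          n(26, "lungfish",
            n(22,
              n(16,
                n(8, "rhinatrema",
                  n(6, "microcaecilia",
                    n(4, "siphonops", n(3, "typhlonectes", "caecilia")))),
                n(14,
                  n(9, "xenopus",
                    n(8, "nanorana",
                      n(6, "pristimantis",
                        n(5, "scinax",
                          n(4, "amazophrynella",
                            n(3, "allobates",
                              n(2, "ameerega", "ranitomeya"))))))),
                  n(7, "hynobius",
                    n(5,
                      n(1.5, "ambystoma_mexicanum", "ambystoma_tigrinum"),
                      n(3, "notophthalmus", "pleurodeles"))))),
              n(18,
                n(8, "platypus",
                  n(5, "elephant", n(3, "cow", "human"))),
                n(14,
                  n(6, "anolis", "king_cobra"),
                  n(12, "chinese_turtle",
                    n(4, "chicken", "zebra_finch"))))))))))
  tree <- parse_newick(.chrono_newick(spec))
  species_model(tree, theta = theta)
}

#' Group assignment of the default taxa
#'
#' @return named character vector taxon -> group (Anura, Caudata,
#'   Gymnophiona, Outgroup).
#' @export
default_groups <- function() {
  c(xenopus = "Anura", nanorana = "Anura", pristimantis = "Anura",
    scinax = "Anura", amazophrynella = "Anura", allobates = "Anura",
    ameerega = "Anura", ranitomeya = "Anura",
    hynobius = "Caudata", ambystoma_mexicanum = "Caudata",
    ambystoma_tigrinum = "Caudata", notophthalmus = "Caudata",
    pleurodeles = "Caudata",
    rhinatrema = "Gymnophiona", microcaecilia = "Gymnophiona",
    siphonops = "Gymnophiona", typhlonectes = "Gymnophiona",
    caecilia = "Gymnophiona",
    lamprey = "Outgroup", elephant_shark = "Outgroup",
    zebrafish = "Outgroup", pufferfish = "Outgroup",
    coelacanth = "Outgroup", lungfish = "Outgroup",
    anolis = "Outgroup", king_cobra = "Outgroup",
    chinese_turtle = "Outgroup", chicken = "Outgroup",
    zebra_finch = "Outgroup", platypus = "Outgroup",
    elephant = "Outgroup", cow = "Outgroup", human = "Outgroup")
}

#' The default species map over the 33 fixture taxa
#'
#' Leaf labels map to themselves as taxon ids, with the four-group
#' assignment of [default_groups()].
#'
#' @return a [species_map()].
#' @export
default_fixture_map <- function() {
  groups <- default_groups()
  taxa <- names(groups)
  species_map(setNames(taxa, taxa), groups)
}

#' The seven default incontestable clans
#'
#' Mammals, birds, birds + reptiles, frogs, salamanders, caecilians and
#' tetrapods over the 33 fixture taxa -- deep vertebrate groups whose
#' monophyly is not in question and which a gene family must be able to
#' recover if its history is pure speciation.
#'
#' @return a [clan_set()] of size 7.
#' @export
default_clans <- function() {
  groups <- default_groups()
  fishes <- c("lamprey", "elephant_shark", "zebrafish", "pufferfish",
              "coelacanth", "lungfish")
  clan_set(list(
    mammals = c("platypus", "elephant", "cow", "human"),
    birds = c("chicken", "zebra_finch"),
    birds_reptiles = c("anolis", "king_cobra", "chinese_turtle",
                       "chicken", "zebra_finch"),
    frogs = names(groups)[groups == "Anura"],
    salamanders = names(groups)[groups == "Caudata"],
    caecilians = names(groups)[groups == "Gymnophiona"],
    tetrapods = setdiff(names(groups), fishes)
  ))
}

#' Default occupancy: family sizes uniform on 6..32 taxa
#'
#' Emulates the family-size range of informative transcriptome-derived data
#' sets (6 to 32 of 33 taxa), with taxa sampled uniformly.
#'
#' @param model a [species_model()] (default the 33-taxon fixture model).
#' @return an [occupancy_config()].
#' @export
default_occupancy <- function(model = default_species_model()) {
  occupancy_config(model$taxa, sizes = 6:32, min_taxa = 4L)
}

## Expected triplet outcome of a duplication + late-loss family with exactly
## one leaf per ingroup order and one outgroup taxon, computed from the
## retained copies without building the tree.  Pairwise divergence = species
## MRCA time when the copies agree, duplication-node time otherwise.  The
## family tree is ultrametric on these times, so its unique nontrivial
## 4-leaf split separates the globally closest pair from the rest; the
## supported ingroup pair is that pair itself or, when the closest pair
## involves the outgroup, its complement.  A tie between non-complementary
## pairs means a polytomy: unresolved.
.expected_triplet <- function(model, taxa, assignment, rounds, dup_spacing,
                              groups, outgroup_taxon) {
  root_time <- max(model$node_time)
  dup_time <- function(r) root_time + (rounds - r + 1) * dup_spacing
  mrca_time <- function(x, y) {
    model$node_time[ape::getMRCA(model$tree, c(x, y))]
  }
  div <- function(x, y) {
    cx <- assignment[[x]]; cy <- assignment[[y]]
    if (cx == cy) mrca_time(x, y)
    else dup_time(.copy_divergence_round(cx, cy, rounds))
  }
  pairs <- utils::combn(taxa, 2L, simplify = FALSE)
  dvals <- vapply(pairs, function(p) div(p[1L], p[2L]), numeric(1L))
  hits <- pairs[dvals == min(dvals)]
  split_pair <- if (length(hits) == 1L) {
    hits[[1L]]
  } else if (length(hits) == 2L && !length(intersect(hits[[1L]],
                                                     hits[[2L]]))) {
    hits[[1L]]  # complementary cherries: same split
  } else {
    return("unresolved")
  }
  ing_pair <- if (outgroup_taxon %in% split_pair) {
    setdiff(taxa, split_pair)
  } else {
    split_pair
  }
  paste(sort(unname(groups[ing_pair])), collapse = "+")
}

#' Generate a synthetic fixture data set
#'
#' Writes, under `out_dir`: the 33-taxon species tree (`species_tree.nwk`),
#' species map and group TSVs, the seven-clan config (`clans.tsv`), three
#' gene-family tree sets (`trees_clean.tsv`, `trees_ils.tsv`,
#' `trees_duploss.tsv`, TSV `family_id<TAB>newick`), and `manifest.json`
#' recording the seed and per-family truth: clean families are species
#' subtrees (no clan violations by construction); ILS families are MSC draws;
#' duplication + late-loss families contain one taxon per amphibian order
#' plus one outgroup, with the retained copies and the triplet topology they
#' imply.  All inputs are synthetic, standing in for transcriptome-derived
#' gene trees.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param n_clean,n_ils,n_dup families per set.
#' @param rounds duplication rounds for the dup set.
#' @return invisibly, the manifest as a list.
#' @export
generate_fixtures <- function(out_dir, seed = 1L, n_clean = 30L, n_ils = 30L,
                              n_dup = 30L, rounds = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  model <- default_species_model()
  groups <- default_groups()
  clans <- default_clans()
  occ <- default_occupancy(model)

  writeLines(write_newick(model$tree), file.path(out_dir, "species_tree.nwk"))
  write.table(data.frame(leaf = model$taxa, taxon = model$taxa),
              file.path(out_dir, "species_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(taxon = names(groups), group = unname(groups)),
              file.path(out_dir, "groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(c("# incontestable clans: name<TAB>comma-separated taxa",
               vapply(names(clans), function(nm) {
                 paste0(nm, "\t", paste(clans[[nm]], collapse = ","))
               }, character(1L))),
             file.path(out_dir, "clans.tsv"))

  write_set <- function(trees, ids, file) {
    writeLines(vapply(seq_along(trees), function(i) {
      paste0(ids[i], "\t", write_newick(trees[[i]]))
    }, character(1L)), file.path(out_dir, file))
  }

  clean <- lapply(seq_len(n_clean), function(i) {
    ape::keep.tip(model$tree, sample_occupancy(occ))
  })
  clean_ids <- sprintf("clean_%03d", seq_len(n_clean))
  write_set(clean, clean_ids, "trees_clean.tsv")

  ils <- lapply(seq_len(n_ils), function(i) {
    simulate_msc_tree(model, sample_occupancy(occ))
  })
  ils_ids <- sprintf("ils_%03d", seq_len(n_ils))
  write_set(ils, ils_ids, "trees_ils.tsv")

  outgroups <- names(groups)[groups == "Outgroup"]
  dup <- list()
  dup_truth <- list()
  for (i in seq_len(n_dup)) {
    taxa <- c(sample(names(groups)[groups == "Anura"], 1L),
              sample(names(groups)[groups == "Caudata"], 1L),
              sample(names(groups)[groups == "Gymnophiona"], 1L),
              sample(outgroups, 1L))
    assignment <- sample.int(2L^rounds, length(taxa), replace = TRUE)
    names(assignment) <- taxa
    tr <- simulate_duploss_family(model, taxa, rounds,
                                  assignment = assignment)
    dup[[i]] <- tr
    dup_truth[[i]] <- list(
      taxa = taxa,
      copies = as.list(assignment),
      expected_topology = .expected_triplet(model, taxa, assignment, rounds,
                                            1, groups, taxa[4L]))
  }
  dup_ids <- sprintf("dup_%03d", seq_len(n_dup))
  write_set(dup, dup_ids, "trees_duploss.tsv")

  manifest <- list(
    seed = as.integer(seed),
    rounds = as.integer(rounds),
    taxa = model$taxa,
    sets = list(
      clean = list(ids = clean_ids, violations_expected = FALSE),
      ils = list(ids = ils_ids),
      duploss = setNames(dup_truth, dup_ids)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
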