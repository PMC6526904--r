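## Gene-tree simulators used to validate the clan filter:
##   (a) ILS only -- standard multispecies coalescent on a rooted, ultrametric
##       species tree with times in coalescent units (theta = 1 per branch by
##       default);
##   (b) early duplication + late loss -- 2^rounds gene copies arise above the
##       species-tree root, every copy tracks the species tree, and each
##       sampled taxon independently retains exactly one copy chosen
##       uniformly (the worst-case late-loss model).

#' Construct a species model for simulation
#'
#' @param tree a rooted, ultrametric `phylo` object; branch lengths are node
#'   time differences in coalescent units.
#' @param theta effective-size scaling applied to every branch (coalescence
#'   rate for k lineages is choose(k,2)/theta); default 1.
#' @return an object of class `species_model` with fields `tree`,
#'   `node_time` (time before present of every node), `theta` and `taxa`.
#' @export
species_model <- function(tree, theta = 1) {
  stopifnot(inherits(tree, "phylo"), theta > 0)
  if (is.null(tree$edge.length)) {
    stop("species tree must carry branch lengths", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("species tree must be rooted", call. = FALSE)
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  tip_depth <- depth[seq_len(ntip)]
  if (diff(range(tip_depth)) > 1e-6 * max(tip_depth)) {
    stop("species tree must be ultrametric", call. = FALSE)
  }
  node_time <- max(tip_depth) - depth
  node_time[seq_len(ntip)] <- 0
  structure(list(tree = tree, node_time = node_time, theta = theta,
                 taxa = tree$tip.label),
            class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat("Species model:", length(x$taxa), "taxa, root at",
      format(max(x$node_time), digits = 4), "coalescent units, theta =",
      x$theta, "\n")
  invisible(x)
}

## Assemble a binary gene tree from parallel node arrays (child ids 0 for
## tips, absolute node times, tip labels).  Children are sorted by smallest
## descendant label so output is canonical.
.nodes_to_newick <- function(root, child1, child2, g_time, g_label) {
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  rec <- function(id) {
    if (child1[id] == 0L) {
      return(list(str = g_label[id], key = g_label[id], time = g_time[id]))
    }
    a <- rec(child1[id])
    b <- rec(child2[id])
    if (b$key < a$key) { tmp <- a; a <- b; b <- tmp }
    str <- paste0("(", a$str, ":", fmt(g_time[id] - a$time), ",",
                  b$str, ":", fmt(g_time[id] - b$time), ")")
    list(str = str, key = a$key, time = g_time[id])
  }
  paste0(rec(root)$str, ";")
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' One gene lineage is sampled per taxon.  Within each species-tree branch,
#' the k extant gene lineages coalesce pairwise at exponential rate
#' choose(k,2)/theta until the branch's start time; lineages remaining at the
#' root keep coalescing until a single lineage is left.  Branch lengths of
#' the returned (rooted, binary) gene tree are in coalescent units; all
#' unrooted clan computation downstream ignores the root placement.
#'
#' Uses the current RNG state; call `set.seed()` for reproducibility.
#'
#' @param model a [species_model()].
#' @param taxa taxon subset to sample (default all); at least 3.
#' @return a `phylo` object with `length(taxa)` tips.
#' @export
simulate_msc_tree <- function(model, taxa = model$taxa) {
  stopifnot(inherits(model, "species_model"))
  if (length(taxa) < 3L) stop("need at least 3 sampled taxa", call. = FALSE)
  sp <- model$tree
  tipidx <- match(taxa, sp$tip.label)
  if (anyNA(tipidx)) {
    stop("taxa not in species model: ",
         paste(taxa[is.na(tipidx)], collapse = ", "), call. = FALSE)
  }
  ntip_sp <- length(sp$tip.label)
  tb <- model$node_time
  theta <- model$theta
  n <- length(taxa)
  maxg <- 2L * n - 1L
  child1 <- integer(maxg); child2 <- integer(maxg)
  g_time <- numeric(maxg); g_label <- character(maxg)
  nxt <- 0L
  lin <- vector("list", ntip_sp + sp$Nnode)
  for (i in seq_len(n)) {
    nxt <- nxt + 1L
    g_time[nxt] <- 0
    g_label[nxt] <- taxa[i]
    lin[[tipidx[i]]] <- c(lin[[tipidx[i]]], nxt)
  }
  coalesce_in <- function(L, t0, t1) {
    t <- t0
    while (length(L) >= 2L) {
      k <- length(L)
      w <- rexp(1L, rate = k * (k - 1) / 2 / theta)
      if (t + w >= t1) break
      t <- t + w
      pair <- sample.int(k, 2L)
      nxt <<- nxt + 1L
      child1[nxt] <<- L[pair[1L]]
      child2[nxt] <<- L[pair[2L]]
      g_time[nxt] <<- t
      L <- c(L[-pair], nxt)
    }
    L
  }
  po <- ape::reorder.phylo(sp, "postorder")
  e <- po$edge
  for (k in seq_len(nrow(e))) {
    ch <- e[k, 2L]
    L <- lin[[ch]]
    if (length(L) >= 2L) L <- coalesce_in(L, tb[ch], tb[e[k, 1L]])
    if (length(L)) lin[[e[k, 1L]]] <- c(lin[[e[k, 1L]]], L)
  }
  root_sp <- ntip_sp + 1L
  L <- coalesce_in(lin[[root_sp]], tb[root_sp], Inf)
  tree <- ape::read.tree(text = .nodes_to_newick(L, child1, child2,
                                                 g_time, g_label))
  tree
}

#' Simulate one single-copy family under early duplication and late loss
#'
#' A complete binary tree of 2^rounds gene copies arises above the species
#' root (duplication round 1 oldest), every copy propagates through the
#' species tree, and each sampled taxon independently retains exactly one
#' copy, chosen uniformly, conditioning the family to be single-copy.  The
#' resulting gene tree joins, per surviving copy, the species subtree of the
#' taxa retaining it (or an MSC draw on those taxa when `ils = TRUE`),
#' following the copy-tree structure with duplication nodes spaced
#' `dup_spacing` coalescent units apart above the root.  With `ils = TRUE` a
#' gene subtree may coalesce deeper than its attachment point; its stem is
#' then clamped at zero length.
#'
#' @param model a [species_model()].
#' @param taxa taxon subset present in the family.
#' @param rounds number of duplication rounds (>= 1).
#' @param assignment optional integer vector (one copy id per taxon)
#'   overriding the uniform loss draw.
#' @param ils apply a coalescent layer within each copy (default `FALSE`:
#'   pure duplication signal).
#' @param dup_spacing time between consecutive duplication rounds.
#' @return a `phylo` object; the copy retained by each taxon is stored in
#'   `attr(tree, "assignment")`.
#' @export
simulate_duploss_family <- function(model, taxa, rounds, assignment = NULL,
                                    ils = FALSE, dup_spacing = 1) {
  stopifnot(inherits(model, "species_model"), rounds >= 1L)
  nc <- 2L^as.integer(rounds)
  if (is.null(assignment)) {
    assignment <- sample.int(nc, length(taxa), replace = TRUE)
  }
  stopifnot(length(assignment) == length(taxa),
            all(assignment >= 1L & assignment <= nc))
  names(assignment) <- taxa
  root_time <- max(model$node_time)
  dup_time <- function(r) root_time + (rounds - r + 1) * dup_spacing
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  subtree <- function(tx) {
    if (length(tx) == 1L) return(list(str = tx, time = 0))
    if (ils && length(tx) >= 3L) {
      tr <- simulate_msc_tree(model, tx)
    } else {
      tr <- ape::keep.tip(model$tree, tx)
    }
    list(str = sub(";\\s*$", "", ape::write.tree(tr)),
         time = max(ape::node.depth.edgelength(tr)))
  }
  join <- function(lo, hi, r) {
    if (lo == hi) {
      tx <- taxa[assignment == lo]
      if (!length(tx)) return(NULL)
      return(subtree(tx))
    }
    mid <- lo + (hi - lo + 1L) %/% 2L - 1L
    a <- join(lo, mid, r + 1L)
    b <- join(mid + 1L, hi, r + 1L)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    t <- dup_time(r)
    list(str = paste0("(", a$str, ":", fmt(t - a$time), ",",
                      b$str, ":", fmt(t - b$time), ")"),
         time = t)
  }
  res <- join(1L, nc, 1L)
  tree <- ape::read.tree(text = paste0(res$str, ";"))
  attr(tree, "assignment") <- assignment
  tree
}

#' Configure the per-family occupancy distribution
#'
#' Occupancy -- the taxon subset represented in a family -- is drawn either
#' from independent per-taxon inclusion probabilities or from a family-size
#' histogram with taxa sampled uniformly.  Draws with fewer than `min_taxa`
#' taxa are rejected and redrawn.
#'
#' @param taxa taxon universe.
#' @param probs per-taxon inclusion probabilities (length 1 or
#'   `length(taxa)`), exclusive with `sizes`.
#' @param sizes vector of family sizes to draw from, with optional weights
#'   `size_probs`.
#' @param size_probs weights for `sizes` (default uniform).
#' @param min_taxa minimum family size (default 4).
#' @return an object of class `occupancy_config`.
#' @export
occupancy_config <- function(taxa, probs = NULL, sizes = NULL,
                             size_probs = NULL, min_taxa = 4L) {
  stopifnot(length(taxa) >= min_taxa)
  if (is.null(probs) == is.null(sizes)) {
    stop("give exactly one of probs or sizes", call. = FALSE)
  }
  if (!is.null(probs)) {
    probs <- rep_len(probs, length(taxa))
    if (any(probs < 0 | probs > 1)) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (sum(probs > 0) < min_taxa) {
      stop("infeasible occupancy: fewer than min_taxa taxa with positive ",
           "inclusion probability", call. = FALSE)
    }
  } else {
    sizes <- as.integer(sizes)
    stopifnot(all(sizes >= 1L), all(sizes <= length(taxa)))
    if (is.null(size_probs)) size_probs <- rep(1, length(sizes))
    stopifnot(length(size_probs) == length(sizes), all(size_probs >= 0),
              sum(size_probs) > 0)
    if (max(sizes[size_probs > 0]) < min_taxa) {
      stop("infeasible occupancy: all family sizes below min_taxa",
           call. = FALSE)
    }
  }
  structure(list(taxa = taxa, probs = probs, sizes = sizes,
                 size_probs = size_probs, min_taxa = as.integer(min_taxa)),
            class = "occupancy_config")
}

#' Draw one taxon subset from an occupancy configuration
#'
#' @param config an [occupancy_config()].
#' @return character vector of sampled taxa (at least `min_taxa`).
#' @export
sample_occupancy <- function(config) {
  stopifnot(inherits(config, "occupancy_config"))
  for (i in seq_len(10000L)) {
    if (!is.null(config$probs)) {
      sel <- config$taxa[runif(length(config$taxa)) < config$probs]
    } else {
      k <- config$sizes[sample.int(length(config$sizes), 1L,
                                   prob = config$size_probs)]
      sel <- sample(config$taxa, k)
    }
    if (length(sel) >= config$min_taxa) return(sel)
  }
  stop("could not draw an occupancy with >= min_taxa taxa", call. = FALSE)
}

#' Run the replicated clan-violation experiment
#'
#' For each replicate, simulates `n_families` gene families under the chosen
#' mode, evaluates every clan on every family, and records the fraction of
#' testable (family, clan) evaluations that are violated.  Under ILS only
#' this fraction stays small when inter-group divergences are deep; under
#' early duplication plus late loss it is large -- the separation on which
#' the filter's validity rests.
#'
#' Reproducibility: each replicate reseeds the RNG with a seed derived
#' deterministically from `seed` and the replicate index, so replicates are
#' independent of each other's draw counts.
#'
#' @param model a [species_model()].
#' @param clans a [clan_set()] over the model's taxa.
#' @param config list with `mode` (`"ils_only"` or `"dup_late_loss"`),
#'   `n_families`, `n_replicates`, `occupancy` (an [occupancy_config()]),
#'   and for the duplication mode `rounds` (default 2) and `ils` (default
#'   `FALSE`).
#' @param seed integer root seed.
#' @return an object of class `violation_summary`: list with `fractions`
#'   (one per replicate), `mean`, `sd`, `mode`, `seed`, `config`.
#' @export
run_experiment <- function(model, clans, config, seed = 1L) {
  stopifnot(inherits(model, "species_model"), inherits(clans, "clan_set"),
            is.list(config))
  mode <- match.arg(config$mode, c("ils_only", "dup_late_loss"))
  n_fam <- as.integer(config$n_families)
  n_rep <- as.integer(config$n_replicates)
  occ <- config$occupancy
  stopifnot(n_fam >= 1L, n_rep >= 1L, inherits(occ, "occupancy_config"))
  rounds <- if (is.null(config$rounds)) 2L else as.integer(config$rounds)
  ils_layer <- isTRUE(config$ils)
  seed <- as.integer(seed)
  fractions <- numeric(n_rep)
  for (rep in seq_len(n_rep)) {
    set.seed((seed + rep * 9973L) %% 2147483647L)
    violated <- 0L
    testable <- 0L
    for (fam in seq_len(n_fam)) {
      taxa <- sample_occupancy(occ)
      tree <- if (mode == "ils_only") {
        simulate_msc_tree(model, taxa)
      } else {
        simulate_duploss_family(model, taxa, rounds, ils = ils_layer)
      }
      st <- .clan_statuses(tree, clans, species_map = NULL)
      violated <- violated + sum(st == "violated")
      testable <- testable + sum(st != "untestable")
    }
    fractions[rep] <- if (testable > 0L) violated / testable else NA_real_
  }
  structure(list(fractions = fractions,
                 mean = mean(fractions, na.rm = TRUE),
                 sd = sd(fractions, na.rm = TRUE),
                 mode = mode, seed = seed,
                 config = config),
            class = "violation_summary")
}

#' @export
print.violation_summary <- function(x, ...) {
  cat("Clan-violation experiment (", x$mode, "), ",
      length(x$fractions), " replicates\n", sep = "")
  cat(sprintf("  mean violated fraction: %.3f (sd %.3f)\n", x$mean, x$sd))
  invisible(x)
}
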