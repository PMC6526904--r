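# Independent oracles used across the suite.

# Random leaf-labelled tree with n tips (rooted shape; clan computation is
# unrooted so rootedness is immaterial).
random_tree <- function(n, labels = paste0("t", seq_len(n))) {
  ape::rtree(n, tip.label = sample(labels))
}

# Clan oracle built on phangorn's split machinery: a taxon subset is a clan
# iff it is vacuous or matches one side of some edge bipartition.
oracle_split_matrix <- function(tree) {
  sp <- phangorn::as.splits(tree)
  m <- as.matrix(sp)
  colnames(m) <- attr(sp, "labels")
  m
}

oracle_is_clan <- function(split_matrix, subset_labels, all_labels) {
  k <- length(subset_labels)
  if (k <= 1L || k == length(all_labels)) return(TRUE)
  memb <- colnames(split_matrix) %in% subset_labels
  any(apply(split_matrix, 1L, function(row) {
    all(row == memb) || all(row == !memb)
  }))
}

# Canonicalize a split (one side as label vector) for set comparison.
canon_split <- function(side, all_labels) {
  other <- setdiff(all_labels, side)
  a <- paste(sort(side), collapse = "|")
  b <- paste(sort(other), collapse = "|")
  min(a, b)
}

split_set <- function(splits, all_labels) {
  sort(vapply(splits, canon_split, character(1L), all_labels = all_labels))
}

# Brute-force late-loss oracle: build the FULL gene tree over every
# (lineage, copy) leaf with explicit numeric times -- species tree
# ((L1:1,L2:1):1,L3:2), duplication round r at time 2 + (rounds - r + 1) --
# then, per assignment, prune to the three retained leaves and read the
# cherry off cophenetic distances.
oracle_full_gene_tree <- function(rounds) {
  rec <- function(lo, hi, r, parent_time) {
    if (lo == hi) {
      sub <- sprintf("((L1.c%d:1,L2.c%d:1):1,L3.c%d:2)", lo, lo, lo)
      return(sprintf("%s:%g", sub, parent_time - 2))
    }
    mid <- lo + (hi - lo + 1L) %/% 2L - 1L
    t <- 2 + (rounds - r + 1)
    sprintf("(%s,%s):%g", rec(lo, mid, r + 1L, t),
            rec(mid + 1L, hi, r + 1L, t), parent_time - t)
  }
  nc <- 2L^rounds
  top_t <- 2 + rounds
  txt <- if (rounds == 0L) {
    "((L1.c1:1,L2.c1:1):1,L3.c1:2);"
  } else {
    paste0(sub(":[-0-9.eE+]+$", "", rec(1L, nc, 1L, top_t)), ";")
  }
  ape::read.tree(text = txt)
}

oracle_classify_combo <- function(full_tree, assignment) {
  tips <- sprintf("L%d.c%d", 1:3, assignment)
  g <- ape::keep.tip(full_tree, tips)
  d <- ape::cophenetic.phylo(g)
  dv <- c(d[tips[1], tips[2]], d[tips[1], tips[3]], d[tips[2], tips[3]])
  c("L1L2", "L1L3", "L2L3")[which.min(dv)]
}

oracle_enumerate <- function(rounds) {
  full <- oracle_full_gene_tree(rounds)
  nc <- 2L^rounds
  combos <- expand.grid(a1 = 1:nc, a2 = 1:nc, a3 = 1:nc)
  cls <- apply(combos, 1L, function(a) oracle_classify_combo(full, a))
  list(total = nrow(combos),
       counts = table(factor(cls, levels = c("L1L2", "L1L3", "L2L3"))),
       orthologs = sum(combos$a1 == combos$a2 & combos$a2 == combos$a3))
}

# Rooted-cherry mismatch of a 3-taxon gene tree against species pair (a, b).
cherry_mismatch <- function(tree, a, b) {
  d <- ape::cophenetic.phylo(tree)
  labs <- rownames(d)
  third <- setdiff(labs, c(a, b))
  d[a, b] > min(d[a, third], d[b, third])
}

# Random additive distance matrix: random topology + positive branch
# lengths; returns the matrix and the generating tree.
random_additive <- function(n) {
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tr <- ape::unroot(tr)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
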