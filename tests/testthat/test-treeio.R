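test_that("newick parsing preserves topology and rejects malformed input", {
  tr <- parse_newick("(A,B,(C,D));")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  sp <- tree_splits(tr)
  expect_length(sp, 1L)
  expect_equal(canon_split(sp[[1]], tr$tip.label),
               canon_split(c("C", "D"), tr$tip.label))

  expect_error(parse_newick("((A,B),(C,D)"), "';'")
  expect_error(parse_newick("((A,B),(C,D);"), "unbalanced")
  expect_error(parse_newick("(A,B),(C,D));"), "unbalanced")
  expect_error(parse_newick("(A,,B);"), "empty leaf")
  expect_error(parse_newick("(A,B,A);"), "duplicate")
  expect_warning(parse_newick("((A,B)node1,C);", quiet = FALSE), "ignored")
})

test_that("serialize-parse round trip preserves the split set", {
  set.seed(11)
  for (i in 1:20) {
    tr <- random_tree(sample(4:10, 1))
    tr$edge.length <- NULL
    txt <- write_newick(tr)
    tr2 <- parse_newick(txt)
    labs <- tr$tip.label
    expect_identical(split_set(tree_splits(tr2), labs),
                     split_set(tree_splits(tr), labs))
    # canonical serializer is invariant to leaf order in the input string
    expect_identical(write_newick(tr2), txt)
  }
})

test_that("splits enumerates internal edges only", {
  expect_identical(split_set(tree_splits(parse_newick("((A,B),(C,D),E);")),
                             LETTERS[1:5]),
                   split_set(list(c("A", "B"), c("C", "D")), LETTERS[1:5]))
  expect_length(tree_splits(parse_newick("(A,B,C,D);")), 0L)
  expect_identical(
    split_set(tree_splits(parse_newick("((((A,B),C),D),E);")), LETTERS[1:5]),
    split_set(list(c("A", "B"), c("A", "B", "C")), LETTERS[1:5]))
})

test_that("a fully resolved unrooted n-leaf tree has n-3 nontrivial splits", {
  set.seed(21)
  for (n in 4:9) {
    tr <- ape::unroot(random_tree(n))
    expect_length(tree_splits(tr), n - 3L)
  }
})

test_that("is_clan matches explicit examples and the vacuous convention", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_true(is_clan(tr, c("A", "B")))
  expect_false(is_clan(tr, c("A", "C")))
  expect_false(is_clan(tr, c("A", "C", "Z")))  # absent member ignored
  expect_true(is_clan(tr, "A"))                # singleton: vacuous
  expect_true(is_clan(tr, "Z"))                # empty after reduction
  expect_true(is_clan(tr, c("A", "B", "C", "D")))  # whole leaf set
})

test_that("is_clan agrees with the phangorn bipartition oracle", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    tr <- random_tree(n)
    m <- oracle_split_matrix(tr)
    labs <- tr$tip.label
    for (j in 1:25) {
      subset <- sample(labs, sample.int(n, 1))
      expect_identical(is_clan(tr, subset),
                       oracle_is_clan(m, subset, labs),
                       info = paste(write_newick(tr), "|",
                                    paste(subset, collapse = ",")))
    }
  }
})

test_that("multicopy leaves must all fall inside the clan block", {
  tr <- parse_newick("((x1,x2),(y1,(x3,z1)));")
  map <- species_map(c(x1 = "X", x2 = "X", x3 = "X", y1 = "Y", z1 = "Z"))
  # clan {X} needs all three X leaves together: x3 is separated
  expect_false(is_clan(tr, "X", map))
  tr2 <- parse_newick("(((x1,x2),x3),(y1,z1));")
  map2 <- species_map(c(x1 = "X", x2 = "X", x3 = "X", y1 = "Y", z1 = "Z"))
  expect_true(is_clan(tr2, "X", map2))
})

test_that("classify_triplet resolves explicit topologies", {
  map <- species_map(
    c(anu1 = "anu1", anu2 = "anu2", cau1 = "cau1", gym1 = "gym1",
      out1 = "out1"),
    c(anu1 = "A", anu2 = "A", cau1 = "C", gym1 = "G", out1 = "Out"))
  tr <- parse_newick("((anu1,cau1),(gym1,out1));")
  expect_identical(classify_triplet(tr, c("A", "C", "G"), "Out", map), "A+C")
  tr <- parse_newick("((gym1,cau1),(anu1,out1));")
  expect_identical(classify_triplet(tr, c("A", "C", "G"), "Out", map), "C+G")
  tr <- parse_newick("((anu1,gym1),(cau1,(anu2,out1)));")
  expect_identical(classify_triplet(tr, c("A", "C", "G"), "Out", map),
                   "unresolved")
  tr <- parse_newick("((anu1,cau1),(anu2,out1));")
  expect_error(classify_triplet(tr, c("A", "C", "G"), "Out", map), "'G'")
})

test_that("classify_triplet is invariant to rerooting and leaf order", {
  map <- species_map(
    setNames(c("a1", "a2", "c1", "c2", "g1", "o1", "o2"),
             c("a1", "a2", "c1", "c2", "g1", "o1", "o2")),
    c(a1 = "A", a2 = "A", c1 = "C", c2 = "C", g1 = "G",
      o1 = "Out", o2 = "Out"))
  tr <- parse_newick("(((a1,a2),(c1,c2)),(g1,(o1,o2)));")
  base <- classify_triplet(tr, c("A", "C", "G"), "Out", map)
  expect_identical(base, "A+C")
  set.seed(41)
  for (i in 1:10) {
    rerooted <- ape::root(tr, outgroup = sample(tr$tip.label, 1),
                          resolve.root = TRUE)
    expect_identical(classify_triplet(rerooted, c("A", "C", "G"), "Out", map),
                     base)
    shuffled <- ape::rotateConstr(tr, sample(tr$tip.label))
    expect_identical(classify_triplet(shuffled, c("A", "C", "G"), "Out", map),
                     base)
  }
})

test_that("prune_species_duplicates keeps the longest clan representative", {
  map <- species_map(c(spX_1 = "X", spX_2 = "X", spX_3 = "X",
                       spY = "Y", spZ = "Z"))
  lens <- c(spX_1 = 300, spX_2 = 120, spX_3 = 200, spY = 100, spZ = 100)

  tr <- parse_newick("((spX_1,spX_2),spY,spZ);")
  pruned <- prune_species_duplicates(tr, map, lens)
  expect_setequal(pruned$tip.label, c("spX_1", "spY", "spZ"))

  # no same-taxon clan: unchanged
  tr2 <- parse_newick("((spX_1,spY),(spX_2,spZ));")
  expect_setequal(prune_species_duplicates(tr2, map, lens)$tip.label,
                  tr2$tip.label)

  # only the cherry {spX_1,spX_2} collapses; spX_3 is elsewhere
  tr3 <- parse_newick("((spX_1,spX_2),(spX_3,spY),spZ);")
  pruned3 <- prune_species_duplicates(tr3, map, lens)
  expect_setequal(pruned3$tip.label, c("spX_1", "spX_3", "spY", "spZ"))

  # ties broken lexicographically
  lens_tie <- c(spX_1 = 100, spX_2 = 100, spX_3 = 100, spY = 1, spZ = 1)
  expect_setequal(prune_species_duplicates(tr, map, lens_tie)$tip.label,
                  c("spX_1", "spY", "spZ"))
  expect_error(prune_species_duplicates(tr, map, lens[-1]), "spX_1")
})

test_that("pruning preserves taxa and never increases leaf count", {
  set.seed(51)
  taxa <- c("X", "Y", "Z", "W")
  for (i in 1:25) {
    n <- sample(4:9, 1)
    tx <- sample(taxa, n, replace = TRUE)
    labs <- paste0(tx, "_", seq_len(n))
    tr <- random_tree(n, labels = labs)
    map <- species_map(setNames(tx, labs))
    lens <- setNames(sample(50:500, n), labs)
    pruned <- prune_species_duplicates(tr, map, lens)
    expect_lte(length(pruned$tip.label), n)
    expect_setequal(unique(map_leaves(pruned$tip.label, map)), unique(tx))
  }
})

test_that("duplicate pruning followed by single-copy check composes", {
  map <- species_map(c(A_1 = "A", A_2 = "A", B = "B", C = "C"))
  lens <- c(A_1 = 10, A_2 = 20, B = 5, C = 5)
  tr <- parse_newick("((A_1,A_2),(B,C));")
  expect_false(is_single_copy(tr, map))
  expect_true(is_single_copy(prune_species_duplicates(tr, map, lens), map))
  expect_true(is_single_copy(parse_newick("(A,B,C);")))
})

test_that("average branch length sums all edges", {
  tr <- parse_newick("((A:0.1,B:0.1):0.1,C:0.1,D:0.1);")
  expect_equal(avg_branch_length(tr), 0.1)
  tr2 <- parse_newick("((A:1,B:1):2,C:1,D:1);")
  expect_equal(avg_branch_length(tr2), 1.2)
  tr3 <- tr2
  tr3$edge.length <- tr3$edge.length * 3.5
  expect_equal(avg_branch_length(tr3), 3.5 * 1.2)
  expect_error(avg_branch_length(parse_newick("((A,B),C);")), "lengths")
})
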