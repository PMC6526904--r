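make_clan_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("load_clans validates the config format", {
  path <- make_clan_file(c(
    "# seven vertebrate groups",
    "mammals\thuman,cow,platypus",
    "birds\tchicken,zebra_finch",
    "frogs\txenopus,nanorana"))
  cs <- load_clans(path)
  expect_s3_class(cs, "clan_set")
  expect_length(cs, 3L)
  expect_identical(cs$mammals, c("human", "cow", "platypus"))

  expect_error(load_clans(make_clan_file("mammals\thuman")), "fewer than 2")
  expect_error(load_clans(make_clan_file(c("a\tx,y", "a\tz,w"))), "duplicate")
  expect_error(load_clans(make_clan_file("just_a_name")), "malformed")
  map <- species_map(c(human = "human", cow = "cow"))
  expect_warning(load_clans(make_clan_file("mammals\thuman,cow,yeti"), map),
                 "yeti")
})

test_that("check_family classifies pass, violated and untestable clans", {
  clans <- clan_set(list(mammals = c("h", "m")))
  keep <- check_family(gene_family("f1", parse_newick("((h,m),(c,f));")),
                       clans)
  expect_identical(unname(keep$status["mammals"]), "pass")
  expect_identical(keep$verdict, "keep")

  bad <- check_family(gene_family("f2", parse_newick("((h,c),(m,f));")),
                      clans)
  expect_identical(unname(bad$status["mammals"]), "violated")
  expect_identical(bad$verdict, "remove")

  vac <- check_family(gene_family("f3", parse_newick("((h,x),(y,z));")),
                      clans)
  expect_identical(unname(vac$status["mammals"]), "untestable")
  expect_identical(vac$verdict, "keep")

  map <- species_map(c(h_1 = "h", h_2 = "h", m = "m", c = "c"))
  multi <- gene_family("f4", parse_newick("((h_1,h_2),(m,c));"))
  expect_error(check_family(multi, clans, map), "multicopy")
})

test_that("filter_families partitions records and reports every clan", {
  clans <- clan_set(list(mammals = c("h", "m"), frogs = c("x", "n")))
  good <- "((h,m),((x,n),c));"
  bad <- "((h,x),((m,n),c));"
  recs <- c(lapply(1:7, function(i) gene_family(paste0("g", i),
                                                parse_newick(good))),
            lapply(1:3, function(i) gene_family(paste0("b", i),
                                                parse_newick(bad))))
  res <- filter_families(recs, clans)
  expect_length(res$kept, 7L)
  expect_length(res$removed, 3L)
  expect_equal(nrow(res$report), 10L)
  expect_named(res$report, c("family_id", "mammals", "frogs", "verdict"))
  # order preserved
  expect_identical(vapply(res$kept, `[[`, "", "family_id"), paste0("g", 1:7))

  # empty clan set keeps everything
  expect_error(clan_set(setNames(list(), character(0))), NA)
  res0 <- filter_families(recs, clan_set(setNames(list(), character(0))))
  expect_length(res0$kept, 10L)
  # all-violating set removes everything
  res1 <- filter_families(recs[8:10], clans)
  expect_length(res1$kept, 0L)
})

test_that("filtering is idempotent and invariant to clan and leaf order", {
  set.seed(61)
  clans <- clan_set(list(c1 = c("t1", "t2"), c2 = c("t3", "t4", "t5")))
  recs <- lapply(1:30, function(i) {
    gene_family(paste0("f", i), random_tree(sample(5:9, 1)))
  })
  res <- filter_families(recs, clans)
  again <- filter_families(res$kept, clans)
  expect_length(again$removed, 0L)
  expect_identical(vapply(again$kept, `[[`, "", "family_id"),
                   vapply(res$kept, `[[`, "", "family_id"))

  rev_clans <- clan_set(list(c2 = c("t3", "t4", "t5"), c1 = c("t1", "t2")))
  res_rev <- filter_families(recs, rev_clans)
  expect_identical(res_rev$report$verdict, res$report$verdict)

  # shuffling leaf order in the newick string changes no verdict
  shuffled <- lapply(recs, function(rec) {
    gene_family(rec$family_id,
                ape::rotateConstr(rec$tree, sample(rec$tree$tip.label)))
  })
  expect_identical(filter_families(shuffled, clans)$report$verdict,
                   res$report$verdict)
})

test_that("informativeness filter enforces groups and minimum taxa", {
  map <- default_fixture_map()
  fam <- function(taxa) {
    gene_family(paste(taxa, collapse = "."),
                ape::keep.tip(default_species_model()$tree, taxa))
  }
  informative <- fam(c("xenopus", "hynobius", "rhinatrema", "human",
                       "cow", "chicken"))
  no_caecilian <- fam(c("xenopus", "nanorana", "scinax", "hynobius",
                        "pleurodeles", "human", "cow", "chicken",
                        "zebrafish", "anolis"))
  too_small <- fam(c("xenopus", "hynobius", "rhinatrema", "human",
                     "chicken"))
  req <- c("Anura", "Caudata", "Gymnophiona", "Outgroup")
  kept <- informativeness_filter(list(informative, no_caecilian, too_small),
                                 map, req, min_taxa = 6L)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$family_id, informative$family_id)
  kept5 <- informativeness_filter(list(too_small), map, req, min_taxa = 5L)
  expect_length(kept5, 1L)
  expect_error(informativeness_filter(list(informative), map, "Dinosauria"),
               "unknown group")
})

test_that("support spectrum counts sum and concentrate without conflict", {
  model <- default_species_model()
  map <- default_fixture_map()
  set.seed(71)
  # conflict-free families: species subtrees always support Anura+Caudata
  recs <- lapply(1:30, function(i) {
    taxa <- c(sample(taxa_of_group(map, "Anura"), 2),
              sample(taxa_of_group(map, "Caudata"), 2),
              sample(taxa_of_group(map, "Gymnophiona"), 1),
              sample(taxa_of_group(map, "Outgroup"), 2))
    gene_family(paste0("s", i), ape::keep.tip(model$tree, taxa))
  })
  tally <- support_spectrum(recs, c("Anura", "Caudata", "Gymnophiona"),
                            "Outgroup", map)
  expect_equal(sum(tally), 30L)
  expect_equal(unname(tally["Anura+Caudata"]), 30L)
  empty <- support_spectrum(list(), c("A", "B", "C"), "Out", NULL)
  expect_equal(sum(empty), 0L)
})
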