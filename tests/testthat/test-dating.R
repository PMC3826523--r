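test_that("LCA mapping and duplication flagging match brute force", {
  stree <- toy_species_tree(5)
  for (seed in 1:100) {
    gtree <- random_gene_tree(8, stree, seed)
    mapping <- lca_map(gtree, stree)
    oracle <- bf_lca(gtree, stree)
    expect_equal(mapping$species_node, unname(oracle))
    dups <- annotate_duplications(gtree, mapping)
    expect_equal(sort(dups), sort(bf_dups(gtree, stree)))
  }
})

test_that("textbook reconciliation cases behave as expected", {
  stree <- toy_species_tree(4)
  # ((A,B),(A,B)): root is a duplication, both children speciations
  g <- ape::read.tree(text = "((a|a@1,b|b@1),(a|a@2,b|b@2));")
  mapping <- lca_map(g, stree)
  dups <- annotate_duplications(g, mapping)
  root <- ape::Ntip(g) + 1L
  expect_equal(dups, root)
  # root and both children map to the a-b ancestor
  ab <- paralogon:::path_mrca(stree$paths, 1, 2)
  expect_equal(mapping$species_node[root], ab)
  expect_equal(mapping$species_node[root + 1L], ab)
  expect_equal(mapping$species_node[root + 2L], ab)

  # cherry (A,A): duplication mapped onto the terminal branch of A
  cherry <- ape::read.tree(text = "(a|a@1,a|a@2);")
  m2 <- lca_map(cherry, stree)
  expect_equal(m2$species_node[3], match("a", stree$phy$tip.label))
  expect_equal(annotate_duplications(cherry, m2), 3L)

  # unknown species fails naming the tip
  bad <- ape::read.tree(text = "((a|a@1,zz|zz@1),b|b@1);")
  expect_error(lca_map(bad, stree), "zz")
})

test_that("window classification follows the branch rules", {
  st <- default_species_tree()
  ds <- figure5_dataset(snapshots = FALSE)
  calls <- quiet_date(ds$gene_trees$OTVPR, st, loci = ds$locus_table)
  tb <- tibble::as_tibble(calls)
  # duplications on the vertebrate stem are dated to the 2R window
  expect_true(all(tb$window[tb$species_label == "Vertebrata" &
                              tb$rule == "branch"] == "2R"))
  # duplications on the teleost stem to the 3R window
  expect_true(all(tb$window[tb$species_label == "Teleostei"] == "3R"))

  ops <- tibble::as_tibble(quiet_date(ds$gene_trees$OPSIN, st,
                                      loci = ds$locus_table))
  # tandem RH2 expansion on the zebrafish terminal branch
  expect_equal(sum(ops$window == "post-3R-local" &
                     ops$species_label == "zebrafish"), 3)
  # retrotransposition on the actinopterygian stem: between the windows
  expect_equal(sum(ops$window == "between-2R-3R" &
                     ops$species_label == "Actinopterygii"), 1)
})

test_that("scripted WGD duplications are dated 100% correctly", {
  ds <- figure5_dataset(snapshots = FALSE)
  st <- ds$species_tree
  calls <- lapply(ds$gene_trees, quiet_date, stree = st,
                  loci = ds$locus_table)
  score <- score_window_recovery(ds, calls)
  expect_equal(score$n_absorbed, 0)
  expect_equal(score$recovery, 1)
  expect_equal(score$n_mislabeled, 0)
})

test_that("window capacity relabels super-quadruplication chains", {
  ds <- figure5_dataset(snapshots = FALSE)
  st <- ds$species_tree
  for (fam in c("OPSIN", "OTVPR")) {
    tb <- tibble::as_tibble(quiet_date(ds$gene_trees[[fam]], st,
                                       loci = ds$locus_table))
    # the pre-2R tandem duplication is pushed out of the 2R window
    expect_equal(sum(tb$window == "pre-window" & tb$rule == "capacity"), 1)
    # at most 2 nested duplications remain per 2R chain (k = 2 WGDs)
  }
  # families without a pre-2R tandem history keep plain 2R labels
  tb <- tibble::as_tibble(quiet_date(ds$gene_trees$GNAT, st,
                                     loci = ds$locus_table))
  expect_equal(sum(tb$window == "pre-window"), 0)
})

test_that("the synteny guard withholds branch labels without local support", {
  st <- default_species_tree()
  # a duplication mapping to the sarcopterygian ancestor with its two copies
  # on different chromosomes: could be a loss-displaced WGD copy pair
  g <- ape::read.tree(text =
    "((human|human@x1,coelacanth|coelacanth@y1),(human|human@x2,coelacanth|coelacanth@y2));")
  loci_far <- as_locus_table(tibble::tibble(
    species = rep(c("human", "coelacanth"), 2),
    locus_id = c("human@x1", "coelacanth@y1", "human@x2", "coelacanth@y2"),
    family = "F", subtype = "unassigned",
    chromosome = c("c1", "c1", "c2", "c2"),
    start = c(1e6, 1e6, 5e6, 5e6), end = c(1e6, 1e6, 5e6, 5e6) + 1,
    strand = "+", has_introns = TRUE))
  tb <- tibble::as_tibble(date_duplications(g, st, loci = loci_far))
  expect_equal(tb$window[tb$rule == "guard"], "unresolved")

  # same topology, copies adjacent on one chromosome: a credible local event
  loci_near <- loci_far
  loci_near$chromosome <- "c1"
  loci_near$start <- c(1e6, 1e6, 1.05e6, 1.05e6)
  loci_near$end <- loci_near$start + 1
  tb2 <- tibble::as_tibble(date_duplications(g, st, loci = loci_near))
  expect_equal(sum(tb2$window == "lineage-local"), 1)

  # intron contrast rescues dispersed copies as a retrotransposition
  loci_retro <- loci_far
  loci_retro$has_introns <- c(TRUE, TRUE, FALSE, FALSE)
  tb3 <- tibble::as_tibble(date_duplications(g, st, loci = loci_retro))
  expect_equal(sum(tb3$window == "lineage-local"), 1)
})

test_that("collapsing weak nodes never manufactures 2R support", {
  st <- toy_species_tree(5, wgd = data.frame(label = c("2R-1", "2R-2"),
                                             node = "N2"))
  for (seed in 1:30) {
    gtree <- random_gene_tree(10, st, seed)
    set.seed(seed + 1000)
    gtree$node.label <- as.character(sample(10:100, gtree$Nnode))
    full <- date_duplications(gtree, st)
    collapsed <- date_duplications(gtree, st, collapse_below = 70)
    expect_lte(sum(collapsed$window == "2R"), sum(full$window == "2R"))
  }
})

test_that("family verdicts aggregate across input trees", {
  ds <- figure5_dataset(snapshots = FALSE)
  st <- ds$species_tree
  true_calls <- quiet_date(ds$gene_trees$GNAI, st, loci = ds$locus_table)
  noisy_tree <- perturb_tree(ds$gene_trees$GNAI, 1, seed = 42)
  noisy_calls <- quiet_date(noisy_tree, st, loci = ds$locus_table)

  both <- family_verdict(list(nj = true_calls, ml = true_calls), st)
  expect_equal(both$aggregate, "supported-by-all")
  expect_false(both$undated)

  none <- quiet_date(ds$gene_trees$DECOY, st, loci = ds$locus_table)
  v0 <- family_verdict(list(nj = none, ml = none), st)
  expect_equal(v0$aggregate, "inconclusive")

  mixed <- family_verdict(list(nj = true_calls, ml = none), st)
  expect_equal(mixed$aggregate, "supported-by-one")

  # a family with no pre-2R species cannot anchor its relative dating
  sub_tips <- ds$gene_trees$GNAI$tip.label[
    !startsWith(ds$gene_trees$GNAI$tip.label, "amphioxus")]
  pruned <- ape::keep.tip(ds$gene_trees$GNAI, sub_tips)
  undated <- quiet_date(pruned, st, loci = ds$locus_table)
  vu <- family_verdict(list(nj = undated), st)
  expect_true(vu$undated)
})
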