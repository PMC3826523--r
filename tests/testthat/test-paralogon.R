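fig5_run <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- suppressMessages(run_all(run_config()))
    }
    memo
  }
})

test_that("the scripted human-like genome yields one 5-block paralogon", {
  run <- fig5_run()
  expect_equal(nrow(run$blocks), 5)
  groups <- tibble::as_tibble(run$groups)
  expect_equal(max(groups$group), 1) # all five blocks connected
  expect_equal(nrow(groups), 5)
})

test_that("edge weights equal the brute-force family/block-pair count", {
  run <- fig5_run()
  ds <- run$dataset
  assign <- paralogon:::assign_loci_to_blocks(run$blocks, run$table)
  el <- igraph::as_data_frame(run$graph, what = "edges")
  for (r in seq_len(nrow(el))) {
    b1 <- el$from[r]; b2 <- el$to[r]
    n <- 0
    for (fam in union(run$selected, "OPSIN")) {
      gtree <- ds$gene_trees[[fam]]
      if (is.null(gtree)) next
      cl <- run$calls[[fam]]
      tips <- paralogon:::gene_tip_info(gtree)
      la <- assign$locus_id[assign$block_id == b1 & assign$family == fam]
      lb <- assign$locus_id[assign$block_id == b2 & assign$family == fam]
      hit <- FALSE
      for (x in la) {
        for (y in lb) {
          join <- ape::getMRCA(gtree, c(tips$tip[tips$locus_id == x],
                                        tips$tip[tips$locus_id == y]))
          w <- cl$window[cl$node == join]
          if (length(w) && w == "2R") hit <- TRUE
        }
      }
      n <- n + hit
    }
    expect_equal(el$weight[r], n)
  }
})

test_that("paralogon assembly partitions blocks and splits monotonically", {
  run <- fig5_run()
  sizes_prev <- NULL
  prev <- NULL
  for (ms in 1:6) {
    groups <- assemble_paralogons(run$graph, min_support = ms)
    tb <- tibble::as_tibble(groups)
    # partition: every block in exactly one group
    expect_setequal(tb$block_id, run$blocks$block_id)
    expect_equal(anyDuplicated(tb$block_id), 0)
    if (!is.null(prev)) {
      # raising min_support only splits: same-group now implies same-group
      # at the lower threshold
      for (g in unique(tb$group)) {
        members <- tb$block_id[tb$group == g]
        expect_equal(length(unique(prev$group[match(members,
                                                    prev$block_id)])), 1)
      }
    }
    prev <- tb
  }
  # above all weights every block is its own group
  solo <- tibble::as_tibble(assemble_paralogons(run$graph,
                                                min_support = 99))
  expect_equal(max(solo$group), nrow(run$blocks))
})

test_that("a loss-free post-2R genome assembles into one 4-block group", {
  st <- default_species_tree()
  log <- script_figure5()
  # drop every loss so all four 2R blocks keep their full gene content
  keep <- log$events$event_type != "loss"
  log2 <- event_log(log$ancestor, log$events[keep, ],
                    subtype_map = log$subtype_map)
  ds <- replay(log2, st, snapshots = FALSE)
  tab <- ds$locus_table
  human <- tab[tab$species == "human", ]
  anchors <- human[human$family == "OPSIN" & human$has_introns, ]
  blocks <- define_blocks(anchors, window = 5e6)
  calls <- lapply(ds$gene_trees, quiet_date, stree = st, loci = tab)
  g <- build_paralogy_graph(blocks, names(ds$gene_trees)[
    names(ds$gene_trees) != "DECOY"], ds$gene_trees, calls, tab)
  groups <- tibble::as_tibble(assemble_paralogons(g, min_support = 2))
  main <- groups[grepl("anc0", groups$block_id), ]
  expect_equal(length(unique(main$group)), 1)
  expect_gte(nrow(main), 4)
})

test_that("ortholog pairs are exactly the speciation-joined tip pairs", {
  # worked example: ((A_x,B_y),(A_z,B_w)) with a duplication at the root
  st <- toy_species_tree(4)
  g <- ape::read.tree(text = "((a|x,b|y),(a|z,b|w));")
  mapping <- lca_map(g, st)
  dups <- annotate_duplications(g, mapping)
  calls <- classify_window(dups, mapping, st)
  calls <- structure(calls, class = c("dup_calls", class(calls)),
                     gtree = g, mapping = mapping, tip_species = c("a", "b"))
  pairs <- map_orthologs(list(F1 = g), list(F1 = calls))
  expect_equal(nrow(pairs), 2)
  expect_setequal(paste(pairs$locus_a, pairs$locus_b),
                  c("x y", "z w"))

  # single-species family: no pairs
  g1 <- ape::read.tree(text = "(a|p,a|q);")
  m1 <- lca_map(g1, st)
  c1 <- structure(classify_window(annotate_duplications(g1, m1), m1, st),
                  class = c("dup_calls", "tbl_df", "tbl", "data.frame"),
                  gtree = g1, mapping = m1, tip_species = "a")
  expect_equal(nrow(map_orthologs(list(F1 = g1), list(F1 = c1))), 0)
})

test_that("ortholog mapping matches brute force and simulator truth", {
  stree <- toy_species_tree(5)
  for (seed in 1:100) {
    gtree <- random_gene_tree(8, stree, seed)
    calls <- date_duplications(gtree, stree)
    pairs <- map_orthologs(list(F = gtree), list(F = calls))
    oracle <- bf_orthologs(gtree, calls$node)
    got <- lapply(seq_len(nrow(pairs)), function(i)
      sort(c(pairs$locus_a[i], pairs$locus_b[i])))
    expect_setequal(vapply(got, paste, "", collapse = "+"),
                    vapply(oracle, paste, "", collapse = "+"))
  }

  # simulator truth: ortholog pairs between species share lineage ancestry
  ds <- figure5_dataset(snapshots = FALSE)
  st <- ds$species_tree
  calls <- lapply(ds$gene_trees, quiet_date, stree = st,
                  loci = ds$locus_table)
  pairs <- map_orthologs(ds$gene_trees, calls)
  hg <- pairs[pairs$species_a == "gar" & pairs$species_b == "human", ]
  lin <- stats::setNames(ds$locus_table$lineage, ds$locus_table$locus_id)
  # gar and human diverged after 2R: orthologous loci must descend from the
  # same 2R-era copy, i.e. carry identical 2R-suffix chains
  wgd_suffix <- function(x) {
    vapply(x, function(l) paste(
      regmatches(l, gregexpr("2R-[0-9]", l))[[1]], collapse = "+"), "")
  }
  expect_true(all(wgd_suffix(lin[hg$locus_a]) ==
                    wgd_suffix(lin[hg$locus_b])))
  # every identical-lineage pair across the two genomes is recovered
  gar_loci <- ds$locus_table[ds$locus_table$species == "gar", ]
  hum_loci <- ds$locus_table[ds$locus_table$species == "human", ]
  shared <- intersect(gar_loci$lineage, hum_loci$lineage)
  for (l in shared) {
    expect_true(any(hg$locus_a == gar_loci$locus_id[gar_loci$lineage == l] &
                      hg$locus_b ==
                        hum_loci$locus_id[hum_loci$lineage == l]))
  }
})

test_that("fission products merge into ancestral units via the outgroup", {
  run <- fig5_run()
  units <- run$units
  expect_equal(length(unique(units$unit)), 4)
  fused <- units$unit[grepl("anc0_2R-1(:|_f)", units$block_id)]
  expect_equal(length(unique(fused)), 1) # the scripted fission pair merges
  expect_false(any(units$flagged))

  # blocks whose orthologs occupy different outgroup chromosomes stay apart
  other <- units$unit[units$block_id %in%
                        c("human:anc0:0", "human:anc0_2R-2:0")]
  expect_equal(length(unique(other)), 2)
})

test_that("scripted translocations are recovered and timed post-3R", {
  run <- fig5_run()
  tr <- run$translocations
  expect_equal(nrow(tr), 2)
  expect_true(all(tr$timing == "post-3R"))
  # the OTR tandem pair moved onto the V2A chromosome...
  expect_true(any(tr$chromosome == "anc0" &
                    tr$source_chromosome == "anc0_2R-2"))
  # ...and the GNAI2/CACNA1D 3R copies onto the GNAI1 3R chromosome
  expect_true(any(tr$chromosome == "anc0_2R-1_3R" &
                    tr$source_chromosome == "anc0"))
})

test_that("genomes arranged like the outgroup produce zero calls", {
  ds <- figure5_dataset()
  st <- ds$species_tree
  gar <- ds$locus_table[ds$locus_table$species == "gar", ]
  anc <- snapshot_as_locus_table(ds, "Actinopterygii")
  orth <- truth_orthologs_to_snapshot(ds, "gar", "Actinopterygii")
  calls <- suppressWarnings(
    detect_translocations(gar, anc, orth, stree = st))
  expect_equal(nrow(calls), 0)
})
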