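test_that("scripted scenario reproduces the proposed chromosome history", {
  ds <- figure5_dataset()

  # pre-2R vertebrate ancestor: 2 opsins, 1 GNAT, 1 GNAI, 2 OT/VP-R,
  # 1 CACNA1-L on one chromosome
  pre <- ds$snapshots[["pre:2R-1"]]
  counts <- table(pre$family[pre$chromosome == "anc0"])
  expect_equal(counts[["OPSIN"]], 2)
  expect_equal(counts[["GNAT"]], 1)
  expect_equal(counts[["GNAI"]], 1)
  expect_equal(counts[["OTVPR"]], 2)
  expect_equal(counts[["CACNA1L"]], 1)

  # gnathostome ancestor after the 2R losses: 5 opsins / 3 / 3 / 6 / 4
  post <- table(ds$snapshots[["Vertebrata"]]$family)
  expect_equal(post[["OPSIN"]], 5)
  expect_equal(post[["GNAT"]], 3)
  expect_equal(post[["GNAI"]], 3)
  expect_equal(post[["OTVPR"]], 6)
  expect_equal(post[["CACNA1L"]], 4)

  # gar-like tip: two RH1 genes, one intron-less, on one chromosome
  tab <- ds$locus_table
  gar_rh1 <- tab[tab$species == "gar" & tab$subtype == "RH1", ]
  expect_equal(nrow(gar_rh1), 2)
  expect_equal(sum(gar_rh1$has_introns), 1)
  expect_equal(length(unique(gar_rh1$chromosome)), 1)

  # zebrafish-like tip: four RH2 genes within one 1 Mb window
  zrh2 <- tab[tab$species == "zebrafish" & tab$subtype == "RH2", ]
  expect_equal(nrow(zrh2), 4)
  expect_equal(length(unique(zrh2$chromosome)), 1)
  expect_lte(diff(range(zrh2$start)), 1e6)
})

test_that("replay is deterministic and honors trivial logs", {
  a <- figure5_dataset()
  b <- figure5_dataset()
  expect_identical(a$locus_table, b$locus_table)
  expect_identical(lapply(a$gene_trees, ape::write.tree),
                   lapply(b$gene_trees, ape::write.tree))

  st <- default_species_tree()
  anc <- tibble::tibble(lineage = c("f.x", "g.y"), family = c("F", "G"),
                        chromosome = "anc0", pos = c(1e6, 2e6))

  # zero events: every tip genome equals the ancestral content
  empty <- event_log(anc, tibble::tibble(event_type = character(),
                                         branch = character(),
                                         order_index = integer(),
                                         params = list()))
  ds0 <- replay(empty, st)
  for (sp in st$phy$tip.label) {
    g <- ds0$locus_table[ds0$locus_table$species == sp, ]
    expect_equal(nrow(g), 2)
    expect_setequal(g$lineage, c("f.x", "g.y"))
  }

  # one WGD, no losses: 2k loci on 2 chromosomes
  one <- event_log(anc, tibble::tibble(event_type = "wgd",
                                       branch = "Vertebrata",
                                       order_index = 1,
                                       params = list(list(label = "2R-1"))))
  st1 <- species_tree(st$phy, data.frame(label = "2R-1",
                                         node = "Vertebrata"))
  ds1 <- replay(one, st1)
  hum <- ds1$locus_table[ds1$locus_table$species == "human", ]
  expect_equal(nrow(hum), 4)
  expect_setequal(unique(hum$chromosome), c("anc0", "anc0_2R-1"))
})

test_that("events referencing dead lineages fail loudly", {
  st <- default_species_tree()
  anc <- tibble::tibble(lineage = "f.x", family = "F",
                        chromosome = "anc0", pos = 1e6)
  log <- event_log(anc, tibble::tibble(
    event_type = c("loss", "loss"), branch = "Vertebrata",
    order_index = 1:2,
    params = list(list(lineage = "f.x"), list(lineage = "f.x"))))
  expect_error(replay(log, st), "dead lineage: f.x")
})

test_that("stochastic simulation is a pure function of its config", {
  a <- simulate_genomes(sim_config(seed = 1), snapshots = FALSE)
  b <- simulate_genomes(sim_config(seed = 1), snapshots = FALSE)
  expect_identical(a$locus_table, b$locus_table)
  expect_identical(a$event_log$events$params, b$event_log$events$params)

  c2 <- simulate_genomes(sim_config(seed = 2), snapshots = FALSE)
  expect_false(identical(a$event_log$events, c2$event_log$events))

  expect_error(sim_config(loss_prob = 1.4, seed = 1), "\\[0, 1\\]")
  expect_error(sim_config(), "seed")
})

test_that("loss-free WGD-only runs conserve 2^k copies per lineage", {
  cfg <- sim_config(loss_prob = 0, n_translocations = 0, seed = 5)
  ds <- simulate_genomes(cfg, snapshots = FALSE)
  tab <- ds$locus_table
  anc_n <- table(cfg$ancestor$family)
  for (fam in names(anc_n)) {
    expect_equal(sum(tab$species == "zebrafish" & tab$family == fam),
                 anc_n[[fam]] * 8) # 2R-1 x 2R-2 x 3R
    expect_equal(sum(tab$species == "human" & tab$family == fam),
                 anc_n[[fam]] * 4)
    expect_equal(sum(tab$species == "amphioxus" & tab$family == fam),
                 anc_n[[fam]] * 1)
  }
})

test_that("per-branch loss frequency matches the binomial expectation", {
  st <- species_tree(ape::read.tree(text = "(a,b)R;"))
  anc <- tibble::tibble(lineage = "f.x", family = "F",
                        chromosome = "c", pos = 1e6)
  p <- 0.3
  n <- 1000
  lost <- logical(n)
  for (s in seq_len(n)) {
    cfg <- sim_config(species_tree = st, ancestor = anc, loss_prob = p,
                      n_translocations = 0, seed = s)
    ds <- simulate_genomes(cfg, snapshots = FALSE)
    lost[s] <- !any(ds$locus_table$species == "a")
  }
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(lost) - p), 3 * se)
})

test_that("NNI perturbation keeps tips and yields a one-move neighbor", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_identical(ape::write.tree(perturb_tree(tr, 0, seed = 1)),
                   ape::write.tree(tr))
  # the single internal edge has exactly two alternative resolutions
  alts <- c("((a,c),(b,d));", "((a,d),(b,c));")
  for (s in 1:10) {
    got <- perturb_tree(tr, 1, seed = s)
    expect_setequal(got$tip.label, tr$tip.label)
    d <- vapply(alts, function(a) {
      as.numeric(ape::dist.topo(ape::unroot(got),
                                ape::unroot(ape::read.tree(text = a))))
    }, numeric(1))
    expect_true(any(d == 0))
  }
  # larger trees: tip set invariant for any n_nni
  big <- ape::rtree(12, rooted = TRUE, br = NULL)
  shaken <- perturb_tree(big, 7, seed = 3)
  expect_setequal(shaken$tip.label, big$tip.label)
  expect_error(perturb_tree(ape::read.tree(text = "(a,(b,c));"), 1, seed = 1),
               "at least 4 tips")
})
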