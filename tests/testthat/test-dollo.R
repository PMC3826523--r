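fig5_pieces <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ds <- figure5_dataset()
      st <- ds$species_tree
      calls <- lapply(ds$gene_trees, quiet_date, stree = st,
                      loci = ds$locus_table)
      lineages <- build_lineages(calls, ds$gene_trees, ds$locus_table)
      memo <<- list(ds = ds, st = st, calls = calls, lineages = lineages,
                    recon = dollo_reconstruct(lineages, st))
    }
    memo
  }
})

test_that("lineage cutting partitions tips by dated duplications", {
  p <- fig5_pieces()
  lin <- p$lineages
  # every extant locus belongs to exactly one lineage
  all_loci <- unlist(lin$loci)
  expect_equal(anyDuplicated(all_loci), 0)
  expect_setequal(all_loci, p$ds$locus_table$locus_id)

  # the opsin repertoire at the gnathostome ancestor: five lineages, four
  # originating in the 2R window plus LWS from the pre-2R tandem pair
  ops <- lin[lin$family == "OPSIN", ]
  expect_equal(sum(ops$origin_window == "2R"), 4)
  lws <- ops[ops$subtype == "LWS", ]
  expect_equal(lws$origin_window, "pre-window")
  # a family without duplications stays one lineage
  expect_equal(sum(lin$family == "DECOY"), 1)
})

test_that("lineage partition equals the brute-force grouping on toys", {
  stree <- toy_species_tree(5)
  for (seed in 1:40) {
    gtree <- random_gene_tree(9, stree, seed)
    calls <- date_duplications(gtree, stree)
    tab <- as_locus_table(tibble::tibble(
      species = sub("\\|.*", "", gtree$tip.label),
      locus_id = sub(".*\\|", "", gtree$tip.label),
      family = "F", subtype = "unassigned", chromosome = "c",
      start = seq_along(gtree$tip.label) * 1e5,
      end = seq_along(gtree$tip.label) * 1e5 + 1,
      strand = "+", has_introns = TRUE))
    lin <- build_lineages(list(F = calls), list(F = gtree), tab)
    # oracle: group tips by (nearest dated-duplication ancestor, child)
    parent <- paralogon:::tree_parents(gtree)
    key <- vapply(seq_len(ape::Ntip(gtree)), function(v) {
      child <- v; pp <- parent[v]
      while (pp != 0 && !(pp %in% calls$node)) { child <- pp; pp <- parent[pp] }
      if (pp == 0) "root" else paste0(pp, ".", child)
    }, character(1))
    oracle_sizes <- sort(as.integer(table(key)))
    expect_equal(sort(lin$n_loci), oracle_sizes)
  }
})

test_that("the V1B absence is explained by one actinopterygian loss", {
  p <- fig5_pieces()
  losses <- p$recon$losses
  v1b <- losses[losses$subtype == "V1B", ]
  expect_equal(nrow(v1b), 1)
  expect_equal(v1b$branch, "Actinopterygii")
  expect_equal(v1b$n_alternatives, 1L)
  # lineages surviving in all descendants incur no losses
  expect_false(any(losses$subtype == "DEC1"))
})

test_that("loss placement matches exhaustive minimal branch cover", {
  stree <- toy_species_tree(5)
  sp <- stree$phy$tip.label
  set.seed(99)
  for (rep in 1:100) {
    origin <- sample(c("N1", "N2", "N3"), 1)
    clade <- stree$phy$tip.label[
      paralogon:::tips_below(stree$phy, paralogon:::node_by_label(stree$phy,
                                                                  origin))]
    survivors <- sample(clade, max(1, sample(length(clade) - 1, 1)))
    unreliable <- if (runif(1) < 0.4) sample(setdiff(clade, survivors),
                                             min(1, length(setdiff(clade, survivors)))) else NULL
    lin <- tibble::tibble(
      lineage_id = "L1", family = "F", subtype = "S",
      origin_node = origin, origin_window = "2R", n_loci = 1L,
      species = list(sort(survivors)), loci = list("x"), flagged = FALSE)
    # minimal call structure carrying what dollo_reconstruct needs
    calls <- list(F = structure(
      tibble::tibble(node = integer(), species_node = integer(),
                     species_label = character(), window = character()),
      gtree = ape::read.tree(text = paste0(
        "(", paste(paste0(survivors, "|", survivors, "@x"),
                   collapse = ","), ");")),
      mapping = NULL))
    lin <- structure(lin, class = c("lineage_set", class(lin)),
                     calls = calls, gtrees = NULL)
    recon <- try(dollo_losses(lin, stree, unreliable),
                 silent = TRUE)
    oracle <- bf_loss_cover(stree, origin, survivors, unreliable)
    got <- recon
    expect_equal(nrow(got), oracle$size)
    if (nrow(got)) expect_equal(prod(got$n_alternatives), oracle$count)
  }
})

test_that("reconstructed content equals the replay snapshots", {
  p <- fig5_pieces()
  content <- p$recon$content
  for (node in unique(content$node)) {
    snap <- p$ds$snapshots[[node]]
    truth <- table(snap$family)
    for (fam in unique(content$family)) {
      expected <- if (fam %in% names(truth)) truth[[fam]] else 0L
      got <- content$n[content$node == node & content$family == fam]
      expect_equal(got, expected,
                   info = paste("node", node, "family", fam))
    }
  }
})

test_that("content is monotone non-increasing between duplication origins", {
  p <- fig5_pieces()
  st <- p$st
  content <- p$recon$content
  # below the teleost ancestor no new opsin lineages arise except the
  # zebrafish tandem RH2s; stickleback counts can only shrink
  get <- function(node, fam) content$n[content$node == node &
                                         content$family == fam]
  for (fam in unique(content$family)) {
    expect_lte(get("stickleback", fam), get("Teleostei", fam))
    expect_lte(get("coelacanth", fam), get("Sarcopterygii", fam))
    expect_lte(get("Sarcopterygii", fam), get("Vertebrata", fam))
  }
})

test_that("Dollo output is invariant to tip ordering", {
  p <- fig5_pieces()
  ds <- p$ds
  st <- p$st
  rot <- lapply(ds$gene_trees, function(tr) {
    r <- ape::read.tree(text = ape::write.tree(ape::ladderize(tr)))
    r
  })
  calls2 <- lapply(rot, quiet_date, stree = st, loci = ds$locus_table)
  lineages2 <- build_lineages(calls2, rot, ds$locus_table)
  recon2 <- dollo_reconstruct(lineages2, st)
  expect_equal(dplyr::arrange(recon2$content, .data$node, .data$family),
               dplyr::arrange(p$recon$content, .data$node, .data$family))
  key <- function(l) dplyr::arrange(l[, c("family", "subtype", "branch",
                                          "n_alternatives")],
                                    .data$family, .data$subtype, .data$branch)
  expect_equal(key(recon2$losses), key(p$recon$losses))
})

test_that("unreliable assemblies widen but never force loss placements", {
  st <- default_species_tree()
  # a lineage absent from gar and both teleosts, with gar marked unreliable:
  # the loss may sit on the actinopterygian stem or the teleost stem
  lin <- tibble::tibble(
    lineage_id = "L1", family = "F", subtype = "S",
    origin_node = "Vertebrata", origin_window = "2R", n_loci = 2L,
    species = list(c("coelacanth", "human")), loci = list(c("a", "b")),
    flagged = FALSE)
  calls <- list(F = structure(
    tibble::tibble(node = integer(), species_node = integer(),
                   species_label = character(), window = character()),
    gtree = ape::read.tree(text = "(coelacanth|coelacanth@a,human|human@b);"),
    mapping = NULL))
  lin <- structure(lin, class = c("lineage_set", class(lin)),
                   calls = calls, gtrees = NULL)
  strict <- dollo_losses(lin, st, character())
  expect_equal(strict$branch, "Actinopterygii")
  expect_equal(strict$n_alternatives, 1L)
  relaxed <- dollo_losses(lin, st, "gar")
  expect_equal(relaxed$branch, "Actinopterygii")
  expect_equal(relaxed$n_alternatives, 2L) # ... or on the teleost stem
})

test_that("repertoire summaries print the scenario integers", {
  p <- fig5_pieces()
  rep <- scenario_summary(p$recon, c("pre:2R-1", "Vertebrata"))
  pre <- stats::setNames(rep[["pre:2R-1"]], rep$family)
  post <- stats::setNames(rep[["Vertebrata"]], rep$family)
  expect_equal(pre[["OPSIN"]], 2L)
  expect_equal(pre[["GNAT"]], 1L)
  expect_equal(pre[["GNAI"]], 1L)
  expect_equal(pre[["OTVPR"]], 2L)
  expect_equal(pre[["CACNA1L"]], 1L)
  expect_equal(post[["OPSIN"]], 5L)
  expect_equal(post[["GNAT"]], 3L)
  expect_equal(post[["GNAI"]], 3L)
  expect_equal(post[["OTVPR"]], 6L)
  expect_equal(post[["CACNA1L"]], 4L)
  expect_error(scenario_summary(p$recon, "Atlantis"), "unknown node")

  # a teleost genome carries two V1A genes (the 3R pair)
  v1a <- count_repertoire(p$ds$locus_table, species = "zebrafish",
                          family = "OTVPR")
  expect_equal(v1a$n[v1a$subtype == "V1A"], 2L)
})
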