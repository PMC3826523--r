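#' The scripted evolutionary scenario for the visual-opsin paralogon
#'
#' Encodes the proposed history of the opsin-bearing chromosome regions as a
#' deterministic event log on [default_species_tree()]:
#'
#' * one ancestral chromosome carrying a visual opsin gene, adjacent GNAT and
#'   GNAI genes, an oxytocin/vasopressin receptor gene and an L-type calcium
#'   channel gene (plus a decoy family on an unlinked chromosome as a
#'   negative control for the synteny screen);
#' * pre-2R local duplications creating the SWS/LWS opsin pair and the V1/V2
#'   receptor pair;
#' * the two rounds of WGD on the vertebrate stem, quadrupling the
#'   chromosome, followed by the losses that leave five opsins (SWS1, SWS2,
#'   RH1, RH2, and a single surviving LWS), three GNAT, three GNAI, six
#'   OT/VP-R and four CACNA1-L genes in the gnathostome ancestor;
#' * loss of V1B and retrotransposition of the intron-bearing RH1 gene to a
#'   distant position on the same chromosome (the intron-less rhodopsin) on
#'   the actinopterygian stem, before the gar-teleost split;
#' * 3R on the teleost stem with retention of duplicates for GNAI1, GNAI2,
#'   V1A, CACNA1D, CACNA1C, CACNA1F and the RH1 retrocopy, post-3R local
#'   duplications of OTR and V2A, and two translocations intermingling the
#'   3R-derived blocks;
#' * post-3R local duplications making four tandem RH2 genes in the
#'   zebrafish lineage, and a fission splitting one 2R chromosome in the
#'   human lineage.
#'
#' @param rho_3r Should the two intron-less rhodopsin genes (rho/rhol) arise
#'   as 3R duplicates (default) or, alternatively, by a post-3R local
#'   duplication in the zebrafish lineage? The data leave this open; both
#'   variants are expressible.
#' @return An `event_log`.
#' @export
script_figure5 <- function(rho_3r = TRUE) {
  anc <- tibble::tribble(
    ~lineage,          ~family,    ~chromosome, ~pos,
    "opsin.OPS",       "OPSIN",    "anc0",      1.0e6,
    "GNAT.GNAT",       "GNAT",     "anc0",      2.0e6,
    "GNAI.GNAI",       "GNAI",     "anc0",      2.1e6,
    "OTVPR.VR",        "OTVPR",    "anc0",      3.0e6,
    "CACNA1L.CACNA1",  "CACNA1L",  "anc0",      4.0e6,
    "decoy.DEC",       "DECOY",    "anc1",      1.0e6)
  ev <- list()
  add <- function(type, branch, params) {
    ev[[length(ev) + 1]] <<- tibble::tibble(
      event_type = type, branch = branch, order_index = length(ev) + 1,
      params = list(params))
  }
  # vertebrate stem: pre-2R local duplications, then 2R, then losses
  add("local_duplication", "Vertebrata",
      list(lineage = "opsin.OPS", offset = 2e5,
           child_ids = c("opsin.SWS", "opsin.LWS")))
  add("local_duplication", "Vertebrata",
      list(lineage = "OTVPR.VR", offset = 2e5,
           child_ids = c("OTVPR.V1", "OTVPR.V2")))
  add("wgd", "Vertebrata", list(label = "2R-1"))
  add("wgd", "Vertebrata", list(label = "2R-2"))
  for (l in c("opsin.LWS", "opsin.LWS_2R-1", "opsin.LWS_2R-1_2R-2",
              "GNAT.GNAT_2R-1_2R-2", "GNAI.GNAI_2R-1_2R-2",
              "OTVPR.V1", "OTVPR.V2_2R-1_2R-2",
              "decoy.DEC_2R-1", "decoy.DEC_2R-2", "decoy.DEC_2R-1_2R-2")) {
    add("loss", "Vertebrata", list(lineage = l))
  }
  # actinopterygian stem: V1B loss; RH1 retrotransposed ~19 Mb away
  add("loss", "Actinopterygii", list(lineage = "OTVPR.V1_2R-1_2R-2"))
  add("retrotransposition", "Actinopterygii",
      list(lineage = "opsin.SWS", dest_chromosome = "anc0", dest_pos = 2.0e7,
           new_id = "opsin.RH1R"))
  # teleost stem: 3R, then loss of all 3R duplicates except the retained set
  add("wgd", "Teleostei", list(label = "3R"))
  retained <- c("GNAI.GNAI_3R", "GNAI.GNAI_2R-1_3R", "OTVPR.V1_2R-1_3R",
                "CACNA1L.CACNA1_3R", "CACNA1L.CACNA1_2R-1_3R",
                "CACNA1L.CACNA1_2R-1_2R-2_3R",
                if (rho_3r) "opsin.RH1R_3R")
  all_3r <- paste0(c("opsin.SWS", "opsin.SWS_2R-1", "opsin.SWS_2R-2",
                     "opsin.SWS_2R-1_2R-2", "opsin.LWS_2R-2", "opsin.RH1R",
                     "GNAT.GNAT", "GNAT.GNAT_2R-1", "GNAT.GNAT_2R-2",
                     "GNAI.GNAI", "GNAI.GNAI_2R-1", "GNAI.GNAI_2R-2",
                     "OTVPR.V1_2R-1", "OTVPR.V1_2R-2",
                     "OTVPR.V2", "OTVPR.V2_2R-1", "OTVPR.V2_2R-2",
                     "CACNA1L.CACNA1", "CACNA1L.CACNA1_2R-1",
                     "CACNA1L.CACNA1_2R-2", "CACNA1L.CACNA1_2R-1_2R-2",
                     "decoy.DEC"), "_3R")
  for (l in setdiff(all_3r, retained)) {
    add("loss", "Teleostei", list(lineage = l))
  }
  # post-3R local duplications of OTR and V2A
  add("local_duplication", "Teleostei",
      list(lineage = "OTVPR.V1_2R-2", offset = 1e4))
  add("local_duplication", "Teleostei",
      list(lineage = "OTVPR.V2", offset = 1e4))
  # post-3R translocations intermingling the 3R-derived blocks
  add("translocation", "Teleostei",
      list(chromosome = "anc0_3R", from = 2.0e6, to = 4.1e6,
           dest_chromosome = "anc0_2R-1_3R", dest_pos = 1.0e7))
  add("translocation", "Teleostei",
      list(chromosome = "anc0_2R-2", from = 3.0e6, to = 3.05e6,
           dest_chromosome = "anc0", dest_pos = 3.0e7))
  # zebrafish lineage: four tandem RH2 genes
  add("local_duplication", "zebrafish",
      list(lineage = "opsin.SWS_2R-1_2R-2", offset = 1e4))
  add("local_duplication", "zebrafish",
      list(lineage = "opsin.SWS_2R-1_2R-2", offset = 2e4))
  add("local_duplication", "zebrafish",
      list(lineage = "opsin.SWS_2R-1_2R-2", offset = 3e4))
  if (!rho_3r) {
    add("local_duplication", "zebrafish",
        list(lineage = "opsin.RH1R", offset = 5e5))
  }
  # human lineage: fission of one 2R chromosome
  add("fission", "human",
      list(chromosome = "anc0_2R-1", breakpoint = 2.5e6))

  subtype_map <- c(
    "opsin.SWS" = "RH1", "opsin.SWS_2R-1" = "SWS1",
    "opsin.SWS_2R-2" = "SWS2", "opsin.SWS_2R-1_2R-2" = "RH2",
    "opsin.LWS_2R-2" = "LWS", "opsin.RH1R" = "RH1",
    "GNAT.GNAT" = "GNAT1", "GNAT.GNAT_2R-1" = "GNAT3",
    "GNAT.GNAT_2R-2" = "GNAT2",
    "GNAI.GNAI" = "GNAI2", "GNAI.GNAI_2R-1" = "GNAI1",
    "GNAI.GNAI_2R-2" = "GNAI3",
    "OTVPR.V1_2R-1" = "V1A", "OTVPR.V1_2R-2" = "OTR",
    "OTVPR.V1_2R-1_2R-2" = "V1B",
    "OTVPR.V2" = "V2A", "OTVPR.V2_2R-1" = "V2C", "OTVPR.V2_2R-2" = "V2B",
    "CACNA1L.CACNA1" = "CACNA1D", "CACNA1L.CACNA1_2R-1" = "CACNA1C",
    "CACNA1L.CACNA1_2R-2" = "CACNA1S",
    "CACNA1L.CACNA1_2R-1_2R-2" = "CACNA1F",
    "decoy.DEC" = "DEC1")
  event_log(anc, dplyr::bind_rows(ev), subtype_map = subtype_map,
            scenario = if (rho_3r) "figure5" else "figure5-rho-local")
}

#' Replay the scripted scenario
#'
#' Convenience wrapper: `replay(script_figure5(...), default_species_tree())`.
#'
#' @inheritParams script_figure5
#' @inheritParams replay
#' @return A `sim_dataset`.
#' @export
figure5_dataset <- function(rho_3r = TRUE, snapshots = TRUE) {
  replay(script_figure5(rho_3r = rho_3r), default_species_tree(),
         snapshots = snapshots)
}

#' Configuration for the stochastic genome-evolution simulator
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: the six-species tree of [default_species_tree()], an ancestral
#' chromosome carrying the seven main-family genes plus ten single-copy
#' neighbor families, loss probability 0.2 per locus per branch, up to two
#' post-3R translocations of three-gene runs, and no gene-tree noise.
#'
#' @param species_tree A [species_tree].
#' @param ancestor Ancestral locus tibble (`lineage, family, chromosome,
#'   pos`).
#' @param loss_prob Per-locus, per-branch loss probability in `[0, 1]`.
#' @param local_dup_prob Per-locus, per-branch local duplication probability.
#' @param n_translocations Number of post-3R translocations (placed on the
#'   3R branch after losses).
#' @param translocation_run Number of adjacent loci per translocated run.
#' @param nni Number of random NNI moves applied to each true gene tree (0 =
#'   trees stay congruent with the history).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species_tree = default_species_tree(),
                       ancestor = default_ancestor(),
                       loss_prob = 0.2, local_dup_prob = 0,
                       n_translocations = 2, translocation_run = 3,
                       nni = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory for stochastic simulation",
                          call. = FALSE)
  for (p in c(loss_prob, local_dup_prob)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(species_tree = species_tree, ancestor = ancestor,
                 loss_prob = loss_prob, local_dup_prob = local_dup_prob,
                 n_translocations = n_translocations,
                 translocation_run = translocation_run,
                 nni = nni, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param n_neighbors Number of single-copy neighbor families flanking the
#'   main genes on the ancestral chromosome.
#' @export
default_ancestor <- function(n_neighbors = 10) {
  main <- tibble::tribble(
    ~lineage,         ~family,   ~chromosome, ~pos,
    "opsin.SWS",      "OPSIN",   "anc0",      1.0e6,
    "opsin.LWS",      "OPSIN",   "anc0",      1.2e6,
    "GNAT.GNAT",      "GNAT",    "anc0",      2.0e6,
    "GNAI.GNAI",      "GNAI",    "anc0",      2.1e6,
    "OTVPR.V1",       "OTVPR",   "anc0",      3.0e6,
    "OTVPR.V2",       "OTVPR",   "anc0",      3.2e6,
    "CACNA1L.CACNA1", "CACNA1L", "anc0",      4.0e6)
  if (n_neighbors == 0) return(main)
  pos <- seq(0.3e6, 4.8e6, length.out = n_neighbors)
  nb <- tibble::tibble(
    lineage = sprintf("NBR%02d.N", seq_len(n_neighbors)),
    family = sprintf("NBR%02d", seq_len(n_neighbors)),
    chromosome = "anc0", pos = pos)
  dplyr::arrange(dplyr::bind_rows(main, nb), .data$pos)
}

#' Simulate genomes under stochastic rates
#'
#' Draws per-branch events from the rates in `config` (WGDs are fixed at
#' their species-tree placements; on a WGD branch they precede the drawn
#' events), assembles an event log, and replays it. Identical config
#' (including seed) gives identical output.
#'
#' @param config A [sim_config()].
#' @param snapshots Passed to [replay()].
#' @return A `sim_dataset`; when `config$nni > 0` it additionally carries
#'   `gene_trees_noisy`.
#' @export
simulate_genomes <- function(config, snapshots = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  stree <- config$species_tree
  phy <- stree$phy
  ntip <- ape::Ntip(phy)
  kids <- children_list(phy)
  labels <- stree$labels
  last_wgd <- if (nrow(stree$wgd)) {
    ids <- unique(stree$wgd$node_id)
    ids[which.max(stree$depths[ids])]
  } else NA_integer_

  ev <- list()
  add <- function(type, branch, params) {
    ev[[length(ev) + 1]] <<- tibble::tibble(
      event_type = type, branch = branch,
      order_index = sum(vapply(ev, function(e) e$branch == branch, TRUE)) + 1,
      params = list(params))
  }

  set.seed(config$seed)

  state0 <- dplyr::mutate(tibble::as_tibble(config$ancestor),
                          strand = "+", has_introns = TRUE)
  recurse <- function(node, state) {
    lab <- labels[node]
    if (node != ntip + 1L) {
      for (w in wgd_on_branch(stree, node)) {
        add("wgd", lab, list(label = w))
        copy <- state
        copy$lineage <- paste0(copy$lineage, "_", w)
        copy$chromosome <- paste0(copy$chromosome, "_", w)
        state <- dplyr::bind_rows(state, copy)
      }
      state <- state[order(state$chromosome, state$pos, state$lineage), ]
      lost <- stats::runif(nrow(state)) < config$loss_prob
      for (l in state$lineage[lost]) add("loss", lab, list(lineage = l))
      state <- state[!lost, ]
      if (config$local_dup_prob > 0) {
        dup <- stats::runif(nrow(state)) < config$local_dup_prob
        for (j in which(dup)) {
          add("local_duplication", lab, list(lineage = state$lineage[j],
                                             offset = 1e4))
          copy <- state[j, ]
          copy$lineage <- paste0(copy$lineage, ".L1")
          copy$pos <- copy$pos + 1e4
          state <- dplyr::bind_rows(state, copy)
        }
      }
      if (!is.na(last_wgd) && node == last_wgd &&
          config$n_translocations > 0) {
        run <- config$translocation_run
        for (t in seq_len(config$n_translocations)) {
          counts <- table(state$chromosome)
          from_chr <- names(counts)[counts >= run + 1]
          if (!length(from_chr)) break
          src <- sample(from_chr, 1)
          loci <- state[state$chromosome == src, ]
          loci <- loci[order(loci$pos), ]
          start <- sample(nrow(loci) - run + 1, 1)
          seg <- loci[start:(start + run - 1), ]
          dest <- sample(setdiff(names(counts), src), 1)
          dest_pos <- 3.0e7 + t * 5e6
          add("translocation", lab,
              list(chromosome = src, from = min(seg$pos), to = max(seg$pos),
                   dest_chromosome = dest, dest_pos = dest_pos))
          mv <- state$chromosome == src & state$pos >= min(seg$pos) &
            state$pos <= max(seg$pos)
          state$pos[mv] <- dest_pos + (state$pos[mv] - min(seg$pos))
          state$chromosome[mv] <- dest
        }
      }
    }
    if (node > ntip) for (ch in kids[[node]]) recurse(ch, state)
  }
  recurse(ntip + 1L, state0)

  log <- event_log(config$ancestor, dplyr::bind_rows(ev),
                   scenario = paste0("random-seed", config$seed))
  out <- replay(log, stree, snapshots = snapshots)
  if (config$nni > 0) {
    out$gene_trees_noisy <- purrr::imap(out$gene_trees, function(tr, fam) {
      if (ape::Ntip(tr) < 4) tr
      else perturb_tree(tr, config$nni,
                        seed = config$seed + utf8ToInt(substr(fam, 1, 1)))
    })
  }
  out
}

#' Perturb a gene tree by random nearest-neighbor interchanges
#'
#' Models topological disagreement between inference methods: each move picks
#' a random internal edge of the rooted tree and swaps one subtree across it
#' (one of the two alternative resolutions of that edge). The tip set is
#' unchanged.
#'
#' @param tree A rooted `phylo` with at least 4 tips when `n_nni > 0`.
#' @param n_nni Number of interchanges (>= 0).
#' @param seed Integer seed.
#' @return A `phylo`.
#' @export
perturb_tree <- function(tree, n_nni, seed) {
  stopifnot(n_nni >= 0)
  if (n_nni == 0) return(tree)
  if (ape::Ntip(tree) < 4) {
    stop("NNI needs a tree with at least 4 tips", call. = FALSE)
  }
  set.seed(seed)
  for (i in seq_len(n_nni)) {
    ntip <- ape::Ntip(tree)
    root <- ntip + 1L
    # internal edges of the unrooted topology: child internal, and either a
    # non-root parent or (for the edge spanning a degree-2 root) an internal
    # sibling
    v_int <- tree$edge[, 2] > ntip
    sib_of <- function(u, v) {
      sibs <- tree$edge[tree$edge[, 1] == u & tree$edge[, 2] != v, 2]
      sibs[sample(length(sibs), 1)]
    }
    cand <- which(v_int & (tree$edge[, 1] != root |
                             vapply(seq_len(nrow(tree$edge)), function(r) {
                               any(tree$edge[tree$edge[, 1] == root &
                                               tree$edge[, 2] !=
                                               tree$edge[r, 2], 2] > ntip)
                             }, logical(1))))
    if (!length(cand)) stop("no internal edge available for NNI",
                            call. = FALSE)
    e <- cand[sample(length(cand), 1)]
    u <- tree$edge[e, 1]
    v <- tree$edge[e, 2]
    ch_v <- tree$edge[tree$edge[, 1] == v, 2]
    c1 <- ch_v[sample(length(ch_v), 1)]
    if (u == root) {
      # NNI across the edge joining the root's two subtrees
      s <- sib_of(u, v)
      ch_s <- tree$edge[tree$edge[, 1] == s, 2]
      c2 <- ch_s[sample(length(ch_s), 1)]
      tree$edge[tree$edge[, 2] == c1, 1] <- s
      tree$edge[tree$edge[, 2] == c2, 1] <- v
    } else {
      s <- sib_of(u, v)
      tree$edge[tree$edge[, 2] == s, 1] <- v
      tree$edge[tree$edge[, 2] == c1, 1] <- u
    }
  }
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  parent <- tree_parents(tree)
  nodes <- tibble::tibble(
    id = as.character(seq_len(n)),
    parent = ifelse(parent == 0, NA_character_, as.character(parent)),
    tip = seq_len(n) <= ntip,
    label = c(tree$tip.label, rep("", tree$Nnode)))
  phylo_from_table(nodes)$phy
}

#' Extract a snapshot genome as a locus table
#'
#' Re-expresses a stored replay snapshot (the genome at a species-tree node,
#' or just before a WGD via `pre:<label>`) as a locus table with the node
#' name as its species, e.g. for use as an ancestral reference genome.
#'
#' @param dataset A `sim_dataset` built with `snapshots = TRUE`.
#' @param node Node label or `pre:<wgd-label>` key.
#' @return A locus tibble (with `lineage` and `home_chr` carried along).
#' @export
snapshot_as_locus_table <- function(dataset, node) {
  snap <- dataset$snapshots[[node]]
  if (is.null(snap)) stop("no snapshot for '", node, "'", call. = FALSE)
  out <- as_locus_table(tibble::tibble(
    species = node, locus_id = paste(node, snap$lineage, sep = "@"),
    family = snap$family, subtype = "unassigned",
    chromosome = snap$chromosome, start = snap$pos, end = snap$pos + 1,
    strand = snap$strand %||% "+",
    has_introns = snap$has_introns %||% TRUE))
  out$lineage <- snap$lineage
  out$home_chr <- snap$home_chr %||% snap$chromosome
  out
}

#' Ground-truth ortholog pairs between a species and a snapshot genome
#'
#' Pairs extant loci of `species` with snapshot loci carrying the same
#' lineage id (the lineage has seen no duplication between the snapshot
#' point and the tip).
#'
#' @inheritParams snapshot_as_locus_table
#' @param species An extant species name.
#' @return A tibble in the format of [map_orthologs()].
#' @export
truth_orthologs_to_snapshot <- function(dataset, species, node) {
  snap <- snapshot_as_locus_table(dataset, node)
  der <- dataset$locus_table[dataset$locus_table$species == species, ]
  m <- dplyr::inner_join(
    dplyr::select(der, family = "family", locus_a = "locus_id",
                  lineage = "lineage"),
    dplyr::select(snap, locus_b = "locus_id", lineage = "lineage"),
    by = "lineage")
  tibble::tibble(family = m$family, species_a = species, locus_a = m$locus_a,
                 species_b = node, locus_b = m$locus_b)
}
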