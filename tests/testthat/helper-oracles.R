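# Brute-force oracles and small fixture builders shared across tests.

fixture_path <- function(name) {
  system.file("extdata", name, package = "paralogon", mustWork = TRUE)
}

table1 <- function() read_locus_table(fixture_path("table1_visual_opsins.tsv"))

# --- random instances -------------------------------------------------------

# species tree on k species, no WGDs unless asked
toy_species_tree <- function(k = 5, wgd = NULL) {
  sp <- letters[seq_len(k)]
  phy <- ape::read.tree(text = paste0(
    "(", sp[1], ",(", sp[2], ",(", sp[3],
    if (k >= 4) paste0(",(", sp[4], if (k >= 5) paste0(",", sp[5]), ")N4"),
    ")N3)N2)N1;"))
  species_tree(phy, wgd)
}

# random gene tree: n tips, species drawn (seeded) from the species tree
random_gene_tree <- function(n, stree, seed) {
  set.seed(seed)
  phy <- ape::rtree(n, rooted = TRUE, br = NULL)
  sp <- sample(stree$phy$tip.label, n, replace = TRUE)
  phy$tip.label <- paste0(sp, "|", sp, "@g", seq_len(n))
  phy$node.label <- NULL
  phy
}

# --- reconciliation oracles -------------------------------------------------

# smallest species clade containing every species below each gene node
bf_lca <- function(gtree, stree) {
  sphy <- stree$phy
  n_all <- ape::Ntip(gtree) + gtree$Nnode
  clade_sets <- lapply(seq_len(ape::Ntip(sphy) + sphy$Nnode), function(v) {
    sphy$tip.label[paralogon:::tips_below(sphy, v)]
  })
  sizes <- lengths(clade_sets)
  vapply(seq_len(n_all), function(v) {
    tipset <- unique(sub("\\|.*$", "", gtree$tip.label[
      paralogon:::tips_below(gtree, v)]))
    cand <- which(vapply(clade_sets, function(s) all(tipset %in% s),
                         logical(1)))
    cand[which.min(sizes[cand])]
  }, integer(1))
}

# duplication iff the species sets of two children overlap in clade terms:
# independent route via explicit tip-set containment of the mapped clades
bf_dups <- function(gtree, stree) {
  map <- bf_lca(gtree, stree)
  sphy <- stree$phy
  clade_sets <- lapply(seq_len(ape::Ntip(sphy) + sphy$Nnode), function(v) {
    sphy$tip.label[paralogon:::tips_below(sphy, v)]
  })
  kids <- paralogon:::children_list(gtree)
  internal <- (ape::Ntip(gtree) + 1L):(ape::Ntip(gtree) + gtree$Nnode)
  internal[vapply(internal, function(v) {
    ms <- map[kids[[v]]]
    for (i in seq_along(ms)[-1]) {
      for (j in seq_len(i - 1)) {
        a <- clade_sets[[ms[i]]]; b <- clade_sets[[ms[j]]]
        if (all(a %in% b) || all(b %in% a)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))]
}

# ortholog pairs by exhaustive tip-pair join check (ape::getMRCA route)
bf_orthologs <- function(gtree, dup_nodes) {
  info <- paralogon:::gene_tip_info(gtree)
  out <- list()
  for (i in seq_len(nrow(info) - 1)) {
    for (j in (i + 1):nrow(info)) {
      if (info$species[i] == info$species[j]) next
      join <- ape::getMRCA(gtree, c(info$tip[i], info$tip[j]))
      if (!(join %in% dup_nodes)) {
        out[[length(out) + 1]] <- sort(c(info$locus_id[i], info$locus_id[j]))
      }
    }
  }
  out
}

# --- Dollo loss placement oracle -------------------------------------------

# minimal sets of branches (edges above the returned node) covering all
# reliable absences without covering any survivor; returns list(size, count,
# sets)
bf_loss_cover <- function(stree, origin_label, survivors, unreliable = NULL) {
  phy <- stree$phy
  o <- paralogon:::node_by_label(phy, origin_label)
  clade <- paralogon:::tips_below(phy, o)
  clade_sp <- phy$tip.label[clade]
  reliable_absent <- setdiff(setdiff(clade_sp, survivors), unreliable)
  if (!length(reliable_absent)) return(list(size = 0L, count = 1L))
  # candidate branches: all nodes strictly below origin
  below <- setdiff(which(vapply(
    seq_len(ape::Ntip(phy) + phy$Nnode),
    function(v) paralogon:::is_ancestor(stree$paths, o, v), logical(1))), o)
  ok <- vapply(below, function(v) {
    tips <- phy$tip.label[paralogon:::tips_below(phy, v)]
    !any(tips %in% survivors)
  }, logical(1))
  cand <- below[ok]
  best <- Inf; count <- 0L
  for (k in seq_len(length(cand))) {
    if (k > best) break
    combos <- utils::combn(cand, k, simplify = FALSE)
    for (cs in combos) {
      covered <- unique(unlist(lapply(cs, function(v)
        phy$tip.label[paralogon:::tips_below(phy, v)])))
      if (all(reliable_absent %in% covered)) {
        if (k < best) { best <- k; count <- 1L }
        else if (k == best) count <- count + 1L
      }
    }
    if (is.finite(best)) break
  }
  list(size = as.integer(best), count = count)
}

# --- misc -------------------------------------------------------------------

# exhaustive minimal-total-distance matching between two locus sets
bf_min_matching <- function(a_starts, b_starts, max_gap) {
  na <- length(a_starts); nb <- length(b_starts)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(nb))) {
    pairs <- list(); cost <- 0
    for (i in seq_len(min(na, nb))) {
      d <- abs(a_starts[i] - b_starts[p[i]])
      if (d <= max_gap) { pairs[[length(pairs) + 1]] <- c(i, p[i]); cost <- cost + d }
    }
    # prefer maximal pairings, then minimal cost
    score <- -length(pairs) * 1e15 + cost
    if (score < best_cost) { best_cost <- score; best <- pairs }
  }
  best
}

quiet_date <- function(...) suppressWarnings(date_duplications(...))
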