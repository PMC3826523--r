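#' Map gene-tree nodes onto the species tree (LCA reconciliation)
#'
#' Each gene-tree node is mapped to the most recent species-tree node
#' ancestral to every species represented below it. The mapping of a node is
#' always an ancestor-or-equal of the mapping of each of its children.
#'
#' @param gtree A rooted gene tree (`phylo`, tips `species|locus_id`).
#' @param stree A [species_tree].
#' @return A tibble `node` (gene-tree node id), `species_node` (species-tree
#'   node id), `species_label`.
#' @export
lca_map <- function(gtree, stree) {
  stopifnot(inherits(gtree, "phylo"), inherits(stree, "species_tree"))
  tips <- gene_tip_info(gtree)
  sp_idx <- match(tips$species, stree$phy$tip.label)
  if (anyNA(sp_idx)) {
    stop("gene-tree tip(s) with species unknown to the species tree: ",
         paste(tips$label[is.na(sp_idx)], collapse = ", "), call. = FALSE)
  }
  n_all <- ape::Ntip(gtree) + gtree$Nnode
  kids <- children_list(gtree)
  gpaths <- tree_paths(gtree)
  map <- integer(n_all)
  map[tips$tip] <- sp_idx
  ord <- order(vapply(gpaths, length, 1L), decreasing = TRUE) # postorder
  for (v in ord) {
    if (v <= ape::Ntip(gtree)) next
    ms <- map[kids[[v]]]
    m <- ms[1]
    for (x in ms[-1]) m <- path_mrca(stree$paths, m, x)
    map[v] <- m
  }
  out <- tibble::tibble(node = seq_len(n_all), species_node = map,
                        species_label = stree$labels[map])
  attr(out, "stree_paths") <- stree$paths
  out
}

#' Flag duplication nodes of a reconciled gene tree
#'
#' An internal node is a duplication when two of its children map to species
#' nodes lying on one root-to-tip path (ancestor-or-equal of each other); for
#' binary nodes this is the classic criterion that the node maps to the same
#' species node as one of its children. The rule extends unchanged to
#' polytomies.
#'
#' @inheritParams lca_map
#' @param mapping Output of [lca_map()].
#' @return Integer vector of duplication node ids.
#' @export
annotate_duplications <- function(gtree, mapping) {
  paths <- attr(mapping, "stree_paths")
  if (is.null(paths)) stop("mapping must come from lca_map()", call. = FALSE)
  kids <- children_list(gtree)
  map <- mapping$species_node[order(mapping$node)]
  internal <- (ape::Ntip(gtree) + 1L):(ape::Ntip(gtree) + gtree$Nnode)
  dup <- vapply(internal, function(v) {
    ms <- map[kids[[v]]]
    for (i in seq_along(ms)[-1]) {
      for (j in seq_len(i - 1)) {
        a <- ms[i]; b <- ms[j]
        if (is_ancestor(paths, a, b) || is_ancestor(paths, b, a)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  internal[dup]
}

find_duplications <- function(gtree, map, stree) {
  mapping <- tibble::tibble(node = seq_along(map), species_node = map)
  attr(mapping, "stree_paths") <- stree$paths
  annotate_duplications(gtree, mapping)
}

# base window of a WGD label: "2R-1" -> "2R"
wgd_window <- function(label) sub("-[0-9]+$", "", label)

# root-most WGD node id of a species tree (NA when no WGD placed)
first_wgd_node <- function(stree) {
  if (!nrow(stree$wgd)) return(NA_integer_)
  ids <- unique(stree$wgd$node_id)
  ids[which.min(stree$depths[ids])]
}

#' Classify duplications into WGD time-windows
#'
#' The species-tree branch a duplication reconciles to determines its
#' time-window label: a branch carrying 2R placements gives `"2R"`, the 3R
#' branch gives `"3R"`, the internal branch(es) between them give
#' `"between-2R-3R"`, branches above the first WGD give `"pre-window"`
#' (or `"unresolved"` when the species tree offers no outgroup above the
#' window), terminal branches of post-3R taxa give `"post-3R-local"`, and all
#' other branches give `"lineage-local"`.
#'
#' @inheritParams annotate_duplications
#' @param nodes Integer duplication node ids (from [annotate_duplications()]).
#' @param stree A [species_tree].
#' @return A tibble `node, species_node, species_label, window`.
#' @export
classify_window <- function(nodes, mapping, stree) {
  map <- mapping$species_node[order(mapping$node)]
  w1 <- first_wgd_node(stree)
  has_outgroup_context <- !is.na(w1) &&
    length(setdiff(seq_len(ape::Ntip(stree$phy)), tips_below(stree$phy, w1))) > 0
  wgd_ids <- unique(stree$wgd$node_id)
  window_of <- function(b) {
    paste(sort(unique(wgd_window(wgd_on_branch(stree, b)))), collapse = "+")
  }
  classify_one <- function(n) {
    if (is.na(w1)) return("lineage-local")
    if (n %in% wgd_ids) return(window_of(n))
    if (is_ancestor(stree$paths, n, w1) && n != w1) {
      return(if (has_outgroup_context) "pre-window" else "unresolved")
    }
    wgd_above <- wgd_ids[vapply(wgd_ids, function(w)
      is_ancestor(stree$paths, w, n) && w != n, logical(1))]
    wgd_below <- wgd_ids[vapply(wgd_ids, function(w)
      is_ancestor(stree$paths, n, w) && w != n, logical(1))]
    if (n > ape::Ntip(stree$phy)) {
      if (length(wgd_above) && length(wgd_below)) {
        up <- wgd_above[which.max(stree$depths[wgd_above])]
        down <- wgd_below[which.min(stree$depths[wgd_below])]
        return(paste0("between-", window_of(up), "-", window_of(down)))
      }
      return("lineage-local")
    }
    # terminal branch: post-WGD-local when the tip lies below a WGD that is
    # not the root-most one (every taxon in scope is post-2R; only the later
    # rounds single out a taxon subset)
    if (length(wgd_above)) {
      low <- wgd_above[which.max(stree$depths[wgd_above])]
      if (low != w1) return(paste0("post-", window_of(low), "-local"))
    }
    "lineage-local"
  }
  sp <- map[nodes]
  tibble::tibble(node = nodes, species_node = sp,
                 species_label = stree$labels[sp],
                 window = vapply(sp, classify_one, character(1)))
}

#' Date all duplications of a gene tree
#'
#' Runs the full per-family dating pipeline: optional collapse of weakly
#' supported nodes into polytomies, LCA mapping, duplication flagging, branch
#' classification ([classify_window()]), and two conservatism rules:
#'
#' * *window capacity*: a branch carrying k WGDs can explain at most k nested
#'   duplications of one gene lineage. Deeper surviving chains have their
#'   uppermost nodes relabelled `"pre-window"` on the first WGD branch
#'   (tandem duplications preceding the window, the classic explanation for
#'   a fifth family member where a quadruplication allows four) and
#'   `"unresolved"` on later WGD branches (before/after cannot be told).
#' * *synteny guard* (when `loci` is supplied): a duplication mapped to a
#'   branch with no WGD keeps its local/lineage label only when its copies
#'   look like a local event: some species carries copies from both sides on
#'   one chromosome within `local_gap`, or the two sides contrast in intron
#'   presence (a retrotransposition signature). Otherwise the node is
#'   `"unresolved"` - it may be a WGD duplication displaced downward by gene
#'   losses, and calling its branch would date it to the wrong window.
#'
#' @inheritParams lca_map
#' @param loci Optional locus tibble used by the synteny guard.
#' @param collapse_below Optional support threshold; internal nodes with
#'   support below it are collapsed into polytomies before dating.
#' @param local_gap Distance (bp) within which same-chromosome copies count
#'   as local. Default 1 Mb.
#' @return An object of class `dup_calls`: a tibble
#'   `node, species_node, species_label, window, rule` with the (possibly
#'   collapsed) gene tree, mapping and tip species in attributes.
#' @export
date_duplications <- function(gtree, stree, loci = NULL, collapse_below = NULL,
                              local_gap = 1e6) {
  if (!is.null(collapse_below)) {
    gtree <- collapse_low_support(gtree, collapse_below)
  }
  mapping <- lca_map(gtree, stree)
  map <- mapping$species_node
  dups <- find_duplications(gtree, map, stree)
  calls <- classify_window(dups, mapping, stree)
  calls$rule <- rep("branch", nrow(calls))

  # window capacity: k WGD rounds turn one gene into at most 2^k lineages.
  # A duplication on the WGD branch whose subtree leaves more than 2^k
  # lineages at the end of the branch cannot itself belong to the window:
  # on the first WGD branch it is relabelled "pre-window" (a tandem
  # duplication preceding the window, the classic reading of a fifth family
  # member where a quadruplication allows four); on later WGD branches the
  # before/after order is undecidable and it becomes "unresolved".
  w1 <- first_wgd_node(stree)
  kids <- children_list(gtree)
  gpaths <- tree_paths(gtree)
  postorder <- order(vapply(gpaths, length, 1L), decreasing = TRUE)
  for (b in unique(stree$wgd$node_id)) {
    k <- length(wgd_on_branch(stree, b))
    on_b <- calls$node[calls$species_node == b]
    if (!length(on_b)) next
    n_exit <- rep(1, ape::Ntip(gtree) + gtree$Nnode)
    for (v in postorder) {
      if (v <= ape::Ntip(gtree)) next
      n_exit[v] <- if (v %in% on_b) sum(n_exit[kids[[v]]]) else 1
    }
    over <- on_b[n_exit[on_b] > 2^k]
    relabel <- if (identical(b, w1)) "pre-window" else "unresolved"
    calls$window[calls$node %in% over] <- relabel
    calls$rule[calls$node %in% over] <- "capacity"
  }

  # synteny guard
  if (!is.null(loci)) {
    loci <- as_locus_table(loci)
    tips <- gene_tip_info(gtree)
    guarded <- grepl("^(lineage-local|post-.*-local|between-)", calls$window)
    for (i in which(guarded)) {
      v <- calls$node[i]
      sides <- lapply(kids[[v]], function(c) {
        tl <- tips[tips$tip %in% tips_below(gtree, c), ]
        dplyr::inner_join(tl, loci, by = c("species", "locus_id"))
      })
      ok <- FALSE
      seen_pair <- FALSE
      for (a in seq_along(sides)[-1]) {
        for (b2 in seq_len(a - 1)) {
          A <- sides[[a]]; B <- sides[[b2]]
          shared <- intersect(A$species, B$species)
          for (s in shared) {
            As <- A[A$species == s, ]; Bs <- B[B$species == s, ]
            seen_pair <- TRUE
            same_chr <- outer(As$chromosome, Bs$chromosome, "==")
            dist <- abs(outer(As$start, Bs$start, "-"))
            if (any(same_chr & dist <= local_gap)) ok <- TRUE
            if (any(outer(As$has_introns, Bs$has_introns, "!="))) ok <- TRUE
          }
        }
      }
      if (!ok) {
        calls$window[i] <- "unresolved"
        calls$rule[i] <- "guard"
      }
    }
  }

  structure(calls,
            class = c("dup_calls", class(calls)),
            gtree = gtree, mapping = mapping,
            tip_species = unique(gene_tip_info(gtree)$species))
}

#' Collapse weakly supported gene-tree nodes into polytomies
#'
#' Internal node labels are read as support values; non-root internal nodes
#' with support below `threshold` are contracted. Nodes without a numeric
#' support value are kept.
#'
#' @inheritParams lca_map
#' @param threshold Support threshold (same scale as the stored values,
#'   e.g. bootstrap percent).
#' @return A `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(gtree, threshold) {
  ntip <- ape::Ntip(gtree)
  support <- suppressWarnings(as.numeric(gtree$node.label %||%
                                           rep(NA, gtree$Nnode)))
  drop <- which(!is.na(support) & support < threshold) + ntip
  drop <- setdiff(drop, ntip + 1L) # never the root
  if (!length(drop)) return(gtree)
  parent <- tree_parents(gtree)
  keep_parent <- function(v) {
    p <- parent[v]
    while (p %in% drop) p <- parent[p]
    p
  }
  nodes <- tibble::tibble(
    id = as.character(seq_len(ntip + gtree$Nnode)),
    parent = ifelse(seq_len(ntip + gtree$Nnode) == ntip + 1L, NA_character_,
                    as.character(vapply(seq_len(ntip + gtree$Nnode),
                                        keep_parent, 1L))),
    tip = seq_len(ntip + gtree$Nnode) <= ntip,
    label = c(gtree$tip.label,
              gtree$node.label %||% rep("", gtree$Nnode)),
    time = as.numeric(node_depths(gtree)))
  nodes <- nodes[!(seq_len(nrow(nodes)) %in% drop), ]
  phylo_from_table(nodes)$phy
}

#' Per-family verdict over several input trees
#'
#' A family's tree is 2R-consistent when it contains at least one duplication
#' dated to the 2R window (analogously 3R-consistent). With several input
#' trees per family (e.g. from different inference methods) the aggregate is
#' `"supported-by-all"` when every tree is 2R-consistent, `"supported-by-one"`
#' when some but not all are, else `"inconclusive"`. `undated` marks families
#' that look 2R-consistent but contain no species diverging before the 2R
#' window, so the relative dating lacks its outgroup anchor.
#'
#' @param calls A list of `dup_calls` objects (one per input tree) for one
#'   family.
#' @param stree A [species_tree].
#' @param window Window label counting as support. Default `"2R"`.
#' @return A one-row tibble `n_trees, verdicts (list), aggregate, undated`.
#' @export
family_verdict <- function(calls, stree, window = "2R") {
  if (!length(calls)) stop("need at least one input tree per family",
                           call. = FALSE)
  per_tree <- vapply(calls, function(cl) {
    has_w <- any(cl$window == window)
    has_3r <- any(cl$window == "3R")
    if (has_w && has_3r) "both"
    else if (has_w) "2R-consistent"
    else if (has_3r) "3R-consistent"
    else "inconclusive"
  }, character(1))
  supp <- per_tree %in% c("2R-consistent", "both")
  aggregate <- if (all(supp)) "supported-by-all"
  else if (any(supp)) "supported-by-one"
  else "inconclusive"
  w1 <- first_wgd_node(stree)
  outgroup_sp <- stree$phy$tip.label[setdiff(seq_len(ape::Ntip(stree$phy)),
                                             tips_below(stree$phy, w1))]
  has_outgroup <- any(vapply(calls, function(cl) {
    any(attr(cl, "tip_species") %in% outgroup_sp)
  }, logical(1)))
  tibble::tibble(n_trees = length(calls), verdicts = list(per_tree),
                 aggregate = aggregate,
                 undated = aggregate != "inconclusive" && !has_outgroup)
}
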