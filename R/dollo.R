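#' Cut dated gene trees into subtype lineages
#'
#' Cutting each gene tree at its dated (non-`"unresolved"`) duplication nodes
#' partitions the extant loci into lineages: every locus belongs to the
#' lineage of (its nearest resolved duplication ancestor, the child branch it
#' descends through), or to the family's root lineage when no duplication
#' lies above it. Loci whose path crosses an unresolved duplication below the
#' cut are flagged.
#'
#' @param calls Named list of `dup_calls` (one per family).
#' @param gtrees Named list of gene trees matching `calls`.
#' @param table Locus tibble (used for subtype labels).
#' @return A `lineage_set` tibble `lineage_id, family, subtype, origin_node,
#'   origin_window, n_loci, species, loci, flagged`, with `calls`/`gtrees`
#'   kept in attributes for downstream content computation.
#' @export
build_lineages <- function(calls, gtrees, table) {
  tbl <- as_locus_table(table)
  out <- list()
  for (fam in sort(names(gtrees))) {
    gtree <- gtrees[[fam]]
    cl <- calls[[fam]]
    if (is.null(cl)) next
    gtree_used <- attr(cl, "gtree") %||% gtree
    tips <- gene_tip_info(gtree_used)
    parent <- tree_parents(gtree_used)
    resolved <- cl$node[cl$window != "unresolved"]
    unresolved <- cl$node[cl$window == "unresolved"]
    key <- character(nrow(tips))
    flagged <- logical(nrow(tips))
    for (i in seq_len(nrow(tips))) {
      v <- tips$tip[i]
      child <- v
      p <- parent[v]
      while (p != 0 && !(p %in% resolved)) {
        if (p %in% unresolved) flagged[i] <- TRUE
        child <- p
        p <- parent[p]
      }
      key[i] <- if (p == 0) "root" else paste0(p, ".", child)
    }
    mapping <- attr(cl, "mapping")
    win_of <- stats::setNames(cl$window, cl$node)
    lab_of <- stats::setNames(cl$species_label, cl$node)
    groups <- split(seq_len(nrow(tips)), key)
    idx <- 0
    for (k in sort(names(groups))) {
      idx <- idx + 1
      g <- groups[[k]]
      dup <- if (k == "root") NA_integer_ else
        as.integer(sub("\\..*$", "", k))
      # the lineage's whole gene-tree segment: where it later continues as
      # daughter lineages (below further duplications) the gene did not
      # disappear, so those species must not read as losses
      seg_top <- if (k == "root") ape::Ntip(gtree_used) + 1L else
        as.integer(sub("^.*\\.", "", k))
      seg_species <- sort(unique(
        sub("\\|.*$", "", gtree_used$tip.label[tips_below(gtree_used,
                                                          seg_top)])))
      st <- tbl$subtype[match(tips$locus_id[g], tbl$locus_id)]
      st <- st[!is.na(st)]
      subtype <- if (length(st)) names(sort(table(st),
                                            decreasing = TRUE))[1]
      else "unassigned"
      origin_node <- if (is.na(dup)) {
        mapping$species_label[mapping$node ==
                                ape::Ntip(gtree_used) + 1L]
      } else unname(lab_of[as.character(dup)])
      origin_window <- if (is.na(dup)) "root" else
        unname(win_of[as.character(dup)])
      out[[length(out) + 1]] <- tibble::tibble(
        lineage_id = sprintf("%s.%02d", fam, idx), family = fam,
        subtype = subtype, origin_node = origin_node,
        origin_window = origin_window, n_loci = length(g),
        species = list(sort(unique(tips$species[g]))),
        segment_species = list(seg_species),
        loci = list(sort(tips$locus_id[g])),
        flagged = any(flagged[g]))
    }
  }
  res <- dplyr::bind_rows(out)
  structure(res, class = c("lineage_set", class(res)),
            calls = calls, gtrees = gtrees)
}

# Count gene lineages crossing a time point in one dated gene tree.
# point: list(node = species node id, phase = "at" or "pre-wgd").
# "at": just at the species node (after all branch events);
# "pre-wgd": on the branch ending at `node`, before its first WGD (i.e.
# after any duplications relabelled "pre-window", before the in-window ones).
crossing_count <- function(cl, stree, point) {
  gtree <- attr(cl, "gtree")
  mapping <- attr(cl, "mapping")
  map <- mapping$species_node[order(mapping$node)]
  win_of <- stats::setNames(cl$window, cl$node)
  n <- point$node
  is_dup <- function(v) v %in% cl$node
  before <- function(v) {
    m <- map[v]
    if (m == n) {
      if (!is_dup(v)) return(FALSE)
      if (point$phase == "at") return(TRUE)
      return(identical(unname(win_of[as.character(v)]), "pre-window"))
    }
    is_ancestor(stree$paths, m, n) # strict ancestor
  }
  at_or_after <- function(v) {
    m <- map[v]
    if (m == n) return(!before(v))
    is_ancestor(stree$paths, n, m)
  }
  total <- 0L
  root <- ape::Ntip(gtree) + 1L
  parent <- tree_parents(gtree)
  for (v in seq_len(ape::Ntip(gtree) + gtree$Nnode)) {
    p <- parent[v]
    if (p == 0) next
    if (before(p) && at_or_after(v)) total <- total + 1L
  }
  if (map[root] == n && at_or_after(root)) total <- total + 1L
  total
}

#' Dollo reconstruction of ancestral gene content
#'
#' Under the single-origin (Dollo) assumption each lineage arises once, at
#' its dated duplication, and can only be lost. Presence at a species-tree
#' node follows from the gene-tree edges crossing that node; losses are
#' placed on the minimal branch set covering all reliable absences: one loss
#' atop each maximal extinct subtree. When assembly-unreliable species are
#' excluded, several equally parsimonious placements can exist along the path
#' from the top of the maximal absent clade down to the MRCA of the reliably
#' absent tips; the topmost edge is reported with the tie count in
#' `n_alternatives`.
#'
#' @param lineages A `lineage_set` from [build_lineages()].
#' @param stree A [species_tree].
#' @param unreliable Character vector of species whose absences may be
#'   assembly artifacts; they never force a loss.
#' @return A `dollo_recon` list: `content` (tibble `node, family, n` over all
#'   species-tree nodes), `losses` (tibble `lineage_id, family, subtype,
#'   branch, n_alternatives`), `lineages`.
#' @export
dollo_reconstruct <- function(lineages, stree, unreliable = character()) {
  stopifnot(inherits(lineages, "lineage_set"))
  calls <- attr(lineages, "calls")
  losses <- dollo_losses(lineages, stree, unreliable)

  # content at every species-tree node by edge crossing
  fams <- sort(unique(lineages$family))
  nodes <- stree$labels[stree$labels != ""]
  content <- tidyr::expand_grid(node = nodes, family = fams)
  content$n <- vapply(seq_len(nrow(content)), function(r) {
    cl <- calls[[content$family[r]]]
    crossing_count(cl, stree,
                   list(node = node_by_label(stree$phy, content$node[r]),
                        phase = "at"))
  }, integer(1))

  structure(list(content = content, losses = losses, lineages = lineages,
                 species_tree = stree, unreliable = unreliable),
            class = "dollo_recon")
}

#' Minimal Dollo loss placements for a lineage set
#'
#' The loss component of [dollo_reconstruct()], usable on its own: one loss
#' atop each maximal extinct subtree within the origin clade, with
#' `n_alternatives` counting the equally parsimonious placements opened up by
#' excluded (`unreliable`) species.
#'
#' @inheritParams dollo_reconstruct
#' @return The losses tibble (see [dollo_reconstruct()]).
#' @export
dollo_losses <- function(lineages, stree, unreliable = character()) {
  phy <- stree$phy
  ntip <- ape::Ntip(phy)
  kids <- children_list(phy)

  losses <- list()
  for (i in seq_len(nrow(lineages))) {
    o <- node_by_label(phy, lineages$origin_node[i])
    members <- lineages$species[[i]]
    clade_sp <- stree$labels[tips_below(phy, o)]
    if (!all(members %in% clade_sp)) {
      stop("lineage ", lineages$lineage_id[i], " present outside the clade ",
           "of its origin node ", lineages$origin_node[i],
           " (violates single origin)", call. = FALSE)
    }
    # species where the lineage or a daughter lineage survives: only truly
    # empty branches count as losses
    survivors <- if ("segment_species" %in% names(lineages)) {
      lineages$segment_species[[i]]
    } else members
    reliable_absent <- setdiff(setdiff(clade_sp, survivors), unreliable)
    if (!length(reliable_absent)) next
    # maximal subtrees below o without survivors, holding >=1 reliable absence
    walk <- function(v) {
      tipset <- stree$labels[tips_below(phy, v)]
      if (any(tipset %in% survivors)) {
        if (v <= ntip) return(invisible())
        for (ch in kids[[v]]) walk(ch)
        return(invisible())
      }
      rel <- intersect(tipset, reliable_absent)
      if (!length(rel)) return(invisible())
      rel_id <- match(rel, phy$tip.label)
      m <- rel_id[1]
      for (x in rel_id[-1]) m <- path_mrca(stree$paths, m, x)
      n_alt <- stree$depths[m] - stree$depths[v] + 1L
      losses[[length(losses) + 1]] <<- tibble::tibble(
        lineage_id = lineages$lineage_id[i],
        family = lineages$family[i], subtype = lineages$subtype[i],
        branch = stree$labels[v], n_alternatives = as.integer(n_alt))
    }
    for (ch in kids[[o]]) {
      if (o <= ntip) break
      walk(ch)
    }
  }
  if (length(losses)) dplyr::bind_rows(losses) else {
    tibble::tibble(lineage_id = character(), family = character(),
                   subtype = character(), branch = character(),
                   n_alternatives = integer())
  }
}

#' @export
print.dollo_recon <- function(x, ...) {
  cat("Dollo reconstruction:", nrow(x$lineages), "lineages,",
      nrow(x$losses), "loss placements\n")
  invisible(x)
}

#' Gene repertoire just before a WGD
#'
#' Counts, per family, the gene lineages present on the WGD-carrying branch
#' immediately before the named WGD event (duplications dated
#' `"pre-window"` count as earlier; in-window duplications as later). This
#' is the ancestral chromosome content the WGD then multiplied.
#'
#' @inheritParams dollo_reconstruct
#' @param wgd_label Label of the WGD (e.g. `"2R-1"` for the point before the
#'   first vertebrate tetraploidization).
#' @return A tibble `family, n`.
#' @export
repertoire_before_wgd <- function(lineages, stree, wgd_label = "2R-1") {
  stopifnot(inherits(lineages, "lineage_set"))
  calls <- attr(lineages, "calls")
  b <- stree$wgd$node_id[stree$wgd$label == wgd_label]
  if (!length(b)) stop("no WGD labelled '", wgd_label,
                       "' on the species tree", call. = FALSE)
  fams <- sort(unique(lineages$family))
  tibble::tibble(
    family = fams,
    n = vapply(fams, function(f) {
      crossing_count(calls[[f]], stree, list(node = b, phase = "pre-wgd"))
    }, integer(1)))
}

#' Repertoire table at selected ancestors
#'
#' Tabulates reconstructed lineage counts per family at the requested
#' species-tree nodes; `pre:<wgd-label>` keys address the point on a branch
#' just before that WGD (e.g. `pre:2R-1`, the pre-2R vertebrate ancestor).
#'
#' @param recon A `dollo_recon` from [dollo_reconstruct()].
#' @param nodes Character vector of node labels and/or `pre:<wgd-label>`
#'   keys.
#' @return A wide tibble, one row per family, one column per requested node.
#' @export
scenario_summary <- function(recon, nodes) {
  stopifnot(inherits(recon, "dollo_recon"))
  stree <- recon$species_tree
  cols <- list()
  fams <- sort(unique(recon$lineages$family))
  for (nd in nodes) {
    if (startsWith(nd, "pre:")) {
      lab <- sub("^pre:", "", nd)
      rep <- repertoire_before_wgd(recon$lineages, stree, wgd_label = lab)
      cols[[nd]] <- rep$n[match(fams, rep$family)]
    } else {
      if (!(nd %in% recon$content$node)) {
        stop("unknown node: ", nd, call. = FALSE)
      }
      sub <- recon$content[recon$content$node == nd, ]
      cols[[nd]] <- sub$n[match(fams, sub$family)]
    }
  }
  dplyr::bind_cols(tibble::tibble(family = fams), tibble::as_tibble(cols))
}
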