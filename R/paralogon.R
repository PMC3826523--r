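# Assign loci of one species to blocks by interval overlap (half-open)
assign_loci_to_blocks <- function(blocks, table) {
  tbl <- as_locus_table(table)
  joined <- dplyr::inner_join(
    tbl, dplyr::select(blocks, "block_id", "species", "chromosome",
                       bstart = "start", bend = "end"),
    by = c("species", "chromosome"), relationship = "many-to-many")
  dplyr::select(
    dplyr::filter(joined, .data$start < .data$bend, .data$end > .data$bstart),
    "locus_id", "family", "block_id")
}

#' Build the weighted paralogy graph over chromosome blocks
#'
#' Nodes are the chromosome blocks of one species. The edge between two
#' blocks is weighted by the number of selected families that contribute a
#' paralog pair spanning the two blocks whose gene-tree join node is dated to
#' `window` (`"2R"` for the vertebrate paralogon; `"3R"` for within-teleost
#' graphs).
#'
#' @param blocks A block tibble (one species) from [define_blocks()].
#' @param families Character vector of selected family names.
#' @param gtrees Named list of gene trees (names = families).
#' @param calls Named list of `dup_calls` matching `gtrees`.
#' @param table Locus tibble.
#' @param window Window label an edge-supporting join must carry.
#' @return An `igraph` with vertex attribute `name` (block ids) and edge
#'   attributes `weight` and `families`.
#' @export
build_paralogy_graph <- function(blocks, families, gtrees, calls, table,
                                 window = "2R") {
  assign <- assign_loci_to_blocks(blocks, table)
  tbl <- as_locus_table(table)
  sp <- unique(blocks$species)
  stopifnot(length(sp) == 1)
  edges <- list()
  for (fam in sort(unique(families))) {
    gtree <- gtrees[[fam]]
    cl <- calls[[fam]]
    if (is.null(gtree) || is.null(cl)) {
      warning("no gene tree/calls for family ", fam, "; skipped",
              call. = FALSE)
      next
    }
    fam_assign <- assign[assign$family == fam, ]
    if (dplyr::n_distinct(fam_assign$block_id) < 2) next
    tips <- gene_tip_info(gtree)
    tips <- tips[tips$species == sp & tips$locus_id %in% fam_assign$locus_id, ]
    if (nrow(tips) < 2) next
    tips$block_id <- fam_assign$block_id[match(tips$locus_id,
                                               fam_assign$locus_id)]
    gpaths <- tree_paths(gtree)
    win_of <- stats::setNames(cl$window, cl$node)
    seen <- character(0)
    for (i in seq_len(nrow(tips) - 1)) {
      for (j in (i + 1):nrow(tips)) {
        b1 <- tips$block_id[i]; b2 <- tips$block_id[j]
        if (b1 == b2) next
        join <- path_mrca(gpaths, tips$tip[i], tips$tip[j])
        w <- win_of[as.character(join)]
        if (!is.na(w) && w == window) {
          key <- paste(sort(c(b1, b2)), collapse = "~")
          seen <- union(seen, key)
        }
      }
    }
    for (key in seen) {
      edges[[length(edges) + 1]] <- tibble::tibble(
        pair = key, family = fam)
    }
  }
  edf <- if (length(edges)) dplyr::bind_rows(edges) else {
    tibble::tibble(pair = character(), family = character())
  }
  agg <- dplyr::summarise(dplyr::group_by(edf, .data$pair),
                          weight = dplyr::n(),
                          families = paste(sort(.data$family),
                                           collapse = ","),
                          .groups = "drop")
  ends <- stringr::str_split_fixed(agg$pair, stringr::fixed("~"), 2)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = ends[, 1], to = ends[, 2],
                   weight = agg$weight, families = agg$families),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(blocks$block_id))))
  g
}

#' Assemble paralogons from the block graph
#'
#' Drops edges below `min_support` shared families and returns the connected
#' components, ordered (and numbered) by their smallest block id. The result
#' partitions the block set for every `min_support`; raising `min_support`
#' can only split groups.
#'
#' @param graph Output of [build_paralogy_graph()].
#' @param min_support Minimum shared-family count for an edge to count.
#' @return A `paralogon_groups` tibble `block_id, group` with the pruned
#'   graph in attribute `graph`.
#' @export
assemble_paralogons <- function(graph, min_support = 2) {
  stopifnot(min_support >= 1)
  pruned <- igraph::delete_edges(
    graph, igraph::E(graph)[igraph::E(graph)$weight < min_support])
  comp <- igraph::components(pruned)
  out <- tibble::tibble(block_id = igraph::V(pruned)$name,
                        comp = comp$membership)
  first <- dplyr::summarise(dplyr::group_by(out, .data$comp),
                            lead = min(.data$block_id), .groups = "drop")
  first <- dplyr::arrange(first, .data$lead)
  first$group <- seq_len(nrow(first))
  out <- dplyr::left_join(out, first, by = "comp")
  out <- dplyr::arrange(dplyr::select(out, "block_id", "group"),
                        .data$group, .data$block_id)
  structure(out, class = c("paralogon_groups", class(out)), graph = pruned,
            min_support = min_support)
}

#' Cross-species ortholog pairs from reconciled gene trees
#'
#' Two loci from different species are orthologs when their gene-tree join
#' node is a speciation (not flagged as a duplication). This replaces
#' similarity-based orthology prediction wherever reconciled trees exist.
#'
#' @inheritParams build_paralogy_graph
#' @return A tibble `family, species_a, locus_a, species_b, locus_b`
#'   (species pair ordered alphabetically).
#' @export
map_orthologs <- function(gtrees, calls) {
  out <- list()
  for (fam in sort(names(gtrees))) {
    gtree <- gtrees[[fam]]
    cl <- calls[[fam]]
    if (is.null(cl)) next
    tips <- gene_tip_info(gtree)
    if (dplyr::n_distinct(tips$species) < 2) next
    gpaths <- tree_paths(gtree)
    dup_nodes <- cl$node
    for (i in seq_len(nrow(tips) - 1)) {
      for (j in (i + 1):nrow(tips)) {
        if (tips$species[i] == tips$species[j]) next
        join <- path_mrca(gpaths, tips$tip[i], tips$tip[j])
        if (join %in% dup_nodes) next
        a <- i; b <- j
        if (tips$species[a] > tips$species[b]) { a <- j; b <- i }
        out[[length(out) + 1]] <- tibble::tibble(
          family = fam,
          species_a = tips$species[a], locus_a = tips$locus_id[a],
          species_b = tips$species[b], locus_b = tips$locus_id[b])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(family = character(), species_a = character(),
                          locus_a = character(), species_b = character(),
                          locus_b = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$family, .data$species_a,
                 .data$locus_a, .data$locus_b)
}

# orthologs of loci of one species in one outgroup species, as a lookup
# locus_id -> outgroup chromosome (modal over ortholog partners)
ortholog_chromosomes <- function(species, outgroup_species, ortholog_pairs,
                                 outgroup_table) {
  og <- as_locus_table(outgroup_table)
  p <- ortholog_pairs
  p1 <- p[p$species_a == species & p$species_b == outgroup_species,
          c("locus_a", "locus_b")]
  p2 <- p[p$species_b == species & p$species_a == outgroup_species,
          c("locus_b", "locus_a")]
  names(p2) <- c("locus_a", "locus_b")
  pairs <- dplyr::bind_rows(p1, p2)
  pairs$og_chr <- og$chromosome[match(pairs$locus_b, og$locus_id)]
  pairs <- pairs[!is.na(pairs$og_chr), ]
  modal <- dplyr::summarise(
    dplyr::group_by(pairs, .data$locus_a),
    og_chr = names(sort(table(.data$og_chr), decreasing = TRUE))[1],
    .groups = "drop")
  stats::setNames(modal$og_chr, modal$locus_a)
}

#' Merge fission products into ancestral units using an outgroup
#'
#' Two same-species blocks are merged into one ancestral unit when at least
#' `min_support` of their genes' orthologs co-locate on a single outgroup
#' chromosome (with at least one contributing gene per block). This is how a
#' lineage-specific linkage break is recognised: the paralogon keeps its raw
#' block count, but the ancestral unit count drops. Blocks without any
#' outgroup ortholog stay unmerged and are flagged.
#'
#' @param blocks Block tibble of one species.
#' @param table Locus tibble covering that species.
#' @param outgroup_table Locus tibble of the outgroup species.
#' @param ortholog_pairs Output of [map_orthologs()].
#' @param min_support Minimum co-locating ortholog count for a merge.
#' @return A tibble `block_id, unit, outgroup_chromosome, n_orthologs,
#'   flagged`.
#' @export
detect_fission <- function(blocks, table, outgroup_table, ortholog_pairs,
                           min_support = 2) {
  sp <- unique(blocks$species)
  stopifnot(length(sp) == 1)
  og_sp <- unique(as_locus_table(outgroup_table)$species)
  stopifnot(length(og_sp) == 1)
  og_of <- ortholog_chromosomes(sp, og_sp, ortholog_pairs, outgroup_table)
  assign <- assign_loci_to_blocks(blocks, table)
  assign$og_chr <- og_of[assign$locus_id]
  per_block <- split(assign, assign$block_id)
  counts <- lapply(per_block, function(a) table(a$og_chr[!is.na(a$og_chr)]))
  ids <- sort(unique(blocks$block_id))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  for (i in seq_along(ids)[-1]) {
    for (j in seq_len(i - 1)) {
      c1 <- counts[[ids[i]]]; c2 <- counts[[ids[j]]]
      shared <- intersect(names(c1), names(c2))
      for (chr in shared) {
        if (c1[[chr]] >= 1 && c2[[chr]] >= 1 &&
            c1[[chr]] + c2[[chr]] >= min_support) {
          g <- g + igraph::edges(c(ids[i], ids[j]))
          break
        }
      }
    }
  }
  comp <- igraph::components(g)
  out <- tibble::tibble(block_id = igraph::V(g)$name,
                        comp = comp$membership)
  first <- dplyr::summarise(dplyr::group_by(out, .data$comp),
                            lead = min(.data$block_id), .groups = "drop")
  first <- dplyr::arrange(first, .data$lead)
  first$unit <- paste0("U", seq_len(nrow(first)))
  out <- dplyr::left_join(out, first, by = "comp")
  out$outgroup_chromosome <- vapply(out$block_id, function(b) {
    cb <- counts[[b]]
    if (is.null(cb) || !length(cb)) NA_character_
    else names(sort(cb, decreasing = TRUE))[1]
  }, character(1))
  out$n_orthologs <- vapply(out$block_id, function(b) {
    cb <- counts[[b]]
    if (is.null(cb)) 0L else as.integer(sum(cb))
  }, integer(1))
  out$flagged <- out$n_orthologs == 0
  dplyr::arrange(dplyr::select(out, "block_id", "unit",
                               "outgroup_chromosome", "n_orthologs",
                               "flagged"),
                 .data$unit, .data$block_id)
}

#' Detect and time translocations against an outgroup
#'
#' For one derived species: each chromosome is assigned a "home" outgroup
#' chromosome by strict majority over its loci's ortholog locations (a tie
#' leaves the chromosome unresolved and uncalled). A maximal run of at least
#' `min_run` consecutive loci (by position, among loci with known orthologs)
#' whose orthologs co-locate on a single *different* outgroup chromosome is
#' called a translocation. When the species tree shows the outgroup diverged
#' before the last WGD and the derived species after it, the move is timed
#' `"post-3R"` (more generally `post-<window>`); otherwise `"unresolved"`.
#'
#' @param derived_table Locus tibble of one derived species.
#' @param outgroup_table Locus tibble of the outgroup (one species).
#' @param ortholog_pairs Output of [map_orthologs()] (or ground-truth pairs).
#' @param stree Optional [species_tree] for timing.
#' @param min_run Minimum run length. Default 2 (single-gene transpositions
#'   are not called unless lowered to 1).
#' @return A tibble `species, chromosome, start, end, n, locus_ids,
#'   source_chromosome, home_chromosome, timing`.
#' @export
detect_translocations <- function(derived_table, outgroup_table,
                                  ortholog_pairs, stree = NULL, min_run = 2) {
  der <- as_locus_table(derived_table)
  sp <- unique(der$species)
  stopifnot(length(sp) == 1)
  og <- as_locus_table(outgroup_table)
  og_sp <- unique(og$species)
  stopifnot(length(og_sp) == 1)
  og_of <- ortholog_chromosomes(sp, og_sp, ortholog_pairs, og)
  der$og_chr <- og_of[der$locus_id]

  timing <- "unresolved"
  if (!is.null(stree)) {
    ids <- unique(stree$wgd$node_id)
    last_wgd <- ids[which.max(stree$depths[ids])]
    tips <- stree$phy$tip.label
    if (og_sp %in% tips && sp %in% tips) {
      below <- stree$phy$tip.label[tips_below(stree$phy, last_wgd)]
      if (!(og_sp %in% below) && sp %in% below) {
        timing <- paste0("post-",
                         wgd_window(wgd_on_branch(stree, last_wgd)[1]))
      } else {
        warning("outgroup '", og_sp, "' did not diverge before the last ",
                "WGD; timing unresolved", call. = FALSE)
      }
    }
  }

  calls <- list()
  for (chr in sort(unique(der$chromosome))) {
    loci <- der[der$chromosome == chr & !is.na(der$og_chr), ]
    loci <- loci[order(loci$start), ]
    if (!nrow(loci)) next
    tab <- sort(table(loci$og_chr), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) next # tie -> unresolved
    home <- names(tab)[1]
    runs <- cumsum(c(TRUE, loci$og_chr[-1] != loci$og_chr[-nrow(loci)]))
    for (r in unique(runs)) {
      seg <- loci[runs == r, ]
      if (seg$og_chr[1] == home || nrow(seg) < min_run) next
      calls[[length(calls) + 1]] <- tibble::tibble(
        species = sp, chromosome = chr,
        start = min(seg$start), end = max(seg$end), n = nrow(seg),
        locus_ids = list(seg$locus_id),
        source_chromosome = seg$og_chr[1], home_chromosome = home,
        timing = timing)
    }
  }
  if (!length(calls)) {
    return(tibble::tibble(species = character(), chromosome = character(),
                          start = double(), end = double(), n = integer(),
                          locus_ids = list(), source_chromosome = character(),
                          home_chromosome = character(), timing = character()))
  }
  dplyr::arrange(dplyr::bind_rows(calls), .data$chromosome, .data$start)
}
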