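#' Genome-evolution simulator
#'
#' `replay()` turns an event log (ancestral chromosome content plus an
#' ordered list of WGD, local-duplication, retrotransposition, loss,
#' translocation and fission events placed on species-tree branches) into
#' extant gene coordinate tables, congruent gene trees and per-node truth
#' labels. It is a pure function of (log, tree). `simulate_genomes()` draws a
#' stochastic event log from per-branch rates and replays it.
#'
#' Mechanics: a WGD doubles every locus of the genome onto a new chromosome
#' (name = parent name + `_label`), preserving order and adjacency; the copy
#' lineage id gains `_label`. Speciation copies the genome into each daughter
#' branch. Losses remove a named lineage; referencing a dead lineage is an
#' error naming the event. Translocations move a contiguous positional run to
#' another chromosome; fissions split a chromosome at a breakpoint.
#' Retrotransposition copies a gene to a new position with
#' `has_introns = FALSE`. Gene-tree node heights follow species-tree depth,
#' with within-branch events ordered by their event order.
#'
#' @param log An `event_log` (see [script_figure5()] or [event_log()]).
#' @param stree A [species_tree].
#' @param snapshots Keep genome snapshots at every species-tree node and just
#'   before each WGD (keyed `pre:<label>`)? Default TRUE.
#' @return A `sim_dataset`: list with `locus_table` (all species),
#'   `chromosome_lengths`, `gene_trees` (one rooted `phylo` per family, tips
#'   `species|locus_id`), `truth` (per family, per internal node: generating
#'   event and expected time-window), `snapshots`, `event_log`,
#'   `species_tree`.
#' @export
replay <- function(log, stree, snapshots = TRUE) {
  stopifnot(inherits(log, "event_log"), inherits(stree, "species_tree"))
  phy <- stree$phy
  ntip <- ape::Ntip(phy)
  kids <- children_list(phy)
  depths <- stree$depths
  labels <- stree$labels
  events <- log$events
  if (nrow(events)) {
    unknown <- setdiff(events$branch, labels)
    if (length(unknown)) {
      stop("event log references unknown branch(es): ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    wgd_ev <- events[events$event_type == "wgd", ]
    for (i in seq_len(nrow(wgd_ev))) {
      lab <- wgd_ev$params[[i]]$label
      placed <- stree$wgd$node[stree$wgd$label == lab]
      if (!length(placed) || placed != wgd_ev$branch[i]) {
        stop("wgd event '", lab, "' is not placed on branch ",
             wgd_ev$branch[i], " of the species tree", call. = FALSE)
      }
    }
  }

  ns <- new.env(parent = emptyenv())
  ns$id <- ns$parent <- integer(0)
  ns$kind <- ns$branch <- ns$family <- ns$tip_label <- character(0)
  ns$event_id <- integer(0)
  ns$time <- numeric(0)
  add_node <- function(parent, kind, branch, event_id, time, family,
                       tip_label = NA_character_) {
    i <- length(ns$id) + 1L
    ns$id[i] <- i
    ns$parent[i] <- parent
    ns$kind[i] <- kind
    ns$branch[i] <- branch
    ns$event_id[i] <- event_id
    ns$time[i] <- time
    ns$family[i] <- family
    ns$tip_label[i] <- tip_label
    i
  }

  anc <- tibble::as_tibble(log$ancestor)
  root_label <- labels[ntip + 1L]
  if (!"strand" %in% names(anc)) anc$strand <- "+"
  if (!"has_introns" %in% names(anc)) anc$has_introns <- TRUE
  # families starting from several ancestral loci are joined under an
  # ancient duplication predating the simulated history, so every family
  # tree has a single root
  fam_root <- integer(0)
  for (f in unique(anc$family[duplicated(anc$family)])) {
    fam_root[[f]] <- add_node(NA_integer_, "root", root_label, NA_integer_,
                              -2, f)
  }
  genome <- dplyr::mutate(anc,
    home_chr = .data$chromosome,
    ptr = vapply(seq_len(nrow(anc)), function(i) {
      parent <- if (anc$family[i] %in% names(fam_root)) {
        fam_root[[anc$family[i]]]
      } else NA_integer_
      add_node(parent, "root", root_label, NA_integer_, -1, anc$family[i])
    }, 1L))

  snaps <- list()
  extant <- list()

  apply_events <- function(genome, branch_label, node_depth) {
    ev <- events[events$branch == branch_label, ]
    if (!nrow(ev)) return(genome)
    ev <- ev[order(ev$order_index), ]
    for (i in seq_len(nrow(ev))) {
      p <- ev$params[[i]]
      t_ev <- node_depth - 1 + ev$order_index[i] / (max(ev$order_index) + 1)
      eid <- ev$event_id[i]
      type <- ev$event_type[i]
      if (type == "wgd") {
        if (snapshots) {
          snaps[[paste0("pre:", p$label)]] <<-
            dplyr::select(genome, -"ptr")
        }
        genome <- genome[order(genome$chromosome, genome$pos,
                               genome$lineage), ]
        d <- vapply(seq_len(nrow(genome)), function(j)
          add_node(genome$ptr[j], "dup", branch_label, eid, t_ev,
                   genome$family[j]), 1L)
        copy <- genome
        copy$lineage <- paste0(copy$lineage, "_", p$label)
        copy$chromosome <- paste0(copy$chromosome, "_", p$label)
        copy$home_chr <- copy$chromosome
        genome$ptr <- d
        copy$ptr <- d
        genome <- dplyr::bind_rows(genome, copy)
      } else if (type == "loss") {
        j <- which(genome$lineage == p$lineage)
        if (!length(j)) {
          stop("event ", eid, " (loss on ", branch_label,
               ") references a dead lineage: ", p$lineage, call. = FALSE)
        }
        genome <- genome[-j, ]
      } else if (type == "local_duplication") {
        j <- which(genome$lineage == p$lineage)
        if (!length(j)) {
          stop("event ", eid, " (local_duplication on ", branch_label,
               ") references a dead lineage: ", p$lineage, call. = FALSE)
        }
        d <- add_node(genome$ptr[j], "dup", branch_label, eid, t_ev,
                      genome$family[j])
        copy <- genome[j, ]
        offset <- p$offset %||% 1e4
        copy$pos <- copy$pos + offset
        if (!is.null(p$child_ids)) {
          genome$lineage[j] <- p$child_ids[1]
          copy$lineage <- p$child_ids[2]
        } else {
          k <- 1L
          while (paste0(copy$lineage, ".L", k) %in% genome$lineage) k <- k + 1L
          copy$lineage <- paste0(copy$lineage, ".L", k)
        }
        genome$ptr[j] <- d
        copy$ptr <- d
        genome <- dplyr::bind_rows(genome, copy)
      } else if (type == "retrotransposition") {
        j <- which(genome$lineage == p$lineage)
        if (!length(j)) {
          stop("event ", eid, " (retrotransposition on ", branch_label,
               ") references a dead lineage: ", p$lineage, call. = FALSE)
        }
        d <- add_node(genome$ptr[j], "dup", branch_label, eid, t_ev,
                      genome$family[j])
        copy <- genome[j, ]
        copy$lineage <- p$new_id %||% paste0(copy$lineage, ".R")
        copy$chromosome <- p$dest_chromosome
        copy$home_chr <- p$dest_chromosome
        copy$pos <- p$dest_pos
        copy$has_introns <- FALSE
        genome$ptr[j] <- d
        copy$ptr <- d
        genome <- dplyr::bind_rows(genome, copy)
      } else if (type == "translocation") {
        j <- which(genome$chromosome == p$chromosome &
                     genome$pos >= p$from & genome$pos <= p$to)
        if (!length(j)) {
          warning("event ", eid, " (translocation on ", branch_label,
                  ") moved no loci", call. = FALSE)
        }
        genome$pos[j] <- p$dest_pos + (genome$pos[j] - p$from)
        genome$chromosome[j] <- p$dest_chromosome
      } else if (type == "fission") {
        j <- which(genome$chromosome == p$chromosome &
                     genome$pos >= p$breakpoint)
        new_chr <- p$new_chromosome %||% paste0(p$chromosome, "_f")
        genome$pos[j] <- genome$pos[j] - p$breakpoint
        genome$chromosome[j] <- new_chr
      } else {
        stop("unknown event type: ", type, call. = FALSE)
      }
    }
    genome
  }

  recurse <- function(node, genome) {
    lab <- labels[node]
    if (node != ntip + 1L) genome <- apply_events(genome, lab, depths[node])
    if (snapshots) snaps[[lab]] <<- dplyr::select(genome, -"ptr")
    if (node <= ntip) {
      genome$locus_id <- paste(lab, genome$lineage, sep = "@")
      for (j in seq_len(nrow(genome))) {
        add_node(genome$ptr[j], "leaf", lab, NA_integer_, depths[node],
                 genome$family[j],
                 tip_label = paste(lab, genome$locus_id[j], sep = "|"))
      }
      genome$species <- lab
      extant[[lab]] <<- genome
      return(invisible())
    }
    spec <- vapply(seq_len(nrow(genome)), function(j)
      add_node(genome$ptr[j], "spec", lab, NA_integer_, depths[node],
               genome$family[j]), 1L)
    genome$ptr <- spec
    for (ch in kids[[node]]) recurse(ch, genome)
  }
  recurse(ntip + 1L, genome)

  subtype_of <- function(lineage) {
    map <- log$subtype_map
    if (is.null(map)) return(rep("unassigned", length(lineage)))
    vapply(lineage, function(l) {
      key <- l
      repeat {
        if (key %in% names(map)) return(unname(map[key]))
        stripped <- sub("(\\.L[0-9]+|\\.R|_[^_.]+)$", "", key)
        if (identical(stripped, key)) return("unassigned")
        key <- stripped
      }
    }, character(1))
  }

  tabs <- dplyr::bind_rows(extant)
  locus_table <- as_locus_table(tibble::tibble(
    species = tabs$species, locus_id = tabs$locus_id, family = tabs$family,
    subtype = subtype_of(tabs$lineage), chromosome = tabs$chromosome,
    start = tabs$pos, end = tabs$pos + 1, strand = tabs$strand,
    has_introns = tabs$has_introns))
  locus_table$lineage <- tabs$lineage
  locus_table$home_chr <- tabs$home_chr
  chrlen <- dplyr::distinct(locus_table, .data$species, .data$chromosome)
  chrlen$length <- log$chromosome_length %||% 5e7

  nodes_df <- tibble::tibble(id = as.character(ns$id),
                             parent = ifelse(is.na(ns$parent), NA_character_,
                                             as.character(ns$parent)),
                             kind = ns$kind, branch = ns$branch,
                             event_id = ns$event_id, time = ns$time,
                             family = ns$family,
                             tip = ns$kind == "leaf",
                             label = ifelse(ns$kind == "leaf", ns$tip_label,
                                            paste0("n", ns$id)))
  gene_trees <- list()
  truth <- list()
  for (fam in sort(unique(nodes_df$family))) {
    sub <- nodes_df[nodes_df$family == fam, ]
    if (sum(sub$tip) < 2) next
    built <- phylo_from_table(sub)
    phy <- built$phy
    ntip_g <- ape::Ntip(phy)
    internal_ids <- built$ids[as.character(ntip_g + seq_len(phy$Nnode))]
    info <- sub[match(internal_ids, sub$id), ]
    tr <- tibble::tibble(
      node = ntip_g + seq_len(phy$Nnode),
      node_label = paste0("n", internal_ids),
      kind = info$kind, branch = info$branch, event_id = info$event_id)
    tr <- dplyr::left_join(
      tr,
      dplyr::select(dplyr::mutate(events,
                                  event_type = .data$event_type),
                    "event_id", "event_type", "params"),
      by = "event_id")
    tr$wgd_label <- vapply(seq_len(nrow(tr)), function(i) {
      if (!is.na(tr$event_id[i]) && identical(tr$event_type[i], "wgd")) {
        tr$params[[i]]$label
      } else NA_character_
    }, character(1))
    tr$truth_window <- vapply(seq_len(nrow(tr)), function(i) {
      if (tr$kind[i] != "dup") return(NA_character_)
      if (!is.na(tr$wgd_label[i])) return(wgd_window(tr$wgd_label[i]))
      truth_local_window(tr$branch[i], tr$event_id[i], events, stree)
    }, character(1))
    gene_trees[[fam]] <- phy
    truth[[fam]] <- dplyr::select(tr, -"params")
  }

  structure(list(locus_table = locus_table,
                 chromosome_lengths = chrlen,
                 gene_trees = gene_trees,
                 truth = truth,
                 snapshots = if (snapshots) snaps else NULL,
                 event_log = log,
                 species_tree = stree),
            class = "sim_dataset")
}

# expected time-window of a non-WGD duplication, from where and when it
# happened (describes the truth; reconciliation may or may not recover it)
truth_local_window <- function(branch, event_id, events, stree) {
  b <- node_by_label(stree$phy, branch)
  w1 <- first_wgd_node(stree)
  wgds_here <- wgd_on_branch(stree, b)
  if (length(wgds_here)) {
    ev <- events[events$branch == branch, ]
    first_wgd_order <- min(ev$order_index[ev$event_type == "wgd"])
    my_order <- events$order_index[events$event_id == event_id]
    before <- my_order < first_wgd_order
    base <- wgd_window(wgds_here[1])
    return(if (before) "pre-window" else paste0("post-", base, "-local"))
  }
  mapping_like <- classify_window(
    nodes = 1L,
    mapping = {
      m <- tibble::tibble(node = 1L, species_node = b,
                          species_label = stree$labels[b])
      attr(m, "stree_paths") <- stree$paths
      m
    }, stree = stree)
  mapping_like$window
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$locus_table), "extant loci,",
      length(unique(x$locus_table$species)), "species,",
      length(x$gene_trees), "gene trees\n")
  invisible(x)
}

#' Construct an event log
#'
#' @param ancestor Tibble of ancestral loci: `lineage, family, chromosome,
#'   pos` (optionally `strand`, `has_introns`).
#' @param events Tibble `event_type, branch, order_index, params` (list
#'   column); an `event_id` is assigned if absent.
#' @param subtype_map Named character vector mapping lineage ids to display
#'   subtypes; unmapped lineages fall back on their longest mapped prefix,
#'   else `"unassigned"`.
#' @param chromosome_length Uniform chromosome length (bp) for the emitted
#'   lengths table.
#' @param scenario Free-text tag.
#' @return An object of class `event_log`.
#' @export
event_log <- function(ancestor, events, subtype_map = NULL,
                      chromosome_length = 5e7, scenario = "custom") {
  events <- tibble::as_tibble(events)
  if (!nrow(events)) {
    events <- tibble::tibble(event_type = character(), branch = character(),
                             order_index = integer(), params = list())
  }
  if (!"event_id" %in% names(events)) {
    events$event_id <- seq_len(nrow(events))
  }
  structure(list(ancestor = tibble::as_tibble(ancestor), events = events,
                 subtype_map = subtype_map,
                 chromosome_length = chromosome_length, scenario = scenario),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("Event log (", x$scenario, "): ", nrow(x$ancestor),
      " ancestral loci, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' The default vertebrate species tree
#'
#' Six species spanning the relevant divergences: an invertebrate chordate
#' outgroup (amphioxus) diverging before 2R, coelacanth and human
#' (sarcopterygians), spotted gar (a pre-3R actinopterygian) and two
#' teleosts. 2R-1 and 2R-2 sit on the vertebrate stem, 3R on the teleost
#' stem.
#'
#' @return A [species_tree].
#' @export
default_species_tree <- function() {
  phy <- ape::read.tree(text = paste0(
    "(amphioxus,((coelacanth,human)Sarcopterygii,",
    "(gar,(zebrafish,stickleback)Teleostei)Actinopterygii)Vertebrata)",
    "Chordata;"))
  species_tree(phy, data.frame(
    label = c("2R-1", "2R-2", "3R"),
    node = c("Vertebrata", "Vertebrata", "Teleostei")))
}
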