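#' Species tree with whole-genome duplication placements
#'
#' A `species_tree` couples a rooted [ape::phylo] tree (tip labels = species,
#' internal node labels = clade names) with an ordered table of whole-genome
#' duplication (WGD) placements. A placement puts a WGD label (for the
#' vertebrate analyses: `"2R-1"`, `"2R-2"`, `"3R"`) on the branch *ending* at a
#' named node; two WGDs on one branch (the two basal vertebrate
#' tetraploidizations) are ordered by their position in `wgd`.
#'
#' @param phy A rooted `phylo` object. All tip labels and internal node labels
#'   must be unique; any node carrying a WGD must be named.
#' @param wgd A data frame with columns `label` (WGD label, unique) and `node`
#'   (label of the node at the lower end of the branch carrying the event).
#'   Row order gives the within-branch event order.
#' @return An object of class `species_tree`.
#' @examples
#' st <- species_tree(
#'   ape::read.tree(text = "((gar,(zebrafish,stickleback)Teleostei)Actinopterygii,human)Vertebrata;"),
#'   data.frame(label = c("2R-1", "2R-2", "3R"),
#'              node  = c("Vertebrata", "Vertebrata", "Teleostei"))
#' )
#' st
#' @export
species_tree <- function(phy, wgd = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("species tree must be rooted", call. = FALSE)
  labels <- node_labels_all(phy)
  named <- labels[labels != ""]
  if (anyDuplicated(named)) {
    stop("species tree names must be unique; duplicated: ",
         paste(unique(named[duplicated(named)]), collapse = ", "), call. = FALSE)
  }
  wgd <- if (is.null(wgd)) {
    tibble::tibble(label = character(), node = character())
  } else {
    tibble::as_tibble(wgd)[, c("label", "node")]
  }
  if (anyDuplicated(wgd$label)) {
    stop("each WGD label may appear on exactly one branch", call. = FALSE)
  }
  wgd$node_id <- if (nrow(wgd)) node_by_label(phy, wgd$node) else integer()
  structure(
    list(phy = phy, wgd = wgd,
         paths = tree_paths(phy), parents = tree_parents(phy),
         depths = node_depths(phy), labels = labels),
    class = "species_tree"
  )
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree:", ape::Ntip(x$phy), "species,",
      x$phy$Nnode, "internal nodes\n")
  if (nrow(x$wgd)) {
    for (i in seq_len(nrow(x$wgd))) {
      cat("  WGD", x$wgd$label[i], "on the branch to", x$wgd$node[i], "\n")
    }
  } else cat("  (no WGD placements)\n")
  invisible(x)
}

# WGD labels carried by the branch ending at node id, in order
wgd_on_branch <- function(stree, node_id) {
  stree$wgd$label[stree$wgd$node_id == node_id]
}

# species node ids on the path (exclusive) between the 2R node and the 3R node
st_root <- function(stree) ape::Ntip(stree$phy) + 1L

#' Read and write species trees with WGD branch annotations
#'
#' Newick files may carry WGD placements as bracketed branch annotations of
#' the form `[wgd=2R-1]` (several labels comma-separated: `[wgd=2R-1,2R-2]`)
#' placed directly after the label of the node at the lower end of the branch,
#' e.g. `(gar,(zebrafish,stickleback)Teleostei[wgd=3R])Actinopterygii;`.
#' Standard Newick parsers treat square brackets as comments, so the
#' annotations are extracted before the tree is handed to [ape::read.tree()]
#' and re-inserted by the writer.
#'
#' @param path File path.
#' @return `read_species_tree()` returns a [species_tree]; `read_gene_tree()`
#'   a rooted `phylo` whose tips are `species|locus_id`.
#' @export
read_species_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  m <- gregexpr("([^][(),;:[:space:]]+)\\[wgd=([^]]+)\\]", txt)
  wgd <- tibble::tibble(label = character(), node = character())
  for (hit in regmatches(txt, m)[[1]]) {
    node <- sub("\\[.*$", "", hit)
    labels <- strsplit(sub("^.*\\[wgd=([^]]+)\\].*$", "\\1", hit), ",")[[1]]
    wgd <- dplyr::bind_rows(wgd, tibble::tibble(label = trimws(labels), node = node))
  }
  clean <- gsub("\\[wgd=[^]]+\\]", "", txt)
  phy <- tryCatch(ape::read.tree(text = clean),
                  error = function(e) stop("Newick parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse error in ", path, call. = FALSE)
  species_tree(phy, wgd)
}

#' @rdname read_species_tree
#' @param x A `species_tree` to serialise.
#' @export
write_species_tree <- function(x, path) {
  stopifnot(inherits(x, "species_tree"))
  txt <- ape::write.tree(x$phy)
  if (nrow(x$wgd)) {
    ann <- dplyr::summarise(dplyr::group_by(x$wgd, .data$node),
                            wgd = paste(.data$label, collapse = ","))
    for (i in seq_len(nrow(ann))) {
      txt <- sub(paste0("(", ann$node[i], ")([:,();])"),
                 paste0("\\1[wgd=", ann$wgd[i], "]\\2"), txt)
    }
  }
  writeLines(txt, path)
  invisible(path)
}

#' @rdname read_species_tree
#' @export
read_gene_tree <- function(path) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("Newick parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse error in ", path, call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip names in ", path, ": ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  phy
}

#' @rdname read_species_tree
#' @param phy A gene tree (`phylo`, tips `species|locus_id`).
#' @export
write_gene_tree <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

# split "species|locus_id" tips
gene_tip_info <- function(gtree) {
  parts <- stringr::str_split_fixed(gtree$tip.label, stringr::fixed("|"), 2)
  tibble::tibble(tip = seq_along(gtree$tip.label),
                 label = gtree$tip.label,
                 species = parts[, 1], locus_id = parts[, 2])
}
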