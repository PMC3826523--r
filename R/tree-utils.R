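# Internal helpers shared by reconciliation, simulation and reconstruction.
# ape numbering: tips 1..Ntip, root Ntip+1, internals Ntip+1..Ntip+Nnode.

tree_parents <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  parent <- integer(n)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  parent
}

# ancestor path per node, ordered root -> node (inclusive)
tree_paths <- function(phy) {
  parent <- tree_parents(phy)
  n <- length(parent)
  root <- ape::Ntip(phy) + 1L
  paths <- vector("list", n)
  for (v in seq_len(n)) {
    p <- v
    path <- v
    while (p != root) {
      p <- parent[p]
      path <- c(p, path)
    }
    paths[[v]] <- path
  }
  paths
}

# last common element of two root->node paths
path_mrca <- function(paths, i, j) {
  a <- paths[[i]]
  b <- paths[[j]]
  k <- min(length(a), length(b))
  eq <- a[seq_len(k)] == b[seq_len(k)]
  a[max(which(eq))]
}

is_ancestor <- function(paths, anc, node) anc %in% paths[[node]]

node_depths <- function(phy) {
  parent <- tree_parents(phy)
  root <- ape::Ntip(phy) + 1L
  depth <- integer(length(parent))
  # preorder: phy$edge rows from reorder(phy) are not guaranteed; iterate
  ord <- order(vapply(tree_paths(phy), length, 1L))
  for (v in ord) depth[v] <- if (v == root) 0L else depth[parent[v]] + 1L
  depth
}

# label of a node: tip label or node label; "" when unnamed
node_labels_all <- function(phy) {
  lab <- c(phy$tip.label, phy$node.label %||% rep("", phy$Nnode))
  if (length(lab) < ape::Ntip(phy) + phy$Nnode) {
    lab <- c(lab, rep("", ape::Ntip(phy) + phy$Nnode - length(lab)))
  }
  lab
}

node_by_label <- function(phy, label) {
  lab <- node_labels_all(phy)
  idx <- match(label, lab)
  if (anyNA(idx)) {
    stop("node label(s) not found in tree: ",
         paste(label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

tips_below <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(node)
  kids <- children_list(phy)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v <= ntip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  sort(out)
}

children_list <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n)
  for (r in seq_len(nrow(phy$edge))) {
    kids[[phy$edge[r, 1]]] <- c(kids[[phy$edge[r, 1]]], phy$edge[r, 2])
  }
  kids
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build an ape phylo from a node table (id, parent [NA at root], tip, label,
# time). Nodes without any tip descendant are dropped, unifurcations are
# suppressed, and the root is pushed down past single-child chains. Returns
# list(phy, ids) where ids maps ape node number -> original id (tips first).
# Edge lengths are time differences when `time` is present.
phylo_from_table <- function(nodes) {
  stopifnot(all(c("id", "parent", "tip", "label") %in% names(nodes)))
  nodes <- tibble::as_tibble(nodes)
  kids <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  has_tip <- stats::setNames(logical(nrow(nodes)), nodes$id)
  # postorder by repeated passes (tables are small)
  remaining <- nodes$id
  while (length(remaining)) {
    progressed <- FALSE
    for (id in remaining) {
      ch <- kids[[id]]
      ch <- ch[!is.na(ch)]
      if (nodes$tip[nodes$id == id]) {
        has_tip[id] <- TRUE
      } else if (!length(ch)) {
        has_tip[id] <- FALSE
      } else if (all(ch %in% names(has_tip)[!(names(has_tip) %in% remaining)])) {
        has_tip[id] <- any(has_tip[ch])
      } else next
      remaining <- setdiff(remaining, id)
      progressed <- TRUE
    }
    if (!progressed) stop("cyclic or disconnected node table", call. = FALSE)
  }
  keep <- nodes[has_tip[nodes$id], ]
  if (!any(keep$tip)) stop("no extant tips", call. = FALSE)
  # reparent to nearest kept ancestor
  par_of <- stats::setNames(nodes$parent, nodes$id)
  nearest_kept <- function(id) {
    p <- par_of[[id]]
    while (!is.na(p) && !(p %in% keep$id)) p <- par_of[[p]]
    p
  }
  keep$parent <- vapply(keep$id, nearest_kept, nodes$parent[1])
  # suppress unifurcations (non-tip nodes with exactly one child), and any
  # single-child chain above the effective root
  repeat {
    cnt <- table(factor(keep$parent, levels = keep$id))
    uni <- keep$id[!keep$tip & cnt[keep$id] == 1]
    root_id <- keep$id[is.na(keep$parent)]
    if (!length(uni)) break
    drop_id <- uni[1]
    child <- keep$id[!is.na(keep$parent) & keep$parent == drop_id]
    keep$parent[keep$id == child] <- keep$parent[keep$id == drop_id]
    keep <- keep[keep$id != drop_id, ]
  }
  tips <- keep[keep$tip, ]
  internals <- keep[!keep$tip, ]
  ntip <- nrow(tips)
  if (ntip == 1) stop("cannot build a phylo with a single tip", call. = FALSE)
  # preorder internal numbering, root first
  root_id <- keep$id[is.na(keep$parent)]
  ord <- character(0)
  stack <- root_id
  kid_map <- split(keep$id, factor(keep$parent, levels = keep$id))
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (!keep$tip[keep$id == v]) {
      ord <- c(ord, v)
      stack <- c(kid_map[[v]], stack)
    }
  }
  num <- stats::setNames(c(seq_len(ntip), ntip + seq_along(ord)),
                         c(tips$id, ord))
  edge <- cbind(unname(num[keep$parent[!is.na(keep$parent)]]),
                unname(num[keep$id[!is.na(keep$parent)]]))
  phy <- list(edge = edge, Nnode = length(ord),
              tip.label = tips$label,
              node.label = internals$label[match(ord, internals$id)])
  if ("time" %in% names(keep)) {
    tm <- stats::setNames(keep$time, keep$id)
    phy$edge.length <- pmax(tm[keep$id[!is.na(keep$parent)]] -
                              tm[keep$parent[!is.na(keep$parent)]], 1e-6)
    names(phy$edge.length) <- NULL
  }
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  ids <- stats::setNames(names(num), unname(num))
  list(phy = phy, ids = ids)
}
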