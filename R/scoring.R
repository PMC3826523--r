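#' Score window recovery against simulator ground truth
#'
#' Compares dated duplication calls with the event log of a simulated
#' dataset. A surviving WGD duplication node is *absorbed by loss* when
#' reconciliation cannot flag it as a duplication at all (reciprocal losses
#' left the two copies on disjoint sides of the relevant species split, so
#' the node is topologically a speciation - hidden paralogy, invisible to
#' any topology-based method); such nodes are excluded from the detectable
#' denominator. A detectable node is *correct* when its window label equals
#' the truth, *unresolved* when labelled so, and *mislabeled* otherwise.
#'
#' @param dataset A `sim_dataset`.
#' @param calls Named list of `dup_calls` computed on `dataset$gene_trees`
#'   (without support collapse, so node numbers align).
#' @return One-row tibble `n_surviving, n_absorbed, n_detectable, n_correct,
#'   n_unresolved, n_mislabeled, recovery`.
#' @export
score_window_recovery <- function(dataset, calls) {
  tot <- absorbed <- correct <- unres <- mis <- 0L
  for (f in names(calls)) {
    tr <- dataset$truth[[f]]
    if (is.null(tr)) next
    wgd <- tr[!is.na(tr$wgd_label), ]
    if (!nrow(wgd)) next
    got <- tibble::as_tibble(calls[[f]])
    win <- got$window[match(wgd$node, got$node)]
    tot <- tot + nrow(wgd)
    absorbed <- absorbed + sum(is.na(win))
    correct <- correct + sum(!is.na(win) & win == wgd$truth_window)
    unres <- unres + sum(!is.na(win) & win == "unresolved")
    mis <- mis + sum(!is.na(win) & win != "unresolved" &
                       win != wgd$truth_window)
  }
  tibble::tibble(n_surviving = tot, n_absorbed = absorbed,
                 n_detectable = tot - absorbed, n_correct = correct,
                 n_unresolved = unres, n_mislabeled = mis,
                 recovery = if (tot > absorbed) correct / (tot - absorbed)
                 else NA_real_)
}

#' Ground-truth translocated groups and their detectability
#'
#' From a simulated dataset, lists the groups of derived-species loci
#' sitting off their home chromosome (one group per (chromosome, home)
#' combination) and marks which are detectable against the given outgroup:
#' the group needs at least `min_run` members with surviving outgroup
#' orthologs, those orthologs must co-locate on an outgroup chromosome that
#' differs from the host chromosome's strict-majority home (a tie leaves the
#' chromosome unresolved by design), and the anchors must be consecutive
#' among the chromosome's ortholog-bearing loci. Moves between chromosomes
#' descending from one pre-WGD chromosome are invisible to a pre-WGD
#' outgroup (it shows the same co-location) and are marked undetectable.
#'
#' @param dataset A `sim_dataset`.
#' @param derived_species,outgroup_species Species names.
#' @param ortholog_pairs Output of [map_orthologs()].
#' @param min_run Minimum anchor count (match [detect_translocations()]).
#' @return Tibble `chromosome, home_chr, n, n_anchors, og_chr, detectable,
#'   locus_ids`.
#' @export
translocation_truth <- function(dataset, derived_species, outgroup_species,
                                ortholog_pairs, min_run = 2) {
  tab <- dataset$locus_table
  der <- tab[tab$species == derived_species, ]
  og <- tab[tab$species == outgroup_species, ]
  og_of <- ortholog_chromosomes(derived_species, outgroup_species,
                                ortholog_pairs, og)
  der$og_chr <- og_of[der$locus_id]
  moved <- der[der$chromosome != der$home_chr, ]
  if (!nrow(moved)) {
    return(tibble::tibble(chromosome = character(), home_chr = character(),
                          n = integer(), n_anchors = integer(),
                          og_chr = character(), detectable = logical(),
                          locus_ids = list()))
  }
  groups <- split(moved, paste(moved$chromosome, moved$home_chr, sep = "|"))
  out <- purrr::map_dfr(groups, function(g) {
    anchors <- g[!is.na(g$og_chr), ]
    host <- der[der$chromosome == g$chromosome[1] & !is.na(der$og_chr), ]
    host <- host[order(host$start), ]
    grp_og <- if (nrow(anchors)) {
      names(sort(table(anchors$og_chr), decreasing = TRUE))[1]
    } else NA_character_
    tabulated <- sort(table(host$og_chr), decreasing = TRUE)
    home <- if (length(tabulated) &&
                (length(tabulated) == 1 || tabulated[1] > tabulated[2])) {
      names(tabulated)[1]
    } else NA_character_
    consecutive <- FALSE
    if (nrow(anchors) >= min_run) {
      idx <- which(host$locus_id %in% anchors$locus_id)
      runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
      consecutive <- any(vapply(runs, length, 1L) >= min_run)
    }
    tibble::tibble(chromosome = g$chromosome[1], home_chr = g$home_chr[1],
                   n = nrow(g), n_anchors = nrow(anchors), og_chr = grp_og,
                   detectable = nrow(anchors) >= min_run && !is.na(home) &&
                     !is.na(grp_og) && grp_og != home && consecutive,
                   locus_ids = list(g$locus_id))
  })
  dplyr::arrange(out, .data$chromosome, .data$home_chr)
}

#' Score translocation recovery on simulated data
#'
#' @param truth Output of [translocation_truth()].
#' @param found Output of [detect_translocations()] for the same species
#'   pair.
#' @param min_run Anchors required to count a truth group as hit.
#' @return One-row tibble `n_groups, n_detectable, n_recovered,
#'   n_timed_post`.
#' @export
score_translocation_recovery <- function(truth, found, min_run = 2) {
  det <- truth[truth$detectable, ]
  hit <- timed <- 0L
  for (i in seq_len(nrow(det))) {
    ids <- det$locus_ids[[i]]
    match_rows <- vapply(found$locus_ids,
                         function(x) sum(ids %in% x) >= min_run, logical(1))
    if (any(match_rows)) {
      hit <- hit + 1L
      if (any(startsWith(found$timing[match_rows], "post-"))) {
        timed <- timed + 1L
      }
    }
  }
  tibble::tibble(n_groups = nrow(truth), n_detectable = nrow(det),
                 n_recovered = hit, n_timed_post = timed)
}
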