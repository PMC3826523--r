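#' Define conserved-synteny chromosome blocks around anchor genes
#'
#' Each anchor gene defines a window of `window` bp in each direction
#' (default 5 Mb, the span used when screening the visual-opsin regions for
#' neighboring families). Blocks on one chromosome that overlap are merged by
#' default and remember every contributing anchor; `merge = FALSE` keeps them
#' separate, which is the right mode when paralogy between two nearby anchors
#' on the same chromosome is itself the question.
#'
#' @param anchors A locus tibble of anchor genes; all rows must share one
#'   species.
#' @param window Flank size in bp (> 0). Default 5e6.
#' @param chromosome_lengths Optional lengths table used to clip blocks; an
#'   anchor chromosome absent from it leaves the block unclipped (with a
#'   warning). Blocks are always clipped at 0.
#' @param merge Merge overlapping same-chromosome blocks? Default TRUE.
#' @return A tibble `block_id, species, chromosome, start, end, anchors`
#'   (list column of anchor locus_ids).
#' @export
define_blocks <- function(anchors, window = 5e6, chromosome_lengths = NULL,
                          merge = TRUE) {
  stopifnot(window > 0)
  anchors <- as_locus_table(anchors)
  if (!nrow(anchors)) stop("no anchor loci supplied", call. = FALSE)
  if (length(unique(anchors$species)) != 1L) {
    stop("anchors must all come from one species", call. = FALSE)
  }
  win <- dplyr::mutate(anchors,
                       bstart = pmax(0, .data$start - window),
                       bend = .data$end + window)
  if (!is.null(chromosome_lengths)) {
    lens <- tibble::as_tibble(chromosome_lengths)
    win <- dplyr::left_join(win, lens, by = c("species", "chromosome"))
    unknown <- unique(win$chromosome[is.na(win$length)])
    if (length(unknown)) {
      warning("no chromosome length for ", paste(unknown, collapse = ", "),
              "; block(s) left unclipped", call. = FALSE)
    }
    win <- dplyr::mutate(win, bend = ifelse(is.na(.data$length), .data$bend,
                                            pmin(.data$bend, .data$length)))
  }
  win <- dplyr::arrange(win, .data$chromosome, .data$bstart, .data$bend)
  pieces <- dplyr::group_split(dplyr::group_by(win, .data$chromosome))
  out <- purrr::map_dfr(pieces, function(g) {
    g$grp <- if (merge) {
      cumsum(c(TRUE, g$bstart[-1] > cummax(g$bend[-nrow(g)])))
    } else {
      seq_len(nrow(g))
    }
    dplyr::summarise(dplyr::group_by(g, .data$grp),
                     species = .data$species[1], chromosome = .data$chromosome[1],
                     start = min(.data$bstart), end = max(.data$bend),
                     anchors = list(.data$locus_id), .groups = "drop")
  })
  out <- dplyr::arrange(out, .data$chromosome, .data$start)
  dplyr::select(
    dplyr::mutate(out, block_id = sprintf("%s:%s:%.0f", .data$species,
                                          .data$chromosome, .data$start)),
    "block_id", "species", "chromosome", "start", "end", "anchors")
}

#' Profile gene-family membership across chromosome blocks
#'
#' Assigns a locus to a block when species and chromosome match and the
#' half-open locus interval overlaps the half-open block interval, then
#' counts members per (family, block). Every family with at least one
#' assigned locus appears in the profile.
#'
#' @param blocks A block tibble from [define_blocks()].
#' @param table A locus tibble.
#' @return A tibble `family, block_id, n_loci`.
#' @export
profile_families <- function(blocks, table) {
  if (!nrow(blocks)) stop("no blocks supplied", call. = FALSE)
  tbl <- as_locus_table(table)
  joined <- dplyr::inner_join(
    tbl, dplyr::select(blocks, "block_id", "species", "chromosome",
                       bstart = "start", bend = "end"),
    by = c("species", "chromosome"), relationship = "many-to-many")
  hits <- dplyr::filter(joined, .data$start < .data$bend,
                        .data$end > .data$bstart)
  dplyr::arrange(
    dplyr::count(hits, .data$family, .data$block_id, name = "n_loci"),
    .data$family, .data$block_id)
}

#' Select families co-occurring on several blocks
#'
#' Keeps families whose profile covers at least `min_blocks` distinct blocks
#' (membership, not copy number: several loci of one family in one block
#' count once). The screens published for these regions used 2 blocks for
#' the human anchor sets and 3 for the zebrafish OT/VP-R set. Families larger
#' than `max_members` are dropped, mirroring the practice of discarding
#' families whose size makes phylogenetic analysis unreliable.
#'
#' @param profile A profile tibble from [profile_families()].
#' @param min_blocks Minimum distinct-block count (>= 2).
#' @param max_members Drop families with more total members than this.
#' @return Sorted character vector of family names.
#' @export
select_families <- function(profile, min_blocks = 2, max_members = 200) {
  stopifnot(min_blocks >= 2)
  agg <- dplyr::summarise(dplyr::group_by(profile, .data$family),
                          blocks = dplyr::n_distinct(.data$block_id),
                          members = sum(.data$n_loci), .groups = "drop")
  sel <- dplyr::filter(agg, .data$blocks >= min_blocks,
                       .data$members <= max_members)
  sort(sel$family)
}

#' Pool family selections from several anchor sets
#'
#' Independent screens around different anchor families identify overlapping
#' family sets; pooling is a sorted set union.
#'
#' @param selections A list of character vectors.
#' @return Sorted character vector without duplicates.
#' @export
pool_selections <- function(selections) {
  sort(unique(unlist(selections, use.names = FALSE)))
}
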