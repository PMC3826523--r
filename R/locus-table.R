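#' Gene locus tables
#'
#' The central tabular container: one row per gene locus with columns
#' `species`, `locus_id`, `family`, `subtype`, `chromosome`, `start`, `end`,
#' `strand`, `has_introns`. Coordinates are 0-based, half-open, in bp.
#' Positions published only at Mb resolution are stored as point anchors
#' (`end = start + 1`). Subtype `"unassigned"` is permitted before dating.
#'
#' `as_locus_table()` validates and normalises a data frame (family/subtype
#' case-normalised to upper case, columns coerced to their canonical types).
#'
#' @param x A data frame with the columns above.
#' @param chromosome_lengths Optional data frame (`species`, `chromosome`,
#'   `length`) used to check `end <= length`.
#' @return A tibble with the canonical column order.
#' @export
as_locus_table <- function(x, chromosome_lengths = NULL) {
  cols <- c("species", "locus_id", "family", "subtype", "chromosome",
            "start", "end", "strand", "has_introns")
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop("locus table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tibble::as_tibble(x)[, cols]
  tbl <- dplyr::mutate(
    tbl,
    species = as.character(.data$species),
    locus_id = as.character(.data$locus_id),
    family = toupper(trimws(as.character(.data$family))),
    subtype = toupper(trimws(as.character(.data$subtype))),
    chromosome = as.character(.data$chromosome),
    start = as.double(.data$start),
    end = as.double(.data$end),
    strand = as.character(.data$strand),
    has_introns = as.logical(.data$has_introns)
  )
  bad <- which(!(tbl$start >= 0 & tbl$start < tbl$end))
  if (length(bad)) {
    stop("invalid coordinates (need 0 <= start < end) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(tbl$strand %in% c("+", "-", "?"))) {
    stop("strand must be one of '+', '-', '?'", call. = FALSE)
  }
  if (anyDuplicated(tbl$locus_id)) {
    stop("locus_id values must be unique within a locus table; duplicated: ",
         paste(unique(tbl$locus_id[duplicated(tbl$locus_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(chromosome_lengths)) {
    lens <- tibble::as_tibble(chromosome_lengths)
    joined <- dplyr::left_join(tbl, lens, by = c("species", "chromosome"))
    over <- which(!is.na(joined$length) & joined$end > joined$length)
    if (length(over)) {
      stop("locus end exceeds chromosome length in row(s): ",
           paste(over, collapse = ", "), call. = FALSE)
    }
  }
  tbl
}

#' Read / write a locus table
#'
#' Tab-separated text with a header row and columns exactly
#' `species, locus_id, family, subtype, chromosome, start, end, strand,
#' has_introns`. Lines starting with `#` are comments. The writer emits rows
#' sorted by (species, chromosome, start, locus_id) so outputs are diffable.
#'
#' @param path File path.
#' @inheritParams as_locus_table
#' @return A validated locus tibble.
#' @export
read_locus_table <- function(path, chromosome_lengths = NULL) {
  cols <- c("species", "locus_id", "family", "subtype", "chromosome",
            "start", "end", "strand", "has_introns")
  header <- names(readr::read_tsv(path, comment = "#", n_max = 0,
                                  show_col_types = FALSE))
  missing <- setdiff(cols, header)
  if (length(missing)) {
    stop(path, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           species = "c", locus_id = "c", family = "c",
                           subtype = "c", chromosome = "c",
                           start = "d", end = "d", strand = "c",
                           has_introns = "l", .default = "c"))
  as_locus_table(raw, chromosome_lengths = chromosome_lengths)
}

#' @rdname read_locus_table
#' @param table A locus tibble.
#' @export
write_locus_table <- function(table, path) {
  out <- dplyr::arrange(as_locus_table(table),
                        .data$species, .data$chromosome, .data$start,
                        .data$locus_id)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname read_locus_table
#' @export
read_chromosome_lengths <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(species = "c", chromosome = "c",
                                          length = "d"))
}

#' Count the gene repertoire per species, family and subtype
#'
#' Tallies loci the way published repertoire tables are read: one row per
#' (species, family, subtype) with the locus count. Counts partition the
#' filtered rows, so the total equals the number of loci retained by the
#' filters. Unknown filter values yield an empty result.
#'
#' @param table A locus tibble (see [as_locus_table()]).
#' @param species,family Optional filters.
#' @return A tibble `species, family, subtype, n`, sorted.
#' @examples
#' tab <- figure5_dataset()$locus_table
#' count_repertoire(tab, species = "zebrafish", family = "opsin")
#' @export
count_repertoire <- function(table, species = NULL, family = NULL) {
  tbl <- as_locus_table(table)
  if (!is.null(species)) tbl <- dplyr::filter(tbl, .data$species %in% !!species)
  if (!is.null(family)) {
    tbl <- dplyr::filter(tbl, .data$family %in% toupper(!!family))
  }
  dplyr::arrange(
    dplyr::count(tbl, .data$species, .data$family, .data$subtype),
    .data$species, .data$family, .data$subtype)
}

#' Find local (tandem) duplicates
#'
#' A cluster is a maximal run of two or more same-species, same-chromosome,
#' same-subtype loci in which consecutive loci (ordered by start) lie at most
#' `max_gap` apart. Tandem clusters are how local duplicates present in real
#' assemblies (e.g. four RH2 genes within ~20 kb), as opposed to
#' WGD-generated copies which land on different paralogon blocks.
#'
#' @inheritParams count_repertoire
#' @param max_gap Maximum start-to-start gap (bp) between consecutive cluster
#'   members. Default 1 Mb.
#' @return A tibble `species, chromosome, subtype, n, locus_ids` (list column,
#'   ordered by position).
#' @export
find_local_duplicates <- function(table, max_gap = 1e6) {
  stopifnot(max_gap > 0)
  tbl <- dplyr::arrange(as_locus_table(table),
                        .data$species, .data$chromosome, .data$subtype,
                        .data$start, .data$locus_id)
  grouped <- dplyr::group_by(tbl, .data$species, .data$chromosome, .data$subtype)
  clustered <- dplyr::mutate(
    grouped,
    cluster = cumsum(c(TRUE, diff(.data$start) > max_gap)))
  out <- dplyr::summarise(
    dplyr::group_by(clustered, .data$species, .data$chromosome, .data$subtype,
                    .data$cluster),
    n = dplyr::n(), locus_ids = list(.data$locus_id), .groups = "drop")
  out <- dplyr::filter(out, .data$n >= 2)
  dplyr::select(dplyr::arrange(out, .data$species, .data$chromosome,
                               .data$subtype, .data$cluster),
                -"cluster")
}

#' Conserved adjacent gene pairs of two families
#'
#' Pairs loci of two families that sit on the same chromosome within
#' `max_gap`, per species, by greedy nearest-first matching (ties broken by
#' smaller start). Each locus joins at most one pair. This captures conserved
#' tandem arrangements such as the GNAT-GNAI gene pairs that flank each other
#' on the 2R-generated chromosomes.
#'
#' @inheritParams find_local_duplicates
#' @param family_a,family_b Family names.
#' @return A tibble `species, chromosome, locus_a, locus_b, distance`.
#' @export
paired_adjacency <- function(table, family_a, family_b, max_gap = 1e6) {
  tbl <- as_locus_table(table)
  fa <- dplyr::filter(tbl, .data$family == toupper(family_a))
  fb <- dplyr::filter(tbl, .data$family == toupper(family_b))
  if (!nrow(fa) || !nrow(fb)) {
    message("paired_adjacency: family absent from table, returning no pairs")
    return(tibble::tibble(species = character(), chromosome = character(),
                          locus_a = character(), locus_b = character(),
                          distance = double()))
  }
  cand <- dplyr::inner_join(
    dplyr::select(fa, sp = "species", chr = "chromosome",
                  locus_a = "locus_id", start_a = "start"),
    dplyr::select(fb, sp = "species", chr = "chromosome",
                  locus_b = "locus_id", start_b = "start"),
    by = c("sp", "chr"), relationship = "many-to-many")
  cand <- dplyr::mutate(cand, distance = abs(.data$start_a - .data$start_b))
  cand <- dplyr::filter(cand, .data$distance <= max_gap)
  cand <- dplyr::arrange(cand, .data$sp, .data$distance, .data$start_a,
                         .data$start_b)
  used_a <- used_b <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$locus_a[i] %in% used_a) && !(cand$locus_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, cand$locus_a[i])
      used_b <- c(used_b, cand$locus_b[i])
    }
  }
  out <- cand[keep, ]
  tibble::as_tibble(dplyr::select(out, species = "sp", chromosome = "chr",
                                  "locus_a", "locus_b", "distance"))
}
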