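#' Configuration for the end-to-end pipeline
#'
#' Either `scenario` names a built-in simulated dataset (`"figure5"`,
#' `"figure5-rho-local"`) or the three path arguments point at input files:
#' a locus table, a species tree with WGD annotations, and a directory of
#' per-family Newick gene trees (`<FAMILY>.nwk`, tips `species|locus_id`).
#' Paths are checked at validation time.
#'
#' @param scenario Built-in scenario name, or `NULL` to load from paths.
#' @param loci,species_tree,gene_trees Input paths (ignored for built-in
#'   scenarios).
#' @param reference_species Species whose blocks anchor the paralogon.
#' @param outgroup_species Pre-3R outgroup used for fission merging and
#'   translocation timing.
#' @param derived_species Post-3R species scanned for translocations.
#' @param anchor_families Families whose loci in the reference species seed
#'   the chromosome blocks; blocks are built around each family's loci, the
#'   per-family selections are pooled, and the union of all anchors defines
#'   the merged block set used downstream.
#' @param window Block window (bp).
#' @param min_blocks Block co-occurrence threshold.
#' @param min_support Paralogon edge support threshold.
#' @param max_gap Local-duplicate gap (bp).
#' @param collapse_below Optional support-collapse threshold for gene trees.
#' @param nodes Ancestor nodes for the repertoire summary (labels or
#'   `pre:<wgd>` keys).
#' @param seed Seed recorded in the log (the scripted scenario itself is
#'   deterministic).
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @return A validated `run_config` list.
#' @export
run_config <- function(scenario = "figure5", loci = NULL, species_tree = NULL,
                       gene_trees = NULL, reference_species = "human",
                       outgroup_species = "gar",
                       derived_species = "zebrafish",
                       anchor_families = c("OPSIN", "GNAT", "GNAI", "OTVPR",
                                           "CACNA1L"),
                       window = 5e6, min_blocks = 2,
                       min_support = 2, max_gap = 1e6, collapse_below = NULL,
                       nodes = c("pre:2R-1", "Vertebrata"), seed = 1,
                       out_dir = NULL) {
  if (is.null(scenario)) {
    for (p in c(loci, species_tree)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input path missing or nonexistent: ", p %||% "(NULL)",
             call. = FALSE)
      }
    }
    if (is.null(gene_trees) || !dir.exists(gene_trees)) {
      stop("gene tree directory missing: ", gene_trees %||% "(NULL)",
           call. = FALSE)
    }
  }
  stopifnot(window > 0, min_blocks >= 2, min_support >= 1, max_gap > 0)
  structure(list(scenario = scenario, loci = loci,
                 species_tree = species_tree, gene_trees = gene_trees,
                 reference_species = reference_species,
                 outgroup_species = outgroup_species,
                 derived_species = derived_species,
                 anchor_families = toupper(anchor_families), window = window,
                 min_blocks = min_blocks, min_support = min_support,
                 max_gap = max_gap, collapse_below = collapse_below,
                 nodes = nodes, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

log_stage <- function(lines, msg) {
  message("[paralogon] ", msg)
  c(lines, paste0(format(Sys.time(), "%H:%M:%S"), "  ", msg))
}

#' Run the full paralogon pipeline
#'
#' Executes: simulate-or-load, block definition around the anchor family,
#' family profiling and selection, per-family duplication dating, paralogy
#' graph and paralogon assembly, fission merging against the outgroup,
#' translocation detection in the derived species, lineage cutting, Dollo
#' reconstruction and the repertoire summary. Every stage's table is written
#' to `out_dir` (tab-separated, deterministic row order) together with a run
#' log recording parameters and seed. Identical configs give identical
#' outputs. A stage failure aborts with the stage named; tables already
#' written are retained.
#'
#' @param config A [run_config()].
#' @return A `paralogon_run` list with all stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lines <- character()
  stage <- "setup"
  result <- tryCatch({
    lines <- log_stage(lines, paste0(
      "run-all: scenario=", config$scenario %||% "files",
      " window=", config$window, " min_blocks=", config$min_blocks,
      " min_support=", config$min_support, " seed=", config$seed))

    stage <- "load"
    if (!is.null(config$scenario)) {
      dataset <- switch(config$scenario,
        "figure5" = figure5_dataset(),
        "figure5-rho-local" = figure5_dataset(rho_3r = FALSE),
        stop("unknown scenario: ", config$scenario, call. = FALSE))
      table <- dataset$locus_table
      stree <- dataset$species_tree
      gtrees <- dataset$gene_trees
    } else {
      dataset <- NULL
      table <- read_locus_table(config$loci)
      stree <- read_species_tree(config$species_tree)
      files <- sort(list.files(config$gene_trees, pattern = "\\.nwk$",
                               full.names = TRUE))
      gtrees <- stats::setNames(lapply(files, read_gene_tree),
                                toupper(sub("\\.nwk$", "", basename(files))))
    }
    lines <- log_stage(lines, paste0("loaded ", nrow(table), " loci, ",
                                     length(gtrees), " gene trees"))

    stage <- "blocks"
    ref <- dplyr::filter(table, .data$species == config$reference_species)
    per_family <- lapply(config$anchor_families, function(f) {
      anch <- dplyr::filter(ref, .data$family == f)
      if (!nrow(anch)) return(character())
      bl <- define_blocks(anch, window = config$window)
      select_families(profile_families(bl, table),
                      min_blocks = config$min_blocks)
    })
    selected <- pool_selections(per_family)
    anchors <- dplyr::filter(ref, .data$family %in% config$anchor_families)
    blocks <- define_blocks(anchors, window = config$window)
    profile <- profile_families(blocks, table)
    families <- union(selected, config$anchor_families)
    lines <- log_stage(lines, paste0(nrow(blocks), " blocks; ",
                                     length(selected), " families selected"))

    stage <- "date"
    calls <- lapply(gtrees[intersect(names(gtrees), c(families,
                                                      names(gtrees)))],
                    date_duplications, stree = stree, loci = table,
                    collapse_below = config$collapse_below,
                    local_gap = config$max_gap)
    verdicts <- dplyr::bind_rows(lapply(names(calls), function(f) {
      dplyr::mutate(family_verdict(calls[f], stree), family = f,
                    .before = 1)
    }))
    lines <- log_stage(lines, paste0(
      sum(vapply(calls, nrow, 1L)), " duplication calls in ",
      length(calls), " families"))

    stage <- "paralogon"
    graph <- build_paralogy_graph(blocks, families, gtrees, calls, table,
                                  window = "2R")
    groups <- assemble_paralogons(graph, min_support = config$min_support)
    orthologs <- map_orthologs(gtrees, calls)
    og_table <- dplyr::filter(table,
                              .data$species == config$outgroup_species)
    units <- detect_fission(blocks, table, og_table, orthologs,
                            min_support = config$min_support)
    lines <- log_stage(lines, paste0(
      max(groups$group), " paralogon group(s); ",
      length(unique(units$unit)), " ancestral unit(s)"))

    stage <- "translocations"
    der_table <- dplyr::filter(table,
                               .data$species == config$derived_species)
    transloc <- detect_translocations(der_table, og_table, orthologs,
                                      stree = stree)
    lines <- log_stage(lines, paste0(nrow(transloc),
                                     " translocation call(s)"))

    stage <- "reconstruct"
    lineages <- build_lineages(calls, gtrees, table)
    recon <- dollo_reconstruct(lineages, stree)
    repertoire <- scenario_summary(recon, config$nodes)
    lines <- log_stage(lines, paste0(nrow(lineages), " lineages; ",
                                     nrow(recon$losses), " losses placed"))

    list(dataset = dataset, table = table, species_tree = stree,
         blocks = blocks, profile = profile, selected = selected,
         calls = calls, verdicts = verdicts, graph = graph, groups = groups,
         orthologs = orthologs, units = units, translocations = transloc,
         lineages = lineages, recon = recon, repertoire = repertoire,
         config = config, log = lines)
  }, error = function(e) {
    stop("run_all failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run(result, config$out_dir)
  }
  structure(result, class = "paralogon_run")
}

# write all stage tables; deterministic row order throughout
write_run <- function(run, dir) {
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")))
  }
  write_locus_table(run$table, file.path(dir, "loci.tsv"))
  w(dplyr::select(dplyr::mutate(run$blocks,
                                anchors = vapply(run$blocks$anchors, paste,
                                                 "", collapse = ",")),
                  "block_id", "species", "chromosome", "start", "end",
                  "anchors"), "blocks")
  w(run$profile, "family_profile")
  w(tibble::tibble(family = run$selected), "selected_families")
  calls_tbl <- dplyr::bind_rows(lapply(names(run$calls), function(f) {
    dplyr::mutate(tibble::as_tibble(run$calls[[f]]), family = f,
                  .before = 1)
  }))
  w(dplyr::arrange(calls_tbl, .data$family, .data$node), "duplication_calls")
  w(dplyr::select(
    dplyr::mutate(run$verdicts,
                  verdicts = vapply(run$verdicts$verdicts, paste, "",
                                    collapse = ",")),
    "family", "n_trees", "verdicts", "aggregate", "undated"), "verdicts")
  w(tibble::as_tibble(run$groups), "paralogon_groups")
  w(run$units, "ancestral_units")
  tr <- dplyr::mutate(run$translocations,
                      locus_ids = vapply(run$translocations$locus_ids, paste,
                                         "", collapse = ","))
  w(tr, "translocations")
  lin <- dplyr::mutate(
    run$lineages,
    species = vapply(run$lineages$species, paste, "", collapse = ","),
    loci = vapply(run$lineages$loci, paste, "", collapse = ","))
  w(tibble::as_tibble(lin), "lineages")
  w(dplyr::arrange(run$recon$content, .data$node, .data$family), "content")
  w(run$recon$losses, "losses")
  w(run$repertoire, "repertoire")
  writeLines(run$log, file.path(dir, "run.log"))
  # cross-species synteny matrix: family x species, chromosomes carrying it
  synteny <- dplyr::summarise(
    dplyr::group_by(run$table, .data$family, .data$species),
    chromosomes = paste(sort(unique(.data$chromosome)), collapse = ","),
    .groups = "drop")
  synteny <- tidyr::pivot_wider(synteny, names_from = "species",
                                values_from = "chromosomes")
  w(dplyr::arrange(synteny, .data$family), "synteny_matrix")
  invisible(dir)
}

#' @export
print.paralogon_run <- function(x, ...) {
  cat("paralogon run (", x$config$scenario %||% "files", ")\n", sep = "")
  cat("  blocks:", nrow(x$blocks), " groups:", max(x$groups$group),
      " units:", length(unique(x$units$unit)), "\n")
  cat("  families dated:", length(x$calls),
      " translocations:", nrow(x$translocations), "\n")
  print(x$repertoire)
  invisible(x)
}
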