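#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy / summarise dating results
#'
#' `tidy()` returns the duplication-call table; `glance()` one row of window
#' counts.
#'
#' @param x A `dup_calls` object.
#' @param ... Unused.
#' @export
tidy.dup_calls <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("node", "species_node", "species_label",
                                 "window", "rule")])
}

#' @rdname tidy.dup_calls
#' @export
glance.dup_calls <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tibble::tibble(n_duplications = nrow(tb),
                 n_2R = sum(tb$window == "2R"),
                 n_3R = sum(tb$window == "3R"),
                 n_pre_window = sum(tb$window == "pre-window"),
                 n_local = sum(grepl("local$", tb$window)),
                 n_unresolved = sum(tb$window == "unresolved"))
}

#' Tidy / summarise a Dollo reconstruction
#'
#' `tidy()` returns the loss placements; `glance()` totals.
#'
#' @param x A `dollo_recon` object.
#' @param ... Unused.
#' @export
tidy.dollo_recon <- function(x, ...) x$losses

#' @rdname tidy.dollo_recon
#' @export
glance.dollo_recon <- function(x, ...) {
  tibble::tibble(n_lineages = nrow(x$lineages),
                 n_losses = nrow(x$losses),
                 n_families = dplyr::n_distinct(x$lineages$family),
                 n_flagged = sum(x$lineages$flagged))
}

#' Tidy / summarise paralogon groups
#'
#' `tidy()` returns block-to-group membership; `glance()` group counts.
#'
#' @param x A `paralogon_groups` object.
#' @param ... Unused.
#' @export
tidy.paralogon_groups <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("block_id", "group")])
}

#' @rdname tidy.paralogon_groups
#' @export
glance.paralogon_groups <- function(x, ...) {
  tb <- tidy.paralogon_groups(x)
  sizes <- table(tb$group)
  tibble::tibble(n_blocks = nrow(tb), n_groups = length(sizes),
                 largest_group = max(sizes),
                 min_support = attr(x, "min_support"))
}
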