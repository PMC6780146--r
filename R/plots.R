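#' Plot the peptide length distribution of an AHTP library
#'
#' Bar chart of entries per peptide length — the usual at-a-glance view of
#' a curated library (typically dominated by tripeptides).
#'
#' @param db AHTP database tibble.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(db) {
  dist <- length_distribution(db)
  ggplot2::ggplot(dist, ggplot2::aes(x = factor(.data$length),
                                     y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Peptide length (residues)", y = "Peptides",
                  title = "AHTP library length distribution") +
    ggplot2::theme_minimal()
}

#' Plot the most abundant peptides per species
#'
#' Faceted bar chart of each species' top peptides by occurrence count —
#' the per-species hit spectrum shortlist.
#'
#' @param comparison An `ahtp_comparison` from [compare_species()].
#' @param n Peptides per species (default 8).
#' @return A ggplot object.
#' @export
plot_top_peptides <- function(comparison, n = 8) {
  long <- comparison$peptides |>
    tidyr::pivot_longer(-"peptide", names_to = "species",
                        values_to = "n_hits")
  top <- long |>
    group_by(.data$species) |>
    arrange(dplyr::desc(.data$n_hits), .data$peptide, .by_group = TRUE) |>
    slice_head(n = n) |>
    ungroup()
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$peptide, .data$n_hits),
    y = .data$n_hits)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~species, scales = "free") +
    ggplot2::labs(x = NULL, y = "Hits",
                  title = "Most abundant AHTPs per species") +
    ggplot2::theme_minimal()
}

#' Plot functional-category counts of mapped proteins
#'
#' @param categories Tibble from [annotate_mapped()] (`category`,
#'   `n_proteins`), or a named list of them (one per species, faceted).
#' @return A ggplot object.
#' @export
plot_category_counts <- function(categories) {
  if (is.data.frame(categories)) {
    categories <- list(mapped = categories)
  }
  long <- bind_rows(categories, .id = "species")
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$category, .data$n_proteins),
    y = .data$n_proteins)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = NULL, y = "Mapped proteins",
                  title = "Functional categories of AHTP-mapped proteins") +
    ggplot2::theme_minimal()
}

#' Plot a cross-species comparison
#'
#' `which = "peptides"` (default) shows the per-peptide hit matrix as
#' grouped bars; `which = "stats"` shows the six summary statistics,
#' faceted on their own scales.
#'
#' @param object An `ahtp_comparison`.
#' @param which `"peptides"` or `"stats"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ahtp_comparison
#' @export
autoplot.ahtp_comparison <- function(object, which = c("peptides", "stats"),
                                     ...) {
  which <- match.arg(which)
  if (which == "peptides") {
    long <- object$peptides |>
      tidyr::pivot_longer(-"peptide", names_to = "species",
                          values_to = "n_hits")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$peptide, y = .data$n_hits,
                                       fill = .data$species)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "AHTP", y = "Hits",
                    title = "AHTP hit numbers by species") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                         hjust = 1))
  } else {
    long <- tidy.ahtp_comparison(object)
    ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$value)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = NULL, y = NULL,
                    title = "Whole-proteome AHTP mapping statistics") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}
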