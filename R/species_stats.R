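#' Summarise a species' mapping results
#'
#' Computes, per species, the standard comparative statistics of a
#' whole-proteome AHTP screen: total hits, number of mapped proteins
#' (proteins carrying at least one hit), total protein count, mapping rate
#' (mapped / total), average hits per mapped protein (total hits / mapped;
#' 0 when nothing mapped), number of distinct panel peptides found, the
#' per-peptide occurrence spectrum, and the number of mapped collagen
#' subunits. Ratios are carried at full precision; rounding to report
#' precision happens only in [format_summary_table()].
#'
#' @param hits Hit tibble from [map_peptides()].
#' @param proteome The proteome the hits were mapped against. Every
#'   `protein_id` in `hits` must exist in it (per species).
#' @param collagen_pattern Regular expression identifying a collagen subunit
#'   from the protein description, matched case-insensitively.
#' @return One row per species in `proteome`: columns `species`,
#'   `total_hits`, `mapped_protein_count`, `total_protein_count`,
#'   `mapping_rate`, `avg_hits_per_mapped`, `distinct_peptides_found`,
#'   `collagen_mapped_count`, and a list-column `peptide_counts` of
#'   per-peptide tibbles (`peptide`, `n`; `sum(n) == total_hits`).
#' @seealso [summarize_counts()], [compare_species()], [rank_proteins()]
#' @export
summarize_species <- function(hits, proteome,
                              collagen_pattern = "collagen") {
  species <- unique(proteome$species)
  rows <- purrr::map(species, function(sp) {
    prot <- filter(proteome, .data$species == sp)
    h <- filter(hits, .data$species == sp)
    orphan <- setdiff(h$protein_id, prot$protein_id)
    if (length(orphan)) {
      stop_integrity(paste0("Hits reference protein_id(s) absent from the ",
                            sp, " proteome: ",
                            paste(head(orphan, 5), collapse = ", ")))
    }
    mapped_ids <- unique(h$protein_id)
    pep <- count(h, .data$peptide, name = "n") |> arrange(.data$peptide)
    total_hits <- nrow(h)
    mapped <- length(mapped_ids)
    total <- nrow(prot)
    tibble(
      species = sp,
      total_hits = total_hits,
      mapped_protein_count = mapped,
      total_protein_count = total,
      mapping_rate = if (total > 0) mapped / total else 0,
      avg_hits_per_mapped = if (mapped > 0) total_hits / mapped else 0,
      distinct_peptides_found = nrow(pep),
      collagen_mapped_count = count_collagen(prot, mapped_ids,
                                             collagen_pattern),
      peptide_counts = list(pep)
    )
  })
  bind_rows(rows)
}

#' Build a species summary from published integer counts
#'
#' Desk-check helper: applies exactly the ratio logic of
#' [summarize_species()] to externally reported integer counts, so printed
#' mapping rates and per-protein averages can be reproduced from a printed
#' table without the underlying sequences.
#'
#' @param counts A data frame with columns `species`, `total_hits`,
#'   `mapped_protein_count`, `total_protein_count` (and optionally
#'   `collagen_mapped_count`).
#' @return A summary tibble as from [summarize_species()], without peptide
#'   spectra.
#' @export
#' @examples
#' summarize_counts(tibble::tibble(
#'   species = "white dolphin", total_hits = 27260,
#'   mapped_protein_count = 11323, total_protein_count = 18387))
summarize_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (!"collagen_mapped_count" %in% names(counts)) {
    counts$collagen_mapped_count <- NA_integer_
  }
  counts |>
    mutate(
      mapping_rate = ifelse(.data$total_protein_count > 0,
                            .data$mapped_protein_count /
                              .data$total_protein_count, 0),
      avg_hits_per_mapped = ifelse(.data$mapped_protein_count > 0,
                                   .data$total_hits /
                                     .data$mapped_protein_count, 0)
    ) |>
    select("species", "total_hits", "mapped_protein_count",
           "total_protein_count", "mapping_rate", "avg_hits_per_mapped",
           "collagen_mapped_count")
}

#' Count mapped collagen subunits
#'
#' A protein counts as a collagen subunit when its description matches
#' `pattern` case-insensitively (default: contains the token "collagen",
#' e.g. "collagen type IV alpha 5" or "Collagen alpha-1(VIII) chain").
#'
#' @param proteome Proteome tibble.
#' @param mapped_ids Protein ids with at least one hit (subset of
#'   `proteome$protein_id`).
#' @param pattern Regular expression applied to descriptions.
#' @return Number of mapped proteins whose description matches.
#' @export
count_collagen <- function(proteome, mapped_ids, pattern = "collagen") {
  sum(grepl(pattern,
            proteome$description[proteome$protein_id %in% mapped_ids],
            ignore.case = TRUE))
}

#' Rank proteins by AHTP hit abundance
#'
#' The proteins carrying the most panel-peptide occurrences — in mammalian
#' screens typically titin and collagen chains top this list.
#'
#' @param hits Hit tibble (one species).
#' @param proteome Matching proteome tibble.
#' @param n Number of proteins to return.
#' @inheritParams summarize_species
#' @return A tibble of the top `n` mapped proteins by `hit_count`
#'   descending (ties by `protein_id` ascending) with columns `protein_id`,
#'   `description`, `hit_count`, `distinct_peptides`, `is_collagen`. Only
#'   mapped proteins appear.
#' @export
rank_proteins <- function(hits, proteome, n = 20,
                          collagen_pattern = "collagen") {
  orphan <- setdiff(hits$protein_id, proteome$protein_id)
  if (length(orphan)) {
    stop_integrity(paste0("Hits reference protein_id(s) absent from the ",
                          "proteome: ", paste(head(orphan, 5), collapse = ", ")))
  }
  hits |>
    group_by(.data$protein_id) |>
    summarise(hit_count = n(),
              distinct_peptides = dplyr::n_distinct(.data$peptide),
              .groups = "drop") |>
    left_join(select(proteome, "protein_id", "description"),
              by = "protein_id") |>
    mutate(is_collagen = grepl(collagen_pattern, .data$description,
                               ignore.case = TRUE)) |>
    arrange(dplyr::desc(.data$hit_count), .data$protein_id) |>
    slice_head(n = n) |>
    select("protein_id", "description", "hit_count", "distinct_peptides",
           "is_collagen")
}

#' Most abundant peptides of a species
#'
#' @param summary One row of a [summarize_species()] result (or a one-row
#'   summary tibble).
#' @param n Number of peptides (default 8, the usual per-species shortlist).
#' @return A tibble `peptide`, `n` sorted by count descending, ties broken
#'   lexicographically; at most `min(n, distinct peptides found)` rows.
#' @export
top_n_peptides <- function(summary, n = 8) {
  if (n < 1) stop_argument("n must be >= 1")
  pep <- summary$peptide_counts[[1]]
  pep |>
    arrange(dplyr::desc(.data$n), .data$peptide) |>
    slice_head(n = n)
}

#' Cross-species comparison of mapping summaries
#'
#' Assembles the comparative report: the six summary statistics as rows with
#' one column per species, and the per-peptide count matrix (union of all
#' peptides observed in any species as rows, zero-filled where a peptide was
#' not found).
#'
#' @param summaries Summary tibble from [summarize_species()] (one row per
#'   species, unique labels) — several species' rows may be combined with
#'   `dplyr::bind_rows()`.
#' @return An object of class `ahtp_comparison`: a list with elements
#'   `stats` (tibble `parameter` x species, full precision) and `peptides`
#'   (tibble `peptide` x species of occurrence counts). Column sums of
#'   `peptides` equal each species' total hits.
#' @seealso [format_summary_table()], [autoplot.ahtp_comparison()]
#' @export
compare_species <- function(summaries) {
  if (nrow(summaries) < 1) stop_argument("Need at least one species summary")
  if (anyDuplicated(summaries$species)) {
    stop_argument("Duplicate species labels in summaries")
  }
  long <- summaries |>
    select("species", "total_hits", "mapped_protein_count",
           "total_protein_count", "mapping_rate", "avg_hits_per_mapped",
           "collagen_mapped_count") |>
    tidyr::pivot_longer(-"species", names_to = "parameter") |>
    tidyr::pivot_wider(names_from = "species", values_from = "value")
  pep <- summaries |>
    select("species", "peptide_counts") |>
    tidyr::unnest("peptide_counts") |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0L) |>
    arrange(.data$peptide)
  structure(list(stats = long, peptides = pep), class = "ahtp_comparison")
}

#' Render a comparison at report precision
#'
#' Rounds the two ratio rows (mapping rate, average hits per mapped
#' protein) half away from zero to `digits` decimals; count rows stay
#' integral. This is the only place rounding is applied.
#'
#' @param x An `ahtp_comparison` or a summary tibble.
#' @param digits Report precision (default 4 decimals).
#' @return A tibble, statistics as rows and species as columns.
#' @export
format_summary_table <- function(x, digits = 4) {
  if (inherits(x, "ahtp_comparison")) {
    stats <- x$stats
  } else {
    stats <- compare_species_counts(x)
  }
  ratio_rows <- stats$parameter %in% c("mapping_rate", "avg_hits_per_mapped")
  stats |>
    mutate(across(-"parameter",
                  ~ ifelse(ratio_rows, report_round(.x, digits), .x)))
}

# stats-only pivot for plain summary tibbles (no peptide spectra required)
compare_species_counts <- function(summaries) {
  summaries |>
    select(all_of(intersect(
      c("species", "total_hits", "mapped_protein_count",
        "total_protein_count", "mapping_rate", "avg_hits_per_mapped",
        "collagen_mapped_count"), names(summaries)))) |>
    tidyr::pivot_longer(-"species", names_to = "parameter") |>
    tidyr::pivot_wider(names_from = "species", values_from = "value")
}

#' @export
print.ahtp_comparison <- function(x, ...) {
  cat("AHTP cross-species comparison (", ncol(x$stats) - 1L,
      " species)\n\n", sep = "")
  print(format_summary_table(x))
  cat("\nPer-peptide counts: ", nrow(x$peptides), " peptides x ",
      ncol(x$peptides) - 1L, " species\n", sep = "")
  invisible(x)
}

#' Tabulate mapped proteins by functional category
#'
#' Joins mapped protein ids against a user-supplied annotation table
#' (protein id to category terms, one row per pair). Each mapped protein
#' contributes 1 to each of its categories; mapped proteins absent from the
#' annotation are counted under the reserved category `"unannotated"`.
#' Category assignment is consumed, never computed, here.
#'
#' @param mapped_ids Character vector of mapped protein ids, or a hit
#'   tibble (its distinct `protein_id`s are used).
#' @param annotation Data frame with columns `protein_id`, `category`.
#' @return A tibble `category`, `n_proteins`, with `"unannotated"` always
#'   present (possibly 0) and last.
#' @export
annotate_mapped <- function(mapped_ids, annotation) {
  if (is.data.frame(mapped_ids)) mapped_ids <- mapped_ids$protein_id
  mapped_ids <- unique(mapped_ids)
  ann <- annotation |>
    filter(.data$protein_id %in% mapped_ids) |>
    distinct(.data$protein_id, .data$category)
  counts <- ann |>
    count(.data$category, name = "n_proteins") |>
    arrange(.data$category)
  n_unann <- length(setdiff(mapped_ids, ann$protein_id))
  bind_rows(counts,
            tibble(category = "unannotated", n_proteins = n_unann))
}
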