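#' Read a curated AHTP database
#'
#' Loads a tab- or comma-separated peptide library with one row per verified
#' antihypertensive peptide (AHTP). The file must have a header with at least
#' `peptide_id` and `sequence` columns; `activity_um` (inhibitory
#' concentration in micromolar, lower = more active, typically an IC50) and
#' `source` (protein or food of origin) are optional and filled with `NA`
#' when absent.
#'
#' Sequences are uppercased before validation. Rows failing validation —
#' sequence shorter than 2 residues, characters outside the 20 canonical
#' amino-acid codes, or a non-positive activity — are dropped with a warning
#' that reports their file line numbers. Duplicate `peptide_id` values are an
#' error. Duplicate sequences across distinct entries are allowed: mapping
#' later collapses them to one search pattern and attributes hits to the
#' sequence, not the entry.
#'
#' @param path Path to the database file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param name Optional label for the database; defaults to the file name.
#' @return A tibble with columns `peptide_id`, `sequence`, `activity_um`,
#'   `source`, carrying the database label as attribute `db_name`.
#' @seealso [select_top_active()], [length_distribution()], [write_ahtp_db()]
#' @export
#' @examples
#' db <- read_ahtp_db(ahtpscan_example("ahtp_db_synthetic.tsv"))
#' nrow(db)
read_ahtp_db <- function(path, format = c("tsv", "csv"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_io(paste0("AHTP database file not found: ", path))
  }
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  needed <- c("peptide_id", "sequence")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop_format(paste0("AHTP database is missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (!"activity_um" %in% names(raw)) raw$activity_um <- NA_character_
  if (!"source" %in% names(raw)) raw$source <- NA_character_

  db <- raw |>
    select(all_of(c("peptide_id", "sequence", "activity_um", "source"))) |>
    mutate(
      sequence = toupper(.data$sequence),
      activity_um = suppressWarnings(as.numeric(.data$activity_um)),
      line = dplyr::row_number() + 1L  # header occupies line 1
    )

  bad <- !is_canonical(db$sequence) | nchar(db$sequence) < 2 |
    (!is.na(db$activity_um) & db$activity_um <= 0)
  if (any(bad)) {
    warn(paste0("Dropped ", sum(bad), " invalid AHTP row(s) at line(s): ",
                paste(db$line[bad], collapse = ", ")))
    db <- db[!bad, ]
  }
  if (nrow(db) == 0) {
    stop_format(paste0("No valid AHTP entries in ", path))
  }
  if (anyDuplicated(db$peptide_id)) {
    dup <- unique(db$peptide_id[duplicated(db$peptide_id)])
    stop_integrity(paste0("Duplicate peptide_id in AHTP database: ",
                          paste(dup, collapse = ", ")))
  }
  db <- select(db, -"line")
  attr(db, "db_name") <- name %||% basename(path)
  log_stage("load_ahtp_db", file = basename(path), n_entries = nrow(db))
  db
}

#' Write an AHTP database
#'
#' Writes the library back in the same TSV dialect [read_ahtp_db()] reads, so
#' that a write/read round trip reproduces the database field for field.
#'
#' @param db AHTP database tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ahtp_db <- function(db, path) {
  readr::write_tsv(db[, c("peptide_id", "sequence", "activity_um", "source")],
                   path, progress = FALSE)
  invisible(path)
}

#' Select the most active peptides as the screening panel
#'
#' Ranks entries by activity (micromolar inhibitory concentration; lower is
#' more active, the IC50 convention for ACE-inhibitory peptides) and keeps
#' the `n` most active. Entries without an activity value are excluded
#' before ranking; ties are broken by sequence, lexicographically ascending,
#' so the panel is deterministic.
#'
#' @param db AHTP database tibble from [read_ahtp_db()].
#' @param n Panel size (default 50, the usual top-active panel).
#' @return A tibble of `min(n, number of activity-bearing entries)` rows in
#'   ascending order of activity.
#' @export
#' @examples
#' db <- read_ahtp_db(ahtpscan_example("ahtp_db_synthetic.tsv"))
#' panel <- select_top_active(db, 50)
select_top_active <- function(db, n = 50) {
  if (n < 1) stop_argument("n must be >= 1")
  ranked <- filter(db, !is.na(.data$activity_um))
  if (nrow(ranked) == 0) {
    stop_argument(paste0("No entry carries an activity value; ",
                         "rank the panel yourself and pass it explicitly"))
  }
  ranked |>
    arrange(.data$activity_um, .data$sequence) |>
    slice_head(n = n)
}

#' Peptide length distribution of an AHTP library
#'
#' Tabulates entries by peptide length. Most verified AHTPs are tripeptides
#' and nearly all are shorter than 10 residues; this is the standard summary
#' of a curated library's composition.
#'
#' @param db AHTP database tibble.
#' @return A tibble with columns `length` and `n`, ascending in `length`;
#'   absent lengths are omitted, and `sum(n)` equals `nrow(db)`.
#' @export
length_distribution <- function(db) {
  if (nrow(db) == 0) return(tibble(length = integer(), n = integer()))
  db |>
    mutate(length = nchar(.data$sequence)) |>
    count(.data$length) |>
    arrange(.data$length)
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
ahtpscan_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "ahtpscan"))
  } else {
    system.file("extdata", file, package = "ahtpscan", mustWork = TRUE)
  }
}
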