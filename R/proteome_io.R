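#' Read a species proteome from protein FASTA
#'
#' Parses a whole-proteome protein FASTA into a tibble, one row per record.
#' The protein identifier is the first whitespace-delimited token of the
#' header; the remainder of the header is kept as the description (needed
#' downstream for collagen/titin detection). Sequences are uppercased and
#' stop characters (`*`) are stripped — translated gene sets often retain
#' terminal or internal stops, and a peptide must never match across a stop
#' position. Ambiguity letters (B, J, O, U, X, Z) are retained; panel
#' peptides are canonical-only, so an ambiguity letter acts as a match
#' breaker. Records whose sequence is empty after sanitation are dropped.
#' Counts of stripped stops and dropped records are logged.
#'
#' No redundancy collapsing is performed: every record counts toward the
#' species' total protein number, matching the convention of using a
#' downloaded gene set as-is.
#'
#' @param path Path to a protein FASTA file.
#' @param species Species label attached to every record (supplied
#'   explicitly, never inferred from the file name).
#' @return A tibble with columns `species`, `protein_id`, `description`,
#'   `sequence`, `length`.
#' @seealso [write_proteome_fasta()], [map_peptides()]
#' @export
read_proteome_fasta <- function(path, species) {
  if (!file.exists(path)) stop_io(paste0("FASTA file not found: ", path))
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0 || !startsWith(trimws(first[nonblank[1]]), ">")) {
    stop_format(paste0("Not FASTA: no '>' header at line ",
                       if (length(nonblank)) nonblank[1] else 1L,
                       " of ", path))
  }
  aa <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_format(paste0("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  )
  headers <- names(aa)
  protein_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(protein_id))) {
    stop_format(paste0("Empty FASTA header in ", path))
  }
  if (anyDuplicated(protein_id)) {
    dup <- unique(protein_id[duplicated(protein_id)])
    stop_integrity(paste0("Duplicate protein_id in ", path, ": ",
                          paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(aa))
  n_stops <- sum(stringr::str_count(seqs, stringr::fixed("*")))
  if (n_stops > 0) seqs <- gsub("*", "", seqs, fixed = TRUE)
  keep <- nzchar(seqs)
  n_empty <- sum(!keep)
  proteome <- tibble(
    species = species,
    protein_id = protein_id[keep],
    description = unname(description[keep]),
    sequence = unname(seqs[keep]),
    length = nchar(unname(seqs[keep]))
  )
  log_stage("read_proteome", species = species, n_proteins = nrow(proteome),
            stops_removed = n_stops, empty_dropped = n_empty)
  proteome
}

#' Write a proteome as wrapped FASTA
#'
#' Writes one record per protein, header `>` + `protein_id` (+ a space and
#' the description when non-empty), sequence wrapped at 60 columns.
#' `read_proteome_fasta(write_proteome_fasta(p))` reproduces `p` field for
#' field.
#'
#' @param proteome Proteome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_io(paste0("Cannot write ", path)))
  on.exit(close(con))
  headers <- paste0(">", proteome$protein_id,
                    ifelse(nzchar(proteome$description),
                           paste0(" ", proteome$description), ""))
  lines <- purrr::map2(headers, proteome$sequence, function(h, s) {
    starts <- seq(1L, nchar(s), by = 60L)
    c(h, substring(s, starts, pmin(starts + 59L, nchar(s))))
  })
  writeLines(unlist(lines), con, sep = "\n")
  invisible(path)
}
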