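#' Map a peptide panel against a proteome (in situ mapping)
#'
#' Locates every exact occurrence of every panel peptide in every protein
#' and records its coordinates — the core screening step. All occurrences
#' are reported: overlapping occurrences of one peptide count separately
#' (`"AAAA"` contains `"AA"` three times) and co-located occurrences of
#' different peptides each count. Matching is case-exact on uppercased
#' input; a protein is scanned independently of all other records, so no
#' match ever spans two records. Ambiguity letters in the proteome never
#' match a canonical panel residue.
#'
#' The matcher runs one finite-automaton pass per pattern over the whole
#' protein set (Biostrings); its contract is defined purely by exact
#' equivalence with the reference [naive_scan()].
#'
#' @param proteome Proteome tibble from [read_proteome_fasta()] or
#'   [generate_proteome()]. May contain several species; records are scanned
#'   in input order.
#' @param panel Character vector of peptide sequences, or an AHTP database
#'   tibble (its unique sequences are used — hits are attributed to the
#'   sequence, not the database entry). Each peptide must be at least 2
#'   residues over the 20 canonical amino-acid codes.
#' @return A hit tibble with columns `species`, `peptide`, `protein_id`,
#'   `start`, `end` (1-based, inclusive; `end = start + nchar(peptide) - 1`),
#'   ordered by protein input order, then `start`, then `peptide`.
#' @seealso [naive_scan()], [summarize_species()], [write_hits()]
#' @export
#' @examples
#' prot <- tibble::tibble(species = "demo", protein_id = "p1",
#'                        description = "", sequence = "AGLPGLP", length = 7)
#' map_peptides(prot, c("GLP", "LGP"))
map_peptides <- function(proteome, panel) {
  panel <- as_panel(panel)
  if (nrow(proteome) == 0) return(empty_hits())
  subject <- Biostrings::AAStringSet(proteome$sequence)
  hits <- purrr::map(panel, function(pep) {
    idx <- Biostrings::startIndex(Biostrings::vmatchPattern(pep, subject))
    lens <- lengths(idx)
    if (sum(lens) == 0) return(NULL)
    row <- rep.int(seq_len(nrow(proteome)), lens)
    tibble(row = row, peptide = pep, start = unlist(idx, use.names = FALSE))
  })
  finalize_hits(hits, proteome)
}

#' Reference sliding-window peptide scan
#'
#' The correctness oracle for [map_peptides()]: the same contract,
#' implemented by direct window-by-window string comparison with no indexing
#' structure. Slower, trivially auditable; every other component that needs
#' independently verified occurrences (synthetic ground truth, equivalence
#' tests) uses this scan.
#'
#' @inheritParams map_peptides
#' @return A hit tibble identical in contract to [map_peptides()].
#' @export
naive_scan <- function(proteome, panel) {
  panel <- as_panel(panel)
  if (nrow(proteome) == 0) return(empty_hits())
  by_len <- split(panel, nchar(panel))
  hits <- purrr::imap(proteome$sequence, function(s, i) {
    L <- nchar(s)
    purrr::imap(by_len, function(peps, klab) {
      k <- as.integer(klab)
      if (k > L) return(NULL)
      windows <- substring(s, 1:(L - k + 1L), k:L)
      purrr::map(peps, function(pep) {
        at <- which(windows == pep)
        if (length(at) == 0) return(NULL)
        tibble(row = i, peptide = pep, start = at)
      })
    })
  })
  finalize_hits(unlist(unlist(hits, recursive = FALSE), recursive = FALSE),
                proteome)
}

as_panel <- function(panel) {
  if (is.data.frame(panel)) panel <- panel$sequence
  panel <- unique(toupper(as.character(panel)))
  if (length(panel) == 0) stop_argument("Panel is empty")
  bad <- panel[!is_canonical(panel) | nchar(panel) < 2]
  if (length(bad)) {
    stop_argument(paste0("Panel sequence(s) invalid (non-canonical or ",
                         "shorter than 2 residues): ",
                         paste(bad, collapse = ", ")))
  }
  panel
}

empty_hits <- function() {
  tibble(species = character(), peptide = character(),
         protein_id = character(), start = integer(), end = integer())
}

finalize_hits <- function(hit_list, proteome) {
  hits <- bind_rows(hit_list)
  if (nrow(hits) == 0) return(empty_hits())
  hits |>
    arrange(.data$row, .data$start, .data$peptide) |>
    mutate(species = proteome$species[.data$row],
           protein_id = proteome$protein_id[.data$row],
           start = as.integer(.data$start),
           end = .data$start + nchar(.data$peptide) - 1L) |>
    select("species", "peptide", "protein_id", "start", "end")
}

#' Write a hit table to TSV
#'
#' Default export is biologist-facing 1-based inclusive coordinates
#' (columns `start_1based`, `end_1based`); `coords = "bed"` switches to a
#' BED-like 0-based half-open layout (`protein_id`, `start`, `end`,
#' `peptide`, `species`).
#'
#' @param hits Hit tibble from [map_peptides()].
#' @param path Output path.
#' @param coords `"one_based"` (default) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, coords = c("one_based", "bed")) {
  coords <- match.arg(coords)
  out <- if (coords == "one_based") {
    tibble(species = hits$species, peptide = hits$peptide,
           protein_id = hits$protein_id,
           start_1based = hits$start, end_1based = hits$end)
  } else {
    tibble(protein_id = hits$protein_id, start = hits$start - 1L,
           end = hits$end, peptide = hits$peptide, species = hits$species)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
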