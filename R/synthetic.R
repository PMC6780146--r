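#' Background amino-acid frequency presets
#'
#' `"uniform"` gives equal probability to the 20 canonical residues —
#' analytically convenient, since a length-k peptide is then expected
#' `(L - k + 1) / 20^k` times in a random length-L protein. `"vertebrate"`
#' is a Swiss-Prot-style average vertebrate composition (normalised).
#'
#' @param preset `"uniform"` or `"vertebrate"`.
#' @return Named numeric vector over the 20 canonical residues, summing
#'   to 1.
#' @export
ahtp_background <- function(preset = c("uniform", "vertebrate")) {
  preset <- match.arg(preset)
  if (preset == "uniform") {
    return(setNames(rep(1 / 20, 20), AA_LETTERS))
  }
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.36, V = 6.86,
         W = 1.10, Y = 2.92)
  f / sum(f)
}

#' Specify a synthetic proteome
#'
#' Bundles and validates the parameters of the synthetic proteome
#' generator: protein count, a truncated log-normal length model, background
#' residue frequencies, a planting plan (which peptides to write into the
#' background, how many copies), the fraction of proteins labelled with a
#' collagen-style description, and the seed.
#'
#' @param n_proteins Number of protein records.
#' @param length_meanlog,length_sdlog Log-normal location and scale of
#'   protein length (residues); draws outside `length_range` are redrawn.
#'   Defaults emulate a vertebrate gene set (median ~500 aa).
#' @param length_range Truncation bounds, default `c(20, 50000)`.
#' @param background_freqs Named probability vector over (a subset of) the
#'   20 canonical residues, summing to 1 within 1e-9. Default uniform; see
#'   [ahtp_background()]. Restricting the support (e.g. omitting `L`) makes
#'   chosen peptides provably absent from the background.
#' @param plant_plan `NULL`, or a data frame with columns `peptide`,
#'   `copies`, and optionally `fraction` (the fraction of proteins eligible
#'   to receive that peptide's copies; `NA` = all). Copies of all planted
#'   peptides are placed at non-overlapping positions.
#' @param collagen_fraction Fraction of proteins whose description is set to
#'   `"collagen type IV alpha 5"`; exactly
#'   `floor(collagen_fraction * n_proteins)` records are labelled, the rest
#'   read `"hypothetical protein"`.
#' @param species Species label of the generated proteome.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A validated object of class `synthetic_spec`.
#' @seealso [generate_proteome()]
#' @export
synthetic_spec <- function(n_proteins,
                           length_meanlog = 6.2,
                           length_sdlog = 0.6,
                           length_range = c(20, 50000),
                           background_freqs = NULL,
                           plant_plan = NULL,
                           collagen_fraction = 0,
                           species = "synthetic",
                           seed = 1L) {
  if (n_proteins < 1) stop_argument("n_proteins must be >= 1")
  background_freqs <- background_freqs %||% ahtp_background("uniform")
  if (is.null(names(background_freqs)) ||
      !all(names(background_freqs) %in% AA_LETTERS)) {
    stop_argument("background_freqs must be named with canonical residues")
  }
  if (any(background_freqs < 0) ||
      abs(sum(background_freqs) - 1) > 1e-9) {
    stop_argument("background_freqs must be non-negative and sum to 1")
  }
  if (!is.null(plant_plan)) {
    plant_plan <- as_tibble(plant_plan)
    if (!all(c("peptide", "copies") %in% names(plant_plan))) {
      stop_argument("plant_plan needs columns peptide and copies")
    }
    if (!"fraction" %in% names(plant_plan)) plant_plan$fraction <- NA_real_
    plant_plan$peptide <- toupper(plant_plan$peptide)
    bad <- plant_plan$peptide[!is_canonical(plant_plan$peptide) |
                                nchar(plant_plan$peptide) < 2]
    if (length(bad)) {
      stop_argument(paste0("Non-canonical plant peptide(s): ",
                           paste(bad, collapse = ", ")))
    }
  }
  if (collagen_fraction < 0 || collagen_fraction > 1) {
    stop_argument("collagen_fraction must be in [0, 1]")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 length_range = length_range,
                 background_freqs = background_freqs,
                 plant_plan = plant_plan,
                 collagen_fraction = collagen_fraction,
                 species = species,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

COLLAGEN_DESC <- "collagen type IV alpha 5"

#' Generate a synthetic proteome with oracle-verified ground truth
#'
#' Draws protein lengths from the truncated log-normal model, fills
#' sequences i.i.d. from the background frequencies, labels a fixed
#' fraction of records with a collagen-style description, then overwrites
#' non-overlapping windows at uniformly chosen offsets with the planted
#' peptides. Ground truth is finalised by running the reference
#' [naive_scan()] over the final sequences: planting can create incidental
#' occurrences at window boundaries, so the truth is never assumed from the
#' plan. Hits at planted coordinates are classed `planted`, all others
#' `background`; their peptide-wise sum is exactly what [map_peptides()]
#' must report.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `proteome` (tibble as from
#'   [read_proteome_fasta()]) and `truth`, an object of class `ahtp_truth`
#'   with elements `planted_hits`, `background_hits` (hit tibbles) and
#'   `per_peptide_totals` (tibble `peptide`, `n`).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_proteome_impl(spec))
}

generate_proteome_impl <- function(spec) {
  n <- spec$n_proteins
  lens <- round(rlnorm(n, spec$length_meanlog, spec$length_sdlog))
  for (i in 1:100) {
    out <- lens < spec$length_range[1] | lens > spec$length_range[2]
    if (!any(out)) break
    lens[out] <- round(rlnorm(sum(out), spec$length_meanlog,
                              spec$length_sdlog))
  }
  lens <- as.integer(pmin(pmax(lens, spec$length_range[1]),
                          spec$length_range[2]))
  freqs <- spec$background_freqs
  big <- paste(sample(names(freqs), sum(lens), replace = TRUE,
                      prob = freqs), collapse = "")
  ends <- cumsum(lens)
  seqs <- substring(big, ends - lens + 1L, ends)

  desc <- rep("hypothetical protein", n)
  n_col <- floor(spec$collagen_fraction * n)
  if (n_col > 0) desc[sample.int(n, n_col)] <- COLLAGEN_DESC

  ids <- sprintf("syn%05d", seq_len(n))
  planted <- list()
  if (!is.null(spec$plant_plan) && nrow(spec$plant_plan) > 0) {
    occupied <- vector("list", n)  # planted [start, end] intervals
    for (r in seq_len(nrow(spec$plant_plan))) {
      pep <- spec$plant_plan$peptide[r]
      copies <- spec$plant_plan$copies[r]
      frac <- spec$plant_plan$fraction[r]
      k <- nchar(pep)
      eligible <- which(lens >= k)
      if (length(eligible) == 0) {
        stop_argument(paste0("Cannot plant ", pep,
                             ": longer than every protein"))
      }
      if (!is.na(frac)) {
        n_target <- max(1L, ceiling(frac * n))
        eligible <- eligible[eligible %in%
                               sample.int(n, min(n_target, n))]
        if (length(eligible) == 0) {
          stop_argument(paste0("No eligible protein for ", pep,
                               " at fraction ", frac))
        }
      }
      for (cp in seq_len(copies)) {
        placed <- FALSE
        for (attempt in 1:2000) {
          p <- if (length(eligible) == 1) eligible else sample(eligible, 1)
          s <- sample.int(lens[p] - k + 1L, 1)
          e <- s + k - 1L
          occ <- occupied[[p]]
          clash <- !is.null(occ) && any(s <= occ[, 2] & e >= occ[, 1])
          if (!clash) {
            substr(seqs[p], s, e) <- pep
            occupied[[p]] <- rbind(occ, c(s, e))
            planted[[length(planted) + 1L]] <-
              tibble(species = spec$species, peptide = pep,
                     protein_id = ids[p], start = s, end = e)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop_argument(paste0("Could not place all copies of ", pep,
                               " without overlap; plan is infeasible"))
        }
      }
    }
  }

  proteome <- tibble(species = spec$species, protein_id = ids,
                     description = desc, sequence = seqs, length = lens)
  planted_hits <- if (length(planted)) {
    bind_rows(planted) |> arrange(match(.data$protein_id, ids),
                                  .data$start, .data$peptide)
  } else empty_hits()

  if (nrow(planted_hits) > 0) {
    all_hits <- naive_scan(proteome, unique(planted_hits$peptide))
    background_hits <- anti_join(
      all_hits, planted_hits,
      by = c("species", "peptide", "protein_id", "start", "end"))
    totals <- count(all_hits, .data$peptide, name = "n") |>
      arrange(.data$peptide)
  } else {
    background_hits <- empty_hits()
    totals <- tibble(peptide = character(), n = integer())
  }
  truth <- structure(list(planted_hits = planted_hits,
                          background_hits = background_hits,
                          per_peptide_totals = totals),
                     class = "ahtp_truth")
  log_stage("generate_proteome", species = spec$species, n_proteins = n,
            residues = sum(lens), planted = nrow(planted_hits))
  list(proteome = proteome, truth = truth)
}

#' Write/read synthetic ground truth
#'
#' One TSV holding both the localized hits (1-based coordinates, with an
#' `origin` column distinguishing planted from incidental background
#' occurrences) and the per-peptide total rows (`origin = "total"`). The
#' round trip through [read_truth()] is lossless.
#'
#' @param truth An `ahtp_truth` object from [generate_proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  hit_rows <- bind_rows(
    mutate(truth$planted_hits, origin = "planted"),
    mutate(truth$background_hits, origin = "background"))
  rows <- bind_rows(
    tibble(origin = hit_rows$origin, species = hit_rows$species,
           peptide = hit_rows$peptide, protein_id = hit_rows$protein_id,
           start = hit_rows$start, end = hit_rows$end, n = NA_integer_),
    tibble(origin = "total", species = NA_character_,
           peptide = truth$per_peptide_totals$peptide,
           protein_id = NA_character_, start = NA_integer_,
           end = NA_integer_, n = truth$per_peptide_totals$n))
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  rows <- readr::read_tsv(path, col_types = readr::cols(
    origin = readr::col_character(), species = readr::col_character(),
    peptide = readr::col_character(), protein_id = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    n = readr::col_integer()), progress = FALSE)
  pick <- function(o) {
    rows |>
      filter(.data$origin == o) |>
      select("species", "peptide", "protein_id", "start", "end")
  }
  structure(list(
    planted_hits = pick("planted"),
    background_hits = pick("background"),
    per_peptide_totals = rows |>
      filter(.data$origin == "total") |>
      select("peptide", "n")),
    class = "ahtp_truth")
}
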