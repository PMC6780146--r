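#' Run the full multi-species AHTP screen
#'
#' End-to-end orchestration: load the AHTP library, select the top-`n`
#' active panel (unless an explicit panel is given), map the panel against
#' each species' proteome, and write per-species hit tables, protein
#' rankings, the cross-species summary at report precision, the per-peptide
#' count matrix, and (when annotation tables are supplied)
#' functional-category counts. On any error, files already written for this
#' run are removed so no partial output survives.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   keys: `db` (AHTP database path), `top_n` (default 50), `panel`
#'   (optional explicit peptide vector, bypassing activity ranking),
#'   `proteomes` (named list, species label -> FASTA path), `annotations`
#'   (optional named list, species label -> annotation TSV with columns
#'   `protein_id`, `category`), `out_dir`, `digits` (report precision,
#'   default 4), `collagen_pattern` (default `"collagen"`).
#' @return Invisibly, an object of class `ahtp_screen`: list with `panel`,
#'   `summaries` (tibble, one row per species), `comparison`
#'   (`ahtp_comparison`), `ranked` and `categories` (named lists of
#'   tibbles), and `files` (paths written). Has [tidy()] and [glance()]
#'   methods.
#' @seealso [run_simulate()], [map_peptides()], [compare_species()]
#' @export
run_screen <- function(config) {
  cfg <- load_config(config)
  species <- names(cfg$proteomes)
  if (is.null(species) || any(!nzchar(species))) {
    stop_argument("Every proteome needs a species label (named list)")
  }
  if (anyDuplicated(species)) {
    stop_argument("Duplicate species labels in config")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  note <- function(path) { written <<- c(written, path); path }

  result <- tryCatch({
    if (is.null(cfg$panel)) {
      db <- read_ahtp_db(cfg$db)
      panel_db <- select_top_active(db, cfg$top_n)
      panel <- unique(panel_db$sequence)
    } else {
      panel <- as_panel(cfg$panel)
    }
    log_stage("panel", size = length(panel))

    summaries <- list()
    ranked <- list()
    categories <- list()
    for (sp in species) {
      prot <- read_proteome_fasta(cfg$proteomes[[sp]], sp)
      hits <- map_peptides(prot, panel)
      log_stage("map", species = sp, hits = nrow(hits))
      write_hits(hits, note(out_path(cfg$out_dir, sp, "hits.tsv")))
      smry <- summarize_species(hits, prot, cfg$collagen_pattern)
      summaries[[sp]] <- smry
      top <- rank_proteins(hits, prot, n = 20, cfg$collagen_pattern)
      ranked[[sp]] <- top
      readr::write_tsv(top, note(out_path(cfg$out_dir, sp,
                                          "top_proteins.tsv")),
                       progress = FALSE)
      if (!is.null(cfg$annotations[[sp]])) {
        ann <- readr::read_tsv(cfg$annotations[[sp]],
                               col_types = readr::cols(
                                 .default = readr::col_character()),
                               progress = FALSE)
        cats <- annotate_mapped(hits, ann)
        categories[[sp]] <- cats
        readr::write_tsv(cats, note(out_path(cfg$out_dir, sp,
                                             "categories.tsv")),
                         progress = FALSE)
      }
    }
    summaries <- bind_rows(summaries)
    comparison <- compare_species(summaries)
    readr::write_tsv(format_summary_table(comparison, cfg$digits),
                     note(file.path(cfg$out_dir, "summary_table.tsv")),
                     progress = FALSE)
    readr::write_tsv(comparison$peptides,
                     note(file.path(cfg$out_dir, "peptide_matrix.tsv")),
                     progress = FALSE)
    structure(list(panel = panel, summaries = summaries,
                   comparison = comparison, ranked = ranked,
                   categories = categories, out_dir = cfg$out_dir,
                   files = written),
              class = "ahtp_screen")
  }, error = function(e) {
    unlink(written)
    abort(paste0("Screen failed; partial outputs removed: ",
                 conditionMessage(e)), class = "ahtpscan_error_screen",
          parent = e)
  })
  log_stage("screen_done", species = length(species),
            files = length(written))
  invisible(result)
}

out_path <- function(dir, species, suffix) {
  file.path(dir, paste0(gsub("[^A-Za-z0-9._-]+", "_", species), "_",
                        suffix))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_io(paste0("Config not found: ", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(top_n = 50, digits = 4, collagen_pattern = "collagen",
                   panel = NULL, annotations = list(),
                   out_dir = "ahtpscan_out")
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$proteomes) || length(cfg$proteomes) == 0) {
    stop_argument("Config must list at least one proteome")
  }
  if (is.null(cfg$panel) && is.null(cfg$db)) {
    stop_argument("Config needs either db or an explicit panel")
  }
  cfg
}

#' Generate and write a synthetic proteome from a spec file
#'
#' Thin orchestration over [generate_proteome()]: reads a YAML spec (keys
#' mirroring [synthetic_spec()] arguments; `background` may be a preset
#' name or a residue->probability map; `plant_plan` a list of
#' `{peptide, copies, fraction}`), writes the proteome FASTA and the
#' ground-truth TSV.
#'
#' @param spec A `synthetic_spec`, or the path to a YAML spec file.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `proteome_path`, `truth_path`, and the
#'   generated `proteome`/`truth` objects.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_synthetic_spec(spec)
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_proteome(spec)
  fasta <- out_path(out_dir, spec$species, "proteome.faa")
  truth <- out_path(out_dir, spec$species, "truth.tsv")
  write_proteome_fasta(gen$proteome, fasta)
  write_truth(gen$truth, truth)
  log_stage("simulate", species = spec$species,
            n_proteins = nrow(gen$proteome))
  invisible(list(proteome_path = fasta, truth_path = truth,
                 proteome = gen$proteome, truth = gen$truth))
}

read_synthetic_spec <- function(path) {
  if (!file.exists(path)) stop_io(paste0("Spec file not found: ", path))
  y <- yaml::read_yaml(path)
  bg <- y$background
  if (is.character(bg)) bg <- ahtp_background(bg)
  if (is.list(bg)) bg <- unlist(bg)
  plan <- if (!is.null(y$plant_plan)) {
    bind_rows(purrr::map(y$plant_plan, function(p) {
      tibble(peptide = p$peptide, copies = p$copies,
             fraction = p$fraction %||% NA_real_)
    }))
  }
  synthetic_spec(
    n_proteins = y$n_proteins,
    length_meanlog = y$length_meanlog %||% 6.2,
    length_sdlog = y$length_sdlog %||% 0.6,
    length_range = unlist(y$length_range %||% c(20, 50000)),
    background_freqs = bg,
    plant_plan = plan,
    collagen_fraction = y$collagen_fraction %||% 0,
    species = y$species %||% "synthetic",
    seed = y$seed %||% 1L)
}

#' @export
print.ahtp_screen <- function(x, ...) {
  cat("AHTP screen: ", length(x$panel), "-peptide panel, ",
      nrow(x$summaries), " species\n", sep = "")
  print(format_summary_table(x$comparison))
  invisible(x)
}

#' Tidy a screen result
#'
#' @param x An `ahtp_screen` object.
#' @param ... Unused.
#' @return One row per species with the summary statistics (the peptide
#'   spectra list-column dropped).
#' @method tidy ahtp_screen
#' @export
tidy.ahtp_screen <- function(x, ...) {
  select(x$summaries, -"peptide_counts")
}

#' @rdname tidy.ahtp_screen
#' @return For `glance()`: a one-row tibble with `n_species`,
#'   `panel_size`, `total_hits`, and `distinct_peptides` found anywhere.
#' @method glance ahtp_screen
#' @export
glance.ahtp_screen <- function(x, ...) {
  tibble(n_species = nrow(x$summaries),
         panel_size = length(x$panel),
         total_hits = sum(x$summaries$total_hits),
         distinct_peptides = nrow(x$comparison$peptides))
}

#' Tidy a cross-species comparison
#'
#' @param x An `ahtp_comparison` object.
#' @param ... Unused.
#' @return Long tibble with columns `parameter`, `species`, `value`.
#' @method tidy ahtp_comparison
#' @export
tidy.ahtp_comparison <- function(x, ...) {
  tidyr::pivot_longer(x$stats, -"parameter", names_to = "species")
}
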