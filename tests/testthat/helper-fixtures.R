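# Shared fixtures: tiny hand-checkable proteomes and randomised generators.
# All randomness in tests runs under withr::local_seed / with_seed.

options(ahtpscan.quiet = TRUE)  # re-enabled locally where logging is tested

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

tiny_proteome <- function(seqs, species = "test",
                          descriptions = rep("", length(seqs))) {
  tibble::tibble(
    species = species,
    protein_id = names(seqs) %||% paste0("p", seq_along(seqs)),
    description = descriptions,
    sequence = unname(seqs),
    length = nchar(unname(seqs))
  )
}

random_proteome <- function(n_proteins, max_len = 200, species = "rand") {
  lens <- sample.int(max_len + 1L, n_proteins, replace = TRUE) - 1L
  seqs <- vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, character(1))
  keep <- lens > 0
  tiny_proteome(setNames(seqs[keep], sprintf("p%04d", which(keep))),
                species = species)
}

random_panel <- function(n_pep, min_len = 2, max_len = 11) {
  unique(vapply(seq_len(n_pep), function(i) {
    k <- sample(min_len:max_len, 1)
    paste(sample(AA20, k, replace = TRUE), collapse = "")
  }, character(1)))
}

empty_hits_fixture <- function() {
  tibble::tibble(species = character(), peptide = character(),
                 protein_id = character(), start = integer(),
                 end = integer())
}

fixture_db_path <- function() {
  system.file("extdata", "ahtp_db_synthetic.tsv", package = "ahtpscan")
}

`%||%` <- rlang::`%||%`
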