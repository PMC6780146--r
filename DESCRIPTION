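Package: ahtpscan
Title: Proteome-Wide In Situ Mapping of Antihypertensive Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput screening of short bioactive antihypertensive
    peptides (AHTPs) against whole-proteome protein sets. Loads and validates
    a curated AHTP library, selects the most active panel by inhibitory
    concentration, locates every exact occurrence of every panel peptide in
    each species' proteome (overlaps included, with coordinates), and
    computes comparative per-species statistics: total hits, mapped proteins,
    mapping rate, average hits per mapped protein, collagen-subunit counts,
    per-peptide hit spectra, protein rankings and functional-category
    tabulations. Includes a synthetic proteome generator with planted
    peptide occurrences and oracle-verified ground truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
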