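---
title: "Methods: proteome-wide AHTP screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide AHTP screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahtpscan)
```

## The screening model

`ahtpscan` treats AHTP discovery as an exact-substring census. The inputs
are a curated library of verified antihypertensive peptides and one
annotated proteome per species. The screen asks, for each species: how
often, and where, do the most active library peptides occur verbatim inside
the species' proteins?

The biological assumptions behind reading exact occurrence as potential are:

* AHTPs are released by proteolysis of single proteins, so only exact,
  contiguous occurrence within one protein record counts — a match never
  spans two records, and stop characters (`*`) are removed before mapping
  precisely so that no peptide can appear to bridge a stop.
* Occurrence count is the quantity of interest, not merely presence:
  a protein containing a peptide five times can, in principle, yield five
  copies per molecule digested. Hence **every** start position is a hit,
  overlapping occurrences included (`AAAA` contains `AA` three times).
  Nothing in the definition of in-situ mapping privileges one occurrence of
  an overlapping pair over the other, and per-occurrence records are what
  "localization is marked" means; per-protein and per-peptide aggregations
  are all derived downstream from the per-occurrence table.
* Activity ranking uses the IC50 convention (micromolar; lower = more
  active), the standard scale for ACE-inhibitory peptides.

### Panel selection

`select_top_active(db, n = 50)` keeps the `n` entries with the lowest
activity value. Entries without an activity are excluded from ranking (if
none carries one, the caller is asked to pass the panel explicitly). Ties
are broken by sequence, lexicographically — determinism was the only
requirement, and sequence order is reproducible across platforms, unlike
file order or hash order. Duplicate sequences across database entries are
collapsed to a single search pattern; hits belong to the peptide sequence,
not to a database entry, because per-species hit totals are per-sequence
quantities.

### Mapping

`map_peptides()` scans an `AAStringSet` of the proteome once per pattern
with Biostrings' exact matcher. The contract, however, is defined purely by
equivalence with `naive_scan()` — a window-by-window string comparison with
no indexing structure — so any correct implementation qualifies, and the
test suite enforces exact equality of the two on hundreds of randomized
instances (mixed protein lengths 0–1000, panels of 1–50 peptides of length
2–11, including low-complexity alphabets where overlaps are dense).

Coordinates are 1-based inclusive throughout the R interface, the native
convention of Biostrings/IRanges and of biologist-facing tables; exports
name the columns `start_1based` / `end_1based`, and a BED-style 0-based
half-open export is available behind a flag. Proteome ambiguity letters
(B, J, O, U, X, Z) are retained in sequences but can never equal a
canonical panel residue, so they act as match breakers rather than
wildcards — the conservative choice for a screen that promises exact
occurrence.

### Summary statistics

For each species: total hits $H$, mapped proteins $M$ (proteins with at
least one hit), total proteins $N$, mapping rate $M/N$, average hits per
mapped protein $H/M$, distinct panel peptides found, the per-peptide
spectrum, and the count of mapped collagen subunits. Two degenerate-input
choices keep the functions total: when $M = 0$ both ratios are defined as
0, and an empty proteome yields rate 0. Ratios are carried at full double
precision everywhere; rounding — half away from zero, default 4 decimals,
matching how such tables are printed — happens only in
`format_summary_table()`. `summarize_counts()` applies the same ratio and
rounding logic to externally reported integer counts, which is how the test
suite desk-checks a published five-mammal summary table: all ten printed
ratios are reproduced at 4 decimals from the printed counts.

The collagen rule is a case-insensitive search for the token "collagen" in
the protein description (configurable regex). Descriptions in RefSeq- and
Ensembl-style protein FASTA carry the word for collagen chains, making the
rule transparent and reproducible; it counts protein *records*, not
collapsed gene-level subunits, because the package deliberately performs no
redundancy collapsing — a species' total protein count is the size of its
gene set as downloaded. Functional categories are consumed from a
user-supplied `protein_id → category` table and never computed; mapped
proteins missing from the table are tallied under the reserved
`"unannotated"` category.

## The synthetic proteome generator

Real comparative screens depend on unversioned downloaded proteomes and an
unpublished activity-ranked panel, so raw hit totals are not reproducible
from a desk. The generator replaces them with fully specified inputs:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | — | records in the proteome (studies of this kind use order 10³–10⁴) |
| `length_meanlog`, `length_sdlog` | 6.2, 0.6 | log-normal protein length (residues); the default gives a median near 500 aa, a right tail into the thousands, and is truncated to [20, 50000] — the shape of real annotated gene sets |
| `background_freqs` | uniform | i.i.d. residue distribution; uniform makes the expected count of a length-$k$ peptide analytic, $(L-k+1)\,20^{-k}$; a Swiss-Prot-style vertebrate preset is provided |
| `plant_plan` | none | peptides to write into the background at non-overlapping, uniformly chosen offsets, with copy numbers and an optional eligible-protein fraction |
| `collagen_fraction` | 0 | fraction of records whose description is set to `"collagen type IV alpha 5"` (a canonical collagen subunit name); exactly `floor(fraction * n)` records, so collagen counts are exact by construction |
| `seed` | 1 | full determinism: one seed, byte-identical FASTA |

Ground truth is *always* finalized by running the `naive_scan()` oracle over
the post-planting sequences: planting can create incidental occurrences at
window boundaries, and deriving truth from the plan alone would bake that
class of off-by-one bug into the tests. Planted coordinates are separated
from background occurrences by an exact coordinate anti-join, and the
peptide-wise totals are, by construction, exactly what `map_peptides()`
must report — the parameter-recovery surface the acceptance tests check.

What the generator does **not** emulate: domain architecture, homology and
isoform structure, residue autocorrelation, and realistic per-protein
composition variance. Uniform-background proteomes are much denser in short
peptide hits than real proteomes (tripeptide hits at rate $20^{-3}$ per
position), so synthetic mapping rates approach 1 and synthetic averages are
far above the 2.3–2.5 range seen on real mammalian gene sets. Passing the
recovery tests therefore demonstrates correctness of the machinery — exact
counting, localization, and bookkeeping — not realism of the background
model; conclusions about real species still require their real proteomes.

## Numerical and interface choices

* **Rounding**: half away from zero, applied at report time only.
  `report_round()` is exported because desk-checking published tables needs
  the identical rule.
* **Tie-breaks**: panel selection (by activity) and peptide rankings (by
  count) both fall back to lexicographic sequence order; protein rankings
  fall back to `protein_id`. All outputs are therefore byte-stable across
  runs, which the tests assert end to end.
* **Validation**: library rows violating the peptide invariants are
  dropped with their file line numbers reported; duplicate peptide or
  protein identifiers are hard errors; orphan protein ids in a hit table
  are integrity errors. `run_screen()` removes its partial outputs on any
  failure, so an output directory never holds a half-finished run.
* **Problem sizes in the test suite** (chosen as the package's standing
  verification workload): 500 randomized instances for matcher/oracle
  equivalence; a 5,000-protein proteome with the full 50-peptide panel
  planted for end-to-end recovery; ≥10⁷ background residues for the
  distribution sanity check (observed tripeptide count within 4 standard
  deviations of the analytic expectation); 10⁶ residues for the
  chi-square composition check at α = 0.001.

## Known limitations

* Exact matching only: no substitution tolerance, no mass-based
  identification, and no modeling of digestion enzymes' cleavage
  specificity — occurrence is treated as potential, not as predicted yield.
* The shipped AHTP library is a synthetic, literature-style stand-in with
  plausible activities; panel membership on real questions should come from
  a curated database supplied by the user.
* The collagen count depends on description strings; proteomes with sparse
  or nonstandard descriptions will undercount unless the regex is adapted.
* Species proteomes are compared as-is; differences in annotation depth
  (total protein counts) propagate directly into hit totals, which is why
  the rate and per-mapped-protein average are the comparable quantities.
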