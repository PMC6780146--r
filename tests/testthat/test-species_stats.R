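three_prot <- function() {
  tiny_proteome(c(p1 = "AGLPAGLP", p2 = "LGPAAA", p3 = "MMMM"),
                species = "demo",
                descriptions = c("collagen type IV alpha 5", "titin", ""))
}

test_that("species summary matches a hand count", {
  prot <- three_prot()
  hits <- map_peptides(prot, c("GLP", "LGP"))
  s <- summarize_species(hits, prot)
  expect_equal(s$total_hits, 3L)
  expect_equal(s$mapped_protein_count, 2L)
  expect_equal(s$total_protein_count, 3L)
  expect_equal(s$mapping_rate, 2 / 3)
  expect_equal(s$avg_hits_per_mapped, 1.5)
  expect_equal(s$distinct_peptides_found, 2L)
  expect_equal(s$collagen_mapped_count, 1L)
  expect_equal(s$peptide_counts[[1]],
               tibble::tibble(peptide = c("GLP", "LGP"), n = c(2L, 1L)))
})

test_that("empty hit tables give the degenerate zero summary", {
  prot <- random_proteome(10, max_len = 20, species = "rand")
  s <- summarize_species(empty_hits_fixture(), prot)
  expect_equal(s$total_hits, 0L)
  expect_equal(s$mapped_protein_count, 0L)
  expect_equal(s$mapping_rate, 0)
  expect_equal(s$avg_hits_per_mapped, 0)
  expect_equal(s$distinct_peptides_found, 0L)
})

test_that("orphan protein ids in hits raise an integrity error", {
  prot <- three_prot()
  hits <- map_peptides(prot, "GLP")
  hits$protein_id[1] <- "ghost"
  expect_error(summarize_species(hits, prot), "ghost",
               class = "ahtpscan_error_integrity")
  expect_error(rank_proteins(hits, prot, 2), class = "ahtpscan_error_integrity")
})

test_that("summary invariants hold on randomized instances", {
  withr::local_seed(202)
  for (i in 1:15) {
    prot <- random_proteome(sample(5:40, 1), max_len = 120)
    panel <- random_panel(sample(3:15, 1), max_len = 3)
    hits <- map_peptides(prot, panel)
    s <- summarize_species(hits, prot)
    expect_equal(sum(s$peptide_counts[[1]]$n), s$total_hits)
    expect_lte(s$mapped_protein_count, s$total_protein_count)
    expect_equal(s$mapping_rate * s$total_protein_count,
                 s$mapped_protein_count)
    if (s$mapped_protein_count >= 1) expect_gte(s$avg_hits_per_mapped, 1)
    expect_lte(s$distinct_peptides_found, length(panel))
  }
})

test_that("protein ranking follows hit count with id tie-break, oracle-checked", {
  prot <- tiny_proteome(c(p1 = "AAAAAA", p2 = "AAAAAA", p3 = "AAG"),
                        descriptions = c("", "Collagen alpha-1(VIII) chain",
                                         ""))
  hits <- map_peptides(prot, c("AA", "AG"))
  top <- rank_proteins(hits, prot, 2)
  expect_equal(top$protein_id, c("p1", "p2"))  # 5-hit tie broken by id
  expect_equal(top$is_collagen, c(FALSE, TRUE))

  all_ranked <- rank_proteins(hits, prot, 10)
  expect_equal(nrow(all_ranked), 3)  # never unmapped proteins
  expect_true(all(all_ranked$distinct_peptides <= all_ranked$hit_count))

  withr::local_seed(17)
  prot2 <- random_proteome(25, max_len = 80)
  hits2 <- map_peptides(prot2, random_panel(8, max_len = 3))
  r <- rank_proteins(hits2, prot2, 1000)
  counts <- table(hits2$protein_id)
  oracle <- names(counts)[order(-as.integer(counts), names(counts))]
  expect_equal(r$protein_id, oracle)
})

test_that("top peptides sort by count with lexicographic ties and truncate", {
  s <- tibble::tibble(peptide_counts = list(
    tibble::tibble(peptide = c("VSV", "GLP", "LGP"), n = c(5L, 10L, 10L))))
  expect_equal(top_n_peptides(s, 2)$peptide, c("GLP", "LGP"))
  expect_equal(nrow(top_n_peptides(s, 8)), 3)

  withr::local_seed(3)
  pep <- tibble::tibble(peptide = random_panel(20, max_len = 4),
                        n = sample.int(5, 20, replace = TRUE))
  got <- top_n_peptides(tibble::tibble(peptide_counts = list(pep)), 1000)
  expect_equal(got$peptide, pep$peptide[order(-pep$n, pep$peptide)])
})

test_that("collagen counting applies the description rule case-insensitively", {
  prot <- tiny_proteome(c(p1 = "AAA", p2 = "AAA", p3 = "AAA"),
                        descriptions = c("collagen type IV alpha 5", "titin",
                                         "Collagen alpha-1(VIII) chain"))
  expect_equal(count_collagen(prot, c("p1", "p2", "p3")), 2)
  expect_equal(count_collagen(prot, "p2"), 0)

  n_col <- 48
  syn <- tiny_proteome(setNames(rep("AAA", 60), paste0("c", 1:60)),
                       descriptions = c(rep("collagen type IV alpha 5", n_col),
                                        rep("other", 12)))
  expect_equal(count_collagen(syn, syn$protein_id), n_col)
})

test_that("cross-species comparison zero-fills and recomputes consistently", {
  a <- tiny_proteome(c(p1 = "AGLPGLP"), species = "sp_a")
  b <- tiny_proteome(c(q1 = "AVSVA"), species = "sp_b")
  panel <- c("GLP", "VSV")
  summaries <- dplyr::bind_rows(
    summarize_species(map_peptides(a, panel), a),
    summarize_species(map_peptides(b, panel), b))
  cmp <- compare_species(summaries)
  pep <- cmp$peptides
  expect_equal(pep$sp_b[pep$peptide == "GLP"], 0L)
  expect_equal(pep$sp_a[pep$peptide == "VSV"], 0L)
  expect_equal(colSums(pep[, c("sp_a", "sp_b")]),
               setNames(as.double(summaries$total_hits),
                        c("sp_a", "sp_b")))
  # each stats column matches its standalone summary
  expect_equal(cmp$stats$sp_a[cmp$stats$parameter == "total_hits"],
               summaries$total_hits[1])
  one <- compare_species(summaries[1, ])
  expect_equal(one$stats$sp_a, cmp$stats$sp_a)

  expect_error(compare_species(dplyr::bind_rows(summaries, summaries[1, ])),
               class = "ahtpscan_error_argument")
})

test_that("published-style integer counts reproduce 4-decimal ratios", {
  s <- summarize_counts(tibble::tibble(
    species = "white dolphin", total_hits = 27260,
    mapped_protein_count = 11323, total_protein_count = 18387))
  expect_equal(report_round(s$mapping_rate, 4), 0.6158)
  expect_equal(report_round(s$avg_hits_per_mapped, 4), 2.4075)
  tab <- format_summary_table(s)
  expect_equal(tab[[2]][tab$parameter == "mapping_rate"], 0.6158)
})

test_that("report rounding is half away from zero", {
  expect_equal(report_round(0.12345, 4), 0.1235)
  expect_equal(report_round(-0.12345, 4), -0.1235)
  expect_equal(report_round(2.5, 0), 3)
  expect_equal(report_round(-2.5, 0), -3)
})

test_that("functional-category tabulation counts multiplicities and the unannotated", {
  ann <- tibble::tibble(
    protein_id = c("p1", "p2", "p2"),
    category = c("binding", "binding", "catalytic activity"))
  got <- annotate_mapped(c("p1", "p2"), ann)
  expect_equal(got$n_proteins[got$category == "binding"], 2L)
  expect_equal(got$n_proteins[got$category == "catalytic activity"], 1L)
  expect_equal(got$n_proteins[got$category == "unannotated"], 0L)

  empty_ann <- tibble::tibble(protein_id = character(),
                              category = character())
  got2 <- annotate_mapped(c("p1", "p2"), empty_ann)
  expect_equal(got2, tibble::tibble(category = "unannotated",
                                    n_proteins = 2L))

  # brute-force tally on a random instance
  withr::local_seed(9)
  ids <- paste0("p", 1:30)
  ann3 <- tibble::tibble(
    protein_id = sample(ids, 50, replace = TRUE),
    category = sample(c("a", "b", "c"), 50, replace = TRUE)) |>
    dplyr::distinct()
  mapped <- sample(ids, 20)
  got3 <- annotate_mapped(mapped, ann3)
  for (cat in c("a", "b", "c")) {
    brute <- sum(vapply(mapped, function(p) {
      any(ann3$protein_id == p & ann3$category == cat)
    }, logical(1)))
    expect_equal(got3$n_proteins[got3$category == cat],
                 if (brute > 0) brute else integer(0))
  }
  brute_un <- sum(!mapped %in% ann3$protein_id)
  expect_equal(got3$n_proteins[got3$category == "unannotated"], brute_un)
})
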