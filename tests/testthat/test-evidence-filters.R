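write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("domain table reader filters by analysis and normalizes ids", {
  f <- write_lines_tmp(c(
    paste("g1.t1", "md5", "500", "Pfam", "PF00067", "p450", "1", "100",
          "1e-10", "T", "2026-01-01", sep = "\t"),
    paste("g2.t1.p1", "md5", "300", "MobiDBLite", "mobidb-lite", "disorder",
          "1", "50", "-", "T", "2026-01-01", sep = "\t")))
  d <- read_domain_table(f)
  expect_equal(d$model_id, "g1")
  expect_equal(d$signature, "PF00067")

  d2 <- read_domain_table(f, analysis_filter = c("Pfam", "MobiDBLite"))
  expect_setequal(d2$model_id, c("g1", "g2"))

  empty <- write_lines_tmp(character(0))
  expect_equal(nrow(read_domain_table(empty)), 0L)

  short <- write_lines_tmp(c("g1\tmd5\t500\tPfam\tPF1", "g2\tonly\ttwo"))
  expect_error(read_domain_table(short), "line 2")
})

test_that("alignment table reader computes clamped reciprocal coverages", {
  row14 <- paste("g1.t1.p1", "SUBJ1", "90.0", "70", "5", "0",
                 "1", "70", "1", "70", "1e-40", "250", "100", "100", sep = "\t")
  f <- write_lines_tmp(row14)
  h <- read_alignment_table(f)
  expect_equal(h$qcov, 0.70)
  expect_equal(h$scov, 0.70)
  expect_equal(h$query_gene, "g1")

  # 12-column dialect requires both sidecars
  row12 <- paste("g1.t1.p1", "SUBJ1", "90.0", "70", "5", "0",
                 "1", "70", "70", "1", "1e-40", "250", sep = "\t")
  f12 <- write_lines_tmp(row12)
  expect_error(read_alignment_table(f12), "reciprocal coverage")

  h12 <- read_alignment_table(f12,
                              query_lengths = c("g1.t1.p1" = 100),
                              subject_lengths = c(SUBJ1 = 80))
  # reversed subject coordinates: absolute span, positive coverage
  expect_equal(h12$scov, 70 / 80)
  expect_error(read_alignment_table(f12, query_lengths = c(other = 10),
                                    subject_lengths = c(SUBJ1 = 80)),
               "missing from length sidecar")

  # coverage clamped to 1 when the alignment exceeds the stated length
  rowx <- paste("q", "s", "90", "120", "0", "0", "1", "120", "1", "120",
                "1e-5", "99", "100", "100", sep = "\t")
  hx <- read_alignment_table(write_lines_tmp(rowx))
  expect_equal(hx$qcov, 1)
})

test_that("reciprocal pass is inclusive at the threshold", {
  hits <- data.frame(qcov = c(0.70, 0.90, 0.69), scov = c(0.70, 0.50, 0.99))
  expect_equal(reciprocal_pass(hits), c(TRUE, FALSE, FALSE))
  expect_equal(reciprocal_pass(hits, threshold = 0.5), c(TRUE, TRUE, TRUE))
})

test_that("annotation rate counts genes with at least one passing hit", {
  g <- generate_genome(generator_params(seed = 51, n_genes = 10,
                                        mono_fraction = 0.2))
  ids <- gene_ids(g$annotation)
  hits <- data.frame(query_gene = ids[1:8],
                     qcov = rep(0.8, 8), scov = rep(0.8, 8),
                     stringsAsFactors = FALSE)
  r <- annotation_rate(g$annotation, hits)
  expect_equal(r$overall, 80)

  expect_equal(annotation_rate(g$annotation, NULL)$overall, 0)

  # a hit straddling the boundary from below does not count
  hits2 <- data.frame(query_gene = ids, qcov = c(0.69, rep(0.9, 9)),
                      scov = rep(0.99, 10), stringsAsFactors = FALSE)
  expect_equal(annotation_rate(g$annotation, hits2)$overall, 90)
})

test_that("mono/multi evidence filters enforce their partitions", {
  g <- generate_genome(generator_params(seed = 52, n_genes = 12,
                                        mono_fraction = 0.5))
  parts <- partition_by_exonic_status(g$annotation)
  mono_ids <- gene_ids(parts$mono)
  dom <- data.frame(model_id_raw = paste0(mono_ids[1], ".t1"),
                    analysis = "Pfam", signature = "PF00001",
                    model_id = mono_ids[1], stringsAsFactors = FALSE)
  r <- filter_mono_by_domain(parts$mono, dom)
  expect_equal(gene_ids(r$annotation), mono_ids[1])
  expect_true(all(r$ledger$reason == "mono_no_domain"))
  expect_error(filter_mono_by_domain(parts$multi, dom), "mono-exonic")

  multi_ids <- gene_ids(parts$multi)
  orth <- data.frame(model_id_raw = paste0(multi_ids[1], ".t1"),
                     group = "OG1", model_id = multi_ids[1],
                     stringsAsFactors = FALSE)
  hits <- data.frame(query_gene = multi_ids[2], qcov = 0.9, scov = 0.9,
                     stringsAsFactors = FALSE)
  r2 <- filter_multi_by_homology(parts$multi, hits, orth)
  # ortholog-only and hit-only genes both kept (disjunctive evidence)
  expect_setequal(gene_ids(r2$annotation), multi_ids[1:2])
  expect_true(all(r2$ledger$reason == "multi_no_evidence"))
  expect_error(filter_multi_by_homology(parts$mono, hits, orth), "multi-exonic")
})

test_that("two-round refinement keeps exactly the evidenced true genes", {
  g <- generate_genome(generator_params(seed = 53, n_genes = 120,
                                        mono_fraction = 0.25))
  ledger <- g$ledger
  st <- classify_exonic_status(g$annotation)
  spurious_mono <- names(st)[st == "mono"][1:15]
  spurious_multi <- names(st)[st == "multi"][1:5]
  ledger$models$provenance[ledger$models$model_id %in%
                             c(spurious_mono, spurious_multi)] <- "spurious_repeat"
  ev <- generate_evidence(ledger, domain_fn_rate = 0, orth_rate = 1, seed = 9)
  res <- two_round_refinement(g$annotation, g$genome, ev$domains, ev$hits,
                              ev$orthologs)
  true_ids <- ev$ledger$models$model_id[ev$ledger$models$provenance == "true"]
  expect_equal(n_genes(res$annotation), 100L)
  expect_setequal(gene_ids(res$annotation), true_ids)
  expect_equal(sum(res$report$rounds$removed), 20L)
  # conservation per round
  expect_equal(res$report$rounds$input - res$report$rounds$removed,
               res$report$rounds$survivors)
})

test_that("fully evidenced input passes two rounds as dedup(input)", {
  g <- generate_genome(generator_params(seed = 54, n_genes = 20))
  ev <- generate_evidence(g$ledger, domain_fn_rate = 0, orth_rate = 1)
  res <- two_round_refinement(g$annotation, g$genome, ev$domains, ev$hits,
                              ev$orthologs)
  expect_true(annotation_identical(res$annotation,
                                   deduplicate_models(g$annotation)$annotation))
})

test_that("empty evidence removes every gene in both rounds", {
  g <- generate_genome(generator_params(seed = 55, n_genes = 10,
                                        mono_fraction = 0.3))
  res <- two_round_refinement(g$annotation, g$genome, NULL, NULL, NULL)
  expect_equal(n_genes(res$annotation), 0L)
  expect_equal(nrow(res$report$ledger), 10L)
})

test_that("refinement monotonicity: ratio falls in round 1, rate never falls", {
  g <- generate_genome(generator_params(seed = 56, n_genes = 60,
                                        mono_fraction = 0.3))
  ev <- generate_evidence(g$ledger, domain_fn_rate = 0.4, orth_rate = 1,
                          seed = 10)
  res <- two_round_refinement(g$annotation, g$genome, ev$domains, ev$hits,
                              ev$orthologs)
  rb <- res$report$before_metrics$mono_multi_ratio
  ra <- res$report$after_metrics$mono_multi_ratio
  expect_lte(ra, rb)
  expect_gte(res$report$after_rate$overall, res$report$before_rate$overall)
})

test_that("annotation rate is nonincreasing in the reciprocal threshold", {
  g <- generate_genome(generator_params(seed = 57, n_genes = 40))
  ev <- generate_evidence(g$ledger, coverage_range = c(0.45, 0.99), seed = 11)
  rates <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(t) {
    annotation_rate(g$annotation, ev$hits, t)$overall
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("domain false-negative rate propagates to mono removals", {
  # expected removed fraction of true mono genes ~ f (binomial, 3 sigma)
  f <- 0.3
  n_mono <- 150L
  g <- generate_genome(generator_params(seed = 58, n_genes = 300,
                                        mono_fraction = 0.5))
  ev <- generate_evidence(g$ledger, domain_fn_rate = f, orth_rate = 1, seed = 12)
  parts <- partition_by_exonic_status(g$annotation)
  r <- filter_mono_by_domain(parts$mono, ev$domains)
  frac <- nrow(r$ledger) / n_genes(parts$mono)
  tol <- 3 * sqrt(f * (1 - f) / n_mono)
  expect_lt(abs(frac - f), tol)
})

test_that("id normalization strips predictor suffixes to a fixed point", {
  expect_equal(normalize_model_ids(c("g1.t1.p1", "g2.t3", "g3-RA", "g4")),
               c("g1", "g2", "g3", "g4"))
  expect_equal(normalize_model_ids("g1.t2.p10"), "g1")
})
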