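test_that("mono:multi ratio arithmetic and degenerate cases", {
  expect_equal(mono_multi_ratio(10, 50), 0.2)
  expect_equal(mono_multi_ratio(0, 50), 0)
  expect_warning(r <- mono_multi_ratio(5, 0), "undefined")
  expect_true(is.na(r))
  expect_error(mono_multi_ratio(-1, 5), "nonnegative")
})

test_that("summary statistics match the hand-computed two-gene fixture", {
  # mono gene: 300 bp CDS; multi gene: 900 bp CDS in 3 segments
  mono <- make_tx("g1.t1", "g1", "chr1", "+", list(c(0, 300)))
  multi <- make_tx("g2.t1", "g2", "chr1", "+",
                   list(c(1000, 1300), c(1400, 1700), c(1800, 2100)))
  ann <- make_ann(mono, multi)
  m <- compute_summary(ann)
  expect_equal(m$total_genes, 2L)
  expect_equal(m$mono_count, 1L)
  expect_equal(m$multi_count, 1L)
  expect_equal(m$mono_multi_ratio, 1.0)
  expect_equal(m$mean_cds_length_bp, 600)
  expect_equal(m$cds_n50_bp, 900)
  expect_equal(m$mean_exons_per_gene, 2)
  expect_equal(m$mean_gene_length_bp, (300 + 1100) / 2)
  expect_equal(m$per_class$n, c(1L, 1L))
  expect_equal(m$per_class$cds_n50_bp, c(300, 900))
})

test_that("empty annotation yields a zero report with undefined ratio", {
  empty <- annotation_set(
    data.frame(transcript_id = character(), gene_id = character(),
               seq_id = character(), strand = character()),
    data.frame(transcript_id = character(), start = integer(), end = integer()),
    data.frame(transcript_id = character(), start = integer(), end = integer(),
               phase = integer()))
  m <- compute_summary(empty)
  expect_equal(m$total_genes, 0L)
  expect_true(is.na(m$mono_multi_ratio))
  expect_equal(m$cds_n50_bp, 0)
})

test_that("planted mono fraction yields the exact mono:multi ratio", {
  g <- generate_genome(generator_params(seed = 21, n_genes = 60,
                                        mono_fraction = 1 / 6))
  m <- compute_summary(g$annotation, g$genome)
  expect_equal(m$mono_count, 10L)
  expect_equal(m$multi_count, 50L)
  expect_equal(m$mono_multi_ratio, 0.2)
  expect_equal(m$genes_with_start_and_stop, 60L)
})

test_that("threshold verdicts follow the published benchmark thresholds", {
  v <- evaluate_thresholds(0.16, annotation_rate = 81, busco_complete = 96)
  expect_true(v$ratio_ok)
  expect_true(v$annotation_rate_ok)
  expect_true(v$busco_ok)

  expect_false(evaluate_thresholds(0.7)$ratio_ok)
  expect_true(is.na(evaluate_thresholds(0.1)$busco_ok))
  expect_true(is.na(evaluate_thresholds(0.1)$annotation_rate_ok))
})

test_that("BUSCO short-summary parsing", {
  f <- tempfile()
  writeLines(c("# BUSCO version is: 5.0.0",
               "\tC:95.9%[S:90.1%,D:5.8%],F:1.0%,M:3.1%,n:1614"), f)
  b <- parse_busco_summary(f)
  expect_equal(b$complete, 95.9)
  expect_equal(b$fragmented, 1.0)
  expect_equal(b$missing, 3.1)

  writeLines("C:95.9%[S:90.1%,D:5.8%],F:1.0%,M:3.0%,n:1614", f)  # sums to 99.9
  expect_equal(parse_busco_summary(f)$missing, 3.0)

  writeLines("F:1.0%,M:3.1%", f)
  expect_error(parse_busco_summary(f), "malformed")
})

test_that("classification partitions genes and respects the representative rule", {
  # gene whose longest-CDS isoform is multi but that has a mono isoform
  iso_mono <- make_tx("g1.t2", "g1", "chr1", "+", list(c(0, 150)))
  iso_multi <- make_tx("g1.t1", "g1", "chr1", "+",
                       list(c(300, 500), c(600, 800)))
  ann <- make_ann(iso_mono, iso_multi)
  expect_equal(unname(classify_exonic_status(ann)["g1"]), "multi")

  g <- generate_genome(generator_params(seed = 22, n_genes = 30,
                                        mono_fraction = 0.3))
  st <- classify_exonic_status(g$annotation)
  m <- compute_summary(g$annotation)
  expect_equal(sum(st == "mono") + sum(st == "multi"), m$total_genes)
})

test_that("ratio monotonicity under class-restricted removals", {
  g <- generate_genome(generator_params(seed = 23, n_genes = 40,
                                        mono_fraction = 0.25))
  st <- classify_exonic_status(g$annotation)
  m0 <- compute_summary(g$annotation)
  drop_mono <- subset_annotation(g$annotation,
                                 setdiff(names(st), names(st)[st == "mono"][1:3]))
  expect_lte(compute_summary(drop_mono)$mono_multi_ratio, m0$mono_multi_ratio)
  drop_multi <- subset_annotation(g$annotation,
                                  setdiff(names(st), names(st)[st == "multi"][1:3]))
  expect_gte(compute_summary(drop_multi)$mono_multi_ratio, m0$mono_multi_ratio)
})

test_that("scale invariance: duplicating every gene preserves ratio and means", {
  g <- generate_genome(generator_params(seed = 24, n_genes = 20))
  a <- g$annotation
  relabel <- function(df, cols) {
    for (c_ in intersect(cols, names(df))) df[[c_]] <- paste0(df[[c_]], "_copy")
    df
  }
  b <- annotation_set(relabel(a$transcripts, c("transcript_id", "gene_id")),
                      relabel(a$exons, "transcript_id"),
                      relabel(a$cds, "transcript_id"))
  both <- combine_annotations(a, b)
  m1 <- compute_summary(a)
  m2 <- compute_summary(both)
  expect_equal(m2$total_genes, 2L * m1$total_genes)
  expect_equal(m2$mono_multi_ratio, m1$mono_multi_ratio)
  expect_equal(m2$mean_cds_length_bp, m1$mean_cds_length_bp)
  expect_equal(m2$mean_gene_length_bp, m1$mean_gene_length_bp)
  expect_equal(m2$cds_n50_bp, m1$cds_n50_bp)
})

test_that("summary equals the brute-force recomputation from raw GFF3 text", {
  for (seed in 31:36) {
    g <- generate_genome(random_small_params(seed))
    gff <- tempfile(fileext = ".gff3")
    fa <- tempfile(fileext = ".fa")
    write_gff3(g$annotation, gff)
    write_fasta(g$genome, fa)
    m <- suppressWarnings(compute_summary(read_gff3(gff, read_fasta(fa)),
                                          read_fasta(fa)))
    o <- oracle_metrics(gff, fa)
    expect_equal(m$total_genes, o$total)
    expect_equal(m$mono_count, o$mono)
    expect_equal(m$multi_count, o$multi)
    expect_equal(m$mono_multi_ratio, o$ratio)
    if (o$total > 0) {
      expect_equal(m$mean_gene_length_bp, o$mean_gene)
      expect_equal(m$mean_cds_length_bp, o$mean_cds)
      expect_equal(m$mean_exons_per_gene, o$mean_ex)
      expect_equal(m$cds_n50_bp, o$n50)
      expect_equal(m$genes_with_start_and_stop, o$complete)
      expect_equal(m$per_class$n, c(o$mono_stats$n, o$multi_stats$n))
      expect_equal(m$per_class$mean_cds_length_bp,
                   c(o$mono_stats$mean_cds, o$multi_stats$mean_cds))
      expect_equal(m$per_class$cds_n50_bp,
                   c(o$mono_stats$n50, o$multi_stats$n50))
    }
  }
})

test_that("report writers serialize an undefined ratio as null", {
  mono <- make_tx("g1.t1", "g1", "chr1", "+", list(c(0, 300)))
  m <- suppressWarnings(compute_summary(make_ann(mono)))
  expect_true(is.na(m$mono_multi_ratio))
  jf <- tempfile(fileext = ".json")
  write_metrics_json(m, jf)
  parsed <- jsonlite::read_json(jf)
  expect_null(parsed$mono_multi_ratio)
  tf <- tempfile(fileext = ".tsv")
  write_metrics_tsv(m, tf)
  expect_equal(nrow(utils::read.delim(tf)), 1L)
})
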