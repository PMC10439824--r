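test_that("FASTA parsing preserves soft-mask case and rejects malformed input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGTacgt"), fa)
  g <- read_fasta(fa)
  expect_equal(unname(g$records["chr1"]), "ACGTacgt")
  expect_equal(unname(g$lengths["chr1"]), 8L)

  writeLines(c(">a", "AC", ">b", "GT"), fa)
  g2 <- read_fasta(fa)
  expect_equal(names(g2$records), c("a", "b"))
  expect_equal(unname(g2$lengths), c(2L, 2L))

  writeLines(c(">a", "AC", ">a", "GT"), fa)
  expect_error(read_fasta(fa), "duplicate sequence id.*a")

  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty|malformed")

  writeLines(c(">a", "ACRT"), fa)
  expect_error(read_fasta(fa), "non-IUPAC.*line 2")
})

test_that("GFF3 reading converts coordinates, synthesizes exons, checks bounds", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t399\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t399\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tCDS\t100\t199\t.\t+\t0\tParent=g1.t1",
    "chr1\tsrc\tCDS\t300\t399\t.\t+\t2\tParent=g1.t1"), gff)
  ann <- read_gff3(gff)
  expect_equal(ann$cds$start, c(99L, 299L))
  expect_equal(ann$cds$end, c(199L, 399L))
  # no exon rows: exons synthesized equal to CDS
  expect_equal(ann$exons[c("start", "end")], ann$cds[c("start", "end")])
  expect_equal(ann$genes$gene_id, "g1")

  genome <- filler_genome(5000, "chr1")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t10000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t10000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tCDS\t100\t10000\t.\t+\t0\tParent=g1.t1"), gff)
  expect_error(read_gff3(gff, genome), "beyond sequence end")

  writeLines(c(
    "##gff-version 3",
    "chrX\tsrc\tgene\t1\t9\t.\t+\t.\tID=g1",
    "chrX\tsrc\tmRNA\t1\t9\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrX\tsrc\tCDS\t1\t9\t.\t+\t0\tParent=g1.t1"), gff)
  expect_error(read_gff3(gff, genome), "unknown seq_id")

  # GTF-like attribute dialect
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tCDS\t10\t39\t.\t+\t0\tgene_id=gX;transcript_id=gX.t1"), gff)
  ann3 <- read_gff3(gff)
  expect_equal(ann3$genes$gene_id, "gX")
  expect_equal(ann3$transcripts$transcript_id, "gX.t1")
  expect_equal(ann3$cds$start, 9L)

  # orphan CDS (parent chain missing) rejected
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tCDS\t10\t39\t.\t+\t0\tParent=nowhere"), gff)
  expect_error(read_gff3(gff), "orphan")
})

test_that("GFF3 writer sorts deterministically and round-trips", {
  a <- make_tx("gB.t1", "gB", "chr2", "+", list(c(50, 350)))
  b <- make_tx("gA.t1", "gA", "chr1", "+", list(c(10, 310)))
  ann <- make_ann(a, b)
  out <- tempfile(fileext = ".gff3")
  write_gff3(ann, out)
  lines <- readLines(out)
  expect_equal(lines[1], "##gff-version 3")
  gene_lines <- grep("\tgene\t", lines, value = TRUE)
  expect_match(gene_lines[1], "^chr1")
  expect_match(gene_lines[2], "^chr2")

  # round trip is structurally identical, and re-writing is byte-identical
  back <- read_gff3(out)
  expect_true(annotation_identical(ann, back))
  out2 <- tempfile(fileext = ".gff3")
  write_gff3(back, out2)
  expect_identical(readLines(out), readLines(out2))

  # empty set: header-only file
  empty <- annotation_set(
    data.frame(transcript_id = character(), gene_id = character(),
               seq_id = character(), strand = character()),
    data.frame(transcript_id = character(), start = integer(), end = integer()),
    data.frame(transcript_id = character(), start = integer(), end = integer(),
               phase = integer()))
  write_gff3(empty, out)
  expect_identical(readLines(out), "##gff-version 3")
  expect_equal(n_genes(read_gff3(out)), 0L)
})

test_that("round trip holds on generated annotations", {
  for (seed in 1:4) {
    g <- generate_genome(random_small_params(seed))
    f <- tempfile(fileext = ".gff3")
    write_gff3(g$annotation, f)
    expect_true(annotation_identical(g$annotation, read_gff3(f, g$genome)))
  }
})

test_that("representative transcript is longest CDS with id tie-break", {
  t1 <- make_tx("g1.t1", "g1", "chr1", "+", list(c(0, 300)))
  t2 <- make_tx("g1.t2", "g1", "chr1", "+", list(c(0, 450)))
  ann <- make_ann(t1, t2)
  expect_equal(select_representative(ann, "g1")$transcript_id, "g1.t2")

  ta <- make_tx("g2.tA", "g2", "chr1", "+", list(c(500, 800)))
  tb <- make_tx("g2.tB", "g2", "chr1", "+", list(c(500, 800)))
  ann2 <- make_ann(ta, tb)
  expect_equal(select_representative(ann2, "g2")$transcript_id, "g2.tA")

  solo <- make_ann(make_tx("g3.t1", "g3", "chr1", "+", list(c(0, 99))))
  expect_equal(select_representative(solo, "g3")$transcript_id, "g3.t1")
  expect_error(select_representative(solo, "missing"), "unknown gene")
})

test_that("CDS extraction honours strand, phase, and soft-masking", {
  genome <- make_genome(chr1 = paste0("ATG", "CCCC", "TAA"))
  ann <- make_ann(make_tx("g1.t1", "g1", "chr1", "+",
                          list(c(0, 3), c(7, 10))))
  expect_equal(extract_cds_sequence(ann, "g1.t1", genome), "ATGTAA")

  gm <- make_genome(chr1 = "TTACAT")
  annm <- make_ann(make_tx("g1.t1", "g1", "chr1", "-", list(c(0, 6))))
  expect_equal(extract_cds_sequence(annm, "g1.t1", gm), "ATGTAA")

  # phase 2 on the 5'-most segment trims two leading bases
  gp <- make_genome(chr1 = "CCATGTAA")
  annp <- make_ann(make_tx("g1.t1", "g1", "chr1", "+", list(c(0, 8, 2))))
  expect_equal(extract_cds_sequence(annp, "g1.t1", gp), "ATGTAA")

  # lowercase (soft-masked) genome yields the same uppercased CDS
  gl <- make_genome(chr1 = tolower("ATGCCCCTAA"))
  annl <- make_ann(make_tx("g1.t1", "g1", "chr1", "+", list(c(0, 3), c(7, 10))))
  expect_equal(extract_cds_sequence(annl, "g1.t1", gl), "ATGTAA")
})

test_that("translation reports start/stop/internal-stop/frame flags", {
  t1 <- translate_cds("ATGAAATAA")
  expect_equal(t1$protein, "MK")
  expect_true(t1$has_start)
  expect_true(t1$has_terminal_stop)
  expect_equal(t1$internal_stop_count, 0L)
  expect_true(t1$length_multiple_of_3)

  expect_equal(translate_cds("ATGTAAAAATAA")$internal_stop_count, 1L)
  expect_false(translate_cds("ATGAA")$length_multiple_of_3)
  expect_equal(translate_cds("ATGANGTAA")$protein, "MX")
  expect_error(translate_cds(""), "non-empty")
})

test_that("intron extraction normalizes strand and flags short gaps", {
  genome <- make_genome(chr1 = paste0("AAA", "GT", "CCCC", "AG", "TTT"))
  ann <- make_ann(make_tx("g1.t1", "g1", "chr1", "+", list(c(0, 3), c(11, 14))))
  ins <- extract_introns(ann, "g1.t1", genome)
  expect_equal(ins$donor, "GT")
  expect_equal(ins$acceptor, "AG")

  # minus strand: genomic text CT...AC normalizes to GT-AG
  gm <- make_genome(chr1 = paste0("AAA", "CT", "CCCC", "AC", "TTT"))
  annm <- make_ann(make_tx("g1.t1", "g1", "chr1", "-", list(c(0, 3), c(11, 14))))
  insm <- extract_introns(annm, "g1.t1", gm)
  expect_equal(insm$donor, "GT")
  expect_equal(insm$acceptor, "AG")

  mono <- make_ann(make_tx("g1.t1", "g1", "chr1", "+", list(c(0, 9))))
  expect_equal(nrow(extract_introns(mono, "g1.t1", genome)), 0L)

  short <- make_ann(make_tx("g1.t1", "g1", "chr1", "+",
                            list(c(0, 3), c(5, 9))))
  inss <- extract_introns(short, "g1.t1", genome)
  expect_true(inss$flagged)
  expect_equal(inss$donor, "NN")
})

test_that("strand symmetry: mirrored genome and coordinates give identical CDS", {
  g <- generate_genome(generator_params(seed = 11, n_genes = 15))
  L <- unname(g$genome$lengths["chr1"])
  mirrored_genome <- genome_sequences(c(chr1 = revcomp(g$genome$records[["chr1"]])))
  tr <- g$annotation$transcripts
  tr$strand <- ifelse(tr$strand == "+", "-", "+")
  mirror <- function(df) {
    s <- L - df$end
    df$end <- L - df$start
    df$start <- s
    df
  }
  ex <- mirror(g$annotation$exons)
  cc <- g$annotation$cds
  # phases stay attached to their segments under mirroring
  cc_m <- mirror(cc)
  mann <- annotation_set(tr, ex, cc_m)
  for (tid in tr$transcript_id) {
    expect_identical(extract_cds_sequence(mann, tid, mirrored_genome),
                     extract_cds_sequence(g$annotation, tid, g$genome))
    a <- extract_introns(g$annotation, tid, g$genome)
    b <- extract_introns(mann, tid, mirrored_genome)
    expect_identical(b$donor, a$donor)
    expect_identical(b$acceptor, a$acceptor)
  }
})

test_that("soft-mask neutrality: uppercasing the genome changes nothing", {
  g <- generate_genome(generator_params(seed = 12, n_genes = 12))
  up <- unmask_genome(g$genome)
  m1 <- compute_summary(g$annotation, g$genome)
  m2 <- compute_summary(g$annotation, up)
  expect_identical(unclass(m1), unclass(m2))
  tid <- g$annotation$transcripts$transcript_id[1]
  expect_identical(extract_cds_sequence(g$annotation, tid, g$genome),
                   extract_cds_sequence(g$annotation, tid, up))
})

test_that("every synthetic true gene translates to a complete clean ORF", {
  g <- generate_genome(generator_params(seed = 13, n_genes = 25))
  for (tid in g$annotation$transcripts$transcript_id) {
    tl <- translate_cds(extract_cds_sequence(g$annotation, tid, g$genome))
    expect_true(tl$has_start)
    expect_true(tl$has_terminal_stop)
    expect_equal(tl$internal_stop_count, 0L)
    expect_true(tl$length_multiple_of_3)
  }
})
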