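# Compact constructors for hand-built fixtures.

make_genome <- function(...) {
  genome_sequences(c(...))
}

# segs: list of c(start, end) or c(start, end, phase), 0-based half-open
make_tx <- function(transcript_id, gene_id, seq_id, strand, segs,
                    exons = NULL) {
  cds <- do.call(rbind, lapply(segs, function(s) {
    data.frame(transcript_id = transcript_id, start = s[1], end = s[2],
               phase = if (length(s) >= 3) s[3] else 0L,
               stringsAsFactors = FALSE)
  }))
  ex <- if (is.null(exons)) cds[c("transcript_id", "start", "end")] else {
    do.call(rbind, lapply(exons, function(s) {
      data.frame(transcript_id = transcript_id, start = s[1], end = s[2],
                 stringsAsFactors = FALSE)
    }))
  }
  list(tx = data.frame(transcript_id = transcript_id, gene_id = gene_id,
                       seq_id = seq_id, strand = strand,
                       stringsAsFactors = FALSE),
       exons = ex, cds = cds)
}

make_ann <- function(...) {
  parts <- list(...)
  annotation_set(do.call(rbind, lapply(parts, `[[`, "tx")),
                 do.call(rbind, lapply(parts, `[[`, "exons")),
                 do.call(rbind, lapply(parts, `[[`, "cds")))
}

# a genome long enough to cover any fixture coordinates, deterministic filler
filler_genome <- function(len = 2000L, seq_id = "chr1") {
  base <- paste(rep("ACGT", ceiling(len / 4)), collapse = "")
  make_genome(stats::setNames(substr(base, 1, len), seq_id))
}

random_small_params <- function(seed) {
  with_seed_test(seed, {
    generator_params(seed = seed,
                     n_genes = sample(8:40, 1),
                     mono_fraction = sample(c(0, 1 / 6, 0.3, 0.5), 1),
                     n_sequences = sample(1:2, 1),
                     repeat_families = 1L, repeat_copies_per_family = 2L)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
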