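#' Parameters for the planted-genome generator
#'
#' The generator emulates the inputs a structural-annotation benchmark
#' consumes: multi-exonic protein-coding genes with canonical GT-AG introns,
#' a controllable mono-exonic fraction (default 1/6, i.e. a true mono:multi
#' ratio of 0.2), soft-masked LTR-like repeats (two identical terminal
#' repeats flanking internal sequence), and intergenic spacer sequence.
#' Class counts are planted exactly (`round(mono_fraction * n_genes)` genes
#' are mono-exonic), so truth-ledger assertions are equalities rather than
#' tolerances.
#'
#' @param seed Integer seed for the genome stream.
#' @param n_sequences Number of sequences genes are distributed over.
#' @param n_genes Number of protein-coding genes to plant.
#' @param mono_fraction Fraction of genes that are single-exon.
#' @param exon_extra_mean Multi-exon CDS segment count is
#'   `2 + rpois(exon_extra_mean)`.
#' @param cds_codons_range Inclusive range of codon counts per gene
#'   (includes start and stop), so total CDS length is at least 330 bp by
#'   default and never trips a 300-bp minimum-length filter.
#' @param min_exon_cds_bp Minimum CDS bases per exon piece.
#' @param intron_bp_range Inclusive intron length range (minimum 60 bp).
#' @param intergenic_bp_range Inclusive intergenic gap range.
#' @param gc_content GC fraction of random sequence.
#' @param repeat_families,repeat_copies_per_family LTR-like repeat content.
#' @param ltr_terminal_bp,repeat_internal_bp Repeat geometry; the internal
#'   region carries an embedded ORF so repeat-derived spurious single-exon
#'   models are structurally plausible.
#' @param softmask_repeats Lowercase the repeat copies.
#' @param sequence_length_bp Optional fixed length per sequence; an error is
#'   raised when the planted elements do not fit, otherwise sequences are
#'   padded with random intergenic tail.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(seed = 1L, n_sequences = 1L, n_genes = 60L,
                             mono_fraction = 1 / 6, exon_extra_mean = 2,
                             cds_codons_range = c(110L, 260L),
                             min_exon_cds_bp = 50L,
                             intron_bp_range = c(60L, 200L),
                             intergenic_bp_range = c(150L, 450L),
                             gc_content = 0.4,
                             repeat_families = 2L,
                             repeat_copies_per_family = 5L,
                             ltr_terminal_bp = 100L,
                             repeat_internal_bp = 600L,
                             softmask_repeats = TRUE,
                             sequence_length_bp = NULL) {
  stopifnot(mono_fraction >= 0, mono_fraction <= 1, n_genes >= 0,
            n_sequences >= 1, min_exon_cds_bp > 0,
            intron_bp_range[1] >= 4, cds_codons_range[1] >= 2,
            gc_content > 0, gc_content < 1,
            ltr_terminal_bp > 0, repeat_internal_bp >= 120)
  structure(as.list(environment()), class = "generator_params")
}

stop_codons <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# internal codons exclude stops and ATG so a truncated or split model can
# never present a spurious in-frame start or stop
internal_codon_pool <- function() setdiff(all_codons(), c(stop_codons, "ATG"))

make_cds_seq <- function(n_codons) {
  pool <- internal_codon_pool()
  paste0("ATG",
         paste(sample(pool, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(stop_codons, 1L))
}

# one gene locus in its own local coordinates (0-based half-open)
make_gene_locus <- function(status, p) {
  n_codons <- sample(seq(p$cds_codons_range[1], p$cds_codons_range[2]), 1L)
  cds_seq <- make_cds_seq(n_codons)
  cds_len <- 3L * n_codons
  k <- if (status == "mono") 1L else {
    min(2L + stats::rpois(1L, p$exon_extra_mean),
        max(2L, cds_len %/% p$min_exon_cds_bp))
  }
  if (k == 1L) {
    pieces <- cds_len
  } else {
    extra <- cds_len - k * p$min_exon_cds_bp
    cuts <- sort(sample.int(extra + 1L, k - 1L, replace = TRUE) - 1L)
    pieces <- diff(c(0L, cuts, extra)) + p$min_exon_cds_bp
  }
  intron_lens <- if (k > 1L) {
    sample(seq(p$intron_bp_range[1], p$intron_bp_range[2]), k - 1L,
           replace = TRUE)
  } else integer(0)
  introns <- vapply(intron_lens, function(L) {
    paste0("GT", random_bases(L - 4L, p$gc_content), "AG")
  }, character(1))

  locus <- character(2L * k - 1L)
  seg_start <- seg_end <- integer(k)
  pos <- 0L
  cds_pos <- 0L
  for (i in seq_len(k)) {
    locus[2L * i - 1L] <- substr(cds_seq, cds_pos + 1L, cds_pos + pieces[i])
    seg_start[i] <- pos
    seg_end[i] <- pos + pieces[i]
    pos <- pos + pieces[i]
    cds_pos <- cds_pos + pieces[i]
    if (i < k) {
      locus[2L * i] <- introns[i]
      pos <- pos + intron_lens[i]
    }
  }
  seq <- paste(locus, collapse = "")
  # phases in transcript 5'->3' order
  phase <- integer(k)
  carry <- 0L
  for (i in seq_len(k)) {
    phase[i] <- (3L - carry) %% 3L
    carry <- (carry + pieces[i]) %% 3L
  }
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") {
    # mirror coordinates; ascending genomic order on the minus strand is the
    # reverse of transcript order, so segment attributes simply reverse
    L <- nchar(seq)
    seq <- revcomp(seq)
    new_start <- rev(L - seg_end)
    seg_end <- rev(L - seg_start)
    seg_start <- new_start
    phase <- rev(phase)
  }
  list(seq = seq, strand = strand, start = seg_start, end = seg_end,
       phase = phase, cds_len = cds_len, n_cds = k)
}

make_repeat_family <- function(p) {
  terminal <- random_bases(p$ltr_terminal_bp, p$gc_content)
  max_codons <- (p$repeat_internal_bp - 12L) %/% 3L
  n_codons <- sample(seq(min(110L, max_codons), max_codons), 1L)
  orf <- make_cds_seq(n_codons)
  pad <- p$repeat_internal_bp - nchar(orf)
  pad_front <- sample.int(pad + 1L, 1L) - 1L
  internal <- paste0(random_bases(pad_front, p$gc_content), orf,
                     random_bases(pad - pad_front, p$gc_content))
  seq <- paste0(terminal, internal, terminal)
  orf_start <- p$ltr_terminal_bp + pad_front
  list(seq = seq, orf_start = orf_start, orf_end = orf_start + nchar(orf))
}

#' Generate a planted toy genome with its true annotation
#'
#' Deterministic per seed: the same `generator_params` produce byte-identical
#' FASTA and GFF3 output. All planted genes are codon-consistent (ATG start,
#' single terminal stop, no internal stops) with canonical GT-AG introns, so
#' the true annotation passes every structural filter untouched.
#'
#' @param params A [generator_params] object.
#' @return List with `genome` ([genome_sequences]), `annotation`
#'   ([annotation_set]), and `ledger` (class `truth_ledger`: `$models` with
#'   per-model provenance and `$repeats` with planted repeat coordinates).
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  with_seed(p$seed, {
    n_mono <- round(p$mono_fraction * p$n_genes)
    statuses <- safe_sample(c(rep("mono", n_mono),
                              rep("multi", p$n_genes - n_mono)), p$n_genes)

    gene_blocks <- lapply(statuses, make_gene_locus, p = p)
    families <- lapply(seq_len(p$repeat_families), function(i) make_repeat_family(p))
    n_rep <- p$repeat_families * p$repeat_copies_per_family
    rep_family <- rep(seq_len(p$repeat_families), each = p$repeat_copies_per_family)

    blocks <- c(lapply(seq_along(gene_blocks), function(i)
                  list(kind = "gene", idx = i)),
                lapply(seq_len(n_rep), function(i)
                  list(kind = "repeat", idx = i)))
    blocks <- if (length(blocks)) blocks[sample(length(blocks))] else blocks
    seq_assign <- if (length(blocks)) {
      rep_len(seq_len(p$n_sequences), length(blocks))
    } else integer(0)

    seq_ids <- sprintf("chr%d", seq_len(p$n_sequences))
    records <- character(p$n_sequences)
    tx_rows <- list(); cds_rows <- list(); exon_rows <- list()
    model_rows <- list(); repeat_rows <- list()

    for (s in seq_len(p$n_sequences)) {
      mine <- blocks[seq_assign == s]
      parts <- character(0)
      offset <- 0L
      add <- function(txt) {
        parts[[length(parts) + 1L]] <<- txt
        offset <<- offset + nchar(txt)
      }
      for (b in mine) {
        add(random_bases(sample(seq(p$intergenic_bp_range[1],
                                    p$intergenic_bp_range[2]), 1L),
                         p$gc_content))
        if (b$kind == "gene") {
          g <- gene_blocks[[b$idx]]
          gid <- sprintf("g%04d", b$idx)
          tid <- paste0(gid, ".t1")
          tx_rows[[length(tx_rows) + 1L]] <- data.frame(
            transcript_id = tid, gene_id = gid, seq_id = seq_ids[s],
            strand = g$strand, stringsAsFactors = FALSE)
          seg <- data.frame(transcript_id = tid, start = offset + g$start,
                            end = offset + g$end, phase = g$phase,
                            stringsAsFactors = FALSE)
          cds_rows[[length(cds_rows) + 1L]] <- seg
          exon_rows[[length(exon_rows) + 1L]] <- seg[c("transcript_id", "start", "end")]
          model_rows[[length(model_rows) + 1L]] <- data.frame(
            model_id = gid, transcript_id = tid, seq_id = seq_ids[s],
            strand = g$strand, class = statuses[b$idx], provenance = "true",
            cds_len = g$cds_len, stringsAsFactors = FALSE)
          add(g$seq)
        } else {
          fam <- rep_family[b$idx]
          f <- families[[fam]]
          rep_seq <- if (p$softmask_repeats) tolower(f$seq) else f$seq
          repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
            seq_id = seq_ids[s], start = offset, end = offset + nchar(rep_seq),
            family = fam, orf_start = offset + f$orf_start,
            orf_end = offset + f$orf_end, stringsAsFactors = FALSE)
          add(rep_seq)
        }
      }
      add(random_bases(sample(seq(p$intergenic_bp_range[1],
                                  p$intergenic_bp_range[2]), 1L),
                       p$gc_content))
      s_seq <- paste(parts, collapse = "")
      if (!is.null(p$sequence_length_bp)) {
        if (nchar(s_seq) > p$sequence_length_bp) {
          stop("planted elements (", nchar(s_seq), " bp) exceed sequence_length_bp (",
               p$sequence_length_bp, "); increase sequence_length_bp")
        }
        s_seq <- paste0(s_seq, random_bases(p$sequence_length_bp - nchar(s_seq),
                                            p$gc_content))
      }
      records[s] <- s_seq
    }

    bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
    transcripts <- bind(tx_rows, data.frame(
      transcript_id = character(), gene_id = character(), seq_id = character(),
      strand = character(), stringsAsFactors = FALSE))
    cds <- bind(cds_rows, data.frame(
      transcript_id = character(), start = integer(), end = integer(),
      phase = integer(), stringsAsFactors = FALSE))
    exons <- bind(exon_rows, data.frame(
      transcript_id = character(), start = integer(), end = integer(),
      stringsAsFactors = FALSE))
    models <- bind(model_rows, data.frame(
      model_id = character(), transcript_id = character(), seq_id = character(),
      strand = character(), class = character(), provenance = character(),
      cds_len = integer(), stringsAsFactors = FALSE))
    repeats <- bind(repeat_rows, data.frame(
      seq_id = character(), start = integer(), end = integer(),
      family = integer(), orf_start = integer(), orf_end = integer(),
      stringsAsFactors = FALSE))
    models <- models[order(models$model_id), , drop = FALSE]
    rownames(models) <- rownames(repeats) <- NULL

    list(genome = genome_sequences(stats::setNames(records, seq_ids)),
         annotation = annotation_set(transcripts, exons, cds,
                                     source_label = "synthetic_truth"),
         ledger = structure(list(models = models, repeats = repeats),
                            class = "truth_ledger"))
  })
}

#' Corruption rates for the planted annotation
#'
#' Each rate controls one corruption operator: `splice_break` mutates a
#' donor GT (fraction of multi-exonic genes), `start_truncate` mutates the
#' start codon (fraction of all genes), `split_multi` breaks one intron of a
#' multi-exonic gene into two fragment genes, `duplicate_model` copies a
#' gene under a new id, and `spurious_mono_in_repeat` plants a single-exon
#' model on the ORF embedded in a repeat copy (fraction of repeat copies).
#' Victim counts are planted exactly (`round(rate * pool size)`); victims
#' are disjoint across operators.
#'
#' @param splice_break,start_truncate,split_multi,duplicate_model,spurious_mono_in_repeat
#'   Rates in `[0, 1]`.
#' @param seed Integer seed for the corruption stream (independent of the
#'   genome stream so one genome can host several corruption experiments).
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(splice_break = 0, start_truncate = 0,
                            split_multi = 0, duplicate_model = 0,
                            spurious_mono_in_repeat = 0, seed = 1L) {
  rates <- c(splice_break, start_truncate, split_multi, duplicate_model,
             spurious_mono_in_repeat)
  if (any(rates < 0 | rates > 1)) stop("corruption rates must be in [0, 1]")
  structure(list(splice_break = splice_break, start_truncate = start_truncate,
                 split_multi = split_multi, duplicate_model = duplicate_model,
                 spurious_mono_in_repeat = spurious_mono_in_repeat,
                 seed = seed), class = "corruption_spec")
}

edit_genome_base <- function(genome, seq_id, pos0, replacement) {
  s <- genome$records[[seq_id]]
  substr(s, pos0 + 1L, pos0 + nchar(replacement)) <- replacement
  genome$records[[seq_id]] <- s
  genome$lengths[[seq_id]] <- nchar(s)
  genome
}

#' Corrupt a true annotation (and genome) with planted defects
#'
#' Splice breaks and start truncations edit the genome sequence so the
#' defect is detectable from sequence alone; splits, duplicates and
#' repeat-derived spurious models edit the annotation. The returned truth
#' ledger describes every model in the corrupted annotation exactly once.
#'
#' @param truth The true [annotation_set] from [generate_genome()].
#' @param genome The matching [genome_sequences].
#' @param spec A [corruption_spec].
#' @param ledger The `truth_ledger` from [generate_genome()].
#' @return List with `annotation` (corrupted), `genome` (possibly edited),
#'   `ledger` (updated).
#' @export
corrupt_annotation <- function(truth, genome, spec, ledger) {
  stopifnot(inherits(spec, "corruption_spec"), inherits(ledger, "truth_ledger"))
  models <- ledger$models
  with_seed(spec$seed, {
    pool <- models$model_id
    multi0 <- models$model_id[models$class == "multi"]
    n_true <- nrow(models)

    pick <- function(ids, n) {
      if (n > length(ids)) stop("not enough uncorrupted genes for requested rates")
      safe_sample(ids, n)
    }
    splice_victims <- pick(multi0, round(spec$splice_break * length(multi0)))
    pool <- setdiff(pool, splice_victims)
    start_victims <- pick(pool, round(spec$start_truncate * n_true))
    pool <- setdiff(pool, start_victims)
    split_victims <- pick(intersect(pool, multi0),
                          round(spec$split_multi * length(multi0)))
    pool <- setdiff(pool, split_victims)
    dup_victims <- pick(pool, round(spec$duplicate_model * n_true))
    n_spur <- round(spec$spurious_mono_in_repeat * nrow(ledger$repeats))
    spur_rows <- if (n_spur > 0) {
      ledger$repeats[sort(safe_sample(seq_len(nrow(ledger$repeats)), n_spur)), ,
                     drop = FALSE]
    } else ledger$repeats[0, , drop = FALSE]

    tx_of <- stats::setNames(models$transcript_id, models$model_id)
    seq_of <- stats::setNames(models$seq_id, models$model_id)
    strand_of <- stats::setNames(models$strand, models$model_id)

    # --- splice breaks: mutate the donor dinucleotide of the 5'-most intron
    for (gid in splice_victims) {
      segs <- cds_segments_of(truth, tx_of[gid])
      k <- nrow(segs)
      if (strand_of[gid] == "+") {
        genome <- edit_genome_base(genome, seq_of[gid], segs$end[1], "CC")
      } else {
        # transcript-first intron sits between the two rightmost segments;
        # its donor occupies the two genomic bases before segment k's start
        genome <- edit_genome_base(genome, seq_of[gid], segs$start[k] - 2L, "GG")
      }
    }
    # --- start truncations: mutate the A of the ATG (keeps frame)
    for (gid in start_victims) {
      segs <- cds_segments_of(truth, tx_of[gid])
      if (strand_of[gid] == "+") {
        genome <- edit_genome_base(genome, seq_of[gid], segs$start[1], "C")
      } else {
        genome <- edit_genome_base(genome, seq_of[gid],
                                   segs$end[nrow(segs)] - 1L, "G")
      }
    }

    transcripts <- truth$transcripts
    exons <- truth$exons
    cds <- truth$cds

    # --- splits: one gene becomes two fragments at a random intron
    new_tx <- list(); new_ex <- list(); new_cds <- list(); new_models <- list()
    for (gid in split_victims) {
      tid <- tx_of[gid]
      segs <- cds_segments_of(truth, tid)
      k <- nrow(segs)
      j <- if (k == 2L) 1L else safe_sample(seq_len(k - 1L), 1L)
      for (part in 1:2) {
        ss <- if (part == 1) segs[seq_len(j), , drop = FALSE]
              else segs[(j + 1):k, , drop = FALSE]
        ngid <- paste0(gid, "_s", part)
        ntid <- paste0(ngid, ".t1")
        new_tx[[length(new_tx) + 1L]] <- data.frame(
          transcript_id = ntid, gene_id = ngid, seq_id = seq_of[gid],
          strand = strand_of[gid], stringsAsFactors = FALSE)
        seg <- data.frame(transcript_id = ntid, start = ss$start, end = ss$end,
                          phase = ss$phase, stringsAsFactors = FALSE)
        new_cds[[length(new_cds) + 1L]] <- seg
        new_ex[[length(new_ex) + 1L]] <- seg[c("transcript_id", "start", "end")]
        new_models[[length(new_models) + 1L]] <- data.frame(
          model_id = ngid, transcript_id = ntid, seq_id = seq_of[gid],
          strand = strand_of[gid],
          class = if (nrow(ss) == 1L) "mono" else "multi",
          provenance = "split_fragment", cds_len = sum(ss$end - ss$start),
          stringsAsFactors = FALSE)
      }
      transcripts <- transcripts[transcripts$transcript_id != tid, , drop = FALSE]
      exons <- exons[exons$transcript_id != tid, , drop = FALSE]
      cds <- cds[cds$transcript_id != tid, , drop = FALSE]
    }

    # --- duplicates: identical model under a new id
    for (gid in dup_victims) {
      tid <- tx_of[gid]
      ngid <- paste0(gid, "_d1")
      ntid <- paste0(ngid, ".t1")
      new_tx[[length(new_tx) + 1L]] <- data.frame(
        transcript_id = ntid, gene_id = ngid, seq_id = seq_of[gid],
        strand = strand_of[gid], stringsAsFactors = FALSE)
      cc <- cds[cds$transcript_id == tid, , drop = FALSE]
      cc$transcript_id <- ntid
      new_cds[[length(new_cds) + 1L]] <- cc
      ee <- exons[exons$transcript_id == tid, , drop = FALSE]
      ee$transcript_id <- ntid
      new_ex[[length(new_ex) + 1L]] <- ee
      new_models[[length(new_models) + 1L]] <- data.frame(
        model_id = ngid, transcript_id = ntid, seq_id = seq_of[gid],
        strand = strand_of[gid],
        class = models$class[models$model_id == gid],
        provenance = "duplicate", cds_len = sum(cc$end - cc$start),
        stringsAsFactors = FALSE)
    }

    # --- spurious single-exon models inside repeat copies
    if (nrow(spur_rows)) {
      for (i in seq_len(nrow(spur_rows))) {
        ngid <- sprintf("sp%03d", i)
        ntid <- paste0(ngid, ".t1")
        new_tx[[length(new_tx) + 1L]] <- data.frame(
          transcript_id = ntid, gene_id = ngid, seq_id = spur_rows$seq_id[i],
          strand = "+", stringsAsFactors = FALSE)
        seg <- data.frame(transcript_id = ntid, start = spur_rows$orf_start[i],
                          end = spur_rows$orf_end[i], phase = 0L,
                          stringsAsFactors = FALSE)
        new_cds[[length(new_cds) + 1L]] <- seg
        new_ex[[length(new_ex) + 1L]] <- seg[c("transcript_id", "start", "end")]
        new_models[[length(new_models) + 1L]] <- data.frame(
          model_id = ngid, transcript_id = ntid, seq_id = spur_rows$seq_id[i],
          strand = "+", class = "mono", provenance = "spurious_repeat",
          cds_len = spur_rows$orf_end[i] - spur_rows$orf_start[i],
          stringsAsFactors = FALSE)
      }
    }

    maybe_rbind <- function(base, lst) if (length(lst)) rbind(base, do.call(rbind, lst)) else base
    transcripts <- maybe_rbind(transcripts, new_tx)
    exons <- maybe_rbind(exons, new_ex)
    cds <- maybe_rbind(cds, new_cds)

    models$provenance[models$model_id %in% splice_victims] <- "splice_broken"
    models$provenance[models$model_id %in% start_victims] <- "start_truncated"
    models <- models[!models$model_id %in% split_victims, , drop = FALSE]
    if (length(new_models)) models <- rbind(models, do.call(rbind, new_models))
    models <- models[order(models$model_id), , drop = FALSE]
    rownames(models) <- NULL

    list(annotation = annotation_set(transcripts, exons, cds,
                                     source_label = "synthetic_corrupted",
                                     provenance_log = "corrupt_annotation"),
         genome = genome,
         ledger = structure(list(models = models, repeats = ledger$repeats),
                            class = "truth_ledger"))
  })
}

#' Generate matched evidence tables for a truth ledger
#'
#' True gene models receive a Pfam domain row with probability
#' `1 - domain_fn_rate`, a similarity hit with reciprocal coverages drawn
#' from `coverage_range` (above 0.70 by default, so the hit passes the
#' reciprocal test), and an ortholog-group row with probability `orth_rate`.
#' Corrupted and spurious models receive no evidence. Evidence identifiers
#' are protein-style (`<transcript>.p1`) to exercise id normalization.
#'
#' @param ledger A `truth_ledger`.
#' @param domain_fn_rate Domain false-negative rate for true genes.
#' @param orth_rate Ortholog assignment probability for true genes.
#' @param coverage_range Range the query/subject coverages are drawn from.
#' @param seed Integer seed for the evidence stream.
#' @return List with `domains` (`domain_evidence`), `hits`
#'   (`similarity_hits`), `orthologs` (`ortholog_evidence`), and the
#'   `ledger` updated with `has_domain`, `ortholog`, `qcov`, `scov`.
#' @export
generate_evidence <- function(ledger, domain_fn_rate = 0, orth_rate = 1,
                              coverage_range = c(0.75, 0.98), seed = 1L) {
  stopifnot(inherits(ledger, "truth_ledger"),
            domain_fn_rate >= 0, domain_fn_rate <= 1,
            orth_rate >= 0, orth_rate <= 1)
  models <- ledger$models
  with_seed(seed, {
    tr <- models[models$provenance == "true", , drop = FALSE]
    n <- nrow(tr)
    raw_id <- paste0(tr$transcript_id, ".p1")
    has_domain <- stats::runif(n) >= domain_fn_rate
    has_orth <- stats::runif(n) < orth_rate
    qcov0 <- stats::runif(n, coverage_range[1], coverage_range[2])
    scov0 <- stats::runif(n, coverage_range[1], coverage_range[2])

    domains <- data.frame(
      model_id_raw = raw_id[has_domain],
      analysis = "Pfam",
      signature = sprintf("PF%05d", sample.int(99999L, sum(has_domain),
                                               replace = TRUE)),
      model_id = normalize_model_ids(raw_id[has_domain]),
      stringsAsFactors = FALSE)
    class(domains) <- c("domain_evidence", class(domains))

    qlen <- pmax(100L, tr$cds_len %/% 3L)
    slen <- sample(100:500, n, replace = TRUE)
    qend <- as.integer(ceiling(qcov0 * qlen))
    send <- as.integer(ceiling(scov0 * slen))
    hits <- data.frame(
      qseqid = raw_id, sseqid = sprintf("SUBJ_%s", tr$model_id),
      pident = round(stats::runif(n, 70, 99), 1),
      length = qend, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = qend, sstart = 1L, send = send,
      evalue = 1e-50, bitscore = round(stats::runif(n, 200, 900), 1),
      qlen = as.numeric(qlen), slen = as.numeric(slen),
      stringsAsFactors = FALSE)
    hits$qcov <- pmin(1, (abs(hits$qend - hits$qstart) + 1) / hits$qlen)
    hits$scov <- pmin(1, (abs(hits$send - hits$sstart) + 1) / hits$slen)
    hits$query_gene <- normalize_model_ids(hits$qseqid)
    class(hits) <- c("similarity_hits", class(hits))

    orthologs <- data.frame(
      model_id_raw = raw_id[has_orth],
      group = sprintf("OG%05d@Viridiplantae", sample.int(99999L, sum(has_orth),
                                                         replace = TRUE)),
      model_id = normalize_model_ids(raw_id[has_orth]),
      stringsAsFactors = FALSE)
    class(orthologs) <- c("ortholog_evidence", class(orthologs))

    models$has_domain <- models$ortholog <- NA
    models$qcov <- models$scov <- NA_real_
    idx <- match(tr$model_id, models$model_id)
    models$has_domain[idx] <- has_domain
    models$ortholog[idx] <- has_orth
    models$qcov[idx] <- hits$qcov
    models$scov[idx] <- hits$scov

    list(domains = domains, hits = hits, orthologs = orthologs,
         ledger = structure(list(models = models, repeats = ledger$repeats),
                            class = "truth_ledger"))
  })
}

#' Write evidence tables in their native text formats
#'
#' Emits an InterProScan-style TSV, a 14-column similarity tabular file, and
#' an EggNOG-style ortholog TSV that round-trip through the package readers.
#'
#' @param evidence The list returned by [generate_evidence()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_evidence_tables <- function(evidence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dom_path <- file.path(dir, "domains.tsv")
  d <- evidence$domains
  writeLines(if (nrow(d)) {
    paste(d$model_id_raw, "md5", "500", d$analysis, d$signature,
          "synthetic Pfam domain", "1", "100", "1e-10", "T", "2026-01-01",
          sep = "\t")
  } else character(0), dom_path)

  hit_path <- file.path(dir, "similarity.tsv")
  h <- evidence$hits
  writeLines(if (nrow(h)) {
    paste(h$qseqid, h$sseqid, h$pident, h$length, h$mismatch, h$gapopen,
          h$qstart, h$qend, h$sstart, h$send,
          format(h$evalue, scientific = TRUE), h$bitscore, h$qlen, h$slen,
          sep = "\t")
  } else character(0), hit_path)

  orth_path <- file.path(dir, "orthologs.tsv")
  o <- evidence$orthologs
  writeLines(c("#query\tseed_ortholog",
               if (nrow(o)) paste(o$model_id_raw, o$group, sep = "\t")),
             orth_path)
  c(domains = dom_path, similarity = hit_path, orthologs = orth_path)
}

#' Write a truth ledger as TSV
#' @param ledger A `truth_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger_models_tsv <- function(ledger, path) {
  utils::write.table(ledger$models, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate a complete fixture bundle on disk
#'
#' Writes the genome FASTA, truth and (optionally) corrupted GFF3, the truth
#' ledger, the evidence tables, and a manifest JSON recording parameters,
#' file paths and checksums.
#'
#' @param params A [generator_params].
#' @param corruption Optional [corruption_spec].
#' @param evidence_args List of arguments passed to [generate_evidence()].
#' @param dir Output directory.
#' @return The manifest list, invisibly.
#' @export
simulate_bundle <- function(params, corruption = NULL,
                            evidence_args = list(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_genome(params)
  ann <- g$annotation
  genome <- g$genome
  ledger <- g$ledger
  files <- c(genome = file.path(dir, "genome.fa"),
             truth = file.path(dir, "truth.gff3"))
  write_gff3(ann, files["truth"])
  if (!is.null(corruption)) {
    cor <- corrupt_annotation(ann, genome, corruption, ledger)
    genome <- cor$genome
    ledger <- cor$ledger
    files["corrupted"] <- file.path(dir, "corrupted.gff3")
    write_gff3(cor$annotation, files["corrupted"])
  }
  write_fasta(genome, files["genome"])
  ev <- do.call(generate_evidence, c(list(ledger = ledger), evidence_args))
  ledger <- ev$ledger
  files <- c(files, write_evidence_tables(ev, dir))
  files["ledger"] <- file.path(dir, "ledger.tsv")
  write_ledger_models_tsv(ledger, files["ledger"])
  manifest <- list(
    params = unclass(params),
    corruption = if (is.null(corruption)) NULL else unclass(corruption),
    files = as.list(stats::setNames(basename(files), names(files))),
    md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                  names(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(manifest)
}
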