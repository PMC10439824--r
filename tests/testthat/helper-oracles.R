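# Independent brute-force oracles. These deliberately re-derive everything
# from raw file text (or from the plain data tables) with their own parsing
# and arithmetic, sharing no code path with the package implementation.

oracle_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# recompute all summary statistics from raw GFF3 (and optionally FASTA) text
oracle_metrics <- function(gff3_path, fasta_path = NULL) {
  lines <- readLines(gff3_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(seq = vapply(f, `[`, "", 1), type = vapply(f, `[`, "", 3),
                   start = as.integer(vapply(f, `[`, "", 4)),
                   end = as.integer(vapply(f, `[`, "", 5)),
                   strand = vapply(f, `[`, "", 7),
                   phase = vapply(f, `[`, "", 8),
                   attrs = vapply(f, `[`, "", 9), stringsAsFactors = FALSE)
  mrna <- df[df$type == "mRNA", ]
  tx2gene <- stats::setNames(oracle_attr(mrna$attrs, "Parent"),
                             oracle_attr(mrna$attrs, "ID"))
  cds <- df[df$type == "CDS", ]
  cds$tx <- oracle_attr(cds$attrs, "Parent")
  ex <- df[df$type == "exon", ]
  ex$tx <- oracle_attr(ex$attrs, "Parent")

  genes <- unique(unname(tx2gene))
  if (length(genes) == 0) {
    return(list(total = 0L, mono = 0L, multi = 0L, ratio = NA_real_))
  }
  # representative: max total CDS length, tie -> smallest transcript id
  cds_len <- tapply(cds$end - cds$start + 1L, cds$tx, sum)
  rep_tx <- vapply(genes, function(g) {
    txs <- names(tx2gene)[tx2gene == g]
    lens <- cds_len[txs]
    lens[is.na(lens)] <- 0
    cand <- txs[lens == max(lens)]
    sort(cand)[1]
  }, character(1))
  n_seg <- tapply(cds$tx, cds$tx, length)
  rep_nseg <- as.integer(n_seg[rep_tx])
  rep_len <- as.numeric(cds_len[rep_tx])
  # gene span from exon rows of all its transcripts
  gene_len <- vapply(genes, function(g) {
    txs <- names(tx2gene)[tx2gene == g]
    rows <- ex[ex$tx %in% txs, ]
    max(rows$end) - min(rows$start) + 1L
  }, numeric(1))
  mono <- rep_nseg == 1L
  oracle_n50 <- function(v) {
    if (!length(v)) return(0)
    v <- sort(v, decreasing = TRUE)
    for (i in seq_along(v)) if (sum(v[1:i]) * 2 >= sum(v)) return(v[i])
  }
  cls <- function(sel) list(
    n = sum(sel),
    mean_gene = if (any(sel)) mean(gene_len[sel]) else NA_real_,
    mean_cds = if (any(sel)) mean(rep_len[sel]) else NA_real_,
    mean_ex = if (any(sel)) mean(rep_nseg[sel]) else NA_real_,
    n50 = oracle_n50(rep_len[sel]))
  out <- list(total = length(genes), mono = sum(mono), multi = sum(!mono),
              ratio = if (sum(!mono) > 0) sum(mono) / sum(!mono) else NA_real_,
              mean_gene = mean(gene_len), mean_cds = mean(rep_len),
              mean_ex = mean(rep_nseg), n50 = oracle_n50(rep_len),
              mono_stats = cls(mono), multi_stats = cls(!mono))
  if (!is.null(fasta_path)) {
    fl <- readLines(fasta_path)
    hdr <- grep("^>", fl)
    seqs <- stats::setNames(vapply(seq_along(hdr), function(i) {
      from <- hdr[i] + 1L
      to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(fl)
      paste(fl[from:to], collapse = "")
    }, character(1)), sub("^>(\\S+).*", "\\1", fl[hdr]))
    strand_of <- stats::setNames(mrna$strand, oracle_attr(mrna$attrs, "ID"))
    seq_of <- stats::setNames(mrna$seq, oracle_attr(mrna$attrs, "ID"))
    complete <- vapply(rep_tx, function(t) {
      rows <- cds[cds$tx == t, ]
      rows <- rows[order(rows$start), ]
      pieces <- substring(seqs[[seq_of[t]]], rows$start, rows$end)
      if (strand_of[t] == "-") {
        s <- paste(vapply(rev(pieces), oracle_revcomp, ""), collapse = "")
        ph <- as.integer(rows$phase[nrow(rows)])
      } else {
        s <- toupper(paste(pieces, collapse = ""))
        ph <- as.integer(rows$phase[1])
      }
      s <- toupper(substring(s, ph + 1))
      nc <- nchar(s) %/% 3
      last <- substring(s, 3 * nc - 2, 3 * nc)
      substring(s, 1, 3) == "ATG" && last %in% c("TAA", "TAG", "TGA")
    }, logical(1))
    out$complete <- sum(complete)
  }
  out
}

# brute-force comparison oracle over the raw annotation tables
oracle_scores <- function(pred, ref, mono_min = 0.80) {
  info <- function(ann) {
    cds <- ann$cds[order(ann$cds$transcript_id, ann$cds$start), ]
    strand <- stats::setNames(ann$transcripts$strand, ann$transcripts$transcript_id)
    seqid <- stats::setNames(ann$transcripts$seq_id, ann$transcripts$transcript_id)
    gene <- stats::setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
    by <- split(cds, cds$transcript_id)
    list(by = by, strand = strand, seqid = seqid, gene = gene,
         tx = ann$transcripts$transcript_id)
  }
  p <- info(pred); r <- info(ref)
  # nucleotide: explicit per-base sets
  bases <- function(x) {
    unlist(lapply(names(x$by), function(t) {
      cc <- x$by[[t]]
      unlist(lapply(seq_len(nrow(cc)), function(i) {
        paste0(x$seqid[t], x$strand[t], ":", seq(cc$start[i] + 1, cc$end[i]))
      }))
    }))
  }
  pb <- unique(bases(p)); rb <- unique(bases(r))
  nt <- c(tp = length(intersect(pb, rb)), fp = length(setdiff(pb, rb)),
          fn = length(setdiff(rb, pb)))
  # transcript: chain equality for multi, greedy reciprocal overlap for mono
  chain <- function(x, t) {
    cc <- x$by[[t]]
    if (is.null(cc) || nrow(cc) < 2) return(NA_character_)
    paste(x$seqid[t], x$strand[t],
          paste(cc$end[-nrow(cc)], cc$start[-1], collapse = ";"))
  }
  p_chain <- vapply(p$tx, function(t) chain(p, t), character(1))
  r_chain <- vapply(r$tx, function(t) chain(r, t), character(1))
  tp_multi <- 0L
  gene_pairs <- list()
  for (k in unique(stats::na.omit(p_chain))) {
    np <- sort(p$tx[!is.na(p_chain) & p_chain == k])
    nr <- sort(r$tx[!is.na(r_chain) & r_chain == k])
    m <- min(length(np), length(nr))
    tp_multi <- tp_multi + m
    if (m > 0) for (i in seq_len(m)) {
      gene_pairs[[length(gene_pairs) + 1L]] <- c(p$gene[np[i]], r$gene[nr[i]])
    }
  }
  mono_iv <- function(x, t) {
    cc <- x$by[[t]]
    if (is.null(cc) || nrow(cc) != 1) return(NULL)
    c(cc$start, cc$end)
  }
  edges <- list()
  for (tp_ in p$tx) {
    ivp <- mono_iv(p, tp_)
    if (is.null(ivp)) next
    for (tr_ in r$tx) {
      if (p$seqid[tp_] != r$seqid[tr_] || p$strand[tp_] != r$strand[tr_]) next
      ivr <- mono_iv(r, tr_)
      if (is.null(ivr)) next
      ov <- max(0, min(ivp[2], ivr[2]) - max(ivp[1], ivr[1]))
      if (ov / (ivp[2] - ivp[1]) >= mono_min && ov / (ivr[2] - ivr[1]) >= mono_min) {
        edges[[length(edges) + 1L]] <- data.frame(
          p = tp_, r = tr_, s = min(ov / (ivp[2] - ivp[1]), ov / (ivr[2] - ivr[1])),
          stringsAsFactors = FALSE)
      }
    }
  }
  tp_mono <- 0L
  if (length(edges)) {
    e <- do.call(rbind, edges)
    e <- e[order(-e$s, pmin(e$p, e$r), pmax(e$p, e$r)), ]
    up <- ur <- character(0)
    for (i in seq_len(nrow(e))) {
      if (e$p[i] %in% up || e$r[i] %in% ur) next
      tp_mono <- tp_mono + 1L
      up <- c(up, e$p[i]); ur <- c(ur, e$r[i])
      gene_pairs[[length(gene_pairs) + 1L]] <- c(p$gene[e$p[i]], r$gene[e$r[i]])
    }
  }
  tp_tx <- tp_multi + tp_mono
  tx <- c(tp = tp_tx, fp = length(p$tx) - tp_tx, fn = length(r$tx) - tp_tx)
  # gene level: one-to-one over induced gene pairs
  gp <- unique(do.call(rbind, c(gene_pairs, list(matrix(character(0), ncol = 2)))))
  tp_g <- 0L
  if (!is.null(gp) && nrow(gp)) {
    gp <- gp[order(pmin(gp[, 1], gp[, 2]), pmax(gp[, 1], gp[, 2])), , drop = FALSE]
    up <- ur <- character(0)
    for (i in seq_len(nrow(gp))) {
      if (gp[i, 1] %in% up || gp[i, 2] %in% ur) next
      tp_g <- tp_g + 1L
      up <- c(up, gp[i, 1]); ur <- c(ur, gp[i, 2])
    }
  }
  ng <- function(ann) length(unique(ann$transcripts$gene_id))
  gene <- c(tp = tp_g, fp = ng(pred) - tp_g, fn = ng(ref) - tp_g)
  list(nucleotide = nt, transcript = tx, gene = gene)
}
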