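#' Transcript matching rule for annotation comparison
#'
#' Multi-exonic transcripts match on exact coding intron-chain equality
#' (same sequence and strand); mono-exonic transcripts match on reciprocal
#' CDS overlap of at least `mono_overlap_min` in both directions. Matching
#' is CDS-based and ignores UTRs.
#'
#' @param mono_overlap_min Reciprocal overlap fraction in (0, 1].
#' @return An object of class `match_rule`.
#' @export
match_rule <- function(mono_overlap_min = 0.80) {
  if (!(mono_overlap_min > 0 && mono_overlap_min <= 1)) {
    stop("`mono_overlap_min` must be in (0, 1]")
  }
  structure(list(mono_overlap_min = mono_overlap_min), class = "match_rule")
}

# per-transcript matching attributes: seq, strand, intron chain key,
# mono CDS interval, total CDS width
tx_match_info <- function(ann) {
  tr <- ann$transcripts
  if (nrow(tr) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      seq_id = character(), strand = character(),
                      n_cds = integer(), chain = character(),
                      cds_start = integer(), cds_end = integer(),
                      cds_w = integer(), stringsAsFactors = FALSE))
  }
  cds <- ann$cds[order(ann$cds$transcript_id, ann$cds$start), , drop = FALSE]
  by_tx <- split(cds[c("start", "end")], cds$transcript_id)
  info <- tr
  idx <- match(info$transcript_id, names(by_tx))
  info$n_cds <- vapply(idx, function(i) if (is.na(i)) 0L else nrow(by_tx[[i]]),
                       integer(1))
  info$chain <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    if (is.na(i) || nrow(by_tx[[i]]) < 2) return(NA_character_)
    cc <- by_tx[[i]]
    n <- nrow(cc)
    paste(cc$end[-n], cc$start[-1], sep = ":", collapse = ",")
  }, character(1))
  info$cds_start <- vapply(idx, function(i) if (is.na(i)) NA_integer_
                           else min(by_tx[[i]]$start), integer(1))
  info$cds_end <- vapply(idx, function(i) if (is.na(i)) NA_integer_
                         else max(by_tx[[i]]$end), integer(1))
  info$cds_w <- vapply(idx, function(i) if (is.na(i)) 0L
                       else sum(by_tx[[i]]$end - by_tx[[i]]$start), integer(1))
  info
}

#' Match predicted transcripts to reference transcripts
#'
#' One-to-one matching restricted to the same sequence and strand:
#' multi-exonic transcripts pair by exact coding intron-chain equality,
#' mono-exonic transcripts pair greedily by reciprocal CDS overlap (largest
#' overlap first, deterministic id-based tie-breaks). Each predicted
#' transcript is matched to at most one reference transcript and vice versa.
#'
#' @param pred,ref [annotation_set]s on the same coordinate space.
#' @param rule A [match_rule].
#' @return data.frame with columns `pred_tx`, `ref_tx`, `class`
#'   (`"multi"`/`"mono"`).
#' @export
match_transcripts <- function(pred, ref, rule = match_rule()) {
  stopifnot(inherits(rule, "match_rule"))
  pi <- tx_match_info(pred)
  ri <- tx_match_info(ref)
  matches <- list()

  # multi-exonic: exact intron-chain equality within (seq, strand)
  pm <- pi[pi$n_cds >= 2, , drop = FALSE]
  rm_ <- ri[ri$n_cds >= 2, , drop = FALSE]
  if (nrow(pm) && nrow(rm_)) {
    pkey <- paste(pm$seq_id, pm$strand, pm$chain, sep = "|")
    rkey <- paste(rm_$seq_id, rm_$strand, rm_$chain, sep = "|")
    for (key in intersect(unique(pkey), unique(rkey))) {
      ps <- sort(pm$transcript_id[pkey == key])
      rs <- sort(rm_$transcript_id[rkey == key])
      n <- min(length(ps), length(rs))
      matches[[length(matches) + 1L]] <-
        data.frame(pred_tx = ps[seq_len(n)], ref_tx = rs[seq_len(n)],
                   class = "multi", stringsAsFactors = FALSE)
    }
  }

  # mono-exonic: reciprocal overlap, greedy one-to-one
  pm1 <- pi[pi$n_cds == 1, , drop = FALSE]
  rm1 <- ri[ri$n_cds == 1, , drop = FALSE]
  if (nrow(pm1) && nrow(rm1)) {
    edges <- list()
    pg <- paste(pm1$seq_id, pm1$strand)
    rg <- paste(rm1$seq_id, rm1$strand)
    for (key in intersect(unique(pg), unique(rg))) {
      pp <- pm1[pg == key, , drop = FALSE]
      rr <- rm1[rg == key, , drop = FALSE]
      for (i in seq_len(nrow(pp))) {
        ov <- pmax(0L, pmin(pp$cds_end[i], rr$cds_end) -
                        pmax(pp$cds_start[i], rr$cds_start))
        fp <- ov / (pp$cds_end[i] - pp$cds_start[i])
        fr <- ov / (rr$cds_end - rr$cds_start)
        ok <- fp >= rule$mono_overlap_min & fr >= rule$mono_overlap_min
        if (any(ok)) {
          edges[[length(edges) + 1L]] <- data.frame(
            pred_tx = pp$transcript_id[i], ref_tx = rr$transcript_id[ok],
            score = pmin(fp, fr)[ok], stringsAsFactors = FALSE)
        }
      }
    }
    if (length(edges)) {
      e <- do.call(rbind, edges)
      # canonical, direction-independent ordering for deterministic symmetry
      lo <- pmin(e$pred_tx, e$ref_tx)
      hi <- pmax(e$pred_tx, e$ref_tx)
      e <- e[order(-e$score, lo, hi), , drop = FALSE]
      used_p <- used_r <- character(0)
      keep <- logical(nrow(e))
      for (i in seq_len(nrow(e))) {
        if (e$pred_tx[i] %in% used_p || e$ref_tx[i] %in% used_r) next
        keep[i] <- TRUE
        used_p <- c(used_p, e$pred_tx[i])
        used_r <- c(used_r, e$ref_tx[i])
      }
      e <- e[keep, , drop = FALSE]
      if (nrow(e)) {
        matches[[length(matches) + 1L]] <-
          data.frame(pred_tx = e$pred_tx, ref_tx = e$ref_tx, class = "mono",
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(matches) == 0) {
    return(data.frame(pred_tx = character(), ref_tx = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, matches)
  rownames(out) <- NULL
  out
}

ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Score a predicted annotation against a reference
#'
#' Sensitivity, precision and F1 at the nucleotide, transcript and gene
#' levels. Transcript level: one-to-one transcript matches under the
#' [match_rule]. Gene level: one-to-one gene pairs induced by transcript
#' matches (a gene counts when at least one of its transcripts matches).
#' Nucleotide level: strand-aware set arithmetic on CDS bases. The
#' `false_positive_rate` column is `1 - precision`, reported for parity with
#' benchmark plots that use that name for the prediction-side error; it is
#' not the classical FPR over a negative class.
#'
#' @param pred,ref [annotation_set]s.
#' @param level `"nucleotide"`, `"transcript"`, `"gene"`, or `"all"`.
#' @param rule A [match_rule].
#' @return data.frame of class `comparison_scores`: one row per level with
#'   `tp`, `fp`, `fn`, `sensitivity`, `precision`, `f1`,
#'   `false_positive_rate`. Undefined quantities (empty basis) are `NA`.
#' @export
score_annotations <- function(pred, ref, level = "all", rule = match_rule()) {
  level <- match.arg(level, c("all", "nucleotide", "transcript", "gene"))
  want <- if (level == "all") c("nucleotide", "transcript", "gene") else level
  rows <- list()

  if ("nucleotide" %in% want) {
    pr <- cds_range_list(pred)
    rr <- cds_range_list(ref)
    keys <- union(names(pr), names(rr))
    tp <- fp <- fn <- 0
    for (k in keys) {
      p <- pr[[k]] %||% IRanges::IRanges()
      r <- rr[[k]] %||% IRanges::IRanges()
      i <- IRanges::intersect(p, r)
      tp <- tp + sum(IRanges::width(i))
      fp <- fp + sum(IRanges::width(p)) - sum(IRanges::width(i))
      fn <- fn + sum(IRanges::width(r)) - sum(IRanges::width(i))
    }
    rows$nucleotide <- c(tp = tp, fp = fp, fn = fn)
  }

  if (any(c("transcript", "gene") %in% want)) {
    m <- match_transcripts(pred, ref, rule)
    if ("transcript" %in% want) {
      rows$transcript <- c(tp = nrow(m),
                           fp = nrow(pred$transcripts) - nrow(m),
                           fn = nrow(ref$transcripts) - nrow(m))
    }
    if ("gene" %in% want) {
      pg <- stats::setNames(pred$transcripts$gene_id, pred$transcripts$transcript_id)
      rg <- stats::setNames(ref$transcripts$gene_id, ref$transcripts$transcript_id)
      pairs <- unique(data.frame(pred_gene = unname(pg[m$pred_tx]),
                                 ref_gene = unname(rg[m$ref_tx]),
                                 stringsAsFactors = FALSE))
      if (nrow(pairs)) {
        lo <- pmin(pairs$pred_gene, pairs$ref_gene)
        hi <- pmax(pairs$pred_gene, pairs$ref_gene)
        pairs <- pairs[order(lo, hi), , drop = FALSE]
        used_p <- used_r <- character(0)
        tp <- 0L
        for (i in seq_len(nrow(pairs))) {
          if (pairs$pred_gene[i] %in% used_p || pairs$ref_gene[i] %in% used_r) next
          tp <- tp + 1L
          used_p <- c(used_p, pairs$pred_gene[i])
          used_r <- c(used_r, pairs$ref_gene[i])
        }
      } else tp <- 0L
      rows$gene <- c(tp = tp, fp = n_genes(pred) - tp, fn = n_genes(ref) - tp)
    }
  }

  out <- do.call(rbind, lapply(names(rows), function(lv) {
    v <- rows[[lv]]
    sens <- ratio_or_na(v["tp"], v["tp"] + v["fn"])
    prec <- ratio_or_na(v["tp"], v["tp"] + v["fp"])
    f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0) {
      2 * sens * prec / (sens + prec)
    } else NA_real_
    data.frame(level = lv, tp = unname(v["tp"]), fp = unname(v["fp"]),
               fn = unname(v["fn"]), sensitivity = unname(sens),
               precision = unname(prec), f1 = unname(f1),
               false_positive_rate = unname(1 - prec),
               stringsAsFactors = FALSE)
  }))
  out <- out[match(want, out$level), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("comparison_scores", class(out))
  out
}

# reduced CDS ranges per (seq_id, strand), over all transcripts
cds_range_list <- function(ann) {
  if (nrow(ann$cds) == 0) return(list())
  strand_of <- stats::setNames(ann$transcripts$strand,
                               ann$transcripts$transcript_id)
  seq_of <- stats::setNames(ann$transcripts$seq_id,
                            ann$transcripts$transcript_id)
  key <- paste(seq_of[ann$cds$transcript_id], strand_of[ann$cds$transcript_id])
  lapply(split(ann$cds[c("start", "end")], key), function(df) {
    IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  })
}

#' Write comparison scores as TSV
#' @param scores A `comparison_scores` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
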