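#' Hierarchical gene-model container
#'
#' An `annotation_set` holds gene -> transcript -> exon/CDS structures in
#' genomic coordinates. Coordinates are stored 0-based half-open throughout
#' the package; the GFF3 reader/writer is the only place 1-based inclusive
#' coordinates appear, which keeps interval arithmetic free of off-by-one
#' adjustments.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `seq_id`, `strand`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`.
#' @param cds data.frame with columns `transcript_id`, `start`, `end`, `phase`.
#' @param source_label Free-text provenance label.
#' @param provenance_log Character vector of applied operations.
#' @param validate Check structural invariants (unique ids, sorted
#'   non-overlapping segments, CDS contained in exons).
#' @return An object of class `annotation_set` with elements `genes`,
#'   `transcripts`, `exons`, `cds`, `source_label`, `provenance_log`.
#' @export
annotation_set <- function(transcripts, exons, cds,
                           source_label = "annoqc",
                           provenance_log = character(),
                           validate = TRUE) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table missing column(s): ",
                           paste(miss, collapse = ", "))
    df[cols]
  }
  transcripts <- need(transcripts, c("transcript_id", "gene_id", "seq_id", "strand"),
                      "transcripts")
  exons <- need(exons, c("transcript_id", "start", "end"), "exons")
  cds <- need(cds, c("transcript_id", "start", "end", "phase"), "cds")
  for (col in c("transcript_id", "gene_id", "seq_id", "strand")) {
    transcripts[[col]] <- as.character(transcripts[[col]])
  }
  exons$transcript_id <- as.character(exons$transcript_id)
  cds$transcript_id <- as.character(cds$transcript_id)
  for (col in c("start", "end")) {
    exons[[col]] <- as.integer(exons[[col]])
    cds[[col]] <- as.integer(cds[[col]])
  }
  cds$phase <- as.integer(cds$phase)

  # canonical row order makes writers deterministic and equality structural
  exons <- exons[order(exons$transcript_id, exons$start, exons$end), , drop = FALSE]
  cds <- cds[order(cds$transcript_id, cds$start, cds$end), , drop = FALSE]
  transcripts <- transcripts[order(transcripts$gene_id, transcripts$transcript_id), ,
                             drop = FALSE]
  rownames(transcripts) <- rownames(exons) <- rownames(cds) <- NULL

  if (validate) {
    validate_annotation_tables(transcripts, exons, cds)
  }
  genes <- derive_gene_table(transcripts, exons, cds)
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, source_label = source_label,
                 provenance_log = provenance_log),
            class = "annotation_set")
}

validate_annotation_tables <- function(transcripts, exons, cds) {
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicate transcript_id: ",
         transcripts$transcript_id[duplicated(transcripts$transcript_id)][1])
  }
  if (!all(transcripts$strand %in% c("+", "-"))) {
    stop("transcript strand must be '+' or '-'")
  }
  known <- transcripts$transcript_id
  orphan <- setdiff(unique(c(exons$transcript_id, cds$transcript_id)), known)
  if (length(orphan)) stop("exon/CDS rows reference unknown transcript: ", orphan[1])
  if (nrow(exons) && any(exons$start >= exons$end)) stop("exon with start >= end")
  if (nrow(cds) && any(cds$start >= cds$end)) stop("CDS with start >= end")
  if (nrow(cds) && !all(cds$phase %in% 0:2)) stop("CDS phase must be 0, 1 or 2")
  check_disjoint <- function(df, what) {
    if (nrow(df) < 2) return(invisible())
    # df is sorted by transcript_id then start
    same <- df$transcript_id[-1] == df$transcript_id[-nrow(df)]
    bad <- same & (df$start[-1] < df$end[-nrow(df)])
    if (any(bad)) stop("overlapping ", what, " segments in transcript ",
                       df$transcript_id[-1][bad][1])
  }
  check_disjoint(exons, "exon")
  check_disjoint(cds, "CDS")
  # every CDS segment contained in some exon of the same transcript
  if (nrow(cds)) {
    ex_by_tx <- split(exons[c("start", "end")], exons$transcript_id)
    for (tx in unique(cds$transcript_id)) {
      ex <- ex_by_tx[[tx]]
      if (is.null(ex)) stop("CDS without exons in transcript ", tx)
      cc <- cds[cds$transcript_id == tx, , drop = FALSE]
      ok <- vapply(seq_len(nrow(cc)), function(i) {
        any(ex$start <= cc$start[i] & cc$end[i] <= ex$end)
      }, logical(1))
      if (!all(ok)) stop("CDS segment not contained in any exon of transcript ", tx)
    }
  }
  invisible()
}

derive_gene_table <- function(transcripts, exons, cds) {
  if (nrow(transcripts) == 0) {
    return(data.frame(gene_id = character(), seq_id = character(),
                      strand = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  seg <- rbind(exons[c("transcript_id", "start", "end")],
               cds[c("transcript_id", "start", "end")])
  tx_start <- tapply(seg$start, seg$transcript_id, min)
  tx_end <- tapply(seg$end, seg$transcript_id, max)
  tr <- transcripts
  tr$start <- as.integer(tx_start[tr$transcript_id])
  tr$end <- as.integer(tx_end[tr$transcript_id])
  if (anyNA(tr$start)) stop("transcript without exon or CDS segments: ",
                            tr$transcript_id[is.na(tr$start)][1])
  seqs <- tapply(tr$seq_id, tr$gene_id, function(x) length(unique(x)))
  strs <- tapply(tr$strand, tr$gene_id, function(x) length(unique(x)))
  if (any(seqs > 1)) stop("gene with transcripts on multiple sequences: ",
                          names(seqs)[seqs > 1][1])
  if (any(strs > 1)) stop("gene with transcripts on multiple strands: ",
                          names(strs)[strs > 1][1])
  genes <- data.frame(
    gene_id = names(tapply(tr$start, tr$gene_id, min)),
    seq_id = as.character(tapply(tr$seq_id, tr$gene_id, `[`, 1)),
    strand = as.character(tapply(tr$strand, tr$gene_id, `[`, 1)),
    start = as.integer(tapply(tr$start, tr$gene_id, min)),
    end = as.integer(tapply(tr$end, tr$gene_id, max)),
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$seq_id, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Number of genes in an annotation set
#' @param ann An [annotation_set].
#' @return Integer count.
#' @export
n_genes <- function(ann) nrow(ann$genes)

#' Gene identifiers of an annotation set
#' @param ann An [annotation_set].
#' @return Character vector.
#' @export
gene_ids <- function(ann) ann$genes$gene_id

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> '", x$source_label, "': ", nrow(x$genes), " gene(s), ",
      nrow(x$transcripts), " transcript(s), ", nrow(x$cds), " CDS segment(s)\n",
      sep = "")
  invisible(x)
}

#' Subset an annotation set to a set of genes
#' @param ann An [annotation_set].
#' @param keep Character vector of gene ids to retain.
#' @param log Optional provenance string appended to the log.
#' @return An [annotation_set].
#' @export
subset_annotation <- function(ann, keep, log = NULL) {
  tr <- ann$transcripts[ann$transcripts$gene_id %in% keep, , drop = FALSE]
  tx <- tr$transcript_id
  annotation_set(tr,
                 ann$exons[ann$exons$transcript_id %in% tx, , drop = FALSE],
                 ann$cds[ann$cds$transcript_id %in% tx, , drop = FALSE],
                 source_label = ann$source_label,
                 provenance_log = c(ann$provenance_log, log),
                 validate = FALSE)
}

#' Combine two annotation sets with disjoint identifiers
#' @param a,b [annotation_set] objects.
#' @return An [annotation_set] holding the union of gene models.
#' @export
combine_annotations <- function(a, b) {
  if (length(intersect(a$genes$gene_id, b$genes$gene_id))) {
    stop("gene ids overlap between the two annotation sets")
  }
  if (length(intersect(a$transcripts$transcript_id, b$transcripts$transcript_id))) {
    stop("transcript ids overlap between the two annotation sets")
  }
  annotation_set(rbind(a$transcripts, b$transcripts),
                 rbind(a$exons, b$exons),
                 rbind(a$cds, b$cds),
                 source_label = a$source_label,
                 provenance_log = unique(c(a$provenance_log, b$provenance_log)),
                 validate = FALSE)
}

#' Structural equality of two annotation sets
#'
#' Compares the gene/transcript/exon/CDS tables in canonical order and ignores
#' source labels and provenance logs.
#'
#' @param a,b [annotation_set] objects.
#' @return Logical scalar.
#' @export
annotation_identical <- function(a, b) {
  isTRUE(all.equal(a$genes, b$genes, check.attributes = FALSE)) &&
    isTRUE(all.equal(a$transcripts, b$transcripts, check.attributes = FALSE)) &&
    isTRUE(all.equal(a$exons, b$exons, check.attributes = FALSE)) &&
    isTRUE(all.equal(a$cds, b$cds, check.attributes = FALSE))
}

#' Read a GFF3 annotation into an annotation set
#'
#' Accepts the common predictor dialects: features linked by `ID`/`Parent`
#' or by GTF-like `gene_id`/`transcript_id` attributes; exons are synthesized
#' from CDS when a transcript carries CDS rows only; CDS rows parented by
#' multiple transcripts are duplicated per parent (with a warning); exon-only
#' noncoding transcripts are dropped with a logged counter, as are
#' CDS-bearing transcripts on strand `.`.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional [genome_sequences]; when supplied every feature is
#'   bounds-checked against it.
#' @param source_label Provenance label; defaults to the file name.
#' @return An [annotation_set]. GFF3 1-based inclusive coordinates are
#'   converted to the internal 0-based half-open convention.
#' @export
read_gff3 <- function(path, genome = NULL, source_label = basename(path)) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  df <- as.data.frame(rtracklayer::readGFF(path))
  log <- character()
  if (nrow(df) == 0) {
    return(annotation_set(
      data.frame(transcript_id = character(), gene_id = character(),
                 seq_id = character(), strand = character()),
      data.frame(transcript_id = character(), start = integer(), end = integer()),
      data.frame(transcript_id = character(), start = integer(), end = integer(),
                 phase = integer()),
      source_label = source_label, provenance_log = "read_gff3: empty file"))
  }
  df$seqid <- as.character(df$seqid)
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  get_attr <- function(col) {
    if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, nrow(df))
  }
  id_attr <- get_attr("ID")
  gene_attr <- get_attr("gene_id")
  tx_attr <- get_attr("transcript_id")
  parents <- if ("Parent" %in% names(df)) {
    lapply(seq_len(nrow(df)), function(i) as.character(df$Parent[[i]]))
  } else {
    rep(list(character(0)), nrow(df))
  }
  first_parent <- vapply(parents, function(p) if (length(p)) p[1] else NA_character_,
                         character(1))

  is_gene <- df$type == "gene"
  is_tx <- df$type %in% c("mRNA", "transcript")
  is_exon <- df$type == "exon"
  is_cds <- df$type == "CDS"
  n_other <- sum(!(is_gene | is_tx | is_exon | is_cds))
  if (n_other > 0) log <- c(log, paste0("read_gff3: ignored ", n_other,
                                        " row(s) of other feature types"))

  gene_ids_seen <- unique(stats::na.omit(c(id_attr[is_gene],
                                           gene_attr[is_gene])))
  # transcript registry: id -> gene parent
  tx_id <- ifelse(!is.na(id_attr), id_attr, tx_attr)[is_tx]
  tx_parent <- ifelse(!is.na(first_parent), first_parent, gene_attr)[is_tx]
  if (any(is.na(tx_id))) stop("mRNA/transcript row without ID or transcript_id")
  tx_map <- stats::setNames(tx_parent, tx_id)
  if (anyNA(tx_map)) {
    # transcript without a gene parent: promote to its own gene
    orphan_tx <- names(tx_map)[is.na(tx_map)]
    tx_map[orphan_tx] <- orphan_tx
    gene_ids_seen <- unique(c(gene_ids_seen, orphan_tx))
  }

  seg_parent_ids <- function(i) {
    p <- parents[[i]]
    if (length(p) == 0 && !is.na(tx_attr[i])) p <- tx_attr[i]
    p
  }

  seg_rows <- which(is_exon | is_cds)
  seg_tx <- vector("list", length(seg_rows))
  multi_parent_cds <- 0L
  for (k in seq_along(seg_rows)) {
    i <- seg_rows[k]
    p <- seg_parent_ids(i)
    if (length(p) == 0) {
      stop("orphan ", df$type[i], " row (no Parent/transcript_id) at ",
           df$seqid[i], ":", df$start[i], "-", df$end[i])
    }
    resolved <- character(0)
    for (pp in p) {
      if (pp %in% names(tx_map)) {
        resolved <- c(resolved, pp)
      } else if (!is.na(tx_attr[i]) && pp == tx_attr[i]) {
        # GTF-like dialect: the segment row itself declares its transcript
        tx_map[pp] <- if (!is.na(gene_attr[i])) gene_attr[i] else pp
        resolved <- c(resolved, pp)
      } else if (pp %in% gene_ids_seen) {
        # segment parented directly by a gene: synthesize one transcript
        syn <- paste0(pp, ".t1")
        tx_map[syn] <- pp
        resolved <- c(resolved, syn)
      } else {
        stop("orphan ", df$type[i], " row: parent '", pp,
             "' has no gene/transcript definition")
      }
    }
    if (is_cds[i] && length(resolved) > 1) multi_parent_cds <- multi_parent_cds + 1L
    seg_tx[[k]] <- resolved
  }
  if (multi_parent_cds > 0) {
    warning(multi_parent_cds,
            " CDS row(s) with multiple parents duplicated per parent")
    log <- c(log, paste0("read_gff3: ", multi_parent_cds,
                         " multi-parent CDS row(s) duplicated"))
  }

  reps <- lengths(seg_tx)
  seg <- data.frame(
    transcript_id = unlist(seg_tx),
    seq_id = rep(df$seqid[seg_rows], reps),
    strand = rep(df$strand[seg_rows], reps),
    type = rep(df$type[seg_rows], reps),
    start = rep(as.integer(df$start[seg_rows]) - 1L, reps),  # -> 0-based
    end = rep(as.integer(df$end[seg_rows]), reps),
    phase = rep(suppressWarnings(as.integer(df$phase[seg_rows])), reps),
    stringsAsFactors = FALSE)

  # per-transcript seq_id/strand from the segments themselves
  tx_ids_used <- unique(seg$transcript_id)
  tx_seq <- tapply(seg$seq_id, seg$transcript_id, `[`, 1)
  tx_strand_u <- tapply(seg$strand, seg$transcript_id, function(s) {
    u <- unique(s); if (length(u) == 1) u else NA_character_
  })
  if (anyNA(tx_strand_u)) stop("transcript with segments on mixed strands: ",
                               names(tx_strand_u)[is.na(tx_strand_u)][1])

  has_cds <- tx_ids_used %in% seg$transcript_id[seg$type == "CDS"]
  strand_ok <- tx_strand_u[tx_ids_used] %in% c("+", "-")
  dropped_dot <- tx_ids_used[has_cds & !strand_ok]
  dropped_noncoding <- tx_ids_used[!has_cds]
  if (length(dropped_dot)) {
    log <- c(log, paste0("read_gff3: dropped ", length(dropped_dot),
                         " CDS-bearing transcript(s) with strand '.'"))
  }
  if (length(dropped_noncoding)) {
    log <- c(log, paste0("read_gff3: ignored ", length(dropped_noncoding),
                         " exon-only noncoding transcript(s)"))
  }
  keep_tx <- setdiff(tx_ids_used[has_cds & strand_ok], NA)
  seg <- seg[seg$transcript_id %in% keep_tx, , drop = FALSE]

  transcripts <- data.frame(
    transcript_id = keep_tx,
    gene_id = unname(ifelse(is.na(tx_map[keep_tx]) | !nzchar(tx_map[keep_tx]),
                            keep_tx, tx_map[keep_tx])),
    seq_id = unname(tx_seq[keep_tx]),
    strand = unname(tx_strand_u[keep_tx]),
    stringsAsFactors = FALSE)

  cds <- seg[seg$type == "CDS", c("transcript_id", "start", "end", "phase")]
  exons <- seg[seg$type == "exon", c("transcript_id", "start", "end")]
  # synthesize exons from CDS for transcripts lacking exon rows
  no_exon <- setdiff(keep_tx, unique(exons$transcript_id))
  if (length(no_exon)) {
    synth <- cds[cds$transcript_id %in% no_exon, c("transcript_id", "start", "end")]
    exons <- rbind(exons, synth)
    log <- c(log, paste0("read_gff3: synthesized exons from CDS for ",
                         length(no_exon), " transcript(s)"))
  }

  # infer missing phases: 0 for the 5'-most segment, propagated downstream
  if (anyNA(cds$phase) && nrow(cds)) {
    cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
    strand_of <- stats::setNames(transcripts$strand, transcripts$transcript_id)
    cds <- do.call(rbind, lapply(split(cds, cds$transcript_id), function(cc) {
      if (!anyNA(cc$phase)) return(cc)
      ord <- if (strand_of[cc$transcript_id[1]] == "-") rev(seq_len(nrow(cc))) else seq_len(nrow(cc))
      ph <- integer(nrow(cc))
      carry <- 0L
      for (j in ord) {
        ph[j] <- (3L - carry) %% 3L
        carry <- (carry + (cc$end[j] - cc$start[j])) %% 3L
      }
      cc$phase <- ph
      cc
    }))
    log <- c(log, "read_gff3: inferred missing CDS phases")
  }

  if (!is.null(genome)) {
    unknown <- setdiff(unique(transcripts$seq_id), names(genome$records))
    if (length(unknown)) stop("unknown seq_id in annotation: ", unknown[1])
    lens <- genome$lengths[seg$seq_id]
    bad <- seg$end > lens | seg$start < 0
    if (any(bad)) {
      b <- which(bad)[1]
      stop("feature beyond sequence end: ", seg$seq_id[b], ":",
           seg$start[b] + 1L, "-", seg$end[b], " (", df$type[1], ") exceeds length ",
           lens[b])
    }
  }

  annotation_set(transcripts, exons, cds, source_label = source_label,
                 provenance_log = log)
}

#' Write an annotation set to GFF3
#'
#' The writer is deterministic: genes are sorted by sequence, start, then
#' gene id; children follow their parents; attributes are normalized to
#' `ID`/`Parent`. Coordinates are re-emitted 1-based inclusive, so
#' `read_gff3(write_gff3(x))` is structurally equal to `x`.
#'
#' @param ann An [annotation_set].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, source = "annoqc") {
  stopifnot(inherits(ann, "annotation_set"))
  lines <- "##gff-version 3"
  genes <- ann$genes  # already sorted seq_id, start, gene_id
  ex_by_tx <- split(ann$exons, ann$exons$transcript_id)
  cds_by_tx <- split(ann$cds, ann$cds$transcript_id)
  fmt <- function(seq_id, type, start0, end0, strand, phase, attrs) {
    paste(seq_id, source, type, start0 + 1L, end0, ".", strand,
          phase, attrs, sep = "\t")
  }
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gl <- fmt(g$seq_id, "gene", g$start, g$end, g$strand, ".",
              paste0("ID=", g$gene_id))
    tr <- ann$transcripts[ann$transcripts$gene_id == g$gene_id, , drop = FALSE]
    tr <- tr[order(tr$transcript_id), , drop = FALSE]
    tls <- lapply(seq_len(nrow(tr)), function(j) {
      t <- tr[j, ]
      ex <- ex_by_tx[[t$transcript_id]]
      cc <- cds_by_tx[[t$transcript_id]]
      span <- range(c(ex$start, ex$end, cc$start, cc$end))
      ml <- fmt(t$seq_id, "mRNA", span[1], span[2], t$strand, ".",
                paste0("ID=", t$transcript_id, ";Parent=", g$gene_id))
      el <- if (!is.null(ex) && nrow(ex)) {
        fmt(t$seq_id, "exon", ex$start, ex$end, t$strand, ".",
            paste0("Parent=", t$transcript_id))
      } else character(0)
      cl <- if (!is.null(cc) && nrow(cc)) {
        fmt(t$seq_id, "CDS", cc$start, cc$end, t$strand, cc$phase,
            paste0("Parent=", t$transcript_id))
      } else character(0)
      c(ml, el, cl)
    })
    out[[i]] <- c(gl, unlist(tls))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, unlist(out)), con, sep = "\n")
  invisible(path)
}
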