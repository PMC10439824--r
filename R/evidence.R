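#' Normalize evidence model identifiers to gene identifiers
#'
#' Protein and transcript identifiers emitted by frame-selection and
#' annotation tools carry suffixes over the gene id (`.p1`, `.t2`, `-RA`).
#' These are stripped repeatedly until a fixed point, which bridges
#' InterProScan/alignment/ortholog tables keyed by protein id back to the
#' gene models they describe.
#'
#' @param ids Character vector of model identifiers.
#' @return Character vector of normalized (gene-level) identifiers.
#' @export
normalize_model_ids <- function(ids) {
  ids <- as.character(ids)
  repeat {
    out <- sub("\\.p[0-9]+$", "", ids)
    out <- sub("\\.t[0-9]+$", "", out)
    out <- sub("-R[A-Z]$", "", out)
    if (identical(out, ids)) return(out)
    ids <- out
  }
}

#' Read an InterProScan-style protein-domain table
#'
#' Consumes the 11-to-15-column InterProScan TSV. Column 1 is the protein
#' accession, column 4 the member-database analysis, column 5 the signature
#' accession. Only rows whose analysis is in `analysis_filter` are retained
#' (Pfam by default). An empty file is valid (no domain evidence).
#'
#' @param path Path to the TSV.
#' @param analysis_filter Character vector of analyses to keep.
#' @return data.frame of class `domain_evidence` with columns
#'   `model_id_raw`, `analysis`, `signature`, `model_id` (normalized).
#' @export
read_domain_table <- function(path, analysis_filter = "Pfam") {
  if (!file.exists(path)) stop("domain table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 5)
  if (length(short)) {
    stop("domain table row with fewer than 5 columns at line ", short[1],
         " of ", path)
  }
  raw <- vapply(fields, `[`, character(1), 1)
  analysis <- vapply(fields, `[`, character(1), 4)
  signature <- vapply(fields, `[`, character(1), 5)
  keep <- analysis %in% analysis_filter
  out <- data.frame(model_id_raw = raw[keep], analysis = analysis[keep],
                    signature = signature[keep],
                    model_id = normalize_model_ids(raw[keep]),
                    stringsAsFactors = FALSE)
  class(out) <- c("domain_evidence", class(out))
  out
}

similarity_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore")

read_length_sidecar <- function(x, what) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    df <- utils::read.table(x, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    x <- stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
  }
  if (is.null(names(x))) stop(what, " lengths must be a named vector or a ",
                              "two-column TSV path")
  x
}

#' Read a tabular similarity-search result with coverages
#'
#' Accepts the standard 12-column BLAST/DIAMOND tabular format, or the
#' 14-column variant with query and subject lengths appended. For the
#' 12-column dialect both length sidecars are required, otherwise reciprocal
#' coverage cannot be computed. Coverages are `(|end - start| + 1) / length`
#' on the 1-based inclusive tabular coordinates, clamped to 1; reversed
#' coordinate pairs (subject frame notation) are handled by the absolute
#' span.
#'
#' @param path Path to the tabular file.
#' @param query_lengths,subject_lengths Named numeric vectors (id -> length)
#'   or paths to two-column TSV files; required for 12-column input.
#' @return data.frame of class `similarity_hits` with the tabular columns
#'   plus `qlen`, `slen`, `qcov`, `scov`, and normalized `query_gene`.
#' @export
read_alignment_table <- function(path, query_lengths = NULL,
                                 subject_lengths = NULL) {
  if (!file.exists(path)) stop("alignment table not found: ", path)
  n_lines <- length(readLines(path, n = 1L, warn = FALSE))
  if (n_lines == 0) {
    df <- data.frame(matrix(nrow = 0, ncol = 14))
    names(df) <- c(similarity_cols, "qlen", "slen")
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) == 12) {
      if (is.null(query_lengths) || is.null(subject_lengths)) {
        stop("cannot compute reciprocal coverage: 12-column table requires ",
             "query_lengths and subject_lengths sidecars")
      }
      names(df) <- similarity_cols
      ql <- read_length_sidecar(query_lengths, "query")
      sl <- read_length_sidecar(subject_lengths, "subject")
      if (!all(df$qseqid %in% names(ql))) {
        stop("query id missing from length sidecar: ",
             setdiff(df$qseqid, names(ql))[1])
      }
      if (!all(df$sseqid %in% names(sl))) {
        stop("subject id missing from length sidecar: ",
             setdiff(df$sseqid, names(sl))[1])
      }
      df$qlen <- unname(ql[df$qseqid])
      df$slen <- unname(sl[df$sseqid])
    } else if (ncol(df) == 14) {
      names(df) <- c(similarity_cols, "qlen", "slen")
    } else {
      stop("alignment table must have 12 or 14 tab-separated columns, found ",
           ncol(df))
    }
  }
  df$qcov <- pmin(1, (abs(df$qend - df$qstart) + 1) / df$qlen)
  df$scov <- pmin(1, (abs(df$send - df$sstart) + 1) / df$slen)
  if (nrow(df) && any(df$qcov <= 0 | df$scov <= 0, na.rm = TRUE)) {
    stop("nonpositive alignment coverage; check length sidecars")
  }
  df$query_gene <- normalize_model_ids(df$qseqid)
  class(df) <- c("similarity_hits", class(df))
  df
}

#' Read an EggNOG-mapper-style ortholog table
#'
#' Comment lines (`#`) are skipped; column 1 is the query model id, and
#' `group_col` carries the ortholog-group (seed ortholog) label.
#'
#' @param path Path to the TSV.
#' @param group_col Column index of the group label.
#' @return data.frame of class `ortholog_evidence` with `model_id_raw`,
#'   `group`, `model_id` (normalized).
#' @export
read_ortholog_table <- function(path, group_col = 2L) {
  if (!file.exists(path)) stop("ortholog table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- data.frame(model_id_raw = character(), group = character(),
                      model_id = character(), stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < group_col)) {
      stop("ortholog table row with fewer than ", group_col, " columns")
    }
    raw <- vapply(fields, `[`, character(1), 1)
    out <- data.frame(model_id_raw = raw,
                      group = vapply(fields, `[`, character(1), group_col),
                      model_id = normalize_model_ids(raw),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("ortholog_evidence", class(out))
  out
}

#' Reciprocal-coverage test for similarity hits
#'
#' A hit passes when the alignment covers at least `threshold` of both the
#' query and the subject length (the "70 percent reciprocal" criterion; the
#' boundary is inclusive).
#'
#' @param hits A `similarity_hits` data.frame.
#' @param threshold Coverage fraction in (0, 1].
#' @return Logical vector, one element per hit.
#' @export
reciprocal_pass <- function(hits, threshold = 0.70) {
  if (is.null(hits) || nrow(hits) == 0) return(logical(0))
  hits$qcov >= threshold & hits$scov >= threshold
}

#' Reciprocal-coverage annotation rate
#'
#' The percentage of genes with at least one similarity hit passing the
#' reciprocal-coverage test, overall and by exonic class. An empty class
#' yields `NA` for that class.
#'
#' @param ann An [annotation_set].
#' @param hits A `similarity_hits` data.frame (or `NULL` for no evidence).
#' @param threshold Reciprocal coverage threshold.
#' @return List with `overall`, `mono`, `multi` (percent), plus
#'   `annotated_genes` and `total_genes` counts.
#' @export
annotation_rate <- function(ann, hits, threshold = 0.70) {
  status <- if (n_genes(ann)) classify_exonic_status(ann) else
    stats::setNames(character(0), character(0))
  annotated <- character(0)
  if (!is.null(hits) && nrow(hits)) {
    annotated <- intersect(unique(hits$query_gene[reciprocal_pass(hits, threshold)]),
                           names(status))
  }
  pct <- function(ids) {
    if (length(ids) == 0) return(NA_real_)
    100 * sum(ids %in% annotated) / length(ids)
  }
  list(overall = if (length(status)) pct(names(status)) else NA_real_,
       mono = pct(names(status)[status == "mono"]),
       multi = pct(names(status)[status == "multi"]),
       annotated_genes = length(annotated),
       total_genes = length(status),
       threshold = threshold)
}

#' Round 1: certify mono-exonic genes by protein domains
#'
#' Single-exon models are the class most inflated by repeat-derived false
#' positives; a gene is kept only if at least one retained domain row maps
#' to it. Passing a set containing multi-exonic genes is an error: the
#' filter is defined on the mono partition.
#'
#' @param mono [annotation_set] of mono-exonic genes.
#' @param domains A `domain_evidence` data.frame.
#' @return List with `annotation` and `ledger`.
#' @export
filter_mono_by_domain <- function(mono, domains) {
  if (n_genes(mono)) {
    status <- classify_exonic_status(mono)
    if (any(status != "mono")) {
      stop("filter_mono_by_domain expects only mono-exonic genes; found multi: ",
           names(status)[status != "mono"][1])
    }
  }
  evidenced <- if (is.null(domains) || nrow(domains) == 0) character(0)
               else unique(domains$model_id)
  rep <- representative_transcripts(mono)
  removed <- setdiff(rep$gene_id, evidenced)
  filter_result(mono, removed, rep, "mono_domain",
                rep("mono_no_domain", length(removed)),
                rep("no retained domain row", length(removed)),
                log = paste0("filter_mono_by_domain: removed ", length(removed)))
}

#' Round 2: certify multi-exonic genes by ortholog or similarity evidence
#'
#' A multi-exonic gene is removed only when it has neither an ortholog-group
#' assignment nor a similarity hit passing the reciprocal-coverage test
#' (disjunctive evidence). Passing mono-exonic genes is an error.
#'
#' @param multi [annotation_set] of multi-exonic genes.
#' @param hits A `similarity_hits` data.frame (or `NULL`).
#' @param orthologs An `ortholog_evidence` data.frame (or `NULL`).
#' @param threshold Reciprocal coverage threshold.
#' @return List with `annotation` and `ledger`.
#' @export
filter_multi_by_homology <- function(multi, hits, orthologs, threshold = 0.70) {
  if (n_genes(multi)) {
    status <- classify_exonic_status(multi)
    if (any(status != "multi")) {
      stop("filter_multi_by_homology expects only multi-exonic genes; found mono: ",
           names(status)[status != "multi"][1])
    }
  }
  orth_ids <- if (is.null(orthologs) || nrow(orthologs) == 0) character(0)
              else unique(orthologs$model_id)
  hit_ids <- if (is.null(hits) || nrow(hits) == 0) character(0)
             else unique(hits$query_gene[reciprocal_pass(hits, threshold)])
  evidenced <- union(orth_ids, hit_ids)
  rep <- representative_transcripts(multi)
  removed <- setdiff(rep$gene_id, evidenced)
  filter_result(multi, removed, rep, "multi_homology",
                rep("multi_no_evidence", length(removed)),
                rep("no ortholog group and no reciprocal hit", length(removed)),
                log = paste0("filter_multi_by_homology: removed ", length(removed)))
}

#' Two-round evidence refinement of an annotation set
#'
#' Implements the two-stage protocol: deduplicate, partition by exonic
#' status, round 1 removes mono-exonic genes without a protein domain (multi
#' genes untouched), round 2 removes multi-exonic genes without an ortholog
#' group or a reciprocal-coverage similarity hit (mono genes, already
#' certified by domains, untouched). Survivors are merged and the summary
#' statistics and annotation rate are recomputed before and after.
#'
#' @param ann An [annotation_set].
#' @param genome Optional [genome_sequences] for ORF completeness in the
#'   before/after reports.
#' @param domains A `domain_evidence` data.frame.
#' @param hits A `similarity_hits` data.frame.
#' @param orthologs An `ortholog_evidence` data.frame.
#' @param threshold Reciprocal coverage threshold.
#' @return List with `annotation` (survivors) and `report` (class
#'   `refinement_report`: per-round counts, before/after `metrics_report`s,
#'   before/after annotation rates, combined rejection ledger).
#' @export
two_round_refinement <- function(ann, genome = NULL, domains = NULL,
                                 hits = NULL, orthologs = NULL,
                                 threshold = 0.70) {
  before_metrics <- suppressWarnings(compute_summary(ann, genome))
  before_rate <- annotation_rate(ann, hits, threshold)
  dd <- deduplicate_models(ann)
  parts <- partition_by_exonic_status(dd$annotation)
  r1 <- filter_mono_by_domain(parts$mono, domains)
  r2 <- filter_multi_by_homology(parts$multi, hits, orthologs, threshold)
  merged <- combine_annotations(r1$annotation, r2$annotation)
  merged$provenance_log <- c(merged$provenance_log, "two_round_refinement")
  after_metrics <- suppressWarnings(compute_summary(merged, genome))
  after_rate <- annotation_rate(merged, hits, threshold)
  rounds <- data.frame(
    stage = c("deduplicate", "round1_mono_domain", "round2_multi_homology"),
    input = c(n_genes(ann), n_genes(parts$mono), n_genes(parts$multi)),
    removed = c(nrow(dd$ledger), nrow(r1$ledger), nrow(r2$ledger)),
    survivors = c(n_genes(dd$annotation), n_genes(r1$annotation),
                  n_genes(r2$annotation)),
    stringsAsFactors = FALSE)
  report <- structure(list(
    rounds = rounds,
    before_metrics = before_metrics, after_metrics = after_metrics,
    before_rate = before_rate, after_rate = after_rate,
    ledger = rbind(dd$ledger, r1$ledger, r2$ledger),
    threshold = threshold), class = "refinement_report")
  list(annotation = merged, report = report)
}

#' @export
print.refinement_report <- function(x, ...) {
  cat("<refinement_report> reciprocal threshold", x$threshold, "\n")
  print(x$rounds, row.names = FALSE)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", v))
  cat(sprintf("  annotation rate: %s -> %s\n", fmt(x$before_rate$overall),
              fmt(x$after_rate$overall)))
  rr <- function(m) ifelse(is.na(m$mono_multi_ratio), "undefined",
                           sprintf("%.3f", m$mono_multi_ratio))
  cat(sprintf("  mono:multi ratio: %s -> %s\n", rr(x$before_metrics),
              rr(x$after_metrics)))
  invisible(x)
}

#' Write a refinement report as JSON
#' @param report A `refinement_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refinement_json <- function(report, path) {
  x <- list(rounds = report$rounds,
            before = unclass(report$before_metrics),
            after = unclass(report$after_metrics),
            before_rate = report$before_rate,
            after_rate = report$after_rate,
            threshold = report$threshold)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Full structural + evidence refinement pipeline
#'
#' Applies the structural filters (canonical splice sites, ORF integrity,
#' minimum CDS length) and then the two-round evidence refinement. This is
#' the recommended post-prediction workflow for a raw predictor output.
#'
#' @param ann An [annotation_set].
#' @param genome A [genome_sequences].
#' @param domains,hits,orthologs Evidence tables (see the readers).
#' @param splice A [splice_rule].
#' @param min_cds_bp Minimum representative CDS length.
#' @param threshold Reciprocal coverage threshold.
#' @param require_start,require_stop,forbid_internal_stop ORF checks.
#' @param skip_structural Apply only the evidence rounds.
#' @return List with `annotation`, `ledger` (all stages), and `report`
#'   (the two-round `refinement_report`).
#' @export
refine_annotation <- function(ann, genome, domains = NULL, hits = NULL,
                              orthologs = NULL, splice = splice_rule("strict"),
                              min_cds_bp = 300L, threshold = 0.70,
                              require_start = TRUE, require_stop = TRUE,
                              forbid_internal_stop = TRUE,
                              skip_structural = FALSE) {
  ledgers <- list()
  cur <- ann
  if (!skip_structural) {
    st <- filter_canonical_splice(cur, genome, splice)
    ledgers$splice <- st$ledger; cur <- st$annotation
    st <- filter_orf_integrity(cur, genome, require_start, require_stop,
                               forbid_internal_stop)
    ledgers$orf <- st$ledger; cur <- st$annotation
    st <- filter_min_cds_length(cur, min_cds_bp)
    ledgers$len <- st$ledger; cur <- st$annotation
  }
  tr <- two_round_refinement(cur, genome, domains, hits, orthologs, threshold)
  ledger <- rbind(do.call(rbind, unname(ledgers)), tr$report$ledger)
  rownames(ledger) <- NULL
  list(annotation = tr$annotation, ledger = ledger, report = tr$report)
}
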