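#' Classify genes as mono- or multi-exonic
#'
#' A gene is mono-exonic when its representative transcript has exactly one
#' CDS segment; otherwise it is multi-exonic. Noncoding representatives (no
#' CDS at all) are an error: such models must be filtered out upstream.
#'
#' @param ann An [annotation_set].
#' @return Named character vector (`"mono"`/`"multi"`), one entry per gene.
#' @export
classify_exonic_status <- function(ann) {
  rep <- representative_transcripts(ann)
  if (any(rep$n_cds == 0)) {
    stop("gene(s) whose representative transcript has no CDS: ",
         rep$gene_id[rep$n_cds == 0][1])
  }
  stats::setNames(ifelse(rep$n_cds == 1L, "mono", "multi"), rep$gene_id)
}

#' Mono:multi ratio
#'
#' The count ratio of single-exon to multi-exon gene models; values near or
#' below 0.2 are typical of curated eukaryotic annotations, and inflation
#' above that is a signature of repeat-derived false positives.
#'
#' @param mono_count,multi_count Nonnegative gene counts.
#' @return `mono_count / multi_count`, or `NA` (with a warning) when
#'   `multi_count` is zero.
#' @export
mono_multi_ratio <- function(mono_count, multi_count) {
  if (mono_count < 0 || multi_count < 0) stop("counts must be nonnegative")
  if (multi_count == 0) {
    warning("multi-exonic count is zero; mono:multi ratio undefined")
    return(NA_real_)
  }
  mono_count / multi_count
}

#' Structural summary statistics of an annotation set
#'
#' Computes the per-gene benchmark statistics over representative
#' transcripts: counts by exonic class, mono:multi ratio, mean gene span and
#' CDS lengths, mean CDS segments per gene, CDS N50, ORF completeness count,
#' and the same length statistics broken down by class.
#'
#' @param ann An [annotation_set].
#' @param genome Optional [genome_sequences]; required for
#'   `genes_with_start_and_stop` (reported `NA` when absent).
#' @return An object of class `metrics_report` (a list; see fields in source).
#' @export
compute_summary <- function(ann, genome = NULL) {
  if (n_genes(ann) == 0) {
    empty_class <- data.frame(
      class = c("mono", "multi"), n = c(0L, 0L),
      mean_gene_length_bp = c(NA_real_, NA_real_),
      mean_cds_length_bp = c(NA_real_, NA_real_),
      mean_exons_per_gene = c(NA_real_, NA_real_),
      cds_n50_bp = c(0, 0), stringsAsFactors = FALSE)
    return(structure(list(
      total_genes = 0L, mono_count = 0L, multi_count = 0L,
      mono_multi_ratio = NA_real_, mean_gene_length_bp = 0,
      mean_cds_length_bp = 0, mean_exons_per_gene = 0, cds_n50_bp = 0,
      genes_with_start_and_stop = if (is.null(genome)) NA_integer_ else 0L,
      per_class = empty_class), class = "metrics_report"))
  }
  rep <- representative_transcripts(ann)
  status <- classify_exonic_status(ann)[rep$gene_id]
  gene_len <- stats::setNames(ann$genes$end - ann$genes$start, ann$genes$gene_id)
  gene_len <- gene_len[rep$gene_id]

  complete <- NA_integer_
  complete_by_gene <- NULL
  if (!is.null(genome)) {
    complete_by_gene <- vapply(seq_len(nrow(rep)), function(i) {
      tl <- translate_cds(extract_cds_sequence(ann, rep$transcript_id[i], genome))
      tl$has_start && tl$has_terminal_stop
    }, logical(1))
    complete <- sum(complete_by_gene)
  }

  class_stats <- function(sel) {
    data.frame(
      n = sum(sel),
      mean_gene_length_bp = if (any(sel)) mean(gene_len[sel]) else NA_real_,
      mean_cds_length_bp = if (any(sel)) mean(rep$cds_len[sel]) else NA_real_,
      mean_exons_per_gene = if (any(sel)) mean(rep$n_cds[sel]) else NA_real_,
      cds_n50_bp = n50(rep$cds_len[sel]))
  }
  per_class <- cbind(data.frame(class = c("mono", "multi"),
                                stringsAsFactors = FALSE),
                     rbind(class_stats(status == "mono"),
                           class_stats(status == "multi")))
  mono_n <- sum(status == "mono")
  multi_n <- sum(status == "multi")
  ratio <- if (multi_n > 0) mono_n / multi_n else {
    warning("multi-exonic count is zero; mono:multi ratio undefined")
    NA_real_
  }
  structure(list(
    total_genes = nrow(rep),
    mono_count = mono_n,
    multi_count = multi_n,
    mono_multi_ratio = ratio,
    mean_gene_length_bp = mean(gene_len),
    mean_cds_length_bp = mean(rep$cds_len),
    mean_exons_per_gene = mean(rep$n_cds),
    cds_n50_bp = n50(rep$cds_len),
    genes_with_start_and_stop = complete,
    per_class = per_class), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  genes: %d (mono %d, multi %d; mono:multi %s)\n",
              x$total_genes, x$mono_count, x$multi_count,
              ifelse(is.na(x$mono_multi_ratio), "undefined",
                     sprintf("%.3f", x$mono_multi_ratio))))
  cat(sprintf("  mean gene length: %.1f bp; mean CDS length: %.1f bp\n",
              x$mean_gene_length_bp, x$mean_cds_length_bp))
  cat(sprintf("  mean CDS segments/gene: %.2f; CDS N50: %d bp\n",
              x$mean_exons_per_gene, as.integer(x$cds_n50_bp)))
  if (!is.na(x$genes_with_start_and_stop)) {
    cat(sprintf("  genes with start & stop codon: %d\n",
                x$genes_with_start_and_stop))
  }
  invisible(x)
}

#' Evaluate a metrics report against benchmark thresholds
#'
#' Applies the published working thresholds for plant structural
#' annotations: mono:multi ratio at or below 0.2 (the "near 0.2" ideal, with
#' an inclusive boundary), reciprocal-similarity annotation rate of at least
#' 80 percent, and BUSCO completeness strictly above 95 percent. Inputs not
#' supplied are reported as not evaluated (`NA`).
#'
#' @param report A `metrics_report`, or a single numeric mono:multi ratio.
#' @param annotation_rate Optional overall annotation rate (percent).
#' @param busco_complete Optional BUSCO complete percentage.
#' @param thresholds List with `ratio_max`, `rate_min`, `busco_min`.
#' @return An object of class `benchmark_verdict`: list with logical (or NA)
#'   `ratio_ok`, `annotation_rate_ok`, `busco_ok`, and the `thresholds` used.
#' @export
evaluate_thresholds <- function(report, annotation_rate = NULL,
                                busco_complete = NULL,
                                thresholds = list(ratio_max = 0.2,
                                                  rate_min = 80,
                                                  busco_min = 95)) {
  ratio <- if (inherits(report, "metrics_report")) report$mono_multi_ratio
           else as.numeric(report)
  structure(list(
    ratio_ok = if (is.na(ratio)) NA else ratio <= thresholds$ratio_max,
    annotation_rate_ok = if (is.null(annotation_rate)) NA
                         else annotation_rate >= thresholds$rate_min,
    busco_ok = if (is.null(busco_complete)) NA
               else busco_complete > thresholds$busco_min,
    thresholds = thresholds), class = "benchmark_verdict")
}

#' @export
print.benchmark_verdict <- function(x, ...) {
  show <- function(v) if (is.na(v)) "not evaluated" else if (v) "PASS" else "FAIL"
  cat("<benchmark_verdict>\n")
  cat("  mono:multi ratio (<=", x$thresholds$ratio_max, "): ", show(x$ratio_ok), "\n", sep = "")
  cat("  annotation rate (>=", x$thresholds$rate_min, "%): ",
      show(x$annotation_rate_ok), "\n", sep = "")
  cat("  BUSCO complete (>", x$thresholds$busco_min, "%): ", show(x$busco_ok), "\n", sep = "")
  invisible(x)
}

#' Parse a BUSCO short-summary text file
#'
#' Extracts the complete/fragmented/missing percentages from the summary
#' line of the form `C:95.9%[S:90.1%,D:5.8%],F:1.0%,M:3.1%,n:1614`.
#'
#' @param path Path to a BUSCO short summary file.
#' @return List with numeric `complete`, `fragmented`, `missing`.
#' @export
parse_busco_summary <- function(path) {
  if (!file.exists(path)) stop("BUSCO summary file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  pat <- "C:([0-9.]+)%\\[.*\\],F:([0-9.]+)%,M:([0-9.]+)%"
  hit <- regmatches(lines, regexec(pat, lines))
  hit <- hit[lengths(hit) == 4]
  if (length(hit) == 0) {
    stop("malformed BUSCO summary: no 'C:...%[...],F:...%,M:...%' line in ", path)
  }
  v <- as.numeric(hit[[1]][2:4])
  if (abs(sum(v) - 100) > 0.5) {
    stop("malformed BUSCO summary: percentages sum to ", sum(v))
  }
  list(complete = v[1], fragmented = v[2], missing = v[3])
}

#' Write a metrics report as a one-row TSV
#' @param report A `metrics_report`.
#' @param path Output path.
#' @param label Row label (annotation name).
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(report, path, label = "annotation") {
  row <- data.frame(
    annotation = label,
    total_genes = report$total_genes,
    mono_count = report$mono_count,
    multi_count = report$multi_count,
    mono_multi_ratio = report$mono_multi_ratio,
    mean_gene_length_bp = report$mean_gene_length_bp,
    mean_cds_length_bp = report$mean_cds_length_bp,
    mean_exons_per_gene = report$mean_exons_per_gene,
    cds_n50_bp = report$cds_n50_bp,
    genes_with_start_and_stop = report$genes_with_start_and_stop,
    stringsAsFactors = FALSE)
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' An undefined mono:multi ratio serializes as `null`, never as 0 or
#' infinity.
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  x <- unclass(report)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(path)
}
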