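#' Splice-site rule
#'
#' The default (strict) rule accepts only the canonical GT-AG intron
#' boundary; the extended rule additionally accepts the minor spliceosomal
#' pairs GC-AG and AT-AC.
#'
#' @param set `"strict"` or `"extended"`, or `NULL` when `pairs` is given.
#' @param pairs Optional custom character vector of `"DONOR-ACCEPTOR"` pairs.
#' @return An object of class `splice_rule`.
#' @export
splice_rule <- function(set = c("strict", "extended"), pairs = NULL) {
  if (is.null(pairs)) {
    set <- match.arg(set)
    pairs <- switch(set, strict = "GT-AG",
                    extended = c("GT-AG", "GC-AG", "AT-AC"))
  } else {
    set <- "custom"
    if (!length(pairs) || !all(grepl("^[ACGTN]{2}-[ACGTN]{2}$", pairs))) {
      stop("`pairs` must be a non-empty vector like 'GT-AG'")
    }
  }
  structure(list(set = set, pairs = pairs), class = "splice_rule")
}

new_ledger <- function(gene_id = character(), transcript_id = character(),
                       filter = character(), reason = character(),
                       detail = character()) {
  data.frame(gene_id = gene_id, transcript_id = transcript_id, filter = filter,
             reason = reason, detail = detail, stringsAsFactors = FALSE)
}

filter_result <- function(ann, removed_gene_ids, rep, filter, reason, detail,
                          log) {
  keep <- setdiff(gene_ids(ann), removed_gene_ids)
  rep_idx <- match(removed_gene_ids, rep$gene_id)
  ledger <- new_ledger(removed_gene_ids, rep$transcript_id[rep_idx],
                       rep(filter, length(removed_gene_ids)), reason, detail)
  list(annotation = subset_annotation(ann, keep, log = log), ledger = ledger)
}

#' Remove genes with non-canonical coding introns
#'
#' A gene is removed when its representative transcript has at least one
#' coding intron whose strand-normalized (donor, acceptor) pair is not in
#' the splice rule. Mono-exonic genes have no coding introns and always
#' survive.
#'
#' @param ann An [annotation_set].
#' @param genome A [genome_sequences].
#' @param rule A [splice_rule].
#' @return List with `annotation` (survivors) and `ledger` (rejections).
#' @export
filter_canonical_splice <- function(ann, genome, rule = splice_rule("strict")) {
  stopifnot(inherits(rule, "splice_rule"))
  rep <- representative_transcripts(ann)
  removed <- character()
  detail <- character()
  for (i in seq_len(nrow(rep))) {
    if (rep$n_cds[i] < 2) next
    ins <- extract_introns(ann, rep$transcript_id[i], genome)
    pairs <- paste0(ins$donor, "-", ins$acceptor)
    bad <- !(pairs %in% rule$pairs)
    if (any(bad)) {
      removed <- c(removed, rep$gene_id[i])
      detail <- c(detail, paste(unique(pairs[bad]), collapse = ","))
    }
  }
  filter_result(ann, removed, rep, "canonical_splice",
                rep("noncanonical_splice", length(removed)), detail,
                log = paste0("filter_canonical_splice[", rule$set, "]: removed ",
                             length(removed)))
}

#' Remove genes whose representative ORF is defective
#'
#' Checks the spliced, phase-trimmed CDS of the representative transcript
#' for an ATG start, a terminal stop codon, and the absence of internal
#' stops. Each enabled check that fails contributes a reason code
#' (`missing_start`, `missing_stop`, `internal_stop`).
#'
#' @param ann An [annotation_set].
#' @param genome A [genome_sequences].
#' @param require_start,require_stop,forbid_internal_stop Enable the checks.
#' @return List with `annotation` and `ledger`.
#' @export
filter_orf_integrity <- function(ann, genome, require_start = TRUE,
                                 require_stop = TRUE,
                                 forbid_internal_stop = TRUE) {
  rep <- representative_transcripts(ann)
  removed <- character()
  reasons <- character()
  for (i in seq_len(nrow(rep))) {
    tl <- translate_cds(extract_cds_sequence(ann, rep$transcript_id[i], genome))
    r <- character()
    if (require_start && !tl$has_start) r <- c(r, "missing_start")
    if (require_stop && !tl$has_terminal_stop) r <- c(r, "missing_stop")
    if (forbid_internal_stop && tl$internal_stop_count > 0) r <- c(r, "internal_stop")
    if (length(r)) {
      removed <- c(removed, rep$gene_id[i])
      reasons <- c(reasons, paste(r, collapse = ";"))
    }
  }
  filter_result(ann, removed, rep, "orf_integrity", reasons, reasons,
                log = paste0("filter_orf_integrity: removed ", length(removed)))
}

#' Remove genes with short coding sequences
#'
#' Gene models whose representative CDS totals fewer than `min_bp` coding
#' bases are removed; the boundary is kept (strictly "shorter than").
#' The 300-bp default mirrors the common minimum for frame-selected
#' transcripts in annotation evidence pipelines.
#'
#' @param ann An [annotation_set].
#' @param min_bp Minimum representative CDS length in bp.
#' @return List with `annotation` and `ledger`.
#' @export
filter_min_cds_length <- function(ann, min_bp = 300L) {
  if (min_bp <= 0) stop("`min_bp` must be positive")
  rep <- representative_transcripts(ann)
  sel <- rep$cds_len < min_bp
  removed <- rep$gene_id[sel]
  detail <- if (any(sel)) paste0(rep$cds_len[sel], "bp<", min_bp, "bp")
            else character(0)
  filter_result(ann, removed, rep, "min_cds_length",
                rep("cds_too_short", length(removed)), detail,
                log = paste0("filter_min_cds_length[", min_bp, "]: removed ",
                             length(removed)))
}

#' Collapse duplicate gene models
#'
#' Two genes are duplicates when their representative transcripts share
#' sequence, strand, and the identical ordered CDS segment coordinates. One
#' survivor is kept per duplicate class (the lexicographically smallest gene
#' id); the others are removed with reason `duplicate_of:<survivor>`.
#'
#' @param ann An [annotation_set].
#' @return List with `annotation` and `ledger`.
#' @export
deduplicate_models <- function(ann) {
  rep <- representative_transcripts(ann)
  if (nrow(rep) == 0) {
    return(list(annotation = ann, ledger = new_ledger()))
  }
  cds_by_tx <- split(ann$cds[c("start", "end")], ann$cds$transcript_id)
  key <- vapply(seq_len(nrow(rep)), function(i) {
    cc <- cds_by_tx[[rep$transcript_id[i]]]
    coords <- if (is.null(cc)) "" else paste(cc$start, cc$end, sep = "-",
                                             collapse = ",")
    paste(rep$seq_id[i], rep$strand[i], coords, sep = "|")
  }, character(1))
  removed <- character()
  reason <- character()
  for (grp in split(rep$gene_id, key)) {
    if (length(grp) < 2) next
    grp <- sort(grp)
    removed <- c(removed, grp[-1])
    reason <- c(reason, rep(paste0("duplicate_of:", grp[1]), length(grp) - 1L))
  }
  filter_result(ann, removed, rep, "deduplicate", reason, reason,
                log = paste0("deduplicate_models: removed ", length(removed)))
}

#' Partition an annotation set by exonic status
#'
#' @param ann An [annotation_set].
#' @return List with disjoint [annotation_set]s `mono` and `multi` whose
#'   union of gene ids equals the input's.
#' @export
partition_by_exonic_status <- function(ann) {
  if (n_genes(ann) == 0) {
    return(list(mono = ann, multi = ann))
  }
  status <- classify_exonic_status(ann)
  list(mono = subset_annotation(ann, names(status)[status == "mono"],
                                log = "partition: mono"),
       multi = subset_annotation(ann, names(status)[status == "multi"],
                                 log = "partition: multi"))
}

#' Write a rejection ledger as TSV
#' @param ledger A rejection-ledger data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger_tsv <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
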