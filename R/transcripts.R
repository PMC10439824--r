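#' Representative transcript per gene
#'
#' Per-gene statistics and filters act on a single isoform. The
#' representative is the transcript with the greatest total CDS length; ties
#' are broken by the lexicographically smallest transcript id, which makes
#' the choice deterministic across runs and platforms.
#'
#' @param ann An [annotation_set].
#' @return data.frame with one row per gene: `gene_id`, `transcript_id`,
#'   `seq_id`, `strand`, `cds_len` (bp), `n_cds` (CDS segment count).
#' @export
representative_transcripts <- function(ann) {
  tr <- ann$transcripts
  if (nrow(tr) == 0) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      seq_id = character(), strand = character(),
                      cds_len = integer(), n_cds = integer(),
                      stringsAsFactors = FALSE))
  }
  w <- ann$cds$end - ann$cds$start
  len_by_tx <- tapply(w, ann$cds$transcript_id, sum)
  n_by_tx <- tapply(w, ann$cds$transcript_id, length)
  tr$cds_len <- as.integer(len_by_tx[tr$transcript_id])
  tr$n_cds <- as.integer(n_by_tx[tr$transcript_id])
  tr$cds_len[is.na(tr$cds_len)] <- 0L
  tr$n_cds[is.na(tr$n_cds)] <- 0L
  o <- order(tr$gene_id, -tr$cds_len, tr$transcript_id)
  tr <- tr[o, , drop = FALSE]
  rep <- tr[!duplicated(tr$gene_id), , drop = FALSE]
  rownames(rep) <- NULL
  rep[c("gene_id", "transcript_id", "seq_id", "strand", "cds_len", "n_cds")]
}

#' Select the representative transcript of one gene
#' @param ann An [annotation_set].
#' @param gene_id A gene identifier present in `ann`.
#' @return One-row data.frame as in [representative_transcripts()].
#' @export
select_representative <- function(ann, gene_id) {
  if (!gene_id %in% ann$genes$gene_id) stop("unknown gene: ", gene_id)
  rep <- representative_transcripts(ann)
  rep[rep$gene_id == gene_id, , drop = FALSE]
}

cds_segments_of <- function(ann, transcript_id) {
  cc <- ann$cds[ann$cds$transcript_id == transcript_id, , drop = FALSE]
  cc[order(cc$start), , drop = FALSE]
}

#' Extract the spliced CDS sequence of a transcript
#'
#' CDS segments are concatenated in transcript 5'->3' order; minus-strand
#' transcripts are reverse-complemented; leading bases are trimmed according
#' to the phase of the 5'-most segment; output is uppercased, so soft-masked
#' (lowercase) genomic stretches do not alter the result.
#'
#' @param ann An [annotation_set].
#' @param transcript_id Transcript identifier.
#' @param genome A [genome_sequences] covering the transcript's sequence.
#' @return Nucleotide string.
#' @export
extract_cds_sequence <- function(ann, transcript_id, genome) {
  tr <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(tr) == 0) stop("unknown transcript: ", transcript_id)
  segs <- cds_segments_of(ann, transcript_id)
  if (nrow(segs) == 0) return("")
  pieces <- vapply(seq_len(nrow(segs)), function(i) {
    genome_sub(genome, tr$seq_id, segs$start[i], segs$end[i])
  }, character(1))
  if (tr$strand == "-") {
    pieces <- revcomp(rev(pieces))
    phase5 <- segs$phase[nrow(segs)]
  } else {
    phase5 <- segs$phase[1]
  }
  s <- toupper(paste(pieces, collapse = ""))
  if (phase5 > 0) s <- substr(s, phase5 + 1L, nchar(s))
  s
}

#' Translate a CDS nucleotide sequence with integrity flags
#'
#' Uses the standard nuclear genetic code. Codons containing ambiguous bases
#' translate to `X`; a trailing partial codon is dropped and reported via
#' `length_multiple_of_3 = FALSE`; a terminal stop is reported but excluded
#' from the protein string.
#'
#' @param seq Non-empty nucleotide string.
#' @return List with `protein`, `has_start`, `has_terminal_stop`,
#'   `internal_stop_count`, `length_multiple_of_3`.
#' @export
translate_cds <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    stop("`seq` must be a non-empty nucleotide string")
  }
  s <- toupper(seq)
  n <- nchar(s)
  ncod <- n %/% 3L
  if (ncod == 0) {
    return(list(protein = "", has_start = FALSE, has_terminal_stop = FALSE,
                internal_stop_count = 0L, length_multiple_of_3 = FALSE))
  }
  codons <- substring(s, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  has_terminal_stop <- aa[ncod] == "*"
  prot <- if (has_terminal_stop) aa[-ncod] else aa
  list(protein = paste(prot, collapse = ""),
       has_start = codons[1] == "ATG",
       has_terminal_stop = has_terminal_stop,
       internal_stop_count = sum(prot == "*"),
       length_multiple_of_3 = (n %% 3L == 0L))
}

#' Coding introns of a transcript with splice-site dinucleotides
#'
#' One intron is reported per gap between consecutive CDS segments. Donor and
#' acceptor dinucleotides are given in transcript 5'->3' orientation
#' (minus-strand introns are reverse-complemented) and uppercased. Introns
#' shorter than 4 bp cannot hold both dinucleotides and are flagged with
#' donor/acceptor `"NN"`.
#'
#' @param ann An [annotation_set].
#' @param transcript_id Transcript identifier.
#' @param genome A [genome_sequences].
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open interior of the splice gap), `strand`, `donor`, `acceptor`,
#'   `flagged`; rows in transcript 5'->3' order. Mono-exonic transcripts
#'   yield zero rows.
#' @export
extract_introns <- function(ann, transcript_id, genome) {
  tr <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(tr) == 0) stop("unknown transcript: ", transcript_id)
  segs <- cds_segments_of(ann, transcript_id)
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), donor = character(),
                      acceptor = character(), flagged = logical(),
                      stringsAsFactors = FALSE)
  k <- nrow(segs)
  if (k < 2) return(empty)
  starts <- segs$end[-k]
  ends <- segs$start[-1]
  donor <- acceptor <- character(k - 1L)
  flagged <- logical(k - 1L)
  for (i in seq_len(k - 1L)) {
    w <- ends[i] - starts[i]
    if (w < 4L) {
      donor[i] <- acceptor[i] <- "NN"
      flagged[i] <- TRUE
      next
    }
    txt <- toupper(genome_sub(genome, tr$seq_id, starts[i], ends[i]))
    if (tr$strand == "+") {
      donor[i] <- substr(txt, 1L, 2L)
      acceptor[i] <- substr(txt, w - 1L, w)
    } else {
      donor[i] <- revcomp(substr(txt, w - 1L, w))
      acceptor[i] <- revcomp(substr(txt, 1L, 2L))
    }
  }
  out <- data.frame(seq_id = tr$seq_id, start = starts, end = ends,
                    strand = tr$strand, donor = donor, acceptor = acceptor,
                    flagged = flagged, stringsAsFactors = FALSE)
  if (tr$strand == "-") out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
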