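#' Genome sequences with per-base soft-mask state
#'
#' A thin container for named nucleotide sequences. Lowercase bases mark
#' soft-masked (repeat-derived) positions, exactly as RepeatMasker-style
#' pipelines emit them; the container preserves case so downstream code can
#' reason about masking without losing sequence.
#'
#' @param records Named character vector, one nucleotide string per sequence.
#' @return An object of class `genome_sequences` with elements `records`
#'   (named character) and `lengths` (named integer).
#' @export
genome_sequences <- function(records) {
  if (!is.character(records) || is.null(names(records)) ||
      any(!nzchar(names(records)))) {
    stop("`records` must be a named character vector")
  }
  if (anyDuplicated(names(records))) {
    dup <- names(records)[duplicated(names(records))][1]
    stop("duplicate sequence id: ", dup)
  }
  bad <- grepl("[^ACGTNacgtn]", records)
  if (any(bad)) {
    stop("sequence ", names(records)[bad][1],
         " contains characters outside {A,C,G,T,N,a,c,g,t,n}")
  }
  structure(list(records = records,
                 lengths = stats::setNames(nchar(records), names(records))),
            class = "genome_sequences")
}

#' Read a (possibly soft-masked) FASTA file
#'
#' Case is preserved, so lowercase soft-masking survives the round trip.
#' The sequence id is the header token before the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A [genome_sequences] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       seqtype = "DNA"),
    error = function(e) stop("empty or malformed FASTA file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1])
  }
  recs <- stats::setNames(vapply(seqs, function(s) as.character(s)[1],
                                 character(1)), ids)
  bad <- grepl("[^ACGTNacgtn]", recs)
  if (any(bad)) {
    # locate the offending line for the error message
    lines <- readLines(path)
    ln <- which(!startsWith(lines, ">") & grepl("[^ACGTNacgtn \t]", lines))[1]
    stop("non-IUPAC nucleotide character in ", path,
         if (!is.na(ln)) paste0(" at line ", ln) else "",
         " (sequence ", ids[bad][1], ")")
  }
  genome_sequences(recs)
}

#' Write genome sequences to FASTA
#'
#' @param genome A [genome_sequences] object.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 60L) {
  stopifnot(inherits(genome, "genome_sequences"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(genome$records)) {
    s <- genome$records[[id]]
    n <- nchar(s)
    starts <- seq.int(1L, max(n, 1L), by = width)
    writeLines(c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, n))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Extract a subsequence (0-based half-open coordinates)
#' @param genome A [genome_sequences] object.
#' @param seq_id Sequence identifier.
#' @param start,end 0-based half-open interval.
#' @return Nucleotide string, case preserved.
#' @keywords internal
genome_sub <- function(genome, seq_id, start, end) {
  s <- genome$records[[seq_id]]
  if (is.null(s)) stop("unknown sequence id: ", seq_id)
  if (start < 0 || end > nchar(s) || start > end) {
    stop("interval [", start, ",", end, ") out of bounds for ", seq_id)
  }
  substr(s, start + 1L, end)
}

#' @export
print.genome_sequences <- function(x, ...) {
  cat("<genome_sequences> ", length(x$records), " sequence(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Uppercase all bases (drop soft-masking) of a genome
#' @param genome A [genome_sequences] object.
#' @return A [genome_sequences] object with all-uppercase records.
#' @export
unmask_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_sequences"))
  genome_sequences(stats::setNames(toupper(genome$records), names(genome$records)))
}
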