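`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a fixed RNG seed, restoring RNG state afterwards
#'
#' All stochastic components of the package (the simulator, the evidence
#' generator) route their randomness through this helper so that a run is
#' fully determined by the seeds carried in its parameter objects.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

#' Reverse-complement nucleotide strings (case preserving)
#' @param x Character vector of ACGTN/acgtn strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", reverse_string(x))
}

random_bases <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  at <- (1 - gc) / 2
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at, gc / 2, gc / 2, at)), collapse = "")
}

# sample() treats a length-1 numeric x as 1:x; this wrapper never does.
safe_sample <- function(x, size) {
  if (size == 0) return(x[0])
  if (length(x) == 1) return(rep(x, length.out = size))
  sample(x, size)
}

# N50 of a set of lengths: largest L such that elements >= L cover at least
# half the summed length. Zero for an empty input.
n50 <- function(lengths) {
  lengths <- lengths[lengths > 0]
  if (length(lengths) == 0) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
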