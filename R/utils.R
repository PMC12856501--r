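#' @keywords internal
"_PACKAGE"

STOP_CODONS_DEFAULT <- c("TAA", "TAG", "TGA")
UORF_TYPES <- c("TYPE1", "TYPE2", "TYPE3", "INCOMPLETE")

#' Validate a nucleotide string
#'
#' Sequences handled by the package are plain uppercase strings over
#' A, C, G, T and N. N never matches a start or stop codon.
#'
#' @param seq character scalar.
#' @param what label used in error messages.
#' @param allow_n allow ambiguous N bases.
#' @return The validated sequence, invisibly.
#' @keywords internal
validate_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- regexpr(sprintf("[^%s]", alphabet), seq)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' in %s at position %d",
                 substr(seq, bad, bad), what, bad), call. = FALSE)
  invisible(seq)
}

#' Reverse complement of a DNA string
#' @param seq character scalar over A,C,G,T,N.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  validate_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC fraction of a sequence
#' @param seq character scalar.
#' @return numeric in [0, 1]; N bases count toward the denominator.
#' @export
gc_fraction <- function(seq) {
  validate_dna(seq)
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / n
}

#' Round half away from zero
#'
#' R's round() uses banker's rounding; reported percentages and fold
#' changes follow the conventional half-up rule instead (32.26, 43.33).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL uses the
# current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# substring codon starting at 1-based position p (length 3)
codon_at <- function(seq, p) substr(seq, p, p + 2L)
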