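#' Global pairwise alignment of an amplicon and a clone sequence
#'
#' Needleman-Wunsch global alignment with affine gap scoring, computed
#' with Biostrings. A gap run of length L costs
#' `gap_open + L * gap_extend`; with the defaults (match +2, mismatch
#' -3, open 5, extend 1) two identical 50-nt sequences score 100.
#'
#' @param reference,query non-empty nucleotide strings.
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend positive gap penalties (subtracted).
#' @param max_len guard against accidentally huge inputs.
#' @return An object of class `pair_alignment`: list with `ref_aligned`
#'   and `query_aligned` (equal-length gapped strings, gaps as `-`),
#'   `score`, and `ops` (run-length encoded operations over columns:
#'   `M` both bases, `D` gap in query / deletion from the reference,
#'   `I` gap in reference / insertion).
#' @export
align_pair <- function(reference, query, match = 2, mismatch = -3,
                       gap_open = 5, gap_extend = 1, max_len = 20000L) {
  validate_dna(reference, "reference", allow_n = FALSE)
  validate_dna(query, "query", allow_n = FALSE)
  if (nchar(reference) == 0L || nchar(query) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  if (nchar(reference) > max_len || nchar(query) > max_len)
    stop("sequence exceeds max_len (", max_len, ")", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(reference, query,
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend,
                                      type = "global")
  ra <- as.character(Biostrings::alignedPattern(pa))
  qa <- as.character(Biostrings::alignedSubject(pa))
  rb <- strsplit(ra, "")[[1]]
  qb <- strsplit(qa, "")[[1]]
  op <- ifelse(rb == "-", "I", ifelse(qb == "-", "D", "M"))
  structure(list(ref_aligned = ra, query_aligned = qa,
                 score = Biostrings::score(pa), ops = rle(op)),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("pair_alignment: score %g, %d columns\n", x$score,
              nchar(x$ref_aligned)))
  invisible(x)
}

# shift a deletion/insertion left through repeat context; stops at
# `floor_pos` (one past the previous edit's footprint)
left_align_del <- function(ref, pos, len, floor_pos) {
  while (pos > floor_pos &&
         substr(ref, pos - 1L, pos - 1L) ==
         substr(ref, pos + len - 1L, pos + len - 1L))
    pos <- pos - 1L
  pos
}

left_align_ins <- function(ref, pos, alt, floor_pos) {
  while (pos > floor_pos &&
         substr(ref, pos - 1L, pos - 1L) ==
         substr(alt, nchar(alt), nchar(alt))) {
    alt <- paste0(substr(alt, nchar(alt), nchar(alt)),
                  substr(alt, 1L, nchar(alt) - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, alt = alt)
}

#' Call edits from a pairwise alignment
#'
#' Converts maximal runs of alignment columns into DEL/INS/SUB edits in
#' 1-based reference coordinates: query gaps become deletions, reference
#' gaps insertions, and maximal runs of mismatching base columns one
#' merged substitution. Indels are left-aligned within repeat context
#' (without crossing a preceding edit), so equivalent alignments yield
#' one canonical edit set.
#'
#' @param aln an [align_pair()] result.
#' @return An `edit_set`; applying it to the reference with
#'   [apply_edits()] reproduces the query exactly.
#' @export
call_variants <- function(aln) {
  stopifnot(inherits(aln, "pair_alignment"))
  rb <- strsplit(aln$ref_aligned, "")[[1]]
  qb <- strsplit(aln$query_aligned, "")[[1]]
  ref <- paste(rb[rb != "-"], collapse = "")
  n <- length(rb)
  edits <- list()
  floor_pos <- 1L   # left-alignment cannot cross the previous edit
  ref_pos <- 1L     # reference position of the current column
  i <- 1L
  while (i <= n) {
    if (rb[i] != "-" && qb[i] != "-" && rb[i] == qb[i]) {
      ref_pos <- ref_pos + 1L; i <- i + 1L
    } else if (qb[i] == "-") {
      j <- i
      while (j <= n && qb[j] == "-") j <- j + 1L
      len <- j - i
      pos <- left_align_del(ref, ref_pos, len, floor_pos)
      edits[[length(edits) + 1L]] <- edit_del(pos, len)
      floor_pos <- pos + len
      ref_pos <- ref_pos + len; i <- j
    } else if (rb[i] == "-") {
      j <- i
      while (j <= n && rb[j] == "-") j <- j + 1L
      alt <- paste(qb[i:(j - 1L)], collapse = "")
      la <- left_align_ins(ref, ref_pos, alt, floor_pos)
      edits[[length(edits) + 1L]] <- edit_ins(la$pos, la$alt)
      floor_pos <- la$pos
      i <- j
    } else { # mismatch run
      j <- i
      while (j <= n && rb[j] != "-" && qb[j] != "-" && rb[j] != qb[j])
        j <- j + 1L
      alt <- paste(qb[i:(j - 1L)], collapse = "")
      edits[[length(edits) + 1L]] <- edit_sub(ref_pos, alt)
      floor_pos <- ref_pos + nchar(alt)
      ref_pos <- ref_pos + (j - i); i <- j
    }
  }
  if (length(edits) == 0) return(empty_edit_set())
  out <- do.call(edit_set, edits)
  out[order(out$pos), , drop = FALSE]
}
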