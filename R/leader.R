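#' Build a transcript model from a leader and a CDS
#'
#' A `leader_context` fixes the coordinate system used throughout the
#' package: the transcript is the concatenation of the 5' leader and the
#' main-ORF coding sequence, and the main start codon (mATG) sits at
#' 1-based position `length(leader) + 1`.
#'
#' @param transcript_id text label.
#' @param leader_seq 5' leader (may be empty) over A,C,G,T,N.
#' @param cds_seq coding sequence; must begin with ATG, have length a
#'   positive multiple of 3, and end in a stop codon (TAA, TAG or TGA).
#' @return An object of class `leader_context`: a list with elements
#'   `transcript_id`, `leader_seq`, `cds_seq`, `transcript_seq` and
#'   `matg_pos` (1-based position of the A of the main ATG).
#' @examples
#' ctx <- leader_context("tx1", "ATGTAACC", "ATGGGGTGA")
#' ctx$matg_pos  # 9
#' @export
leader_context <- function(transcript_id, leader_seq, cds_seq) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  validate_dna(leader_seq, "leader_seq")
  validate_dna(cds_seq, "cds_seq")
  n_cds <- nchar(cds_seq)
  if (n_cds < 6L || n_cds %% 3L != 0L)
    stop("cds_seq length must be a positive multiple of 3 (>= 6)", call. = FALSE)
  if (substr(cds_seq, 1L, 3L) != "ATG")
    stop("cds_seq must begin with ATG", call. = FALSE)
  last <- substr(cds_seq, n_cds - 2L, n_cds)
  if (!last %in% STOP_CODONS_DEFAULT)
    stop("cds_seq must end in a stop codon (TAA, TAG or TGA), got ", last,
         call. = FALSE)
  structure(
    list(transcript_id = transcript_id,
         leader_seq = leader_seq,
         cds_seq = cds_seq,
         transcript_seq = paste0(leader_seq, cds_seq),
         matg_pos = nchar(leader_seq) + 1L),
    class = "leader_context")
}

#' @export
print.leader_context <- function(x, ...) {
  cat(sprintf("leader_context '%s': %d nt leader + %d nt CDS (mATG at %d)\n",
              x$transcript_id, nchar(x$leader_seq), nchar(x$cds_seq),
              x$matg_pos))
  invisible(x)
}
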