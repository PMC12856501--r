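#' Enumerate SpCas9 protospacer candidates
#'
#' Scans both strands of a reference for 20-mers immediately 5' of an
#' NGG PAM. Coordinates are 1-based on the plus strand; minus-strand
#' candidates report the protospacer as the reverse complement of the
#' covered reference window. The blunt SpCas9 cut falls between
#' protospacer bases 17 and 18 (3 nt 5' of the PAM); `cut_pos` is the
#' plus-strand position of the base immediately 3' of the cut.
#'
#' @param seq reference nucleotide string.
#' @return Data frame of class `guide_candidates` with columns
#'   `protospacer`, `strand`, `pam`, `pam_start`, `start`, `end`
#'   (reference window covered by the protospacer), `cut_pos` and
#'   `gc_fraction`. Sequences shorter than 23 nt yield zero rows.
#' @export
enumerate_protospacers <- function(seq) {
  validate_dna(seq)
  n <- nchar(seq)
  out <- list()
  if (n >= 23L) {
    bases <- strsplit(seq, "")[[1]]
    for (i in seq_len(n - 22L)) {
      # plus strand: protospacer [i, i+19], PAM [i+20, i+22] = NGG
      if (bases[i + 21L] == "G" && bases[i + 22L] == "G") {
        proto <- substr(seq, i, i + 19L)
        out[[length(out) + 1L]] <- data.frame(
          protospacer = proto, strand = "+",
          pam = substr(seq, i + 20L, i + 22L), pam_start = i + 20L,
          start = i, end = i + 19L, cut_pos = i + 17L,
          gc_fraction = gc_fraction(proto))
      }
      # minus strand: PAM (CCN on plus) at [i, i+2], protospacer [i+3, i+22]
      if (bases[i] == "C" && bases[i + 1L] == "C") {
        win <- substr(seq, i + 3L, i + 22L)
        out[[length(out) + 1L]] <- data.frame(
          protospacer = revcomp(win), strand = "-",
          pam = revcomp(substr(seq, i, i + 2L)), pam_start = i + 2L,
          start = i + 3L, end = i + 22L, cut_pos = i + 6L,
          gc_fraction = gc_fraction(win))
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(protospacer = character(0), strand = character(0),
               pam = character(0), pam_start = integer(0),
               start = integer(0), end = integer(0), cut_pos = integer(0),
               gc_fraction = numeric(0))
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("guide_candidates", "data.frame")
  df
}

#' Rank guide candidates by proximity to uATGs
#'
#' Filters candidates to a GC window and a maximum cut-to-uATG distance,
#' then sorts ascending by that distance; ties break by ascending
#' `cut_pos`, then plus strand before minus.
#'
#' @param candidates output of [enumerate_protospacers()].
#' @param uatg_positions 1-based positions of uATG first bases (non-empty).
#' @param max_dist maximum |cut_pos - uATG| in nt.
#' @param gc_bounds length-2 numeric, inclusive GC-fraction window.
#' @return The filtered, ordered data frame with an added
#'   `dist_to_nearest_uatg` column.
#' @export
rank_guides <- function(candidates, uatg_positions, max_dist = 50L,
                        gc_bounds = c(0.30, 0.80)) {
  stopifnot(is.data.frame(candidates), length(uatg_positions) >= 1L,
            length(gc_bounds) == 2L)
  if (nrow(candidates) == 0) {
    candidates$dist_to_nearest_uatg <- integer(0)
    return(candidates)
  }
  d <- vapply(candidates$cut_pos,
              function(cp) min(abs(cp - uatg_positions)), numeric(1))
  candidates$dist_to_nearest_uatg <- as.integer(d)
  keep <- candidates$gc_fraction >= gc_bounds[1] &
          candidates$gc_fraction <= gc_bounds[2] &
          candidates$dist_to_nearest_uatg <= max_dist
  out <- candidates[keep, , drop = FALSE]
  out <- out[order(out$dist_to_nearest_uatg, out$cut_pos,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate a known protospacer in a reference
#'
#' Finds every exact match of a 20-nt protospacer on either strand and
#' flags whether an NGG PAM is immediately adjacent (3' of the
#' protospacer on its strand).
#'
#' @param reference nucleotide string.
#' @param protospacer 20-nt string.
#' @return Data frame with `start`, `end` (plus-strand window), `strand`
#'   and `pam_ok`.
#' @export
locate_guide <- function(reference, protospacer) {
  validate_dna(reference, "reference")
  validate_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L)
    stop("protospacer must be exactly 20 nt", call. = FALSE)
  n <- nchar(reference)
  hits <- list()
  find_all <- function(pat) {
    res <- integer(0); from <- 1L
    repeat {
      p <- regexpr(pat, substr(reference, from, n), fixed = TRUE)
      if (p < 1L) break
      res <- c(res, p + from - 1L)
      from <- p + from
    }
    res
  }
  for (s in find_all(protospacer)) {
    pam <- substr(reference, s + 20L, s + 22L)
    hits[[length(hits) + 1L]] <- data.frame(
      start = s, end = s + 19L, strand = "+",
      pam_ok = nchar(pam) == 3L && substr(pam, 2L, 3L) == "GG")
  }
  rc <- revcomp(protospacer)
  for (s in find_all(rc)) {
    # PAM on the minus strand lies 5' of the window on the plus strand
    pam_ok <- s >= 4L && substr(reference, s - 3L, s - 2L) == "CC"
    hits[[length(hits) + 1L]] <- data.frame(
      start = s, end = s + 19L, strand = "-", pam_ok = pam_ok)
  }
  df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               pam_ok = logical(0))
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}
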