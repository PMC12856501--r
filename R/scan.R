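#' Scanner configuration
#'
#' @param min_length_nt minimum complete-uORF length in nt, counted from
#'   the uATG through the stop codon inclusive. Must be a multiple of 3
#'   and at least 6 (start + stop with no intervening codon). The default
#'   of 6 retains even the shortest biologically reported uORFs.
#' @param include_incomplete keep uORFs whose reading frame runs off the
#'   transcript end without a stop codon.
#' @param stop_codons stop-codon set.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(min_length_nt = 6L, include_incomplete = FALSE,
                        stop_codons = STOP_CODONS_DEFAULT) {
  min_length_nt <- as.integer(min_length_nt)
  if (is.na(min_length_nt) || min_length_nt < 6L || min_length_nt %% 3L != 0L)
    stop("min_length_nt must be a multiple of 3 and >= 6", call. = FALSE)
  stop_codons <- toupper(stop_codons)
  if (!all(nchar(stop_codons) == 3L))
    stop("stop_codons must be 3-nt strings", call. = FALSE)
  structure(list(min_length_nt = min_length_nt,
                 include_incomplete = isTRUE(include_incomplete),
                 stop_codons = stop_codons),
            class = "scan_config")
}

#' Find ATG start codons in a region
#'
#' Reports every 1-based position `p <= region_end` at which the sequence
#' reads ATG. The codon may extend beyond `region_end` but must lie
#' entirely within the sequence. N never matches.
#'
#' @param seq nucleotide string over A,C,G,T,N.
#' @param region_end last allowed start position (defaults to the full
#'   sequence).
#' @return Integer vector of 1-based positions, ascending.
#' @examples
#' find_start_codons("ATGAATG")  # 1, 5
#' @export
find_start_codons <- function(seq, region_end = nchar(seq)) {
  validate_dna(seq)
  region_end <- min(as.integer(region_end), nchar(seq) - 2L)
  if (is.na(region_end) || region_end < 1L) return(integer(0))
  hits <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr("ATG", substr(seq, from, nchar(seq)), fixed = TRUE)
    if (p < 1L) break
    p <- p + from - 1L
    if (p > region_end) break
    hits <- c(hits, p)
    from <- p + 1L
  }
  hits
}

#' Extend a uATG to its stop codon and classify the uORF
#'
#' Walks codons from `uatg_pos` in steps of 3 across the whole transcript
#' (leader plus CDS); the first stop codon encountered closes the uORF.
#' Classification follows the position of that stop relative to the main
#' ATG: entirely upstream gives a Type 1 (non-overlapping) uORF; a stop
#' inside the main ORF gives Type 2 (out-of-frame overlapping) when the
#' uATG is out of frame, or Type 3 (N-terminal extension, sharing the
#' main ORF's stop) when in frame. An out-of-frame uORF that never meets
#' a stop is INCOMPLETE. Codons containing N are neither starts nor
#' stops.
#'
#' @param ctx a [leader_context()].
#' @param uatg_pos 1-based transcript position of the uATG (must be
#'   strictly upstream of the main ATG).
#' @param config a [scan_config()].
#' @return A list with elements `uatg_pos`, `stop_start`, `stop_end`
#'   (1-based inclusive; NA when incomplete), `length_nt` (uATG through
#'   stop inclusive; NA when incomplete), `utype`, `frame_offset`
#'   (`(uatg_pos - 1) %% 3`) and `in_frame_with_morf`.
#' @export
scan_uorf <- function(ctx, uatg_pos, config = scan_config()) {
  stopifnot(inherits(ctx, "leader_context"))
  uatg_pos <- as.integer(uatg_pos)
  if (uatg_pos >= ctx$matg_pos)
    stop("uatg_pos must lie strictly upstream of the main ATG", call. = FALSE)
  tx <- ctx$transcript_seq
  if (codon_at(tx, uatg_pos) != "ATG")
    stop("no ATG at position ", uatg_pos, call. = FALSE)
  in_frame <- (uatg_pos - ctx$matg_pos) %% 3L == 0L
  n <- nchar(tx)
  stop_start <- NA_integer_
  p <- uatg_pos + 3L
  while (p + 2L <= n) {
    if (codon_at(tx, p) %in% config$stop_codons) {
      stop_start <- p
      break
    }
    p <- p + 3L
  }
  if (is.na(stop_start)) {
    utype <- "INCOMPLETE"
    stop_end <- NA_integer_
    length_nt <- NA_integer_
  } else {
    stop_end <- stop_start + 2L
    length_nt <- stop_end - uatg_pos + 1L
    utype <- if (stop_end < ctx$matg_pos) "TYPE1"
             else if (in_frame) "TYPE3"
             else "TYPE2"
  }
  list(uatg_pos = uatg_pos, stop_start = stop_start, stop_end = stop_end,
       length_nt = length_nt, utype = utype,
       frame_offset = (uatg_pos - 1L) %% 3L,
       in_frame_with_morf = in_frame)
}

#' Annotate all uORFs in a 5' leader
#'
#' Finds every ATG strictly upstream of the main start codon, extends
#' each to its stop and classifies it. Overlapping and nested uORFs are
#' all retained. Complete uORFs shorter than `config$min_length_nt` are
#' dropped; incomplete uORFs are kept only when
#' `config$include_incomplete` is set. Counts always reflect the
#' retained rows.
#'
#' @param ctx a [leader_context()].
#' @param config a [scan_config()].
#' @return An object of class `uorf_annotation`: list with `context`,
#'   `uorfs` (data frame sorted by `uatg_pos`), `counts_by_type` (named
#'   integer vector over TYPE1/TYPE2/TYPE3/INCOMPLETE) and
#'   `total_complete`.
#' @examples
#' ctx <- leader_context("tx1", "ATGTAACC", "ATGGGGTGA")
#' annotate_leader(ctx)$counts_by_type
#' @export
annotate_leader <- function(ctx, config = scan_config()) {
  stopifnot(inherits(ctx, "leader_context"))
  starts <- find_start_codons(ctx$transcript_seq, ctx$matg_pos - 1L)
  rows <- lapply(starts, function(p) scan_uorf(ctx, p, config))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(uatg_pos = r$uatg_pos, stop_start = r$stop_start,
               stop_end = r$stop_end, length_nt = r$length_nt,
               utype = r$utype, frame_offset = r$frame_offset,
               in_frame_with_morf = r$in_frame_with_morf)))
  if (is.null(df)) df <- empty_uorf_frame()
  keep <- (df$utype == "INCOMPLETE" & config$include_incomplete) |
          (df$utype != "INCOMPLETE" & df$length_nt >= config$min_length_nt)
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$uatg_pos), , drop = FALSE]
  rownames(df) <- NULL
  counts <- table(factor(df$utype, levels = UORF_TYPES))
  counts <- stats::setNames(as.integer(counts), UORF_TYPES)
  structure(list(context = ctx, uorfs = df, counts_by_type = counts,
                 total_complete = sum(counts[c("TYPE1", "TYPE2", "TYPE3")])),
            class = "uorf_annotation")
}

empty_uorf_frame <- function() {
  data.frame(uatg_pos = integer(0), stop_start = integer(0),
             stop_end = integer(0), length_nt = integer(0),
             utype = character(0), frame_offset = integer(0),
             in_frame_with_morf = logical(0))
}

#' @export
print.uorf_annotation <- function(x, ...) {
  cat(sprintf("uORF annotation of '%s' (%d nt leader): %d complete uORF(s)\n",
              x$context$transcript_id, nchar(x$context$leader_seq),
              x$total_complete))
  cat("  counts:", paste(sprintf("%s=%d", names(x$counts_by_type),
                                 x$counts_by_type), collapse = " "), "\n")
  if (nrow(x$uorfs)) print(x$uorfs)
  invisible(x)
}

#' @method as.data.frame uorf_annotation
#' @export
as.data.frame.uorf_annotation <- function(x, ...) {
  df <- x$uorfs
  if (nrow(df))
    df <- cbind(transcript_id = x$context$transcript_id,
                uorf_index = seq_len(nrow(df)), df)
  df
}

#' Write an annotation report
#'
#' Emits a TSV (one row per uORF, 1-based inclusive coordinates) and a
#' JSON summary with the per-type counts.
#'
#' @param ann a [annotate_leader()] result.
#' @param tsv_path,json_path output paths (NULL skips either).
#' @param provenance optional named list written as `#` header lines.
#' @return Invisibly, the paths written.
#' @export
write_annotation <- function(ann, tsv_path = NULL, json_path = NULL,
                             provenance = NULL) {
  stopifnot(inherits(ann, "uorf_annotation"))
  if (!is.null(tsv_path)) {
    df <- as.data.frame(ann)
    if (nrow(df) == 0)
      df <- cbind(transcript_id = character(0), uorf_index = integer(0),
                  empty_uorf_frame())
    df <- df[, c("transcript_id", "uorf_index", "uatg_pos", "stop_end",
                 "length_nt", "utype", "in_frame_with_morf")]
    names(df)[names(df) == "uatg_pos"] <- "uatg_pos_1based"
    names(df)[names(df) == "stop_end"] <- "stop_end_1based"
    write_tsv_report(df, tsv_path, provenance)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(transcript_id = ann$context$transcript_id,
           counts_by_type = as.list(ann$counts_by_type),
           total_complete = ann$total_complete,
           uatg_positions = ann$uorfs$uatg_pos),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
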