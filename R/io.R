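#' Read a FASTA file
#'
#' Sequences are uppercased and U is normalized to T. Duplicate record
#' identifiers and non-IUPAC characters are rejected; record order is
#' preserved.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  # first whitespace-delimited token of the header line is the ID
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  seqs <- chartr("u", "T", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTNRYSWKMBDHV]", seqs[i])
    if (bad > 0L)
      stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                   substr(seqs[i], bad, bad), ids[i], bad), call. = FALSE)
  }
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a leader/CDS transcript model from FASTA
#'
#' Accepts either two records named `<id>_leader` and `<id>_cds`, or a
#' single record plus an explicit `leader_len`.
#'
#' @param path FASTA path.
#' @param transcript_id id prefix; defaults to the common prefix found.
#' @param leader_len leader length for the single-record layout.
#' @return A [leader_context()].
#' @export
read_leader_context <- function(path, transcript_id = NULL,
                                leader_len = NULL) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  if (!is.null(leader_len)) {
    if (length(seqs) != 1L)
      stop("leader_len layout expects a single FASTA record", call. = FALSE)
    tx <- seqs[[1]]
    if (leader_len >= nchar(tx))
      stop("leader_len exceeds the transcript length", call. = FALSE)
    return(leader_context(if (is.null(transcript_id)) ids[1] else transcript_id,
                          substr(tx, 1L, leader_len),
                          substr(tx, leader_len + 1L, nchar(tx))))
  }
  leaders <- grep("_leader$", ids, value = TRUE)
  if (length(leaders) != 1L)
    stop("expected exactly one '<id>_leader' record (or pass leader_len)",
         call. = FALSE)
  id <- sub("_leader$", "", leaders)
  cds_id <- paste0(id, "_cds")
  if (!cds_id %in% ids)
    stop("missing record '", cds_id, "'", call. = FALSE)
  leader_context(id, seqs[[leaders]], seqs[[cds_id]])
}

# TSV with `#`-prefixed provenance header lines
write_tsv_report <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    for (k in names(provenance))
      writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  writeLines("# coordinates: 1-based inclusive", con)
  df[] <- lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "."
    col
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated report or input table
#'
#' @param path TSV path; `#` lines are treated as comments and "." as NA.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    na.strings = ".", stringsAsFactors = FALSE)
}
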