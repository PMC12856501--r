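#' Edit constructors
#'
#' Edits are expressed in 1-based reference coordinates. A deletion
#' removes `del_len` bases starting at `pos`; a substitution replaces
#' `nchar(alt_seq)` bases starting at `pos`; an insertion places
#' `alt_seq` immediately before `pos` (so `pos = 1` prepends and
#' `pos = nchar(ref) + 1` appends).
#'
#' @param pos 1-based reference position.
#' @param del_len deletion length (DEL).
#' @param alt_seq inserted/replacement bases (INS/SUB).
#' @return A one-row `edit_set` data frame with columns `kind`, `pos`,
#'   `del_len`, `alt_seq`.
#' @name edits
NULL

#' @rdname edits
#' @export
edit_del <- function(pos, del_len) {
  stopifnot(del_len >= 1)
  new_edit_set(data.frame(kind = "DEL", pos = as.integer(pos),
                          del_len = as.integer(del_len),
                          alt_seq = NA_character_))
}

#' @rdname edits
#' @export
edit_ins <- function(pos, alt_seq) {
  validate_dna(alt_seq, "alt_seq")
  stopifnot(nchar(alt_seq) >= 1)
  new_edit_set(data.frame(kind = "INS", pos = as.integer(pos),
                          del_len = 0L, alt_seq = alt_seq))
}

#' @rdname edits
#' @export
edit_sub <- function(pos, alt_seq) {
  validate_dna(alt_seq, "alt_seq")
  stopifnot(nchar(alt_seq) >= 1)
  new_edit_set(data.frame(kind = "SUB", pos = as.integer(pos),
                          del_len = 0L, alt_seq = alt_seq))
}

#' Combine edits into an edit set
#' @param ... `edit_set` rows from [edit_del()], [edit_ins()], [edit_sub()].
#' @return An `edit_set` data frame.
#' @export
edit_set <- function(...) {
  parts <- list(...)
  if (length(parts) == 0) return(empty_edit_set())
  new_edit_set(do.call(rbind, parts))
}

new_edit_set <- function(df) {
  class(df) <- c("edit_set", "data.frame")
  df
}

#' @rdname edit_set
#' @export
empty_edit_set <- function() {
  new_edit_set(data.frame(kind = character(0), pos = integer(0),
                          del_len = integer(0), alt_seq = character(0)))
}

# reference footprint [start, end] of an edit row; insertions are
# zero-width and sit between pos-1 and pos (end = pos - 1).
edit_span <- function(e) {
  end <- switch(e$kind,
                DEL = e$pos + e$del_len - 1L,
                SUB = e$pos + nchar(e$alt_seq) - 1L,
                INS = e$pos - 1L)
  c(e$pos, end)
}

check_edits <- function(reference, edits) {
  n <- nchar(reference)
  if (nrow(edits) == 0) return(invisible(edits))
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (!e$kind %in% c("DEL", "INS", "SUB"))
      stop("unknown edit kind: ", e$kind, call. = FALSE)
    sp <- edit_span(e)
    lo <- sp[1]; hi <- sp[2]
    if (e$kind == "INS") {
      if (lo < 1L || lo > n + 1L)
        stop(sprintf("insertion position %d outside reference (1..%d)",
                     lo, n + 1L), call. = FALSE)
    } else if (lo < 1L || hi > n) {
      stop(sprintf("%s span [%d,%d] outside reference (1..%d)",
                   e$kind, lo, hi, n), call. = FALSE)
    }
  }
  spans <- t(vapply(seq_len(nrow(edits)),
                    function(i) edit_span(edits[i, ]), integer(2)))
  ord <- order(spans[, 1], spans[, 2])
  for (k in seq_len(nrow(edits) - 1L)) {
    a <- ord[k]; b <- ord[k + 1L]
    # two insertions at the same point have ambiguous order -> conflict
    overlap <- spans[b, 1] <= spans[a, 2] ||
      (edits$kind[a] == "INS" && edits$kind[b] == "INS" &&
       edits$pos[a] == edits$pos[b])
    if (overlap)
      stop(sprintf("overlapping edits: %s at %d and %s at %d",
                   edits$kind[a], edits$pos[a], edits$kind[b], edits$pos[b]),
           call. = FALSE)
  }
  invisible(edits)
}

#' Apply a set of edits to a reference sequence
#'
#' Edits are applied as if simultaneous: their spans must be pairwise
#' non-overlapping in reference coordinates, and positions always refer
#' to the unedited reference. Alongside the edited sequence a coordinate
#' map is produced, giving for every surviving (non-deleted) reference
#' position its 1-based position in the edited sequence; substituted
#' positions survive (they map onto their replacement base).
#'
#' @param reference nucleotide string.
#' @param edits an `edit_set` (see [edit_set()]).
#' @param allele_id label for the resulting allele.
#' @return An object of class `edited_allele`: list with `allele_id`,
#'   `seq`, `edits`, `net_length_change` and `coord_map` (integer vector
#'   of length `nchar(reference)`, NA at deleted positions, strictly
#'   increasing elsewhere).
#' @examples
#' apply_edits("AAACCCGGG", edit_del(4, 3))$seq  # "AAAGGG"
#' @export
apply_edits <- function(reference, edits = empty_edit_set(),
                        allele_id = "allele") {
  validate_dna(reference, "reference")
  check_edits(reference, edits)
  n <- nchar(reference)
  if (nrow(edits)) {
    ord <- order(vapply(seq_len(nrow(edits)),
                        function(i) edit_span(edits[i, ])[1], integer(1)))
    edits <- edits[ord, , drop = FALSE]
  }
  pieces <- character(0)
  coord_map <- integer(n)
  out_len <- 0L    # edited length emitted so far
  cursor <- 1L     # next unconsumed reference position
  emit_ref <- function(from, to) {
    if (to < from) return(invisible())
    pieces[[length(pieces) + 1L]] <<- substr(reference, from, to)
    coord_map[from:to] <<- out_len + seq_len(to - from + 1L)
    out_len <<- out_len + (to - from + 1L)
  }
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    emit_ref(cursor, e$pos - 1L)
    cursor <- max(cursor, e$pos)
    if (e$kind == "DEL") {
      coord_map[e$pos:(e$pos + e$del_len - 1L)] <- NA_integer_
      cursor <- e$pos + e$del_len
    } else if (e$kind == "SUB") {
      w <- nchar(e$alt_seq)
      pieces[[length(pieces) + 1L]] <- e$alt_seq
      coord_map[e$pos:(e$pos + w - 1L)] <- out_len + seq_len(w)
      out_len <- out_len + w
      cursor <- e$pos + w
    } else { # INS before pos
      pieces[[length(pieces) + 1L]] <- e$alt_seq
      out_len <- out_len + nchar(e$alt_seq)
    }
  }
  emit_ref(cursor, n)
  seq <- paste(pieces, collapse = "")
  structure(list(allele_id = allele_id, seq = seq, edits = edits,
                 net_length_change = nchar(seq) - n,
                 coord_map = coord_map),
            class = "edited_allele")
}

#' @export
print.edited_allele <- function(x, ...) {
  cat(sprintf("edited_allele '%s': %d edit(s), net length change %+d\n",
              x$allele_id, nrow(x$edits), x$net_length_change))
  invisible(x)
}

#' Read an edit specification table
#'
#' TSV with columns `allele_id`, `kind`, `pos_1based`, `del_len`,
#' `alt_seq` ("." for missing). Returns a named list of `edit_set`
#' objects, one per allele.
#'
#' @param path TSV path.
#' @return Named list of `edit_set` data frames.
#' @export
read_edit_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  need <- c("allele_id", "kind", "pos_1based", "del_len", "alt_seq")
  if (!all(need %in% names(df)))
    stop("edit table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$allele_id), function(d) {
    rows <- lapply(seq_len(nrow(d)), function(i) {
      kind <- toupper(d$kind[i]); pos <- as.integer(d$pos_1based[i])
      switch(kind,
             DEL = edit_del(pos, as.integer(d$del_len[i])),
             INS = edit_ins(pos, d$alt_seq[i]),
             SUB = edit_sub(pos, d$alt_seq[i]),
             stop("unknown edit kind: ", kind, call. = FALSE))
    })
    do.call(edit_set, rows)
  })
  out[unique(df$allele_id)]
}
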