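# A reference uATG at p "survives" in an edited allele when all three of
# its bases have images under the coordinate map, those images are
# consecutive, and the edited trinucleotide still reads ATG (so a
# substitution that rewrites a base back to the same letter, or an edit
# elsewhere, does not count as destruction).
uatg_survival <- function(positions, allele) {
  cm <- allele$coord_map
  vapply(positions, function(p) {
    img <- cm[p:(p + 2L)]
    if (anyNA(img) || img[2L] != img[1L] + 1L || img[3L] != img[1L] + 2L)
      return(NA_integer_)
    if (substr(allele$seq, img[1L], img[1L] + 2L) == "ATG") img[1L]
    else NA_integer_
  }, integer(1))
}

#' Compare uORF annotations before and after editing
#'
#' Matches reference uATGs to edited-allele uATGs through the coordinate
#' map of the edited allele: a reference uATG with no surviving image is
#' destroyed, an edited-allele uATG with no reference preimage is
#' created, and surviving uATGs contribute a type transition.
#'
#' @param before,after `uorf_annotation` objects for the reference and
#'   the edited allele.
#' @param allele the `edited_allele` linking the two coordinate systems.
#' @return An object of class `uorf_delta`: list with `counts_before`,
#'   `counts_after`, `total_before`, `total_after`,
#'   `percent_change_total` (100 x (after - before) / before; NA when
#'   the reference has no complete uORFs), per-type percent changes,
#'   `uatgs_destroyed`, `uatgs_created` (positions), and
#'   `type_transitions` (data frame `ref_pos`, `edited_pos`,
#'   `before_type`, `after_type`).
#' @export
diff_annotations <- function(before, after, allele) {
  stopifnot(inherits(before, "uorf_annotation"),
            inherits(after, "uorf_annotation"),
            inherits(allele, "edited_allele"))
  ref_pos <- before$uorfs$uatg_pos
  img <- uatg_survival(ref_pos, allele)
  destroyed <- ref_pos[is.na(img)]
  surviving_ref <- ref_pos[!is.na(img)]
  surviving_img <- img[!is.na(img)]
  # a surviving uATG may still be absent from `after` (e.g. filtered by
  # min length); treat that as destroyed so counts stay conserved
  in_after <- surviving_img %in% after$uorfs$uatg_pos
  destroyed <- sort(c(destroyed, surviving_ref[!in_after]))
  surviving_ref <- surviving_ref[in_after]
  surviving_img <- surviving_img[in_after]
  created <- setdiff(after$uorfs$uatg_pos, surviving_img)

  bt <- before$uorfs$utype[match(surviving_ref, before$uorfs$uatg_pos)]
  at <- after$uorfs$utype[match(surviving_img, after$uorfs$uatg_pos)]
  transitions <- data.frame(ref_pos = surviving_ref,
                            edited_pos = surviving_img,
                            before_type = bt, after_type = at)

  tb <- before$total_complete
  ta <- after$total_complete
  pct <- if (tb > 0) 100 * (ta - tb) / tb else NA_real_
  per_type <- vapply(c("TYPE1", "TYPE2", "TYPE3"), function(ty) {
    b <- before$counts_by_type[[ty]]
    if (b > 0) 100 * (after$counts_by_type[[ty]] - b) / b else NA_real_
  }, numeric(1))
  structure(list(counts_before = before$counts_by_type,
                 counts_after = after$counts_by_type,
                 total_before = tb, total_after = ta,
                 percent_change_total = pct,
                 percent_change_by_type = per_type,
                 uatgs_destroyed = destroyed,
                 uatgs_created = sort(created),
                 type_transitions = transitions),
            class = "uorf_delta")
}

#' @export
print.uorf_delta <- function(x, ...) {
  cat(sprintf("uORF delta: total %d -> %d (%s%%)\n", x$total_before,
              x$total_after,
              if (is.na(x$percent_change_total)) "NA"
              else sprintf("%+.1f", x$percent_change_total)))
  cat(sprintf("  uATGs destroyed: %d  created: %d\n",
              length(x$uatgs_destroyed), length(x$uatgs_created)))
  chg <- x$type_transitions[x$type_transitions$before_type !=
                              x$type_transitions$after_type, ]
  if (nrow(chg))
    cat("  type transitions:",
        paste(sprintf("%s->%s@%d", chg$before_type, chg$after_type,
                      chg$ref_pos), collapse = " "), "\n")
  invisible(x)
}

#' Predict the uORF landscape of a CRISPR allele
#'
#' Applies the edits to the transcript, recomputes the main-ATG position
#' through the coordinate map, re-annotates the edited leader, and
#' reports the before/after delta. Edits must stay within the 5' leader
#' unless `allow_cds_edits` is set; either way the edited CDS must still
#' be a valid main ORF (start ATG, frame intact, terminal stop).
#'
#' @param ctx a [leader_context()].
#' @param edits an `edit_set` in transcript coordinates.
#' @param config a [scan_config()].
#' @param allow_cds_edits permit edits at or beyond the main ATG.
#' @param allele_id label for the edited allele.
#' @return List with `allele` (`edited_allele`), `context` (edited
#'   `leader_context`), `annotation` (edited-allele `uorf_annotation`)
#'   and `delta` (`uorf_delta`).
#' @export
predict_edit_outcome <- function(ctx, edits = empty_edit_set(),
                                 config = scan_config(),
                                 allow_cds_edits = FALSE,
                                 allele_id = "edited") {
  stopifnot(inherits(ctx, "leader_context"))
  check_edits(ctx$transcript_seq, edits)
  if (!allow_cds_edits && nrow(edits)) {
    spans <- t(vapply(seq_len(nrow(edits)),
                      function(i) edit_span(edits[i, ]), integer(2)))
    if (any(spans[, 2] >= ctx$matg_pos))
      stop("edits extend into the CDS; set allow_cds_edits = TRUE",
           call. = FALSE)
  }
  allele <- apply_edits(ctx$transcript_seq, edits, allele_id = allele_id)
  new_matg <- allele$coord_map[ctx$matg_pos]
  if (is.na(new_matg) ||
      substr(allele$seq, new_matg, new_matg + 2L) != "ATG")
    stop("edit destroys the main ATG", call. = FALSE)
  new_leader <- substr(allele$seq, 1L, new_matg - 1L)
  new_cds <- substr(allele$seq, new_matg, nchar(allele$seq))
  edited_ctx <- tryCatch(
    leader_context(paste0(ctx$transcript_id, ":", allele_id),
                   new_leader, new_cds),
    error = function(e) stop("edited allele no longer has a valid CDS: ",
                             conditionMessage(e), call. = FALSE))
  before <- annotate_leader(ctx, config)
  after <- annotate_leader(edited_ctx, config)
  delta <- diff_annotations(before, after, allele)
  list(allele = allele, context = edited_ctx, annotation = after,
       delta = delta)
}

#' Write a uORF delta report
#'
#' JSON with the full delta plus a one-row TSV with per-type counts and
#' the relative change in total uORF count.
#'
#' @param delta a `uorf_delta`.
#' @param allele_id label used in the TSV row.
#' @param tsv_path,json_path output paths (NULL skips either).
#' @param provenance optional named list written as `#` header lines.
#' @return Invisibly, the paths written.
#' @export
write_delta <- function(delta, allele_id = "edited", tsv_path = NULL,
                        json_path = NULL, provenance = NULL) {
  stopifnot(inherits(delta, "uorf_delta"))
  if (!is.null(tsv_path)) {
    df <- data.frame(allele_id = allele_id,
                     type1_before = delta$counts_before[["TYPE1"]],
                     type2_before = delta$counts_before[["TYPE2"]],
                     type3_before = delta$counts_before[["TYPE3"]],
                     type1_after = delta$counts_after[["TYPE1"]],
                     type2_after = delta$counts_after[["TYPE2"]],
                     type3_after = delta$counts_after[["TYPE3"]],
                     total_before = delta$total_before,
                     total_after = delta$total_after,
                     percent_change_total =
                       round_half_up(delta$percent_change_total, 2),
                     uatgs_destroyed = length(delta$uatgs_destroyed),
                     uatgs_created = length(delta$uatgs_created))
    write_tsv_report(df, tsv_path, provenance)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(allele_id = allele_id,
           counts_before = as.list(delta$counts_before),
           counts_after = as.list(delta$counts_after),
           total_before = delta$total_before,
           total_after = delta$total_after,
           percent_change_total = delta$percent_change_total,
           uatgs_destroyed = delta$uatgs_destroyed,
           uatgs_created = delta$uatgs_created,
           type_transitions = delta$type_transitions),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}
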