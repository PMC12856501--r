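# canonical string signature of one edit; SUB signatures are the only
# kind per-base read noise can fabricate
edit_signature <- function(e) {
  switch(e$kind,
         DEL = sprintf("DEL:%d:%d", e$pos, e$del_len),
         INS = sprintf("INS:%d:%s", e$pos, e$alt_seq),
         SUB = sprintf("SUB:%d:%s", e$pos, e$alt_seq))
}

edit_set_signature <- function(edits) {
  if (nrow(edits) == 0) return(character(0))
  vapply(seq_len(nrow(edits)), function(i) edit_signature(edits[i, ]),
         character(1))
}

#' Classify the zygosity of an edited line from clone edit sets
#'
#' Each sequenced clone contributes one normalized edit set (e.g. from
#' [call_variants()]). Per-base Sanger read errors manifest as
#' substitutions, and with many clones two reads can hit the same base
#' by chance, so a substitution is treated as allelic only when it
#' recurs in at least a quarter of the clones (and never fewer than
#' `min_support`); a real heterozygous or chimeric substitution is
#' carried by one-half or one-third of clones and passes easily, while
#' coincident read errors do not. Indels are never filtered -- read
#' noise does not fabricate them. Clones are then grouped by their
#' filtered signature and signatures supported by fewer than
#' `min_support` clones are discarded as noise. The surviving distinct
#' signatures S decide
#' the call: all empty gives wild-type, a single non-empty signature
#' homozygous, two signatures heterozygous, three or more chimeric.
#'
#' Clone counting cannot distinguish homozygous from hemizygous lines;
#' homozygous calls carry `hemizygous_possible = TRUE`.
#'
#' @param clone_edit_sets list of `edit_set` data frames, one per clone
#'   (at least 2 clones).
#' @param line_id label.
#' @param min_support minimum clones supporting an edit and an allele
#'   signature (default 2).
#' @return An object of class `zygosity_call`: list with `line_id`,
#'   `category` (HOMOZYGOUS / HETEROZYGOUS / CHIMERIC / WILD_TYPE),
#'   `allele_signatures` (data frame `signature`, `n_clones`),
#'   `n_clones` and `hemizygous_possible`.
#' @export
classify_zygosity <- function(clone_edit_sets, line_id = "line",
                              min_support = 2L) {
  if (!is.list(clone_edit_sets) || length(clone_edit_sets) < 2L)
    stop("need at least 2 clones", call. = FALSE)
  sigs <- lapply(clone_edit_sets, edit_set_signature)
  # a substitution is allelic when it recurs in >= 1/4 of clones;
  # coincident read errors at one base stay far below that
  sub_support <- max(min_support, ceiling(length(clone_edit_sets) / 4))
  support <- table(unlist(lapply(sigs, unique)))
  noise <- if (length(support))
    names(support)[support < sub_support &
                     startsWith(names(support), "SUB")]
  else character(0)
  clone_sig <- vapply(sigs, function(s)
    paste(sort(s[!s %in% noise]), collapse = ";"), character(1))
  tab <- table(clone_sig)
  tab <- tab[tab >= min_support]
  if (length(tab) == 0)
    stop("insufficient clone support: no allele signature reaches ",
         min_support, " clones", call. = FALSE)
  sig_df <- data.frame(signature = names(tab), n_clones = as.integer(tab))
  sig_df <- sig_df[order(-sig_df$n_clones, sig_df$signature), ,
                   drop = FALSE]
  rownames(sig_df) <- NULL
  nonempty <- sig_df$signature != ""
  category <- if (!any(nonempty)) "WILD_TYPE"
              else if (nrow(sig_df) == 1L) "HOMOZYGOUS"
              else if (nrow(sig_df) == 2L) "HETEROZYGOUS"
              else "CHIMERIC"
  structure(list(line_id = line_id, category = category,
                 allele_signatures = sig_df,
                 n_clones = length(clone_edit_sets),
                 hemizygous_possible = category == "HOMOZYGOUS"),
            class = "zygosity_call")
}

#' @export
print.zygosity_call <- function(x, ...) {
  cat(sprintf("zygosity_call '%s': %s (%d clone(s), %d signature(s))\n",
              x$line_id, x$category, x$n_clones,
              nrow(x$allele_signatures)))
  invisible(x)
}

#' Genotype one line from clone sequences
#'
#' Aligns every clone to the reference amplicon, calls variants, and
#' classifies zygosity.
#'
#' @param reference amplicon sequence.
#' @param clone_seqs character vector of clone sequences.
#' @param line_id label.
#' @param min_support see [classify_zygosity()].
#' @param ... scoring parameters passed to [align_pair()].
#' @return A `zygosity_call` with an extra element `clone_edits` (list
#'   of per-clone `edit_set`s).
#' @export
genotype_line <- function(reference, clone_seqs, line_id = "line",
                          min_support = 2L, ...) {
  stopifnot(is.character(clone_seqs), length(clone_seqs) >= 2L)
  clone_edits <- lapply(clone_seqs, function(q)
    call_variants(align_pair(reference, q, ...)))
  call <- classify_zygosity(clone_edits, line_id = line_id,
                            min_support = min_support)
  call$clone_edits <- clone_edits
  call
}

#' Cohort-level editing statistics
#'
#' Computes transformation efficiency (transgenic events per explant),
#' editing efficiency (edited lines per transgenic event) and the
#' per-category breakdown over transgenic events. Percentages are
#' rounded half-up to 2 decimals; zero denominators give NA rather than
#' an error.
#'
#' @param n_explants,n_transgenic cohort counts
#'   (`n_transgenic <= n_explants`).
#' @param calls list of `zygosity_call`s (at most `n_transgenic`);
#'   transgenic events without a call count as unedited.
#' @return An object of class `cohort_summary` with counts and
#'   percentage fields.
#' @examples
#' calls <- rep(list(structure(list(category = "HETEROZYGOUS"),
#'                             class = "zygosity_call")), 3)
#' summarize_cohort(10, 5, calls)
#' @export
summarize_cohort <- function(n_explants, n_transgenic, calls = list()) {
  n_explants <- as.integer(n_explants)
  n_transgenic <- as.integer(n_transgenic)
  if (n_transgenic > n_explants)
    stop("n_transgenic cannot exceed n_explants", call. = FALSE)
  cats <- vapply(calls, function(x) x$category, character(1))
  if (length(cats) > n_transgenic)
    stop("more zygosity calls than transgenic events", call. = FALSE)
  n_hom <- sum(cats == "HOMOZYGOUS")
  n_het <- sum(cats == "HETEROZYGOUS")
  n_chi <- sum(cats == "CHIMERIC")
  n_edited <- n_hom + n_het + n_chi
  pct <- function(num, den) if (is.na(den) || den == 0) NA_real_
                            else round_half_up(100 * num / den, 2)
  structure(list(
    n_explants = n_explants, n_transgenic = n_transgenic,
    n_edited = n_edited, n_homozygous = n_hom, n_heterozygous = n_het,
    n_chimeric = n_chi,
    transformation_efficiency_pct = pct(n_transgenic, n_explants),
    editing_efficiency_pct = pct(n_edited, n_transgenic),
    homozygous_pct = pct(n_hom, n_transgenic),
    heterozygous_pct = pct(n_het, n_transgenic),
    chimeric_pct = pct(n_chi, n_transgenic)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat(sprintf("cohort: %d explants, %d transgenic, %d edited\n",
              x$n_explants, x$n_transgenic, x$n_edited))
  cat(sprintf("  transformation %s  editing %s\n",
              fmt(x$transformation_efficiency_pct),
              fmt(x$editing_efficiency_pct)))
  cat(sprintf("  homozygous %s  heterozygous %s  chimeric %s\n",
              fmt(x$homozygous_pct), fmt(x$heterozygous_pct),
              fmt(x$chimeric_pct)))
  invisible(x)
}
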