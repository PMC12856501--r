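#' Specification for planting uORFs in a synthetic leader
#'
#' @param leader_len leader length in nt.
#' @param planted data frame with columns `utype` (TYPE1/TYPE2/TYPE3),
#'   `length_nt` (honoured for TYPE1; ignored for TYPE2/TYPE3, whose
#'   realized length is set by where the CDS provides the stop) and
#'   optional `uatg_pos` (NA lets the sampler choose).
#' @param forbid_stray_atg reject leaders containing sense-strand ATGs
#'   other than the planted ones (the CDS filler never contains internal
#'   ATGs, so the whole transcript window is covered).
#' @param max_attempts rejection-sampler budget.
#' @param cds_len CDS filler length (multiple of 3, >= 36); the filler
#'   starts with ATG, ends in TAA, contains no internal ATG, no in-frame
#'   internal stop, and carries stop codons in both shifted frames so
#'   out-of-frame uORFs terminate inside the main ORF.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(leader_len, planted, forbid_stray_atg = TRUE,
                       max_attempts = 5000L, cds_len = 60L) {
  leader_len <- as.integer(leader_len)
  stopifnot(leader_len >= 3L, is.data.frame(planted),
            all(c("utype", "length_nt") %in% names(planted)))
  if (!"uatg_pos" %in% names(planted)) planted$uatg_pos <- NA_integer_
  if (!all(planted$utype %in% c("TYPE1", "TYPE2", "TYPE3")))
    stop("planted utype must be TYPE1, TYPE2 or TYPE3", call. = FALSE)
  cds_len <- as.integer(cds_len)
  if (cds_len %% 3L != 0L || cds_len < 36L)
    stop("cds_len must be a multiple of 3 and >= 36", call. = FALSE)
  for (i in seq_len(nrow(planted))) {
    ty <- planted$utype[i]; len <- planted$length_nt[i]
    p <- planted$uatg_pos[i]
    if (ty == "TYPE1") {
      if (is.na(len) || len %% 3L != 0L || len < 6L)
        stop(sprintf("infeasible: TYPE1 length %s is not a multiple of 3 >= 6",
                     len), call. = FALSE)
      if (len > leader_len)
        stop(sprintf("infeasible: TYPE1 length %d exceeds leader length %d",
                     len, leader_len), call. = FALSE)
      if (!is.na(p) && (p < 1L || p + len - 1L > leader_len))
        stop(sprintf("infeasible: TYPE1 uORF at %d with length %d leaves the leader",
                     p, len), call. = FALSE)
    } else if (!is.na(p) && (p < 1L || p + 2L > leader_len)) {
      stop(sprintf("infeasible: uATG at %d outside the leader", p),
           call. = FALSE)
    }
  }
  structure(list(leader_len = leader_len, planted = planted,
                 forbid_stray_atg = isTRUE(forbid_stray_atg),
                 max_attempts = as.integer(max_attempts),
                 cds_len = cds_len),
            class = "plant_spec")
}

# CDS filler: ATG + random safe codons + frame-1 stop motif (CTA ACC,
# codons 5-6) + frame-2 stop motif (CCT AAC, codons 9-10) + TAA.
generate_cds <- function(cds_len) {
  n_codons <- cds_len %/% 3L
  safe <- c("CAA", "CAC", "CAG", "CCA", "CCC", "CCG", "CCT", "CGA",
            "CGC", "CGG", "CTC", "CTT", "GAA", "GAC", "GAG", "GCA",
            "GCC", "GCG", "GCT", "GGA", "GGC", "GGG", "GTC", "GTT",
            "TCC", "TCT", "TTC", "TTT", "AAC", "ACC", "AGC", "AAG")
  for (try in 1:100) {
    codons <- c("ATG", sample(safe, n_codons - 2L, replace = TRUE), "TAA")
    codons[5:6] <- c("CTA", "ACC")   # TAA in frame +1
    codons[9:10] <- c("CCT", "AAC")  # TAA in frame +2
    cds <- paste(codons, collapse = "")
    interior_ok <- !grepl("ATG", substr(cds, 2L, cds_len), fixed = TRUE)
    frame0 <- vapply(seq(4L, cds_len - 5L, by = 3L),
                     function(q) codon_at(cds, q), character(1))
    if (interior_ok && !any(frame0 %in% STOP_CODONS_DEFAULT)) return(cds)
  }
  stop("internal error: could not build a CDS filler", call. = FALSE)
}

#' Plant uORFs into a random leader under hard sequence constraints
#'
#' A rejection sampler with a constrained left-to-right filler: planted
#' uATGs (and, for TYPE1, their in-frame stop codons at the requested
#' distance) are fixed first, then every remaining base is drawn from
#' the letters that do not create an unplanned ATG (when
#' `forbid_stray_atg`) or a premature in-frame stop inside a planted
#' uORF. Overlapping and nested planted uORFs are permitted; an attempt
#' whose fixed bases collide, or whose final scan does not reproduce the
#' plant plan exactly, is discarded and re-drawn. Truth is defined as
#' the scanner's output on the final sequence, never the plan itself.
#'
#' @param spec a [plant_spec()].
#' @param seed integer seed (reproducible output).
#' @param config [scan_config()] used for the truth annotation.
#' @param transcript_id label.
#' @return An object of class `truth_bundle`: list with `context`
#'   ([leader_context()]), `truth_annotation` ([annotate_leader()] on
#'   the final sequence), `planted_map` (data frame mapping each spec
#'   entry to its realized uORF) and `attempts`.
#' @examples
#' tb <- plant_leader(plant_spec(30, data.frame(utype = "TYPE1",
#'                                              length_nt = 9)),
#'                    seed = 1)
#' tb$truth_annotation$counts_by_type
#' @export
plant_leader <- function(spec, seed = NULL, config = scan_config(),
                         transcript_id = "synthetic") {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(seed, {
    for (attempt in seq_len(spec$max_attempts)) {
      bundle <- plant_leader_once(spec, config, transcript_id)
      if (!is.null(bundle)) {
        bundle$attempts <- attempt
        return(bundle)
      }
    }
    stop("infeasible plant spec: no valid leader in ", spec$max_attempts,
         " attempts (constraints cannot all be satisfied)", call. = FALSE)
  })
}

plant_leader_once <- function(spec, config, transcript_id) {
  L <- spec$leader_len
  matg <- L + 1L
  pl <- spec$planted
  n_pl <- nrow(pl)
  # 1. draw uATG positions
  pos <- integer(n_pl)
  for (i in seq_len(n_pl)) {
    if (!is.na(pl$uatg_pos[i])) { pos[i] <- pl$uatg_pos[i]; next }
    cand <- switch(pl$utype[i],
      TYPE1 = seq_len(L - pl$length_nt[i] + 1L),
      TYPE3 = {
        x <- seq_len(L - 2L); x[(matg - x) %% 3L == 0L]
      },
      TYPE2 = {
        x <- seq_len(L - 2L); x[(matg - x) %% 3L != 0L]
      })
    if (length(cand) == 0) return(NULL)
    pos[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  if (anyDuplicated(pos)) return(NULL)
  # 2. fix planted bases
  fx <- rep(NA_character_, L)
  place <- function(at, bases) {
    idx <- at + seq_along(bases) - 1L
    ok <- is.na(fx[idx]) | fx[idx] == bases
    if (!all(ok)) return(FALSE)
    fx[idx] <<- bases
    TRUE
  }
  for (i in seq_len(n_pl)) {
    if (!place(pos[i], c("A", "T", "G"))) return(NULL)
    if (pl$utype[i] == "TYPE1") {
      stop_codon <- sample(config$stop_codons, 1L)
      if (!place(pos[i] + pl$length_nt[i] - 3L,
                 strsplit(stop_codon, "")[[1]])) return(NULL)
    }
  }
  # 3. constraint sets for the filler
  atg_ok <- pos
  stop_forbidden <- integer(0)
  for (i in seq_len(n_pl)) {
    p <- pos[i]
    q <- switch(pl$utype[i],
      TYPE1 = if (pl$length_nt[i] >= 9L)
                seq(p + 3L, p + pl$length_nt[i] - 6L, by = 3L)
              else integer(0),
      # stop must not appear in this frame anywhere else in the leader
      if (p + 3L <= L) seq(p + 3L, L, by = 3L) else integer(0))
    stop_forbidden <- c(stop_forbidden, q[q + 2L <= L])
  }
  # 4. constrained left-to-right fill
  bases <- fx
  window_bad <- function(q) {
    if (q < 1L || q + 2L > L) return(FALSE)
    tri <- bases[q:(q + 2L)]
    if (anyNA(tri)) return(FALSE)
    tri <- paste(tri, collapse = "")
    if (spec$forbid_stray_atg && tri == "ATG" && !(q %in% atg_ok))
      return(TRUE)
    tri %in% config$stop_codons && q %in% stop_forbidden
  }
  for (i in seq_len(L)) {
    if (!is.na(fx[i])) {
      if (window_bad(i - 2L) || window_bad(i - 1L) || window_bad(i))
        return(NULL)
      next
    }
    ok_base <- NULL
    for (b in sample(c("A", "C", "G", "T"))) {
      bases[i] <- b
      if (!window_bad(i - 2L) && !window_bad(i - 1L) && !window_bad(i)) {
        ok_base <- b
        break
      }
    }
    if (is.null(ok_base)) return(NULL)
    bases[i] <- ok_base
  }
  leader <- paste(bases, collapse = "")
  cds <- generate_cds(spec$cds_len)
  ctx <- leader_context(transcript_id, leader, cds)
  ann <- annotate_leader(ctx, config)
  # 5. verify the plan is realized exactly
  realized <- ann$uorfs
  if (spec$forbid_stray_atg &&
      !setequal(realized$uatg_pos, pos)) return(NULL)
  planted_map <- data.frame(spec_index = seq_len(n_pl),
                            utype = pl$utype,
                            length_nt = pl$length_nt,
                            uatg_pos = pos)
  for (i in seq_len(n_pl)) {
    row <- realized[realized$uatg_pos == pos[i], ]
    if (nrow(row) != 1L || row$utype != pl$utype[i]) return(NULL)
    if (pl$utype[i] == "TYPE1" && row$length_nt != pl$length_nt[i])
      return(NULL)
    planted_map$realized_length_nt[i] <- row$length_nt
  }
  structure(list(context = ctx, truth_annotation = ann,
                 planted_map = planted_map),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("truth_bundle: %d planted uORF(s) in a %d nt leader (attempt %d)\n",
              nrow(x$planted_map), nchar(x$context$leader_seq),
              x$attempts))
  print(x$truth_annotation)
  invisible(x)
}

#' Emulation of the study's control (CK) leader
#'
#' Plants five non-overlapping-type (Type 1) uORFs of 57, 15, 30, 54 and
#' 84 nt into a 192-nt leader under the no-stray-ATG constraint. The sum
#' of the lengths (240 nt) exceeds the leader, so the realized uORFs
#' necessarily overlap, matching the only consistent reading of the
#' published summary. The exact published bases are not emulated, only
#' their summary statistics.
#'
#' @param seed integer seed.
#' @param ... passed to [plant_leader()].
#' @return A `truth_bundle`.
#' @export
plant_ck_leader <- function(seed = NULL, ...) {
  spec <- plant_spec(192L,
                     data.frame(utype = "TYPE1",
                                length_nt = c(57L, 15L, 30L, 54L, 84L)))
  plant_leader(spec, seed = seed, transcript_id = "CK", ...)
}

#' Simulate a CRISPR edit pattern on a planted leader
#'
#' Draws edit sets realizing a named lesion profile on a synthetic
#' leader and verifies the realized uORF delta with
#' [predict_edit_outcome()] before returning; unsatisfiable profiles
#' raise an infeasibility error.
#'
#' Profiles:
#' \describe{
#'   \item{`disrupt_k_uatg`}{`k` uATGs destroyed by 3-bp deletions
#'     spanning each chosen start codon; no new starts created and the
#'     complete-uORF total drops by exactly `k`.}
#'   \item{`preserve_all_uatg`}{applies `lesions` (default: one 29-bp
#'     deletion and one 4-bp insertion, the profile of the study's first
#'     edited line) at positions that destroy and create no uATGs.}
#'   \item{`convert_to_type3`}{removes the in-frame stop codon(s) of a
#'     uORF that shares the main ORF's frame, so it becomes an
#'     N-terminal extension (Type 3) sharing the main stop.}
#'   \item{`lesion_sizes`}{places `lesions` at random non-overlapping
#'     leader positions with no constraint on the outcome.}
#' }
#'
#' @param truth a `truth_bundle` from [plant_leader()].
#' @param pattern profile name (see above).
#' @param k number of uATGs to disrupt (`disrupt_k_uatg`).
#' @param lesions data frame with columns `kind` (DEL/INS) and `len`.
#' @param seed integer seed; edits are deterministic per seed.
#' @param max_tries resampling budget for the verification loop.
#' @return An `edit_set` satisfying the profile.
#' @export
simulate_edit_pattern <- function(truth,
                                  pattern = c("disrupt_k_uatg",
                                              "preserve_all_uatg",
                                              "convert_to_type3",
                                              "lesion_sizes"),
                                  k = 2L, lesions = NULL, seed = NULL,
                                  max_tries = 200L) {
  stopifnot(inherits(truth, "truth_bundle"))
  pattern <- match.arg(pattern)
  ctx <- truth$context
  ann <- truth$truth_annotation
  with_seed(seed, switch(pattern,
    disrupt_k_uatg = {
      if (k == 0L) return(empty_edit_set())
      starts <- ann$uorfs$uatg_pos
      if (k > length(starts))
        stop("infeasible: only ", length(starts), " uATG(s) available",
             call. = FALSE)
      for (try in seq_len(max_tries)) {
        chosen <- sort(starts[sample.int(length(starts), k)])
        edits <- do.call(edit_set, lapply(chosen, edit_del, del_len = 3L))
        out <- tryCatch(predict_edit_outcome(ctx, edits),
                        error = function(e) NULL)
        if (!is.null(out) &&
            length(out$delta$uatgs_destroyed) == k &&
            length(out$delta$uatgs_created) == 0L &&
            out$delta$total_after == out$delta$total_before - k)
          return(edits)
      }
      stop("infeasible: could not disrupt ", k,
           " uATGs without side effects", call. = FALSE)
    },
    preserve_all_uatg = {
      if (is.null(lesions))
        lesions <- data.frame(kind = c("DEL", "INS"), len = c(29L, 4L))
      for (try in seq_len(max_tries)) {
        edits <- place_random_lesions(ctx, lesions,
                                      avoid = ann$uorfs$uatg_pos)
        if (is.null(edits)) next
        out <- tryCatch(predict_edit_outcome(ctx, edits),
                        error = function(e) NULL)
        if (!is.null(out) &&
            length(out$delta$uatgs_destroyed) == 0L &&
            length(out$delta$uatgs_created) == 0L)
          return(edits)
      }
      stop("infeasible: could not place lesions preserving every uATG",
           call. = FALSE)
    },
    convert_to_type3 = {
      inframe <- ann$uorfs$uatg_pos[ann$uorfs$in_frame_with_morf]
      if (length(inframe) == 0)
        stop("infeasible: no uATG shares the main ORF's frame",
             call. = FALSE)
      for (p in inframe[sample.int(length(inframe))]) {
        stops <- inframe_leader_stops(ctx, p)
        if (length(stops) == 0) next
        edits <- do.call(edit_set, lapply(stops, edit_del, del_len = 3L))
        out <- tryCatch(predict_edit_outcome(ctx, edits),
                        error = function(e) NULL)
        if (!is.null(out) && out$delta$counts_after[["TYPE3"]] >= 1L)
          return(edits)
      }
      stop("infeasible: removing in-frame stops never yielded a Type 3 uORF",
           call. = FALSE)
    },
    lesion_sizes = {
      if (is.null(lesions))
        stop("lesion_sizes profile requires `lesions`", call. = FALSE)
      for (try in seq_len(max_tries)) {
        edits <- place_random_lesions(ctx, lesions, avoid = integer(0))
        if (!is.null(edits)) return(edits)
      }
      stop("infeasible: could not place the requested lesions",
           call. = FALSE)
    }))
}

# stops in the frame of uATG p, strictly within the leader
inframe_leader_stops <- function(ctx, p) {
  stops <- integer(0)
  q <- p + 3L
  while (q + 2L < ctx$matg_pos) {
    if (codon_at(ctx$transcript_seq, q) %in% STOP_CODONS_DEFAULT)
      stops <- c(stops, q)
    q <- q + 3L
  }
  stops
}

# random non-overlapping lesions in the leader avoiding uATG trinucleotides;
# NULL when a draw collides
place_random_lesions <- function(ctx, lesions, avoid) {
  L <- ctx$matg_pos - 1L
  taken <- logical(L)
  for (p in avoid) taken[p:min(p + 2L, L)] <- TRUE
  rows <- list()
  for (i in seq_len(nrow(lesions))) {
    kind <- toupper(lesions$kind[i]); len <- as.integer(lesions$len[i])
    if (kind == "DEL") {
      if (len > L) return(NULL)
      p <- sample(L - len + 1L, 1L)
      if (any(taken[p:(p + len - 1L)])) return(NULL)
      taken[p:(p + len - 1L)] <- TRUE
      rows[[i]] <- edit_del(p, len)
    } else if (kind == "INS") {
      p <- sample(L, 1L)
      if (p > 1L && taken[p - 1L] && taken[p]) return(NULL)
      rows[[i]] <- edit_ins(p, paste(sample(c("C", "G", "T"), len,
                                            replace = TRUE),
                                     collapse = ""))
    } else stop("lesion kind must be DEL or INS", call. = FALSE)
  }
  edits <- do.call(edit_set, rows)
  tryCatch({ check_edits(ctx$transcript_seq, edits); edits },
           error = function(e) NULL)
}

#' Simulate Sanger-sequenced clones from a mixture of alleles
#'
#' Clones are drawn from the allele mixture and perturbed with
#' independent per-base substitution errors, emulating read noise in
#' base-called clone sequences. Truth labels are retained.
#'
#' @param alleles named character vector of allele sequences.
#' @param proportions mixing proportions (same length, sums to 1).
#' @param n_clones number of clones to draw.
#' @param error_rate per-base substitution probability in [0, 0.02].
#' @param seed integer seed.
#' @return Data frame with `clone_id`, `truth_allele`, `seq`.
#' @export
simulate_clones <- function(alleles, proportions = NULL, n_clones = 16L,
                            error_rate = 0.005, seed = NULL) {
  stopifnot(is.character(alleles), length(alleles) >= 1L)
  if (is.null(names(alleles)))
    names(alleles) <- paste0("allele", seq_along(alleles))
  if (is.null(proportions))
    proportions <- rep(1 / length(alleles), length(alleles))
  stopifnot(length(proportions) == length(alleles),
            abs(sum(proportions) - 1) < 1e-8)
  if (error_rate < 0 || error_rate > 0.02)
    stop("error_rate must be in [0, 0.02]", call. = FALSE)
  with_seed(seed, {
    picks <- sample(names(alleles), n_clones, replace = TRUE,
                    prob = proportions)
    seqs <- vapply(picks, function(a) {
      s <- strsplit(alleles[[a]], "")[[1]]
      hit <- which(stats::runif(length(s)) < error_rate)
      for (i in hit)
        s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
      paste(s, collapse = "")
    }, character(1))
    data.frame(clone_id = sprintf("clone%02d", seq_len(n_clones)),
               truth_allele = picks, seq = unname(seqs))
  })
}

#' Simulate qPCR Ct and metabolite tables with planted effect sizes
#'
#' Ct values are generated under the 2^-ddCt model: the target gene's
#' treatment Ct is shifted by -log2(fold) relative to the calibrator,
#' with Gaussian well-level noise, so [ddct()] recovers the planted fold
#' in expectation. Metabolite concentrations are drawn lognormally
#' around per-line analyte means.
#'
#' @param gene_folds named numeric vector: planted expression fold of
#'   each target gene (treatment vs calibrator).
#' @param analyte_means data frame with `line_id` plus the four analyte
#'   columns `TanI`, `TanIIA`, `CPT`, `DHT` (mg/g DW means per line);
#'   defaults to [study_tanshinone_means()].
#' @param conditions names of the calibrator and treatment conditions.
#' @param ct_sd Gaussian sd of each Ct well (cycles).
#' @param analyte_cv lognormal coefficient of variation of metabolite
#'   replicates.
#' @param n_bio,n_tech biological and technical replicates per cell.
#' @param n_met_rep metabolite replicates per line and analyte.
#' @param base_ct_target,base_ct_ref calibrator-condition mean Ct of the
#'   target and reference genes.
#' @param seed integer seed.
#' @return List with `ct` (a [ddct()]-ready data frame) and
#'   `metabolites` (a [tanshinone_summary()]-ready data frame).
#' @export
simulate_expression_tables <- function(gene_folds,
                                       analyte_means = study_tanshinone_means(),
                                       conditions = c("CK", "edited"),
                                       ct_sd = 0.1, analyte_cv = 0.05,
                                       n_bio = 3L, n_tech = 3L,
                                       n_met_rep = 3L,
                                       base_ct_target = 26,
                                       base_ct_ref = 20, seed = NULL) {
  stopifnot(is.numeric(gene_folds), !is.null(names(gene_folds)),
            all(gene_folds > 0), ct_sd >= 0, length(conditions) == 2L)
  with_seed(seed, {
    rows <- list()
    add <- function(sample_id, gene, role, condition, mean_ct) {
      for (tech in seq_len(n_tech))
        rows[[length(rows) + 1L]] <<-
          data.frame(sample_id = sample_id, gene = gene, role = role,
                     condition = condition, replicate = tech,
                     ct = stats::rnorm(1, mean_ct, ct_sd))
    }
    for (cond_i in 1:2) {
      cond <- conditions[cond_i]
      for (b in seq_len(n_bio)) {
        sid <- sprintf("%s_bio%d", cond, b)
        add(sid, "reference_gene", "reference", cond, base_ct_ref)
        for (g in names(gene_folds)) {
          shift <- if (cond_i == 2L) -log2(gene_folds[[g]]) else 0
          add(sid, g, "target", cond, base_ct_target + shift)
        }
      }
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL

    met <- list()
    sdlog <- sqrt(log(1 + analyte_cv^2))
    for (i in seq_len(nrow(analyte_means))) {
      for (a in TANSHINONE_ANALYTES) {
        mu <- analyte_means[[a]][i]
        for (r in seq_len(n_met_rep))
          met[[length(met) + 1L]] <- data.frame(
            line_id = analyte_means$line_id[i], analyte = a,
            mg_per_g_dw = if (sdlog > 0)
              stats::rlnorm(1, log(mu) - sdlog^2 / 2, sdlog) else mu,
            replicate = r)
      }
    }
    metabolites <- do.call(rbind, met)
    rownames(metabolites) <- NULL
    list(ct = ct, metabolites = metabolites)
  })
}

#' Per-line tanshinone means emulating the study's totals
#'
#' Synthetic per-analyte means whose sums reproduce the published total
#' tanshinone accumulation: 2.85 mg/g DW for the control and 3.39, 5.11,
#' 5.15 and 2.85 mg/g DW for the four edited lines (folds 1.19, 1.79,
#' 1.81 and 1.00). The per-analyte split of the control total (Tan I
#' 0.55, Tan IIA 1.20, CPT 0.70, DHT 0.40) is a synthetic stand-in --
#' the per-analyte absolute concentrations are not published -- and each
#' line scales all four analytes by its TTA fold.
#'
#' @return Data frame with `line_id`, `TanI`, `TanIIA`, `CPT`, `DHT`.
#' @export
study_tanshinone_means <- function() {
  ck <- c(TanI = 0.55, TanIIA = 1.20, CPT = 0.70, DHT = 0.40) # sums 2.85
  tta <- c(CK = 2.85, Del1 = 3.39, Del2 = 5.11, Del3 = 5.15, Del4 = 2.85)
  out <- data.frame(line_id = names(tta))
  for (a in names(ck)) out[[a]] <- ck[[a]] * tta / 2.85
  rownames(out) <- NULL
  out
}
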