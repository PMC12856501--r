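#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per sample and gene before any
#' differencing. For each sample, dCt = Ct(target) - Ct(reference gene);
#' ddCt = mean dCt(condition) - mean dCt(calibrator); the relative
#' quantity is 2^-ddCt. Per-sample relative quantities (against the
#' calibrator mean dCt) provide the dispersion estimate.
#'
#' @param records data frame with columns `sample_id`, `gene`, `role`
#'   (`target` or `reference`), `condition`, `replicate`, `ct`. Each
#'   sample needs both its target-gene and reference-gene wells. Ct
#'   values outside 10-40 cycles trigger a warning.
#' @param calibrator name of the calibrator condition.
#' @return Data frame with one row per (gene, condition):
#'   `delta_ct` (condition mean), `delta_delta_ct`, `rq`, `rq_sd`, `n`
#'   (biological samples). The calibrator rows have `rq == 1` by
#'   construction.
#' @examples
#' ct <- expand.grid(sample_id = c("s1", "s2"), gene = "GOI",
#'                   condition = c("CK", "mut"), stringsAsFactors = FALSE)
#' tgt <- transform(ct, role = "target", replicate = 1,
#'                  ct = ifelse(condition == "mut", 24, 25))
#' ref <- transform(ct, role = "reference", replicate = 1, ct = 20,
#'                  gene = "ACT")
#' ddct(rbind(tgt, ref), calibrator = "CK")
#' @export
ddct <- function(records, calibrator) {
  need <- c("sample_id", "gene", "role", "condition", "replicate", "ct")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(records$role %in% c("target", "reference")))
    stop("role must be 'target' or 'reference'", call. = FALSE)
  if (!is.numeric(records$ct) || any(!is.finite(records$ct)))
    stop("ct values must be finite numbers", call. = FALSE)
  if (any(records$ct < 10 | records$ct > 40))
    warning("Ct values outside the typical 10-40 cycle range")
  if (!calibrator %in% records$condition)
    stop("calibrator condition '", calibrator, "' absent from records",
         call. = FALSE)
  # average technical replicates
  mean_ct <- stats::aggregate(ct ~ sample_id + gene + role + condition,
                              data = records, FUN = mean)
  ref <- mean_ct[mean_ct$role == "reference", ]
  tgt <- mean_ct[mean_ct$role == "target", ]
  if (nrow(ref) == 0)
    stop("missing cell: no reference-gene records", call. = FALSE)
  out <- list()
  for (g in unique(tgt$gene)) {
    for (cond in unique(records$condition)) {
      cell <- tgt[tgt$gene == g & tgt$condition == cond, ]
      if (nrow(cell) == 0)
        stop(sprintf("missing cell: target gene '%s' in condition '%s'",
                     g, cond), call. = FALSE)
      rcell <- ref[ref$condition == cond, ]
      dct <- cell$ct - rcell$ct[match(cell$sample_id, rcell$sample_id)]
      if (anyNA(dct))
        stop(sprintf(
          "missing cell: reference gene for sample '%s' in condition '%s'",
          cell$sample_id[which(is.na(dct))[1]], cond), call. = FALSE)
      out[[paste(g, cond)]] <-
        data.frame(gene = g, condition = cond,
                   delta_ct = mean(dct), n = length(dct),
                   sample_dct = I(list(dct)))
    }
  }
  df <- do.call(rbind, out)
  res <- list()
  for (g in unique(df$gene)) {
    cal <- df[df$gene == g & df$condition == calibrator, ]
    for (i in which(df$gene == g)) {
      ddc <- df$delta_ct[i] - cal$delta_ct
      rq_samples <- 2^-(df$sample_dct[[i]] - cal$delta_ct)
      res[[length(res) + 1L]] <-
        data.frame(gene = g, condition = df$condition[i],
                   delta_ct = df$delta_ct[i], delta_delta_ct = ddc,
                   rq = 2^-ddc,
                   rq_sd = if (df$n[i] > 1) stats::sd(rq_samples)
                           else NA_real_,
                   n = df$n[i])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Relative translational efficiency from dual-luciferase data
#'
#' Translational efficiency of a construct is its LUC/REN activity ratio
#' divided by its LUC/REN mRNA ratio; the relative TE compares a
#' treatment construct with a control.
#'
#' @param activity_ratio_treat,activity_ratio_ctrl LUC/REN activity
#'   ratios (positive).
#' @param mrna_ratio_treat,mrna_ratio_ctrl LUC/REN mRNA ratios
#'   (positive).
#' @return Relative translational efficiency (treatment over control).
#' @examples
#' translational_efficiency(2.214, 1.035, 1, 1)  # ~2.139
#' @export
translational_efficiency <- function(activity_ratio_treat,
                                     activity_ratio_ctrl,
                                     mrna_ratio_treat, mrna_ratio_ctrl) {
  vals <- c(activity_ratio_treat, activity_ratio_ctrl,
            mrna_ratio_treat, mrna_ratio_ctrl)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("all ratios must be positive finite numbers", call. = FALSE)
  (activity_ratio_treat / mrna_ratio_treat) /
    (activity_ratio_ctrl / mrna_ratio_ctrl)
}

TANSHINONE_ANALYTES <- c("TanI", "TanIIA", "CPT", "DHT")

#' Total tanshinone accumulation and fold changes versus control
#'
#' Total tanshinone accumulation (TTA) is the sum of the four quantified
#' tanshinones (Tan I, Tan IIA, cryptotanshinone, dihydrotanshinone) in
#' mg/g dry weight. Replicate measurements are averaged per line and
#' analyte before summation. Fold changes versus the control line are
#' reported rounded half-up to 2 decimals and per-analyte percent
#' increases to 1 decimal.
#'
#' @param table data frame with columns `line_id`, `analyte` (TanI,
#'   TanIIA, CPT, DHT), `mg_per_g_dw` and optionally `replicate`.
#' @param ck_line_id control line identifier (must be present).
#' @return Data frame with one row per line: the four analyte means,
#'   `tta`, `fold_vs_ck` and `pct_increase_<analyte>` columns. The
#'   control row has `fold_vs_ck == 1`.
#' @export
tanshinone_summary <- function(table, ck_line_id = "CK") {
  need <- c("line_id", "analyte", "mg_per_g_dw")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!ck_line_id %in% table$line_id)
    stop("control line '", ck_line_id, "' absent from table", call. = FALSE)
  bad <- setdiff(unique(table$analyte), TANSHINONE_ANALYTES)
  if (length(bad))
    stop("unknown analyte(s): ", paste(bad, collapse = ", "), call. = FALSE)
  means <- stats::aggregate(mg_per_g_dw ~ line_id + analyte, data = table,
                            FUN = mean)
  lines <- unique(table$line_id)
  wide <- lapply(lines, function(l) {
    m <- means[means$line_id == l, ]
    v <- stats::setNames(m$mg_per_g_dw, m$analyte)
    if (!all(TANSHINONE_ANALYTES %in% names(v)))
      stop(sprintf("line '%s' is missing analyte(s): %s", l,
                   paste(setdiff(TANSHINONE_ANALYTES, names(v)),
                         collapse = ", ")), call. = FALSE)
    c(v[TANSHINONE_ANALYTES], tta = sum(v[TANSHINONE_ANALYTES]))
  })
  df <- as.data.frame(do.call(rbind, wide))
  df <- cbind(line_id = lines, df)
  ck <- df[df$line_id == ck_line_id, ]
  df$fold_vs_ck <- round_half_up(df$tta / ck$tta, 2)
  for (a in TANSHINONE_ANALYTES)
    df[[paste0("pct_increase_", a)]] <-
      round_half_up(100 * (df[[a]] - ck[[a]]) / ck[[a]], 1)
  rownames(df) <- NULL
  df
}

#' Two-sample t test
#'
#' Pooled-variance Student's t test by default, Welch's when
#' `equal_variance = FALSE`; two-sided p value. When both samples have
#' zero variance the test degenerates: equal means give t = 0, p = 1,
#' unequal means t = +/-Inf, p = 0.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param equal_variance pool the variance estimate.
#' @return List with `t`, `df` and `p_value`.
#' @export
two_sample_t <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    df <- if (equal_variance) length(x) + length(y) - 2L else NA_real_
    if (mean(x) == mean(y))
      return(list(t = 0, df = df, p_value = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = equal_variance)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
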