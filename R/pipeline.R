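pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("uorfkit")),
           error = function(e) "unknown")
}

#' Assemble a pipeline configuration
#'
#' @param reference FASTA with `<id>_leader` / `<id>_cds` records.
#' @param edits edit-specification TSV (see [read_edit_table()]); NULL
#'   skips the edit stage.
#' @param clones named list of per-line clone multi-FASTA paths; NULL
#'   skips genotyping.
#' @param ct Ct TSV for [ddct()]; NULL skips expression.
#' @param metabolites metabolite TSV for [tanshinone_summary()]; NULL
#'   skips the metabolite stage.
#' @param calibrator calibrator condition in the Ct table.
#' @param ck_line control line in the metabolite table.
#' @param n_explants,n_transgenic cohort counts for
#'   [summarize_cohort()].
#' @param guide_max_dist,guide_gc_bounds guide-ranking parameters.
#' @param min_support clone support threshold for genotyping.
#' @param seed seed recorded in output headers.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference, edits = NULL, clones = NULL,
                            ct = NULL, metabolites = NULL,
                            calibrator = "CK", ck_line = "CK",
                            n_explants = NA_integer_,
                            n_transgenic = NA_integer_,
                            guide_max_dist = 50L,
                            guide_gc_bounds = c(0.30, 0.80),
                            min_support = 2L, seed = NA_integer_) {
  structure(list(reference = reference, edits = edits, clones = clones,
                 ct = ct, metabolites = metabolites,
                 calibrator = calibrator, ck_line = ck_line,
                 n_explants = n_explants, n_transgenic = n_transgenic,
                 guide_max_dist = guide_max_dist,
                 guide_gc_bounds = guide_gc_bounds,
                 min_support = min_support, seed = seed),
            class = "pipeline_config")
}

#' Write a complete synthetic study into a directory
#'
#' Generates every input the pipeline consumes: a control leader with
#' five planted Type 1 uORFs (see [plant_ck_leader()]), edit
#' specifications emulating the study's four edited-line profiles,
#' clone sets for two lines (one homozygous, one heterozygous), and Ct
#' and metabolite tables with planted effect sizes. All randomness
#' derives from `seed`, so identical calls write identical files.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @param n_clones clones per genotyped line.
#' @param error_rate per-base clone substitution error.
#' @return A [pipeline_config()] pointing at the generated files.
#' @export
synthesize_study <- function(dir, seed = 1L, n_clones = 8L,
                             error_rate = 0.002) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- plant_ck_leader(seed = seed)
  ctx <- truth$context
  write_fasta(c(CK_leader = ctx$leader_seq, CK_cds = ctx$cds_seq),
              file.path(dir, "reference.fa"))

  profiles <- list(
    Del1 = simulate_edit_pattern(truth, "preserve_all_uatg",
                                 seed = seed + 101L),
    Del2 = simulate_edit_pattern(truth, "disrupt_k_uatg", k = 2L,
                                 seed = seed + 102L),
    Del3 = simulate_edit_pattern(truth, "disrupt_k_uatg", k = 2L,
                                 seed = seed + 103L),
    Del4 = simulate_edit_pattern(truth, "preserve_all_uatg",
                                 lesions = data.frame(kind = "DEL",
                                                      len = c(5L, 7L)),
                                 seed = seed + 104L))
  rows <- do.call(rbind, lapply(names(profiles), function(a) {
    e <- profiles[[a]]
    data.frame(allele_id = a, kind = e$kind, pos_1based = e$pos,
               del_len = ifelse(e$kind == "DEL", e$del_len, NA),
               alt_seq = e$alt_seq)
  }))
  write_tsv_report(rows, file.path(dir, "edits.tsv"),
                   provenance = list(seed = seed))

  wt <- ctx$transcript_seq
  hom_allele <- apply_edits(wt, profiles$Del2, "Del2")$seq
  het_allele <- apply_edits(wt, profiles$Del3, "Del3")$seq
  clone_paths <- list()
  cl1 <- simulate_clones(c(Del2 = hom_allele), n_clones = n_clones,
                         error_rate = error_rate, seed = seed + 201L)
  clone_paths$line_hom <- file.path(dir, "clones_line_hom.fa")
  write_fasta(stats::setNames(cl1$seq, cl1$clone_id), clone_paths$line_hom)
  cl2 <- simulate_clones(c(WT = wt, Del3 = het_allele),
                         proportions = c(0.5, 0.5), n_clones = n_clones,
                         error_rate = error_rate, seed = seed + 202L)
  clone_paths$line_het <- file.path(dir, "clones_line_het.fa")
  write_fasta(stats::setNames(cl2$seq, cl2$clone_id), clone_paths$line_het)

  tabs <- simulate_expression_tables(
    gene_folds = c(SmKSL1 = 2, SmHMGR1 = 1.5),
    conditions = c("CK", "edited"), seed = seed + 301L)
  write_tsv_report(tabs$ct, file.path(dir, "ct.tsv"),
                   provenance = list(seed = seed))
  write_tsv_report(tabs$metabolites, file.path(dir, "metabolites.tsv"),
                   provenance = list(seed = seed))

  pipeline_config(reference = file.path(dir, "reference.fa"),
                  edits = file.path(dir, "edits.tsv"),
                  clones = clone_paths,
                  ct = file.path(dir, "ct.tsv"),
                  metabolites = file.path(dir, "metabolites.tsv"),
                  n_explants = 93L, n_transgenic = 30L, seed = seed)
}

#' Run the analysis pipeline
#'
#' Stages run in dependency order: annotate the reference leader,
#' predict edit outcomes, design guides, genotype clone sets, and
#' compute expression/metabolite statistics. Each stage writes its
#' report into `outdir`; a manifest with an MD5 checksum per artifact
#' is written last. A stage failure halts the run with a stage-named
#' error and downstream outputs are not produced.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created).
#' @return List with `status` (0), `manifest` (data frame `file`,
#'   `md5`) and `manifest_path`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$reference) || !file.exists(config$reference))
    stop("pipeline config error: reference FASTA not found: ",
         config$reference, call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  prov <- list(tool = paste0("uorfkit ", pkg_version()),
               seed = config$seed,
               config_md5 = unname(tools::md5sum(cfg_json)))
  artifacts <- cfg_json
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ctx <- stage("annotate", read_leader_context(config$reference))
  ann <- stage("annotate", annotate_leader(ctx))
  ann_tsv <- file.path(outdir, "annotation.tsv")
  ann_json <- file.path(outdir, "annotation.json")
  stage("annotate", write_annotation(ann, ann_tsv, ann_json, prov))
  artifacts <- c(artifacts, ann_tsv, ann_json)

  if (!is.null(config$edits)) {
    edit_sets <- stage("edit", read_edit_table(config$edits))
    allele_seqs <- character(0)
    for (a in names(edit_sets)) {
      out <- stage("edit", predict_edit_outcome(ctx, edit_sets[[a]],
                                                allele_id = a))
      dj <- file.path(outdir, sprintf("delta_%s.json", a))
      dt <- file.path(outdir, sprintf("delta_%s.tsv", a))
      stage("edit", write_delta(out$delta, a, dt, dj, prov))
      artifacts <- c(artifacts, dt, dj)
      allele_seqs[[a]] <- out$allele$seq
    }
    fa <- file.path(outdir, "edited_alleles.fa")
    stage("edit", write_fasta(allele_seqs, fa))
    artifacts <- c(artifacts, fa)
  }

  guides <- stage("guides", {
    cand <- enumerate_protospacers(ctx$transcript_seq)
    rank_guides(cand, ann$uorfs$uatg_pos,
                max_dist = config$guide_max_dist,
                gc_bounds = config$guide_gc_bounds)
  })
  gt <- file.path(outdir, "guides.tsv")
  stage("guides", write_tsv_report(guides, gt, prov))
  artifacts <- c(artifacts, gt)

  if (!is.null(config$clones)) {
    calls <- list()
    for (line in names(config$clones)) {
      clones <- stage("genotype", read_fasta(config$clones[[line]]))
      calls[[line]] <- stage("genotype",
        genotype_line(ctx$transcript_seq, unname(clones), line_id = line,
                      min_support = config$min_support))
    }
    zj <- file.path(outdir, "zygosity.json")
    jsonlite::write_json(
      lapply(calls, function(x)
        list(line_id = x$line_id, category = x$category,
             n_clones = x$n_clones,
             allele_signatures = x$allele_signatures)),
      zj, auto_unbox = TRUE, pretty = TRUE)
    artifacts <- c(artifacts, zj)
    if (!is.na(config$n_explants) && !is.na(config$n_transgenic)) {
      cs <- stage("genotype",
                  summarize_cohort(config$n_explants, config$n_transgenic,
                                   calls))
      ct_tsv <- file.path(outdir, "cohort.tsv")
      write_tsv_report(as.data.frame(unclass(cs)), ct_tsv, prov)
      artifacts <- c(artifacts, ct_tsv)
    }
  }

  if (!is.null(config$ct)) {
    expr <- stage("stats", ddct(read_tsv(config$ct),
                                calibrator = config$calibrator))
    et <- file.path(outdir, "expression.tsv")
    stage("stats", write_tsv_report(expr, et, prov))
    artifacts <- c(artifacts, et)
  }
  if (!is.null(config$metabolites)) {
    tans <- stage("stats", tanshinone_summary(read_tsv(config$metabolites),
                                              ck_line_id = config$ck_line))
    tt <- file.path(outdir, "tanshinones.tsv")
    stage("stats", write_tsv_report(tans, tt, prov))
    artifacts <- c(artifacts, tt)
  }

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)))
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  mp <- file.path(outdir, "manifest.tsv")
  write_tsv_report(manifest, mp, prov)
  list(status = 0L, manifest = manifest, manifest_path = mp)
}
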