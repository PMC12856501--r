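test_that("a minimal planted uORF round-trips through the scanner", {
  spec <- plant_spec(20, data.frame(utype = "TYPE1", length_nt = 6))
  tb <- plant_leader(spec, seed = 3)
  ann <- tb$truth_annotation
  expect_equal(ann$total_complete, 1L)
  expect_equal(ann$uorfs$utype, "TYPE1")
  expect_equal(ann$uorfs$length_nt, 6L)
})

test_that("infeasible plant specs fail with a named constraint", {
  expect_error(plant_spec(20, data.frame(utype = "TYPE1", length_nt = 7)),
               "multiple of 3")
  expect_error(plant_spec(20, data.frame(utype = "TYPE1", length_nt = 30)),
               "exceeds leader length")
  expect_error(plant_spec(20, data.frame(utype = "TYPE1", length_nt = 9,
                                         uatg_pos = 15)),
               "leaves the leader")
  # arithmetically satisfiable but over-constrained in sequence space
  spec <- plant_spec(9, data.frame(utype = "TYPE1",
                                   length_nt = c(9, 9, 9)),
                     max_attempts = 50)
  expect_error(plant_leader(spec, seed = 1), "infeasible")
})

test_that("requested uATG positions and types are honoured", {
  spec <- plant_spec(40, data.frame(utype = c("TYPE1", "TYPE3"),
                                    length_nt = c(12, NA),
                                    uatg_pos = c(5, 26)))
  tb <- plant_leader(spec, seed = 9)
  ann <- tb$truth_annotation
  expect_setequal(ann$uorfs$uatg_pos, c(5, 26))
  expect_equal(ann$uorfs$utype[ann$uorfs$uatg_pos == 5], "TYPE1")
  expect_equal(ann$uorfs$utype[ann$uorfs$uatg_pos == 26], "TYPE3")
})

test_that("planted Type 2 uORFs terminate inside the main ORF", {
  spec <- plant_spec(30, data.frame(utype = "TYPE2", length_nt = NA))
  tb <- plant_leader(spec, seed = 4)
  u <- tb$truth_annotation$uorfs
  expect_equal(u$utype, "TYPE2")
  expect_gte(u$stop_end, tb$context$matg_pos)
  expect_false(u$in_frame_with_morf)
})

test_that("the control-leader emulation reproduces the published summary", {
  tb <- plant_ck_leader(seed = 27)
  ann <- tb$truth_annotation
  expect_equal(nchar(tb$context$leader_seq), 192L)
  expect_equal(ann$total_complete, 5L)
  expect_equal(unname(ann$counts_by_type[["TYPE1"]]), 5L)
  expect_setequal(ann$uorfs$length_nt, c(57, 15, 30, 54, 84))
})

test_that("truth equals the brute-force oracle and no stray ATG remains", {
  for (seed in 1:3) {
    tb <- plant_ck_leader(seed = seed)
    orc <- oracle_annotate(tb$context)
    expect_equal(tb$truth_annotation$uorfs$uatg_pos, orc$uatg_pos)
    expect_equal(tb$truth_annotation$uorfs$utype, orc$utype)
    # sense-strand ATG count in leader + 30-nt CDS window equals the
    # planted count plus the main ATG
    window <- paste0(tb$context$leader_seq,
                     substr(tb$context$cds_seq, 1, 30))
    atg_count <- length(gregexpr("(?=ATG)", window, perl = TRUE)[[1]])
    expect_equal(atg_count, 5L + 1L)
  }
})

test_that("planting is reproducible per seed", {
  a <- plant_ck_leader(seed = 11)
  b <- plant_ck_leader(seed = 11)
  expect_identical(a$context$transcript_seq, b$context$transcript_seq)
  c <- plant_ck_leader(seed = 12)
  expect_false(identical(a$context$leader_seq, c$context$leader_seq))
})

test_that("edit patterns satisfy their profiles", {
  tb <- plant_ck_leader(seed = 5)
  expect_equal(nrow(simulate_edit_pattern(tb, "disrupt_k_uatg", k = 0)),
               0L)
  ed <- simulate_edit_pattern(tb, "preserve_all_uatg", seed = 6)
  out <- predict_edit_outcome(tb$context, ed)
  expect_length(out$delta$uatgs_destroyed, 0)
  expect_length(out$delta$uatgs_created, 0)
  expect_equal(out$allele$net_length_change, -25L)

  ed2 <- simulate_edit_pattern(tb, "lesion_sizes",
                               lesions = data.frame(kind = "DEL",
                                                    len = c(5, 7)),
                               seed = 7)
  expect_equal(sum(ed2$del_len), 12L)
  # identical seeds give identical edit sets
  expect_identical(simulate_edit_pattern(tb, "disrupt_k_uatg", k = 2,
                                         seed = 8),
                   simulate_edit_pattern(tb, "disrupt_k_uatg", k = 2,
                                         seed = 8))
})

test_that("clone simulation respects error rate and mixing", {
  ref <- "ACGTACGTACGTACGTACGTACGAACCGGT"
  cl <- simulate_clones(c(a = ref), n_clones = 5, error_rate = 0,
                        seed = 1)
  expect_true(all(cl$seq == ref))
  expect_error(simulate_clones(c(a = ref), error_rate = 0.5), "0.02")

  mut <- paste0(substr(ref, 1, 10), substr(ref, 15, 30))
  cl2 <- simulate_clones(c(WT = ref, mut = mut), c(0.5, 0.5),
                         n_clones = 8, error_rate = 0, seed = 2)
  sets <- lapply(cl2$seq, function(q)
    call_variants(align_pair(ref, q)))
  expect_equal(classify_zygosity(sets)$category, "HETEROZYGOUS")
})

test_that("expression tables carry the planted effects", {
  tabs <- simulate_expression_tables(c(G1 = 2), ct_sd = 0,
                                     analyte_cv = 0, seed = 3)
  res <- ddct(tabs$ct, calibrator = "CK")
  expect_equal(res$rq[res$gene == "G1" & res$condition == "edited"], 2)

  s <- tanshinone_summary(tabs$metabolites, "CK")
  expect_equal(s$tta[s$line_id == "CK"], 2.85)
  expect_equal(s$fold_vs_ck[match(c("Del1", "Del2", "Del3", "Del4"),
                                  s$line_id)],
               c(1.19, 1.79, 1.81, 1.00))
})
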