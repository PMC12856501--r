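test_that("find_start_codons matches direct inspection and rejects bad input", {
  expect_equal(find_start_codons("ATGAATG", 7), c(1L, 5L))
  expect_equal(find_start_codons("CCCCCC", 6), integer(0))
  # codon must lie fully inside the sequence even past region_end
  expect_equal(find_start_codons("CCATG", 5), 3L)
  expect_equal(find_start_codons("CCCCAT", 6), integer(0))
  # N never matches
  expect_equal(find_start_codons("ATNATG", 6), 4L)
  expect_error(find_start_codons("ACGXACGT", 8), "position 4")
})

test_that("find_start_codons equals exhaustive substring comparison", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_dna(1000)
    expected <- which(vapply(1:998, function(p)
      substr(s, p, p + 2) == "ATG", logical(1)))
    expect_equal(find_start_codons(s, 1000), as.integer(expected))
  }
})

test_that("scan_uorf classifies the three positional types", {
  # stop entirely upstream of the main ATG: non-overlapping (Type 1)
  ctx <- leader_context("t", "ATGTAACC", "ATGGGGTGA")
  u <- scan_uorf(ctx, 1)
  expect_equal(u$utype, "TYPE1")
  expect_equal(c(u$stop_start, u$stop_end), c(4L, 6L))
  expect_equal(u$length_nt, 6L)

  # out-of-frame uATG terminating inside the main ORF (Type 2)
  ctx2 <- leader_context("t", "AATGCC", "ATGCTAACCTAA")
  u2 <- scan_uorf(ctx2, 2)
  expect_equal(u2$utype, "TYPE2")
  expect_equal(c(u2$stop_start, u2$stop_end), c(11L, 13L))
  expect_equal(u2$length_nt, 12L)
  expect_false(u2$in_frame_with_morf)

  # in-frame uATG with no upstream stop: N-terminal extension (Type 3)
  ctx3 <- leader_context("t", "ATGAAA", "ATGTGA")
  u3 <- scan_uorf(ctx3, 1)
  expect_equal(u3$utype, "TYPE3")
  expect_equal(c(u3$stop_start, u3$stop_end), c(10L, 12L))
  expect_equal(u3$length_nt, 12L)
  expect_true(u3$in_frame_with_morf)
  # Type 3 shares the main ORF's stop
  expect_equal(u3$stop_end, ctx3$matg_pos + nchar(ctx3$cds_seq) - 1L)

  expect_error(scan_uorf(ctx, ctx$matg_pos), "upstream")
})

test_that("annotate_leader counts and filters correctly", {
  empty <- annotate_leader(leader_context("t", "CCCCCC", "ATGTAA"))
  expect_equal(nrow(empty$uorfs), 0L)
  expect_equal(sum(empty$counts_by_type), 0L)
  expect_equal(empty$total_complete, 0L)

  ann <- annotate_leader(leader_context("t", "ATGTAACC", "ATGGGGTGA"))
  expect_equal(unname(ann$counts_by_type[c("TYPE1", "TYPE2", "TYPE3")]),
               c(1L, 0L, 0L))
  expect_equal(ann$total_complete, 1L)

  # a 6-nt uORF survives the default threshold but not min_length_nt = 9
  strict <- annotate_leader(leader_context("t", "ATGTAACC", "ATGGGGTGA"),
                            scan_config(min_length_nt = 9))
  expect_equal(strict$total_complete, 0L)
})

test_that("a uATG at the very end of the leader reads into the CDS", {
  # uATG occupies the last three leader bases; its ORF continues through
  # the main ORF in frame and shares the terminal stop (Type 3)
  ctx <- leader_context("t", "CCCATG", "ATGTAA")
  ann <- annotate_leader(ctx)
  expect_equal(ann$uorfs$uatg_pos, 4L)
  expect_equal(ann$uorfs$utype, "TYPE3")
  expect_equal(ann$uorfs$length_nt, 9L)
})

test_that("annotation equals the brute-force oracle on random transcripts", {
  set.seed(21)
  for (rep in 1:25) {
    ctx <- random_leader_context(max_leader = 400)
    ann <- annotate_leader(ctx)
    orc <- oracle_annotate(ctx)
    expect_equal(ann$uorfs$uatg_pos, orc$uatg_pos)
    expect_equal(ann$uorfs$utype, orc$utype)
    expect_equal(ann$uorfs$length_nt, orc$length_nt)
    # type partition and length divisibility
    complete <- ann$uorfs[ann$uorfs$utype != "INCOMPLETE", ]
    expect_true(all(complete$length_nt %% 3 == 0))
    expect_true(all(complete$utype[complete$utype == "TYPE3"] ==
                      "TYPE3" &
                    ann$uorfs$in_frame_with_morf[ann$uorfs$utype ==
                                                   "TYPE3"]))
    expect_true(all(ann$uorfs$stop_end[ann$uorfs$utype == "TYPE1"] <
                      ctx$matg_pos))
    expect_equal(ann$total_complete, nrow(complete))
  }
})

test_that("annotation is deterministic", {
  ctx <- leader_context("t", "ATGAAATGATAGCCATGCC", "ATGCACTGTTAA")
  a1 <- annotate_leader(ctx)
  a2 <- annotate_leader(ctx)
  expect_identical(a1, a2)
})

test_that("incomplete uORFs are reported only on request", {
  # out-of-frame uATG, no stop anywhere downstream in its frame
  ctx <- leader_context("t", "CATGCC", "ATGCACCACTAA")
  # frame of uATG at 2: walk 5,8,11,14 -> CCA TGC ACC ACT (+ end)
  default <- annotate_leader(ctx)
  expect_equal(default$counts_by_type[["INCOMPLETE"]], 0L)
  with_inc <- annotate_leader(ctx, scan_config(include_incomplete = TRUE))
  expect_equal(with_inc$counts_by_type[["INCOMPLETE"]], 1L)
  expect_true(is.na(with_inc$uorfs$stop_start[1]))
})
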