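test_that("protospacer enumeration matches the exhaustive oracle", {
  set.seed(71)
  for (rep in 1:10) {
    s <- random_dna(500)
    got <- enumerate_protospacers(s)
    want <- oracle_protospacers(s)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$protospacer, want$protospacer)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})

test_that("sequences without a PAM-compatible dinucleotide yield nothing", {
  s <- paste(rep("AT", 11), collapse = "")  # 22 nt, no GG or CC
  expect_equal(nrow(enumerate_protospacers(s)), 0L)
  expect_equal(nrow(enumerate_protospacers("ACGT")), 0L)
})

test_that("every reported candidate re-validates at its coordinates", {
  set.seed(72)
  s <- random_dna(300)
  cand <- enumerate_protospacers(s)
  for (i in seq_len(nrow(cand))) {
    win <- substr(s, cand$start[i], cand$end[i])
    if (cand$strand[i] == "+") {
      expect_equal(win, cand$protospacer[i])
      pam <- substr(s, cand$end[i] + 1, cand$end[i] + 3)
      expect_match(pam, "^.GG$")
    } else {
      expect_equal(revcomp(win), cand$protospacer[i])
      pam_plus <- substr(s, cand$start[i] - 3, cand$start[i] - 1)
      expect_match(pam_plus, "^CC.$")
    }
    expect_equal(nchar(cand$protospacer[i]), 20L)
  }
})

test_that("enumeration is symmetric under reverse complement", {
  set.seed(73)
  s <- random_dna(200)
  fwd <- enumerate_protospacers(s)
  rev <- enumerate_protospacers(revcomp(s))
  n <- nchar(s)
  # a plus candidate on the reverse complement mirrors a minus candidate
  mirrored_start <- sort(n - rev$end + 1)
  expect_equal(sort(fwd$start), mirrored_start)
  expect_equal(sort(fwd$protospacer), sort(rev$protospacer))
})

test_that("a planted protospacer with a PAM is recovered on the plus strand", {
  g1 <- "CCTAAACCCTGTTCCGCCAC"
  set.seed(74)
  s <- paste0(random_dna(40), g1, "TGG", random_dna(40))
  cand <- enumerate_protospacers(s)
  hit <- cand[cand$protospacer == g1 & cand$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 41L)
  expect_equal(hit$pam, "TGG")
  # cut site between protospacer bases 17 and 18
  expect_equal(hit$cut_pos, 41L + 17L)
})

test_that("guides are ranked by cut-to-uATG distance with fixed tie-breaks", {
  set.seed(75)
  for (rep in 1:10) {
    s <- random_dna(400)
    cand <- enumerate_protospacers(s)
    if (nrow(cand) == 0) next
    uatgs <- sort(sample(400, 3))
    ranked <- rank_guides(cand, uatgs, max_dist = 100,
                          gc_bounds = c(0, 1))
    if (nrow(ranked) == 0) next
    # oracle ordering on (dist, cut_pos, strand)
    d <- vapply(ranked$cut_pos, function(cp) min(abs(cp - uatgs)),
                numeric(1))
    expect_equal(ranked$dist_to_nearest_uatg, as.integer(d))
    key <- order(d, ranked$cut_pos, match(ranked$strand, c("+", "-")))
    expect_equal(key, seq_len(nrow(ranked)))
    expect_true(all(d <= 100))
  }
})

test_that("rank_guides filters by GC content and distance", {
  s <- paste0("AAAAAAA", "CCTAAACCCTGTTCCGCCAC", "TGGAAAA")
  cand <- enumerate_protospacers(s)
  expect_gt(nrow(cand), 0)
  none <- rank_guides(cand, uatg_positions = 1, max_dist = 2)
  expect_equal(nrow(none), 0L)
  gc_blocked <- rank_guides(cand, uatg_positions = 25, max_dist = 1000,
                            gc_bounds = c(0.9, 1.0))
  expect_equal(nrow(gc_blocked), 0L)
})

test_that("locate_guide finds exact hits and flags PAM adjacency", {
  g2 <- "TGGCAGTCAAATGAAAAATG"
  set.seed(76)
  expect_equal(nrow(locate_guide(random_dna(100), g2)), 0L)

  ref <- paste0("ACGTACGTAC", g2, "AGG", "TTTT")
  hit <- locate_guide(ref, g2)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$start, 11L)
  expect_true(hit$pam_ok)

  # reverse-complement placement: protospacer on the minus strand with
  # its PAM 3' on that strand (CC just 5' on the plus strand)
  ref2 <- paste0("AAAA", "CCT", revcomp(g2), "GGGG")
  hit2 <- locate_guide(ref2, g2)
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$strand, "-")
  expect_true(hit2$pam_ok)

  ref3 <- paste0("AAAA", "TAT", revcomp(g2), "GGGG")
  hit3 <- locate_guide(ref3, g2)
  expect_false(hit3$pam_ok)
})
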