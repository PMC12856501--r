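make_ct <- function(target_shift = 0, n_bio = 3, n_tech = 2, noise = 0,
                    seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cond in c("CK", "mut")) {
    for (b in seq_len(n_bio)) {
      sid <- paste0(cond, b)
      for (tech in seq_len(n_tech)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, gene = "ACT", role = "reference",
          condition = cond, replicate = tech,
          ct = 20 + rnorm(1, 0, noise))
        shift <- if (cond == "mut") target_shift else 0
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, gene = "GOI", role = "target",
          condition = cond, replicate = tech,
          ct = 25 + shift + rnorm(1, 0, noise))
      }
    }
  }
  do.call(rbind, rows)
}

test_that("relative quantity follows the ddCt identities", {
  # identical Ct everywhere: rq exactly 1
  res <- ddct(make_ct(0), calibrator = "CK")
  expect_equal(res$rq, c(1, 1))
  expect_equal(res$delta_delta_ct, c(0, 0))

  # target one cycle earlier in treatment: ddCt -1, rq 2
  res2 <- ddct(make_ct(-1), calibrator = "CK")
  mut <- res2[res2$condition == "mut", ]
  expect_equal(mut$delta_delta_ct, -1)
  expect_equal(mut$rq, 2)

  # calibrator rq is 1 by construction and rq is monotone in ddCt
  for (shift in c(-2, -0.5, 0.5, 2)) {
    r <- ddct(make_ct(shift), calibrator = "CK")
    expect_equal(r$rq[r$condition == "CK"], 1)
    expect_equal(r$rq[r$condition == "mut"], 2^-shift)
  }
})

test_that("technical replicates are averaged before differencing", {
  tab <- make_ct(0, n_bio = 2, n_tech = 1)
  # perturb one technical pair so only its mean matters
  extra <- tab[tab$sample_id == "mut1" & tab$role == "target", ]
  extra$replicate <- 2
  extra$ct <- extra$ct - 2
  tab2 <- rbind(tab, extra)
  tab2$ct[tab2$sample_id == "mut1" & tab2$role == "target" &
            tab2$replicate == 1] <-
    tab2$ct[tab2$sample_id == "mut1" & tab2$role == "target" &
              tab2$replicate == 1] + 2
  res <- ddct(tab2, calibrator = "CK")
  expect_equal(res$rq[res$condition == "mut"], 1)
})

test_that("missing design cells are reported by name", {
  tab <- make_ct(0)
  expect_error(ddct(tab[tab$condition != "mut" | tab$role != "target", ],
                    calibrator = "CK"), "missing cell.*mut")
  expect_error(ddct(tab, calibrator = "nope"), "calibrator")
  expect_warning(ddct(transform(tab, ct = ct + 30), calibrator = "CK"),
                 "range")
})

test_that("planted folds are recovered from noisy Ct tables", {
  for (f in c(0.5, 1, 2, 4)) {
    rqs <- vapply(1:30, function(s) {
      tab <- make_ct(-log2(f), n_bio = 3, n_tech = 3, noise = 0.1,
                     seed = 1000 + s)
      r <- ddct(tab, calibrator = "CK")
      r$rq[r$condition == "mut"]
    }, numeric(1))
    expect_lt(abs(mean(rqs) - f) / f, 0.1)
  }
})

test_that("translational efficiency is an activity/mRNA double ratio", {
  expect_equal(translational_efficiency(1.5, 1.5, 1.5, 1.5), 1)
  # mutated-uATG construct vs wild type with unchanged mRNA ratios
  expect_equal(translational_efficiency(2.214, 1.035, 1, 1),
               2.214 / 1.035)
  # transcriptional changes cancel
  expect_equal(translational_efficiency(4, 2, 4, 2), 1)
  expect_error(translational_efficiency(-1, 1, 1, 1), "positive")
})

test_that("total tanshinone accumulation is exactly additive", {
  tab <- expand.grid(line_id = c("CK", "L1"),
                     analyte = c("TanI", "TanIIA", "CPT", "DHT"),
                     stringsAsFactors = FALSE)
  tab$mg_per_g_dw <- 1
  s <- tanshinone_summary(tab, "CK")
  expect_equal(s$tta, c(4, 4))
  expect_equal(s$fold_vs_ck, c(1, 1))
})

test_that("TTA folds reproduce the printed values", {
  tta <- c(CK = 2.85, Del2 = 5.11, Del3 = 5.15, Del1 = 3.39)
  tab <- do.call(rbind, lapply(names(tta), function(l)
    data.frame(line_id = l, analyte = c("TanI", "TanIIA", "CPT", "DHT"),
               mg_per_g_dw = tta[[l]] / 4)))
  s <- tanshinone_summary(tab, "CK")
  expect_equal(s$fold_vs_ck[match(c("Del2", "Del3", "Del1"), s$line_id)],
               c(1.79, 1.81, 1.19))
  expect_equal(s$fold_vs_ck[s$line_id == "CK"], 1)
})

test_that("missing analytes raise a named error", {
  tab <- data.frame(line_id = "CK", analyte = c("TanI", "TanIIA", "CPT"),
                    mg_per_g_dw = 1)
  expect_error(tanshinone_summary(tab, "CK"), "DHT")
  expect_error(tanshinone_summary(
    data.frame(line_id = "CK", analyte = "Tan9", mg_per_g_dw = 1), "CK"),
    "unknown analyte")
})

test_that("two-sample t test handles standard and degenerate cases", {
  x <- c(1, 2, 3)
  res <- two_sample_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  y <- c(101, 102, 103) + rnorm(3, 0, 1e-3)
  expect_lt(two_sample_t(x, y)$p_value, 0.001)

  # both samples constant
  expect_equal(two_sample_t(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(two_sample_t(c(1, 1), c(2, 2))$p_value, 0)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")

  # with equal n and equal sample variances Student and Welch coincide
  set.seed(101)
  a <- rnorm(6); b <- a + 0.5
  st <- two_sample_t(a, b, equal_variance = TRUE)
  we <- two_sample_t(a, b, equal_variance = FALSE)
  expect_equal(st$t, we$t, tolerance = 1e-9)
  expect_equal(st$df, we$df, tolerance = 1e-9)
  expect_equal(st$p_value, we$p_value, tolerance = 1e-7)
})

test_that("half-up rounding matches reported display precision", {
  expect_equal(round_half_up(32.255, 2), 32.26)
  expect_equal(round_half_up(43.335, 2), 43.34)
  expect_equal(round_half_up(1.785, 2), 1.79)
  expect_equal(round_half_up(-1.785, 2), -1.79)
  expect_equal(round_half_up(100 * 13 / 30, 2), 43.33)
})
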