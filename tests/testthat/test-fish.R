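test_that("proportion_se reproduces published percentage cells", {
  expect_equal(proportion_se(67, 259), list(pct = 25.9, se = 2.72))
  expect_equal(proportion_se(244, 293), list(pct = 83.3, se = 2.18))
  expect_equal(proportion_se(15, 173), list(pct = 8.7, se = 2.14))
  expect_equal(proportion_se(0, 100), list(pct = 0, se = 0))
  expect_error(proportion_se(1, 0), "n = 0")
  expect_error(proportion_se(5, 3), "k <= n")
})

test_that("every shipped timing-count percentage matches the recomputation", {
  cnt <- fxn_timing_counts()
  for (s in unique(cnt$sample)) {
    for (f in unique(cnt$fraction)) {
      tt <- timing_table_for(cnt, s, f)
      for (j in colnames(tt$counts)) {
        if (tt$totals[[j]] <= 10) {
          expect_true(all(is.na(tt$pct[, j])))
        } else {
          for (i in rownames(tt$counts)) {
            ps <- proportion_se(tt$counts[i, j], tt$totals[[j]])
            expect_equal(tt$pct[i, j], ps$pct)
            expect_equal(tt$se[i, j], ps$se)
          }
        }
      }
    }
  }
})

test_that("timing tables suppress percentages at small substage totals", {
  recs <- data.frame(
    pattern = c(rep("SS", 5), rep("DD", 3), rep("SD", 12)),
    substage = c(rep("late", 8), rep("mid", 12)),
    stringsAsFactors = FALSE
  )
  tt <- build_timing_table(recs)
  expect_equal(tt$counts["SS", "late"], 5L)
  expect_true(is.na(tt$pct["SS", "late"]))    # late total is 8 <= 10
  expect_equal(tt$pct["SD", "mid"], 100)      # mid total is 12 > 10
  expect_error(build_timing_table(data.frame(pattern = "XX",
                                             substage = "mid")),
               "unknown pattern")
  # tally equals a hand count
  expect_equal(unname(tt$totals), c(0L, 12L, 8L))
})

test_that("hybridization efficiency follows the scoring formula", {
  expect_equal(hybridization_efficiency(40, 30, 20, 4, 2, 100), 93)
  expect_equal(hybridization_efficiency(0, 0, 0, 0, 0, 50), 0)
  set.seed(8)
  for (i in 1:20) {
    k <- rmultinom(1, 200, rep(1 / 6, 6))[, 1]
    tot <- sum(k) + k[6]
    got <- hybridization_efficiency(k[1], k[2], k[3], k[4], k[5], tot)
    expect_equal(got, 100 * (k[1] + k[2] + k[3] + (k[4] + k[5]) / 2) / tot)
  }
  expect_error(hybridization_efficiency(1, 1, 1, 0, 0, 0), "total = 0")
  expect_error(hybridization_efficiency(10, 10, 10, 0, 0, 5), "at least")
})

test_that("chi-square comparison matches the 2x2 closed form", {
  m <- matrix(c(10, 90, 50, 50), nrow = 4)  # counts per pattern, one column
  a <- matrix(0L, 4, 3, dimnames = list(c("SS", "SD", "DD", "OTHER"),
                                        c("early", "mid", "late")))
  b <- a
  a[, "mid"] <- c(10, 90, 0, 0)
  b[, "mid"] <- c(50, 50, 0, 0)
  got <- compare_patterns(a, b, "mid", c("SS", "SD"))
  n <- 200
  chi2 <- (10 * 50 - 90 * 50)^2 * n / (100 * 100 * 60 * 140)
  expect_equal(got$chi2, chi2)
  expect_equal(got$df, 1)
  same <- compare_patterns(a, a, "mid", c("SS", "SD"))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  a0 <- a; a0[, "mid"] <- 0
  expect_error(compare_patterns(a0, a0, "mid", c("SS", "SD")), "degenerate")
})

test_that("simulated nuclei follow the two-independent-allele model", {
  subm <- matrix(c(0.9, 0.1, 0, 0.1, 0.8, 0.1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("S1", "S2"),
                                 c("early", "mid", "late")))
  # degenerate probabilities
  all_ss <- simulate_nuclei(timing_sim_params(
    c(S1 = 0, S2 = 0), subm, c(S1 = 200, S2 = 200),
    detection_failure_prob = 0, seed = 2))
  expect_true(all(all_ss$pattern == "SS"))
  all_dd <- simulate_nuclei(timing_sim_params(
    c(S1 = 1, S2 = 1), subm, c(S1 = 200, S2 = 200),
    detection_failure_prob = 0, seed = 2))
  expect_true(all(all_dd$pattern == "DD"))
  # p = 0.5: DD fraction converges to p^2 = 0.25
  half <- simulate_nuclei(timing_sim_params(
    c(S1 = 0.5, S2 = 0.5), subm, c(S1 = 5000, S2 = 5000),
    detection_failure_prob = 0, seed = 3))
  dd <- mean(half$pattern == "DD")
  ci <- binom.test(sum(half$pattern == "DD"), nrow(half),
                   conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.25 && 0.25 <= ci[2])
})

test_that("pattern frequencies converge to the binomial expectation scaled
           by detection", {
  p <- 0.3
  fail <- 0.1
  subm <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list("S2", c("early", "mid", "late")))
  recs <- simulate_nuclei(timing_sim_params(
    c(S2 = p), subm, c(S2 = 1e5), detection_failure_prob = fail, seed = 4))
  f <- table(factor(recs$pattern, c("SS", "SD", "DD", "OTHER"))) / nrow(recs)
  expected <- c((1 - p)^2, 2 * p * (1 - p), p^2) * (1 - fail)
  sds <- sqrt(expected * (1 - expected) / nrow(recs))
  expect_true(all(abs(f[1:3] - expected) < 3.3 * sds))
})

test_that("a timing shift of the published size is detected with high
           power at the study's sample sizes", {
  subm <- matrix(c(0.1, 0.85, 0.05), 1,
                 dimnames = list("S2", c("early", "mid", "late")))
  hits <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    ctrl <- simulate_nuclei(timing_sim_params(
      c(S2 = 0.55), subm, c(S2 = 500), detection_failure_prob = 0.06,
      seed = 100 + i))
    frda <- simulate_nuclei(timing_sim_params(
      c(S2 = 0.42), subm, c(S2 = 500), detection_failure_prob = 0.10,
      seed = 900 + i))
    p <- compare_patterns(build_timing_table(ctrl),
                          build_timing_table(frda), "mid")$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.8)
})
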