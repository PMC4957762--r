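test_that("the dilution series starts at 4.5e4 copies in 1:3 steps", {
  lv <- dilution_series()
  expect_length(lv, 6L)
  expect_equal(lv[1], 45000)
  expect_equal(lv, c(45000, 15000, 5000, 5000 / 3, 5000 / 9, 5000 / 27))
})

test_that("a perfect 1:3 series fits the analytic standard curve", {
  lv <- dilution_series()
  ct <- 35 - log2(10) * log10(lv)      # 100% efficiency line
  curve <- fit_standard_curve(rep(lv, 3), rep(ct, 3))
  expect_equal(curve$slope, -log2(10), tolerance = 1e-9)
  expect_equal(curve$efficiency_pct, 100, tolerance = 1e-6)
  # successive dilution steps are log2(3) cycles apart
  expect_equal(diff(ct), rep(log2(3), 5), tolerance = 1e-9)
  # quantify at the intercept returns 1 copy
  expect_equal(quantify(curve$intercept, curve, extrapolate_ct = Inf), 1)
  # noise-free recovery within 0.5 percent
  expect_true(all(abs(quantify(ct, curve) / lv - 1) < 0.005))
  expect_error(quantify(max(curve$ct_range) + 5, curve), "range")
  expect_error(fit_standard_curve(c(10, 100), c(20, 25)), "slope")
})

test_that("scheme A normalizes to the control-site average", {
  q <- c(F1 = 1, F2 = 4, C1 = 2, C2 = 2, C3 = 2)
  a <- enrich_scheme_a(q)
  expect_equal(unname(a[["F1"]]), 0.5)
  expect_equal(unname(a[["F2"]]), 2)
  # algebraic identity: normalized control values average exactly 1
  set.seed(6)
  for (i in 1:20) {
    q <- stats::setNames(runif(6, 0.1, 10),
                         c("F1", "F2", "F3", "C1", "C2", "C3"))
    a <- enrich_scheme_a(q)
    expect_equal(mean(a[c("C1", "C2", "C3")]), 1)
  }
  expect_error(enrich_scheme_a(c(F1 = 1, C1 = 0, C2 = 0, C3 = 0)), "zero")
})

test_that("scheme B equals 1 exactly at the origin threshold and is
           scale-invariant", {
  q <- c(F1 = 5, C1 = 9, LB2C1 = 0.5, LB2_origin = 7.5)
  fold <- lb2_enrichment_fold(q)
  expect_equal(fold, 15)
  b <- enrich_scheme_b(q, fold)
  expect_equal(unname(b[["LB2_origin"]]), 1)
  expect_equal(unname(b[["F1"]]), (5 / 0.5) / 15)
  # half-threshold ratio gives 0.5
  q2 <- c(F1 = 7.5 / 2 * 0.5, LB2C1 = 0.5)
  expect_equal(unname(enrich_scheme_b(q2, 7.5)[["F1"]]), 0.5)
  # multiplying all quantities leaves scheme B unchanged
  b2 <- enrich_scheme_b(q * 37.5, fold)
  expect_equal(b2, b)
  # fold outside the plausible quality-control range warns
  expect_warning(enrich_scheme_b(q, 300), "plausible range")
  expect_error(enrich_scheme_b(q, -1), "positive")
})

test_that("pooling returns group means and SEs with single-sample flags", {
  e1 <- c(F1 = 0.4, C1 = 1.2)
  e2 <- c(F1 = 0.6, C1 = 1.0)
  e3 <- c(F1 = 1.1, C1 = 1.3)
  pooled <- pool_enrichments(list(e1, e2, e3), c("ctrl", "ctrl", "frda"))
  f1 <- pooled[pooled$group == "ctrl" & pooled$primer_set == "F1", ]
  expect_equal(f1$mean, 0.5)
  expect_equal(f1$se, stats::sd(c(0.4, 0.6)) / sqrt(2))
  single <- pooled[pooled$group == "frda" & pooled$primer_set == "F1", ]
  expect_equal(single$se, 0)
  expect_false(single$se_defined)
  two_equal <- pool_enrichments(list(e1, e1), c("g", "g"))
  expect_equal(two_equal$se, c(0, 0))
})

test_that("plate simulation and quantification round-trip the true
           quantities", {
  tq <- c(F1 = 800, C1 = 5000, LB2C1 = 300, LB2_origin = 6000)
  plate <- simulate_sns_plate(tq, "line1", ct_sd = 0, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(plate, path, row.names = FALSE)
  q <- quantify_plate(read_plate_table(path))
  expect_equal(q[names(tq)], tq, tolerance = 1e-6, ignore_attr = TRUE)
  # with realistic Ct noise the recovery stays within a few percent
  plate2 <- simulate_sns_plate(tq, "line1", ct_sd = 0.25, seed = 12)
  q2 <- quantify_plate(plate2)
  expect_true(all(abs(q2[names(tq)] / tq - 1) < 0.15))
})

test_that("a small dormant-origin excess is invisible under scheme A but
           crosses the threshold after scheme-B pooling", {
  # true enrichment relative to the origin threshold: control sites above,
  # gene sites slightly below in control cells and 1.2x higher in mutants
  sim_line <- function(name, gene_level, seed) {
    fold <- 30
    base <- 500
    tq <- c(F1 = gene_level * fold * base, F2 = gene_level * fold * base,
            C1 = 1.5 * fold * base, C2 = 1.4 * fold * base,
            C3 = 1.6 * fold * base,
            LB2C1 = base, LB2_origin = fold * base)
    # lognormal noise, CV ~30% at the low-abundance gene sites and ~12%
    # at the control/reference sites (replicate-averaged)
    set.seed(seed)
    cv <- c(0.3, 0.3, 0.12, 0.12, 0.12, 0.12, 0.12)
    tq <- tq * exp(stats::rnorm(length(tq), 0, cv))
    plate <- simulate_sns_plate(tq, name, ct_sd = 0.2, seed = seed + 1)
    quantify_plate(plate)
  }
  # two control and two mutant lines, two isolation experiments each;
  # the contrast sits at the assay's detection limit by construction
  ctrl <- lapply(201:204, function(s) sim_line("ctrl", 0.85, s))
  frda <- lapply(301:304, function(s) sim_line("frda", 1.02, s))
  schemeA <- lapply(c(ctrl, frda), enrich_scheme_a)
  schemeB <- lapply(c(ctrl, frda), function(q) {
    enrich_scheme_b(q, lb2_enrichment_fold(q))
  })
  groups <- rep(c("control", "FRDA"), each = 4)
  pooledB <- pool_enrichments(schemeB, groups)
  f_ctrl <- pooledB$mean[pooledB$group == "control" &
                           pooledB$primer_set %in% c("F1", "F2")]
  f_frda <- pooledB$mean[pooledB$group == "FRDA" &
                           pooledB$primer_set %in% c("F1", "F2")]
  c_all <- pooledB$mean[pooledB$primer_set %in% c("C1", "C2", "C3")]
  # control sites reach the threshold in both groups; gene sites stay
  # below it in the control pool and reach it only in the mutant pool
  expect_true(all(c_all >= 1))
  expect_true(all(f_ctrl < 1))
  expect_gte(max(f_frda), 1)
  expect_gt(mean(f_frda), mean(f_ctrl))
  # scheme A flattens the same contrast: group means differ by far less
  # than the spread of the normalized values
  pooledA <- pool_enrichments(schemeA, groups)
  fa_c <- pooledA[pooledA$group == "control" & pooledA$primer_set == "F1", ]
  fa_f <- pooledA[pooledA$group == "FRDA" & pooledA$primer_set == "F1", ]
  expect_lt(abs(fa_f$mean - fa_c$mean), 2 * (fa_c$se + fa_f$se))
})
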