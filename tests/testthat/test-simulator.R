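test_that("simulation is deterministic given the seed and extends stably", {
  loc <- fxn_locus()
  p <- sim_params(loc, n_molecules = 15, seed = 9)
  a <- simulate_molecules(p)
  b <- simulate_molecules(p)
  expect_identical(a$molecules, b$molecules)
  expect_identical(a$truth$origins, b$truth$origins)
  # growing n_molecules leaves earlier molecules unchanged
  p2 <- sim_params(loc, n_molecules = 20, seed = 9)
  c <- simulate_molecules(p2)
  expect_identical(c$molecules[1:15], a$molecules)
})

test_that("a single always-firing origin gives symmetric deterministic
           kinematics", {
  loc <- fxn_locus()
  p <- sim_params(
    loc, n_molecules = 10,
    origin_sites = data.frame(pos_kb = 417, efficiency = 1),
    dormant_gene_origin_prob = 0, unidirectional_prob = 0,
    pause_rate_per_kb = 0, fork_rate_cv = 1e-6, arm_jitter_cv = 1e-6,
    firing_window_min = c(0, 1e-9), firing_sync_sd_min = 0,
    fragment_mean_kb = 800, fragment_sd_kb = 1e-6,
    probe_dropout_prob = 0, measurement_noise_sd_kb = 0, seed = 5
  )
  sim <- simulate_molecules(p)
  for (i in seq_along(sim$molecules)) {
    m <- sim$molecules[[i]]
    fr <- sim$truth$fragments[i, ]
    if (fr$frag_start_kb > 417 - 90 || fr$frag_end_kb < 417 + 90) next
    tr <- m$tracks
    p1 <- tr[tr$label == "P1", ]
    p2 <- tr[tr$label == "P2", ]
    # one central P1 of 2 * 30 * 1.4 = 84 kb flanked by two 42 kb P2 tracks
    expect_equal(nrow(p1), 1L)
    expect_equal(nrow(p2), 2L)
    expect_equal(p1$end - p1$start, 84, tolerance = 0.1)
    expect_equal(unname(p2$end - p2$start), c(42, 42), tolerance = 0.1)
  }
})

test_that("dormant origins require the expanded allele", {
  locN <- fxn_locus(expanded = FALSE)
  p <- sim_params(locN, n_molecules = 80, seed = 3)
  sim <- simulate_molecules(p)
  gi <- locN$gene_interval_kb
  o <- sim$truth$origins
  expect_false(any(o$origin_pos_kb >= gi[1] & o$origin_pos_kb <= gi[2]))
  # expanded allele with probability 0 also yields no gene origins
  locE <- fxn_locus(expanded = TRUE)
  sim0 <- simulate_molecules(sim_params(locE, n_molecules = 80,
                                        dormant_gene_origin_prob = 0,
                                        seed = 3))
  o0 <- sim0$truth$origins
  expect_false(any(o0$dormant))
})

test_that("label conservation bounds hold per fork arm", {
  loc <- fxn_locus()
  p <- sim_params(loc, n_molecules = 40, measurement_noise_sd_kb = 0,
                  seed = 17)
  sim <- simulate_molecules(p)
  a <- sim$truth$arms
  tot <- a$p1_len_kb + a$p2_len_kb
  bound <- a$rate_kb_min * 60 + 1e-6
  expect_true(all(tot <= bound))
  # arms that never paused, merged or ran off and fired before the pulses
  o <- sim$truth$origins
  key_a <- paste(a$molecule_id, signif(a$origin_pos_kb, 10))
  key_o <- paste(o$molecule_id, signif(o$origin_pos_kb, 10))
  t0 <- o$fire_time_min[match(key_a, key_o)]
  free <- !a$stalled & !a$hit_limit & a$n_pauses == 0 & t0 < 0
  expect_true(all(abs(tot[free] - a$rate_kb_min[free] * 60) < 1e-6))
})

test_that("increasing the pause rate cannot lengthen second-pulse tracks", {
  loc <- fxn_locus()
  mean_p2 <- function(pr) {
    sim <- simulate_molecules(sim_params(
      loc, n_molecules = 150, pause_rate_per_kb = pr,
      pause_duration_mean_min = 40, measurement_noise_sd_kb = 0, seed = 77
    ))
    a <- sim$truth$arms
    mean(a$p2_len_kb[!a$stalled])
  }
  lo <- mean_p2(0)
  hi <- mean_p2(0.01)
  expect_lt(hi, lo)
})

test_that("truth summaries are computed from ground truth", {
  loc <- fxn_locus(expanded = TRUE)
  sim <- simulate_molecules(sim_params(loc, n_molecules = 120, seed = 21))
  ts <- truth_summary(sim$truth)
  expect_equal(ts$n_molecules, 120L)
  expect_true(ts$replicating_fraction_pct > 0)
  expect_true(all(ts$iods_kb > 0))
  # hand-recompute one molecule's IODs from the origin table
  o <- sim$truth$origins[sim$truth$origins$kind_truth != "UNOBSERVABLE", ]
  counts <- table(o$molecule_id)
  id <- names(counts)[counts >= 3][1]
  skip_if(is.na(id))
  pos <- sort(o$origin_pos_kb[o$molecule_id == id])
  expect_true(all(diff(pos) %in% ts$iods_kb))
})

test_that("dormant-origin frequency in truth matches the configured
           probability", {
  loc <- fxn_locus(expanded = TRUE)
  sim <- simulate_molecules(sim_params(loc, n_molecules = 600,
                                       dormant_gene_origin_prob = 0.2,
                                       seed = 13))
  ts <- truth_summary(sim$truth)
  frags <- sim$truth$fragments
  n_cov <- sum(frags$covers_gene & frags$replicating)
  ci <- stats::binom.test(round(ts$dormant_freq * n_cov), n_cov,
                          p = 0.2)$conf.int
  expect_true(ci[1] <= 0.2 && 0.2 <= ci[2])
})
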