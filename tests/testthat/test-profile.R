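test_that("fork rate is P2 length over pulse time, averaged over arms", {
  ev <- classify1(tracks_df(c(61, 100, "P2"), c(100, 140, "P1"),
                            c(140, 179, "P2")))
  fr <- fork_rate(ev, pulse2_min = 30)
  expect_equal(unname(fr$arms), c(39, 39) / 30)
  expect_equal(fr$event, 1.3)
  ev2 <- classify1(tracks_df(c(52, 100, "P2"), c(100, 140, "P1"),
                             c(140, 188, "P2")))
  expect_equal(fork_rate(ev2)$event, 1.6)
})

test_that("inter-origin distances pair consecutive origins per molecule", {
  mk <- function(id, positions) {
    do.call(rbind, lapply(positions, function(p) {
      classify1(tracks_df(c(p - 30, p - 10, "P2"), c(p - 10, p + 10, "P1"),
                          c(p + 10, p + 30, "P2")))[1, ]
    })) -> ev
    ev$molecule_id <- id
    ev
  }
  ev <- rbind(mk("a", c(50, 150)), mk("b", c(110)))
  expect_equal(inter_origin_distances(ev), 100)
  ev2 <- mk("c", c(110, 140, 220) * 2)  # origins at 220, 280, 440
  d <- inter_origin_distances(ev2)
  # equals the brute-force consecutive-pairs oracle
  pos <- sort(ev2$origin_pos_kb)
  expect_equal(d, pos[-1] - pos[-3])
  expect_length(inter_origin_distances(mk("d", 300)), 0L)
})

test_that("contaminated intervals are not measured as IODs", {
  ev <- rbind(
    classify1(tracks_df(c(70, 100, "P2"), c(100, 140, "P1"),
                        c(140, 170, "P2"))),
    classify1(tracks_df(c(570, 600, "P2"), c(600, 640, "P1"),
                        c(640, 670, "P2")))
  )
  blocker <- ev[1, ]
  blocker$kind <- "AMBIGUOUS_EXCLUDED"
  blocker$origin_pos_kb <- NA_real_
  blocker$pos_kb <- 400
  expect_length(inter_origin_distances(rbind(ev, blocker)), 0L)
  expect_equal(inter_origin_distances(rbind(ev, blocker), strict = FALSE),
               500)
})

test_that("replicating fraction reproduces the published count ratios", {
  expect_equal(replicating_fraction(39, 61), 63.9)
  expect_equal(replicating_fraction(70, 124), 56.5)
  expect_equal(replicating_fraction(0, 10), 0.0)
  expect_error(replicating_fraction(0, 0), "undefined")
})

test_that("gene-origin ratios reproduce the published per-line values", {
  # ratio = central-probe bidirectional origins / molecules carrying them
  fake_events <- function(n_orig, n_mol, pos = 400) {
    data.frame(
      molecule_id = paste0("m", rep_len(seq_len(n_mol), n_orig)),
      kind = "BIDIRECTIONAL", origin_pos_kb = pos, stringsAsFactors = FALSE
    )
  }
  loc <- fxn_locus()
  g <- gene_origin_stats(fake_events(20, 18), loc)
  expect_equal(g$origins_per_origin_molecule, 1.11)
  expect_equal(gene_origin_stats(fake_events(17, 11), loc)$
                 origins_per_origin_molecule, 1.55)
  expect_equal(gene_origin_stats(fake_events(19, 14), loc)$
                 origins_per_origin_molecule, 1.36)
  g0 <- gene_origin_stats(fake_events(5, 5, pos = 10), loc)  # outside probe
  expect_equal(g0$origins_per_origin_molecule, 0)
  expect_true(g0$undefined)
})

test_that("repeat template calls follow fork direction and gene strand", {
  loc <- fxn_locus()  # repeat at 395, gene on + strand
  rightward <- classify1(tracks_df(c(330, 370, "P1"), c(370, 410, "P2"),
                                   c(500, 540, "P1"), c(540, 580, "P2")))
  r <- repeat_template_orientation(rightward, loc)
  # the first fork crosses 395 moving right (with transcription): lagging
  expect_equal(r$lagging, 1)
  expect_equal(r$leading, 0)
  leftward <- classify1(tracks_df(c(250, 290, "P2"), c(290, 330, "P1"),
                                  c(370, 410, "P2"), c(410, 450, "P1")))
  l <- repeat_template_orientation(leftward, loc)
  expect_equal(l$leading, 1)
  none <- repeat_template_orientation(rightward[0, ], loc)
  expect_equal(none$lagging + none$leading, 0)
})

test_that("unidirectional length statistics use the stated CV convention", {
  ev <- data.frame(
    molecule_id = c("a", "b", "c"), kind = "UNIDIRECTIONAL",
    length_kb = c(50, 100, 150), span_start_kb = c(200, 300, 400),
    span_end_kb = c(250, 400, 550), stringsAsFactors = FALSE
  )
  s <- unidirectional_length_stats(ev)
  expect_equal(s$mean, 100)
  expect_equal(s$cv_pct, 40.8, tolerance = 0.05)
  one <- unidirectional_length_stats(ev[1, ])
  expect_equal(one$cv_pct, 0)
  # central filter keeps only tracks inside the probe-to-probe window
  loc <- fxn_locus()   # central window [175, 620]
  ev$span_start_kb <- c(100, 300, 400)
  cen <- unidirectional_length_stats(ev, loc, "central")
  expect_equal(cen$n, 2L)
  expect_equal(sort(cen$lengths), c(100, 150))
})

test_that("profile summaries are internally consistent", {
  loc <- fxn_locus(expanded = TRUE)
  sim <- simulate_molecules(sim_params(loc, n_molecules = 80, seed = 37))
  res <- classify_molecules(sim$molecules, loc)
  pr <- summarize_profile("sim", res$molecules, res$events, loc)
  expect_s3_class(pr, "replication_profile")
  expect_equal(sum(pr$fork_counts), pr$total_forks)
  expect_equal(unname(pr$fork_counts[["UNIDIRECTIONAL"]]),
               sum(res$events$kind == "UNIDIRECTIONAL"))
  expect_lte(pr$replicating_molecules, pr$total_molecules)
  expect_equal(pr$replicating_fraction_pct,
               round(100 * pr$replicating_molecules / pr$total_molecules, 1))
  expect_output(print(pr), "Replication profile")
})

test_that("Kruskal-Wallis comparison matches a hand-ranked oracle", {
  x <- c(1, 2, 3)
  y <- c(10, 20, 30)
  got <- compare_profiles(list(a = x, b = y))
  # hand ranking: ranks 1:6, group sums 6 and 15; H = 12/(n(n+1)) * sum(R^2/n_i) - 3(n+1)
  H <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(got$H, H)
  expect_equal(got$df, 1)
  same <- compare_profiles(list(a = x, b = x))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_error(compare_profiles(list(a = x, b = numeric(0))), "empty")
  expect_error(compare_profiles(list(a = x)), "two samples")
})

test_that("equal-rate samples rarely reach significance", {
  set.seed(11)
  hits <- 0L
  for (i in 1:60) {
    vals <- lapply(1:4, function(j) rlnorm(25, log(1.4), 0.35))
    names(vals) <- paste0("s", 1:4)
    if (compare_profiles(vals)$p < 0.05) hits <- hits + 1L
  }
  expect_lte(hits / 60, 0.15)
})
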