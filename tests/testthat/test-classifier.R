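test_that("a P1 track flanked by two P2 tracks is a bidirectional origin at
           the P1 midpoint", {
  ev <- classify1(tracks_df(c(80, 100, "P2"), c(100, 140, "P1"),
                            c(140, 160, "P2")))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "BIDIRECTIONAL")
  expect_equal(ev$origin_pos_kb, 120)
  expect_equal(ev$rate_kb_min, (20 + 20) / 2 / 30)
})

test_that("facing P1 ends across an unlabeled center pair into one origin", {
  ev <- classify1(tracks_df(c(60, 100, "P2"), c(100, 140, "P1"),
                            c(160, 200, "P1"), c(200, 240, "P2")))
  expect_equal(ev$kind, "BIDIRECTIONAL")
  expect_equal(ev$origin_pos_kb, 150)
  expect_equal(ev$rate_kb_min, 40 / 30)
  # P1-based arm rates are exact for a paired origin
  expect_equal(ev$left_p1_rate, 40 / 30)
  expect_true(ev$left_p1_exact)
})

test_that("an arm missing its distal P2 across the center is a unilateral
           pause at the truncated P1 end", {
  ev <- classify1(tracks_df(c(60, 100, "P2"), c(100, 140, "P1"),
                            c(160, 200, "P1")))
  expect_equal(ev$kind, "PAUSED_UNILATERAL")
  expect_equal(ev$origin_pos_kb, 150)
  expect_equal(ev$pause_pos_kb, 200)
})

test_that("a single-arm structure without same-direction support reads as a
           unilateral pause (blue-only rule)", {
  # right neighbor shows active replication but travels the other way
  ev <- classify1(tracks_df(c(80, 100, "P2"), c(100, 140, "P1"),
                            c(420, 440, "P1"), c(440, 460, "P2")))
  left <- ev[ev$pos_kb < 300, ]
  expect_equal(left$kind, "PAUSED_UNILATERAL")
  expect_equal(left$pause_pos_kb, 140)
})

test_that("a single-arm structure moving with an adjacent structure is a
           unidirectional fork", {
  # two structures both moving rightward; the second is a lone P1+P2
  ev <- classify1(tracks_df(c(100, 140, "P1"), c(140, 180, "P2"),
                            c(420, 450, "P1"), c(450, 480, "P2")))
  expect_equal(ev$kind, c("UNIDIRECTIONAL", "UNIDIRECTIONAL"))
  expect_equal(ev$direction, c("right", "right"))
  expect_equal(ev$length_kb, c(80, 60))
  expect_true(all(is.na(ev$origin_pos_kb)))
})

test_that("isolated tracks are excluded as ambiguous", {
  ev <- classify1(tracks_df(c(100, 140, "P1"), c(140, 180, "P2")),
                  keep_excluded = TRUE)
  expect_equal(ev$kind, "AMBIGUOUS_EXCLUDED")
  expect_equal(ev$exclusion_reason, "isolated")
  # red-only structures are never interpretable
  ev2 <- classify1(tracks_df(c(100, 140, "P2"), c(400, 440, "P2"),
                             c(440, 470, "P1"), c(470, 500, "P2")),
                   keep_excluded = TRUE)
  expect_true("red_only" %in% ev2$exclusion_reason)
})

test_that("empty molecules produce no events", {
  ev <- classify1(empty_tracks())
  expect_equal(nrow(ev), 0L)
})

test_that("a P2 shared by two converging forks marks a termination", {
  ev <- classify1(tracks_df(c(60, 100, "P2"), c(100, 140, "P1"),
                            c(140, 180, "P2"), c(180, 220, "P1"),
                            c(220, 260, "P2")),
                  keep_excluded = TRUE)
  expect_equal(sum(ev$kind == "TERMINATION"), 1L)
  bid <- ev[ev$kind == "BIDIRECTIONAL", ]
  expect_equal(bid$origin_pos_kb, c(120, 200))
  # shared arms carry no rate
  expect_true(all(is.na(bid$rate_kb_min)))
})

test_that("a blue bridge between facing P1 ends is a termination and its
           halves anchor the flanking origins", {
  ev <- classify1(tracks_df(
    c(40, 80, "P2"), c(80, 120, "P1"),        # left origin's outer arm
    c(160, 240, "P1"),                        # pulse-1 merge bridge
    c(280, 320, "P1"), c(320, 360, "P2")      # right origin's outer arm
  ), keep_excluded = TRUE)
  expect_equal(sum(ev$kind == "TERMINATION"), 1L)
  expect_equal(ev$pos_kb[ev$kind == "TERMINATION"], 200)
  org <- ev[ev$kind == "PAUSED_UNILATERAL", ]
  expect_equal(org$origin_pos_kb, c(140, 260))
})

test_that("grossly asynchronous sister arms are called asynchronous", {
  ev <- classify1(tracks_df(c(31, 100, "P2"), c(100, 140, "P1"),
                            c(140, 160, "P2")))
  expect_equal(ev$kind, "ASYNCHRONOUS")
  expect_true(is.na(ev$rate_kb_min))
  # fork_rate() refuses asynchronous events
  expect_error(fork_rate(ev), "bidirectional")
})

test_that("events outside the probe-framed span are excluded", {
  loc <- fxn_locus()
  # molecule shows only probes 1 and 2; an origin beyond probe 2's end
  ev <- classify1(tracks_df(c(80, 100, "P2"), c(100, 140, "P1"),
                            c(140, 160, "P2"),
                            c(540, 560, "P2"), c(560, 600, "P1"),
                            c(600, 620, "P2")),
                  keep_excluded = TRUE, probes = 1:2)
  out <- ev[ev$pos_kb > 500, ]
  expect_equal(out$kind, "AMBIGUOUS_EXCLUDED")
  expect_equal(out$exclusion_reason, "not_framed")
  expect_equal(ev$kind[ev$pos_kb < 500], "BIDIRECTIONAL")
})

test_that("classification requires an oriented molecule", {
  m <- molecule("m", tracks_df(c(10, 20, "P1")), units = "kb")
  expect_error(classify_molecule(m, fxn_locus()), "oriented")
})

test_that("every labeled track is assigned to an event or an exclusion", {
  loc <- fxn_locus(expanded = TRUE)
  sim <- simulate_molecules(sim_params(loc, n_molecules = 60, seed = 19))
  res <- classify_molecules(sim$molecules, loc)
  for (m in res$molecules) {
    ev <- res$events[res$events$molecule_id == m$molecule_id, ]
    if (nrow(m$tracks) == 0L) next
    tr_lo <- to_region(m, min(m$tracks$start))
    tr_hi <- to_region(m, max(m$tracks$end))
    expect_gt(nrow(ev), 0L)
    # event spans jointly cover the track extent
    expect_lte(min(ev$span_start_kb, na.rm = TRUE), tr_lo + 1e-6)
    expect_gte(max(ev$span_end_kb, na.rm = TRUE), tr_hi - 1e-6)
  }
})

test_that("classification is invariant under coordinate reversal", {
  loc <- fxn_locus()
  sim <- simulate_molecules(sim_params(
    loc, n_molecules = 25, probe_dropout_prob = 0,
    measurement_noise_sd_kb = 0, seed = 23
  ))
  res <- classify_molecules(sim$molecules, loc)
  flipped <- lapply(sim$molecules, reverse_molecule)
  res2 <- classify_molecules(flipped, loc)
  for (m in res$molecules) {
    a <- res$events[res$events$molecule_id == m$molecule_id, ]
    b <- res2$events[res2$events$molecule_id == m$molecule_id, ]
    a <- a[order(a$kind, round(a$pos_kb, 3)), ]
    b <- b[order(b$kind, round(b$pos_kb, 3)), ]
    expect_equal(a$kind, b$kind)
    expect_equal(a$pos_kb, b$pos_kb, tolerance = 1e-6)
  }
})

test_that("noise-free bidirectional origins are mapped within 2 kb under
           synchronous kinematics", {
  loc <- fxn_locus()
  sim <- simulate_molecules(sim_params(
    loc, n_molecules = 300, measurement_noise_sd_kb = 0,
    probe_dropout_prob = 0, arm_jitter_cv = 1e-6, pause_rate_per_kb = 0,
    unidirectional_prob = 0, seed = 29
  ))
  res <- classify_molecules(sim$molecules, loc)
  mm <- match_events_to_truth(res$events, sim$truth, tol_kb = 2)
  tab <- mm$table[mm$table$kind_truth == "BIDIRECTIONAL" &
                    !is.na(mm$table$kind_classified), ]
  expect_gt(nrow(tab), 20)
  expect_true(all(abs(tab$pos_error_kb) <= 2, na.rm = TRUE))
})
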