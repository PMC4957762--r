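test_that("pixel-to-kb conversion follows the combing calibration", {
  cal <- calibration(2, 0.16125)
  expect_equal(px_to_kb(1, cal), 0.3225)
  expect_equal(px_to_kb(0, cal), 0)
  expect_equal(px_to_kb(100, cal), 32.25)
  expect_equal(cal$pixel_kb, 0.3225)
  expect_error(px_to_kb(-1, cal), "non-negative")
  expect_error(calibration(-2, 0.16125), "positive")
})

test_that("pixel conversion is linear", {
  cal <- calibration()
  set.seed(1)
  a <- runif(50, 0, 5000)
  b <- runif(50, 0, 5000)
  expect_true(all(abs(px_to_kb(a + b, cal) -
                        (px_to_kb(a, cal) + px_to_kb(b, cal))) < 1e-9))
  expect_equal(um_to_kb(1, cal), 2)
})

test_that("locus map enforces probe layout invariants", {
  loc <- fxn_locus()
  expect_s3_class(loc, "locus_map")
  expect_equal(nrow(loc$probes), 3L)
  expect_equal(loc$central_probe, "RP11-265B8")
  gaps <- loc$probes$start_kb[-1] - loc$probes$end_kb[-3]
  expect_true(abs(gaps[1] - gaps[2]) > 0.10 * max(gaps))
  # overlapping probes rejected
  expect_error(locus_map(
    "x", "chr1", 0L, 1000000L,
    rbind(probe_spec("a", 0, 200), probe_spec("b", 100, 400)),
    gene_interval_kb = c(120, 150), repeat_pos_kb = 130
  ), "non-overlapping")
  # repeat must sit inside the gene interval
  expect_error(locus_map(
    "x", "chr1", 0L, 1000000L,
    rbind(probe_spec("a", 0, 200), probe_spec("b", 300, 500)),
    gene_interval_kb = c(320, 400), repeat_pos_kb = 500
  ), "repeat_pos_kb")
})

test_that("locus map round-trips through YAML", {
  loc <- fxn_locus(expanded = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_locus_yaml(loc, path)
  loc2 <- read_locus_yaml(path)
  expect_equal(loc2$probes, loc$probes)
  expect_equal(loc2$gene_interval_kb, loc$gene_interval_kb)
  expect_equal(loc2$repeat_pos_kb, loc$repeat_pos_kb)
  expect_true(loc2$expanded)
})

test_that("molecule validation rejects malformed tracks", {
  expect_error(molecule("m", tracks_df(c(10, 5, "P1"))), "start >= end")
  expect_error(molecule("m", data.frame(start = 1, end = 2, label = "XX")),
               "unknown track label")
  expect_error(
    molecule("m", tracks_df(c(0, 10, "P1"), c(5, 15, "P1"))),
    "overlapping"
  )
  # overlapping tracks of different labels are allowed
  expect_s3_class(molecule("m", tracks_df(c(0, 10, "P1"), c(5, 15, "P2"))),
                  "molecule")
})

test_that("track tables round-trip byte-identically in canonical form", {
  loc <- fxn_locus()
  sim <- simulate_molecules(sim_params(loc, n_molecules = 3, seed = 4))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_track_table(sim$molecules, p1, locus_name = loc$region_name)
  mols <- read_track_table(p1)
  expect_length(mols, 3L)
  expect_equal(attr(mols, "locus_name"), loc$region_name)
  write_track_table(mols, p2, locus_name = loc$region_name)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("track table reader validates records with location info", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("molecule_id", "record_type", "start", "end", "label",
                 "flag", "units"), collapse = "\t")
  # empty file with header -> empty set
  writeLines(c("# locus=test", hdr), path)
  expect_length(read_track_table(path), 0L)
  # malformed interval names the molecule and line
  writeLines(c(hdr, "molX\tTRACK\t10\t5\tP1\t0\tkb"), path)
  expect_error(read_track_table(path), "molX")
  # unknown label
  writeLines(c(hdr, "molX\tTRACK\t1\t5\tQ9\t0\tkb"), path)
  expect_error(read_track_table(path), "unknown track label")
  # mixed units within a molecule
  writeLines(c(hdr, "molX\tTRACK\t1\t5\tP1\t0\tkb",
               "molX\tTRACK\t6\t9\tP2\t0\tum"), path)
  expect_error(read_track_table(path), "mixed units")
  # overlapping same-label tracks rejected at parse time
  writeLines(c(hdr, "molY\tTRACK\t1\t5\tP1\t0\tkb",
               "molY\tTRACK\t4\t9\tP1\t0\tkb"), path)
  expect_error(read_track_table(path), "molY")
})

test_that("pixel-unit tables convert to kb at load time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# locus=test", "# stretch_kb_per_um=2", "# pixel_um=0.16125",
    paste(c("molecule_id", "record_type", "start", "end", "label",
            "flag", "units"), collapse = "\t"),
    "m1\tPROBE\t0\t100\t?\t1\tpx",
    "m1\tTRACK\t100\t200\tP1\t0\tpx"
  ), path)
  mols <- read_track_table(path)
  expect_equal(mols[[1]]$units, "kb")
  expect_equal(mols[[1]]$tracks$start, 32.25)
  expect_equal(mols[[1]]$probe_signals$end, 32.25)
  expect_true(mols[[1]]$probe_signals$flag)
})
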