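# Shared fixtures for the test suite. All molecules are built in region
# coordinates with a known anchor so expected event positions are explicit.

# A molecule pre-anchored at region coordinates (anchor 0), showing all
# three probes of the default locus plus the given tracks.
anchored_molecule <- function(id, tracks, locus = fxn_locus(),
                              probes = seq_len(nrow(locus$probes))) {
  pr <- locus$probes[probes, , drop = FALSE]
  m <- molecule(
    id,
    tracks = tracks,
    probe_signals = data.frame(start = pr$start_kb, end = pr$end_kb,
                               flag = pr$orientation_flag),
    units = "kb"
  )
  m$oriented <- TRUE
  m$anchor_offset_kb <- 0
  m
}

tracks_df <- function(...) {
  # tracks_df(c(80, 100, "P2"), c(100, 140, "P1"), ...)
  rows <- list(...)
  data.frame(
    start = vapply(rows, function(r) as.numeric(r[1]), numeric(1)),
    end = vapply(rows, function(r) as.numeric(r[2]), numeric(1)),
    label = vapply(rows, function(r) r[3], character(1)),
    stringsAsFactors = FALSE
  )
}

# classify a single anchored molecule and drop excluded rows by default
classify1 <- function(tracks, keep_excluded = FALSE, locus = fxn_locus(),
                      cfg = classifier_config(), ...) {
  m <- anchored_molecule("t1", tracks, locus = locus, ...)
  ev <- classify_molecule(m, locus, cfg)
  if (!keep_excluded) ev <- ev[ev$kind != "AMBIGUOUS_EXCLUDED", ]
  rownames(ev) <- NULL
  ev
}
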