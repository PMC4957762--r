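#' Classifier configuration
#'
#' @param gap_tol_kb Maximum unlabeled gap (kb) between tracks grouped into
#'   one contiguous labeled structure (~1.5 um of fiber).
#' @param async_ratio Sister-arm P2-length ratio above which a bidirectional
#'   event is called asynchronous. The threshold is a free parameter of the
#'   scheme (the field never quantifies "different rates").
#' @param max_pair_gap_kb Maximum unlabeled span between two facing P1 ends
#'   paired as the two arms of one origin that fired before the first pulse.
#' @param pair_p1_ratio_max Maximum ratio of the two facing P1 lengths for
#'   pairing: sister arms labeled over the same pulse have comparable P1
#'   extents, whereas unrelated facing structures usually do not.
#' @param min_track_kb Shortest track accepted (1 pixel equivalent).
#' @param tol_frac Probe-template matching tolerance for auto-orientation.
#' @param pulse1_min,pulse2_min Pulse durations used for rate computation.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(gap_tol_kb = 3,
                              async_ratio = 2.0,
                              max_pair_gap_kb = 250,
                              pair_p1_ratio_max = 2.5,
                              min_track_kb = 0.3225,
                              tol_frac = 0.10,
                              pulse1_min = 30,
                              pulse2_min = 30) {
  stopifnot(gap_tol_kb > 0, async_ratio > 1, max_pair_gap_kb > 0,
            pair_p1_ratio_max > 1, min_track_kb >= 0, pulse2_min > 0)
  structure(as.list(environment()), class = "classifier_config")
}

empty_events <- function() {
  data.frame(
    molecule_id = character(0), kind = character(0),
    origin_pos_kb = numeric(0), pos_kb = numeric(0),
    left_p1_kb = numeric(0), left_p2_kb = numeric(0),
    right_p1_kb = numeric(0), right_p2_kb = numeric(0),
    direction = character(0), rate_kb_min = numeric(0),
    left_arm_rate = numeric(0), right_arm_rate = numeric(0),
    left_arm_complete = logical(0), right_arm_complete = logical(0),
    left_p1_rate = numeric(0), right_p1_rate = numeric(0),
    left_p1_exact = logical(0), right_p1_exact = logical(0),
    pause_pos_kb = numeric(0), pause_pos2_kb = numeric(0),
    length_kb = numeric(0), span_start_kb = numeric(0),
    span_end_kb = numeric(0), exclusion_reason = character(0),
    stringsAsFactors = FALSE
  )
}

event_row <- function(molecule_id, kind, origin_pos_kb = NA_real_,
                      pos_kb = NA_real_, left_p1 = NA_real_,
                      left_p2 = NA_real_, right_p1 = NA_real_,
                      right_p2 = NA_real_, direction = NA_character_,
                      rate = NA_real_, arm_rates = c(NA_real_, NA_real_),
                      arm_complete = c(NA, NA),
                      p1_rates = c(NA_real_, NA_real_),
                      p1_exact = c(NA, NA),
                      pause = NA_real_, pause2 = NA_real_,
                      length_kb = NA_real_, span = c(NA_real_, NA_real_),
                      reason = NA_character_) {
  data.frame(
    molecule_id = molecule_id, kind = kind, origin_pos_kb = origin_pos_kb,
    pos_kb = pos_kb, left_p1_kb = left_p1, left_p2_kb = left_p2,
    right_p1_kb = right_p1, right_p2_kb = right_p2, direction = direction,
    rate_kb_min = rate, left_arm_rate = arm_rates[1],
    right_arm_rate = arm_rates[2],
    left_arm_complete = arm_complete[1], right_arm_complete = arm_complete[2],
    left_p1_rate = p1_rates[1], right_p1_rate = p1_rates[2],
    left_p1_exact = as.logical(p1_exact[1]),
    right_p1_exact = as.logical(p1_exact[2]),
    pause_pos_kb = pause,
    pause_pos2_kb = pause2, length_kb = length_kb,
    span_start_kb = span[1], span_end_kb = span[2],
    exclusion_reason = reason, stringsAsFactors = FALSE
  )
}

#' Classify the labeled tracks of one oriented molecule
#'
#' Implements the reading scheme for two-pulse labeled fibers. Tracks are
#' grouped into contiguous structures (gaps below `gap_tol_kb`), then:
#'
#' 1. a single P1 track flanked by P2 on both sides, or two facing
#'    P1 ends across an unlabeled center, is a bidirectional origin
#'    (mapped at the P1 midpoint, or at the midpoint between the facing
#'    inner P1 ends);
#' 2. an origin arm whose distal P2 is missing is a paused/arrested fork
#'    (unilateral, or bilateral — counted as a single event since it
#'    reflects one origin firing), with the pause mapped at the truncated
#'    P1 end;
#' 3. sister arms whose P2 lengths differ by more than `async_ratio`-fold
#'    are asynchronous;
#' 4. a lone P1+P2 structure supported by other replication signals on the
#'    same fiber is a unidirectional fork (its origin cannot be placed);
#' 5. a P2 track shared by two converging forks, or a blue-only track
#'    bridging two facing P1 ends, is a termination;
#' 6. anything else (isolated tracks, red-only structures, structures not
#'    framed by the probe signals) is excluded with a reason.
#'
#' @param m An oriented [molecule()] (see [orient_molecule()]).
#' @param locus A [locus_map()].
#' @param cfg A [classifier_config()].
#' @return A data frame of events (one row per event); excluded structures
#'   appear with `kind = "AMBIGUOUS_EXCLUDED"` and an `exclusion_reason`.
#' @export
classify_molecule <- function(m, locus, cfg = classifier_config()) {
  stopifnot(inherits(m, "molecule"), inherits(locus, "locus_map"),
            inherits(cfg, "classifier_config"))
  if (!isTRUE(m$oriented)) {
    stop(sprintf("molecule '%s' must be oriented before classification",
                 m$molecule_id), call. = FALSE)
  }
  id <- m$molecule_id
  tr <- m$tracks
  if (nrow(tr) == 0L) return(empty_events())
  tr$start <- to_region(m, tr$start)
  tr$end <- to_region(m, tr$end)
  tr <- tr[tr$end - tr$start >= cfg$min_track_kb, , drop = FALSE]
  if (nrow(tr) == 0L) return(empty_events())
  tr <- tr[order(tr$start), , drop = FALSE]

  framed <- c(-Inf, Inf)
  if (nrow(m$probe_signals) > 0L) {
    framed <- c(min(to_region(m, m$probe_signals$start)),
                max(to_region(m, m$probe_signals$end)))
  }
  # visible extent of the fiber (no counterstain: only signals are seen);
  # a P2 tip at the outermost signal may be cut, so such arms are not
  # considered complete for rate computation
  extent <- range(c(tr$start, tr$end, framed[is.finite(framed)]))

  ## group into structures; merge same-label neighbours within a structure
  gap_prev <- c(Inf, tr$start[-1L] - tr$end[-nrow(tr)])
  tr$struct <- cumsum(gap_prev > cfg$gap_tol_kb)
  structs <- lapply(split(tr, tr$struct), function(s) {
    out <- list()
    for (r in seq_len(nrow(s))) {
      n <- length(out)
      if (n > 0L && out[[n]]$label == s$label[r]) {
        out[[n]]$end <- max(out[[n]]$end, s$end[r])
      } else {
        out[[n + 1L]] <- s[r, c("start", "end", "label")]
      }
    }
    do.call(rbind, out)
  })
  ns <- length(structs)
  first_lab <- vapply(structs, function(s) s$label[1L], character(1))
  last_lab <- vapply(structs, function(s) s$label[nrow(s)], character(1))
  blue_only <- vapply(structs, function(s) all(s$label == "P1"), logical(1))

  events <- list()
  add_event <- function(e) events[[length(events) + 1L]] <<- e

  ## rule 5b: a blue-only track between two facing P1 ends is the fused P1
  ## of two forks that merged during pulse 1 (a termination); each half of
  ## the bridge is the inner arm of one of the two flanking origins, so the
  ## bridge can take part in a facing-P1 pairing on both of its sides
  bridge_like <- rep(FALSE, ns)
  for (k in seq_len(ns)) {
    if (blue_only[k] && k > 1L && k < ns &&
        last_lab[k - 1L] == "P1" && first_lab[k + 1L] == "P1") {
      s <- structs[[k]]
      add_event(event_row(id, "TERMINATION",
                          pos_kb = (s$start[1L] + s$end[nrow(s)]) / 2,
                          span = c(s$start[1L], s$end[nrow(s)])))
      bridge_like[k] <- TRUE
    }
  }

  ## pair facing P1 ends of adjacent structures (origin fired before the
  ## pulses: the origin lies in the unlabeled center). Sister arms labeled
  ## over the same interval have comparable P1 lengths, so grossly unequal
  ## facing P1s are not paired. A bridge contributes half its P1 per side.
  paired_right <- rep(FALSE, ns)   # structure k paired with k+1
  edge_p1 <- function(k, side) {
    s <- structs[[k]]
    j <- if (side == "first") 1L else nrow(s)
    len <- s$end[j] - s$start[j]
    if (bridge_like[k]) len / 2 else len
  }
  for (k in seq_len(max(0L, ns - 1L))) {
    # a single-segment structure has one edge; only a bridge may use it for
    # two pairings (its halves belong to different origins)
    if (k > 1L && paired_right[k - 1L] && nrow(structs[[k]]) == 1L &&
        !bridge_like[k]) next
    sl <- structs[[k]]
    sr <- structs[[k + 1L]]
    gap <- sr$start[1L] - sl$end[nrow(sl)]
    p1a <- edge_p1(k, "last")
    p1b <- edge_p1(k + 1L, "first")
    # a bridge half is truncated at the merge point, so its length carries
    # no information about the sister arm; skip the ratio test then
    ratio_ok <- bridge_like[k] || bridge_like[k + 1L] ||
      max(p1a, p1b) / min(p1a, p1b) <= cfg$pair_p1_ratio_max
    if (last_lab[k] == "P1" && first_lab[k + 1L] == "P1" &&
        gap <= cfg$max_pair_gap_kb && ratio_ok) {
      paired_right[k] <- TRUE
    }
  }

  ## helper: arm evidence for the j-th row (a P1 core) of a structure
  arm_p2 <- function(s, j, side) {
    i <- if (side == "left") j - 1L else j + 1L
    if (i < 1L || i > nrow(s)) return(NULL)
    if (s$label[i] != "P2") return(NULL)
    shared <- if (side == "left") {
      i - 1L >= 1L && s$label[i - 1L] == "P1"
    } else {
      i + 1L <= nrow(s) && s$label[i + 1L] == "P1"
    }
    list(len = s$end[i] - s$start[i], shared = shared)
  }

  classify_origin <- function(origin_pos, p1l, p2l, p1r, p2r, span,
                              pause_l = NA_real_, pause_r = NA_real_,
                              tip_l = NA_real_, tip_r = NA_real_,
                              paired = FALSE, bridge_l = FALSE,
                              bridge_r = FALSE) {
    has_l <- !is.null(p2l)
    has_r <- !is.null(p2r)
    # a paired event fired before pulse 1, so an intact arm's P1 length is
    # rate x pulse-1 duration, unaffected by the fork's later fate. A P1
    # half truncated at a pulse-1 merge (bridge) still bounds the rate
    # from below and enters as a right-censored observation. Arms whose P1
    # is clearly shorter than their own P2 (a pulse-1 anomaly) and paused
    # arms without a P2 (pause onset unknown) are not rate evidence.
    p1rate <- function(p1_len, p2, is_bridge) {
      if (!paired || p1_len <= 0) return(c(NA_real_, NA))
      v <- p1_len / cfg$pulse1_min
      if (is_bridge) return(c(v, FALSE))
      if (is.null(p2)) return(c(v, FALSE))  # paused side: pause onset unknown
      if (!p2$shared && p1_len + cfg$gap_tol_kb < p2$len) {
        return(c(v, FALSE))                 # pulse-1 anomaly: P1 incomplete
      }
      c(v, TRUE)
    }
    if (has_l && has_r) {
      # an arm is complete when its P2 is not shared with a converging fork
      # and its distal tip ends strictly inside the visible signal extent
      # (a tip that is itself the outermost signal may be cut by the
      # invisible fragment end)
      ok_l <- !p2l$shared && !is.na(tip_l) && tip_l > extent[1] + 0.5
      ok_r <- !p2r$shared && !is.na(tip_r) && tip_r < extent[2] - 0.5
      ratio <- max(p2l$len, p2r$len) / min(p2l$len, p2r$len)
      # asynchrony only needs the SHORTER arm certified complete: a cut
      # longer arm could only make the true ratio larger
      ok_shorter <- if (p2l$len <= p2r$len) ok_l else ok_r
      if (ok_shorter && ratio > cfg$async_ratio) {
        return(event_row(id, "ASYNCHRONOUS", origin_pos_kb = origin_pos,
                         pos_kb = origin_pos, left_p1 = p1l, left_p2 = p2l$len,
                         right_p1 = p1r, right_p2 = p2r$len, span = span))
      }
      rate <- if (ok_l && ok_r) (p2l$len + p2r$len) / 2 / cfg$pulse2_min
        else NA_real_
      return(event_row(
        id, "BIDIRECTIONAL", origin_pos_kb = origin_pos,
        pos_kb = origin_pos, left_p1 = p1l,
        left_p2 = p2l$len, right_p1 = p1r, right_p2 = p2r$len,
        rate = rate,
        # an unshared arm whose tip may be cut is a right-censored rate
        arm_rates = c(if (!p2l$shared) p2l$len / cfg$pulse2_min else NA_real_,
                      if (!p2r$shared) p2r$len / cfg$pulse2_min else NA_real_),
        arm_complete = c(ok_l, ok_r),
        p1_rates = c(p1rate(p1l, p2l, bridge_l)[1],
                     p1rate(p1r, p2r, bridge_r)[1]),
        p1_exact = c(p1rate(p1l, p2l, bridge_l)[2],
                     p1rate(p1r, p2r, bridge_r)[2]),
        span = span))
    }
    if (has_l || has_r) {
      return(event_row(id, "PAUSED_UNILATERAL", origin_pos_kb = origin_pos,
                       pos_kb = origin_pos, left_p1 = p1l,
                       left_p2 = if (has_l) p2l$len else NA_real_,
                       right_p1 = p1r,
                       right_p2 = if (has_r) p2r$len else NA_real_,
                       p1_rates = c(p1rate(p1l, p2l, bridge_l)[1],
                                    p1rate(p1r, p2r, bridge_r)[1]),
                       p1_exact = c(p1rate(p1l, p2l, bridge_l)[2],
                                    p1rate(p1r, p2r, bridge_r)[2]),
                       pause = if (has_l) pause_r else pause_l, span = span))
    }
    event_row(id, "PAUSED_BILATERAL", origin_pos_kb = origin_pos,
              pos_kb = origin_pos, left_p1 = p1l, right_p1 = p1r,
              p1_rates = c(p1rate(p1l, NULL, bridge_l)[1],
                           p1rate(p1r, NULL, bridge_r)[1]),
              p1_exact = c(p1rate(p1l, NULL, bridge_l)[2],
                           p1rate(p1r, NULL, bridge_r)[2]),
              pause = pause_l, pause2 = pause_r, span = span)
  }

  halves <- list()   # deferred single-arm candidates

  for (k in seq_len(ns)) {
    if (bridge_like[k]) next
    s <- structs[[k]]
    cores <- which(s$label == "P1")
    used_left_edge <- k > 1L && paired_right[k - 1L]
    used_right_edge <- paired_right[k]

    if (length(cores) == 0L) {
      add_event(event_row(id, "AMBIGUOUS_EXCLUDED",
                          pos_kb = (s$start[1L] + s$end[nrow(s)]) / 2,
                          span = c(s$start[1L], s$end[nrow(s)]),
                          reason = "red_only"))
      next
    }

    ## emit terminations at P2 segments shared by two converging forks
    for (i in seq_len(nrow(s))) {
      if (s$label[i] == "P2" && i > 1L && i < nrow(s) &&
          s$label[i - 1L] == "P1" && s$label[i + 1L] == "P1") {
        add_event(event_row(id, "TERMINATION",
                            pos_kb = (s$start[i] + s$end[i]) / 2,
                            span = c(s$start[i], s$end[i])))
      }
    }

    for (ci in seq_along(cores)) {
      j <- cores[ci]
      is_left_edge <- j == 1L
      is_right_edge <- j == nrow(s)
      if ((is_right_edge && used_right_edge) ||
          (is_left_edge && used_left_edge)) {
        next  # consumed by a pairing; handled below
      }
      p2l <- arm_p2(s, j, "left")
      p2r <- arm_p2(s, j, "right")
      p1_len <- s$end[j] - s$start[j]
      span <- c(s$start[max(1L, j - 1L)], s$end[min(nrow(s), j + 1L)])
      if (!is.null(p2l) && !is.null(p2r)) {
        add_event(classify_origin((s$start[j] + s$end[j]) / 2,
                                  p1_len / 2, p2l, p1_len / 2, p2r, span,
                                  tip_l = s$start[j - 1L],
                                  tip_r = s$end[j + 1L]))
      } else if (is.null(p2l) && is.null(p2r)) {
        ## standalone blue-only core: paused bilateral if supported
        halves[[length(halves) + 1L]] <- list(
          type = "blue", p1 = p1_len, span = c(s$start[j], s$end[j]),
          origin = (s$start[j] + s$end[j]) / 2, struct = k
        )
      } else {
        ## single-arm P1+P2 pattern: defer to the context pass
        dirn <- if (!is.null(p2r)) "right" else "left"
        p2len <- if (!is.null(p2r)) p2r$len else p2l$len
        shared <- if (!is.null(p2r)) p2r$shared else p2l$shared
        halves[[length(halves) + 1L]] <- list(
          type = "arm", p1 = p1_len, p2 = p2len, dir = dirn,
          shared = shared, span = span, struct = k,
          origin = (s$start[j] + s$end[j]) / 2,
          facing = if (dirn == "right") "left" else "right"
        )
      }
    }
  }

  ## paired origins: origin in the unlabeled center between facing P1 ends
  for (k in which(paired_right)) {
    sl <- structs[[k]]
    sr <- structs[[k + 1L]]
    jl <- nrow(sl)            # left structure's last row (P1)
    jr <- 1L                  # right structure's first row (P1)
    origin_pos <- (sl$end[jl] + sr$start[jr]) / 2
    p2l <- arm_p2(sl, jl, "left")
    p2r <- arm_p2(sr, jr, "right")
    span <- c(sl$start[max(1L, jl - 1L)], sr$end[min(nrow(sr), jr + 1L)])
    # an arm taken from a termination bridge is truncated at the merge
    # point (the bridge midpoint), not at its visible end
    pl <- if (bridge_like[k]) (sl$start[jl] + sl$end[jl]) / 2
      else sl$start[jl]
    pr <- if (bridge_like[k + 1L]) (sr$start[jr] + sr$end[jr]) / 2
      else sr$end[jr]
    add_event(classify_origin(origin_pos,
                              edge_p1(k, "last"), p2l,
                              edge_p1(k + 1L, "first"), p2r, span,
                              pause_l = pl, pause_r = pr,
                              tip_l = if (!is.null(p2l)) sl$start[jl - 1L]
                                else NA_real_,
                              tip_r = if (!is.null(p2r)) sr$end[jr + 1L]
                                else NA_real_,
                              paired = TRUE, bridge_l = bridge_like[k],
                              bridge_r = bridge_like[k + 1L]))
  }

  ## context pass: single-arm and blue-only candidates need support from
  ## other replication signals on the same fiber. A single P1+P2 arm is a
  ## unidirectional fork when another structure on the fiber travels in
  ## the same direction; with other replication signals but no
  ## same-direction support it reads as a unilaterally paused origin.
  n_support <- length(events) + length(halves)
  p2_support <- any(vapply(events, function(e) {
    e$kind %in% c("BIDIRECTIONAL", "ASYNCHRONOUS", "PAUSED_UNILATERAL",
                  "TERMINATION")
  }, logical(1))) ||
    any(vapply(halves, function(h) identical(h$type, "arm"), logical(1)))
  struct_dirs <- lapply(seq_len(ns), function(k) {
    s <- structs[[k]]
    out <- character(0)
    for (j in which(s$label == "P1")) {
      if (j > 1L && s$label[j - 1L] == "P2") out <- c(out, "left")
      if (j < nrow(s) && s$label[j + 1L] == "P2") out <- c(out, "right")
    }
    unique(out)
  })
  for (h in halves) {
    supported <- n_support >= 2L
    if (h$type == "blue") {
      if (supported && p2_support) {
        add_event(event_row(id, "PAUSED_BILATERAL", origin_pos_kb = h$origin,
                            pos_kb = h$origin, left_p1 = h$p1 / 2,
                            right_p1 = h$p1 / 2, pause = h$span[1],
                            pause2 = h$span[2], span = h$span))
      } else {
        add_event(event_row(id, "AMBIGUOUS_EXCLUDED", pos_kb = h$origin,
                            span = h$span, reason = "isolated_blue_only"))
      }
    } else {
      ## an arm whose P1 faces a blue termination bridge is the outer arm
      ## of a fork pair that merged during pulse 1: its origin cannot be
      ## mapped and it is not a unidirectional fork
      nb <- if (h$facing == "left") h$struct - 1L else h$struct + 1L
      same_dir <- any(vapply(seq_len(ns), function(k) {
        k != h$struct && h$dir %in% struct_dirs[[k]]
      }, logical(1)))
      if (nb >= 1L && nb <= ns && bridge_like[nb]) {
        add_event(event_row(id, "AMBIGUOUS_EXCLUDED", pos_kb = mean(h$span),
                            span = h$span, reason = "termination_flank"))
      } else if (supported && same_dir) {
        add_event(event_row(id, "UNIDIRECTIONAL",
                            pos_kb = mean(h$span),
                            left_p1 = if (h$dir == "left") NA_real_ else h$p1,
                            right_p1 = if (h$dir == "right") NA_real_ else h$p1,
                            direction = h$dir,
                            length_kb = h$p1 + (if (h$shared) 0 else h$p2),
                            span = h$span))
      } else if (supported) {
        ## origin inside the P1, pause at the truncated P1 end
        pause_at <- if (h$dir == "left") h$span[2] else h$span[1]
        add_event(event_row(id, "PAUSED_UNILATERAL",
                            origin_pos_kb = h$origin,
                            pos_kb = h$origin,
                            left_p1 = h$p1 / 2, right_p1 = h$p1 / 2,
                            left_p2 = if (h$dir == "left") h$p2 else NA_real_,
                            right_p2 = if (h$dir == "right") h$p2 else NA_real_,
                            pause = pause_at, span = h$span))
      } else {
        add_event(event_row(id, "AMBIGUOUS_EXCLUDED", pos_kb = mean(h$span),
                            span = h$span, reason = "isolated"))
      }
    }
  }

  ev <- if (length(events)) do.call(rbind, events) else empty_events()

  ## events must be framed by the probe signals: the mapped position (the
  ## origin, or the structure midpoint) must lie within the probe-framed
  ## span; arms may extend beyond it, since a contiguous labeled run is
  ## itself evidence of an uninterrupted filament
  if (nrow(ev)) {
    anchor_pos <- ifelse(is.na(ev$origin_pos_kb), ev$pos_kb,
                         ev$origin_pos_kb)
    outside <- !is.na(anchor_pos) &
      (anchor_pos < framed[1] - cfg$gap_tol_kb |
         anchor_pos > framed[2] + cfg$gap_tol_kb)
    if (any(outside)) {
      ev$exclusion_reason[outside] <- "not_framed"
      ev$kind[outside] <- "AMBIGUOUS_EXCLUDED"
      ev$origin_pos_kb[outside] <- NA_real_
      ev$rate_kb_min[outside] <- NA_real_
      ev$left_arm_rate[outside] <- NA_real_
      ev$right_arm_rate[outside] <- NA_real_
      ev$left_p1_rate[outside] <- NA_real_
      ev$right_p1_rate[outside] <- NA_real_
    }
  }
  rownames(ev) <- NULL
  ev
}

#' Classify a set of molecules
#'
#' Auto-orients unoriented molecules against the locus template, then
#' classifies each informative molecule's tracks.
#'
#' @param molecules List of [molecule()] objects (any mix of oriented and
#'   raw).
#' @param locus A [locus_map()].
#' @param cfg A [classifier_config()].
#' @return A list with `events` (row-bound event table), `molecules`
#'   (the oriented molecules that were classified) and `rejected`
#'   (non-informative molecules and reasons).
#' @export
classify_molecules <- function(molecules, locus, cfg = classifier_config()) {
  ori <- orient_molecules(molecules, locus, tol_frac = cfg$tol_frac)
  evs <- lapply(ori$oriented, classify_molecule, locus = locus, cfg = cfg)
  events <- if (length(evs)) do.call(rbind, evs) else empty_events()
  rownames(events) <- NULL
  list(events = events, molecules = ori$oriented, rejected = ori$rejected)
}

#' Compare classified events with simulation ground truth
#'
#' For every ground-truth origin that is observable in principle — all of
#' its labeled segments are inside the fragment (no arm was cut by a fork
#' merge or the fragment end), its expected pattern is decidable under the
#' reading rules, and it lies within the span framed by the observed probe
#' signals — the nearest classified event is looked up within `tol_kb` and
#' the event kinds are compared.
#'
#' @param events Event table from [classify_molecules()].
#' @param truth Ground truth from [simulate_molecules()].
#' @param tol_kb Position tolerance for matching origins.
#' @return A list with `n_eval`, `n_matched`, `kind_match_frac`, and the
#'   per-origin comparison table.
#' @export
match_events_to_truth <- function(events, truth, tol_kb = 2) {
  stopifnot(inherits(truth, "ground_truth"))
  orgs <- truth$origins
  frags <- truth$fragments
  if (!nrow(orgs)) {
    return(list(n_eval = 0L, n_matched = 0L, kind_match_frac = NA_real_,
                table = data.frame()))
  }
  dec <- truth_decidable(truth)
  orgs <- orgs[dec & orgs$interior & orgs$kind_truth != "UNOBSERVABLE", ,
               drop = FALSE]
  # restrict to origins mapped within the probe-framed span of the molecule
  fr <- frags[match(orgs$molecule_id, frags$molecule_id), ]
  keep <- !is.na(fr$framed_start_kb) &
    orgs$origin_pos_kb >= fr$framed_start_kb &
    orgs$origin_pos_kb <= fr$framed_end_kb
  orgs <- orgs[keep, , drop = FALSE]
  if (!nrow(orgs)) {
    return(list(n_eval = 0L, n_matched = 0L, kind_match_frac = NA_real_,
                table = data.frame()))
  }
  rows <- lapply(seq_len(nrow(orgs)), function(i) {
    o <- orgs[i, ]
    ev <- events[events$molecule_id == o$molecule_id, , drop = FALSE]
    got <- NA_character_
    pos_err <- NA_real_
    if (o$kind_truth == "UNIDIRECTIONAL") {
      cand <- ev[ev$kind == "UNIDIRECTIONAL" &
                   ev$pos_kb >= o$span_start_kb - tol_kb &
                   ev$pos_kb <= o$span_end_kb + tol_kb, , drop = FALSE]
      if (nrow(cand)) got <- "UNIDIRECTIONAL"
      if (is.na(got) && nrow(ev)) {
        near <- ev[!is.na(ev$pos_kb) &
                     ev$pos_kb >= o$span_start_kb - tol_kb &
                     ev$pos_kb <= o$span_end_kb + tol_kb, , drop = FALSE]
        if (nrow(near)) got <- near$kind[1L]
      }
    } else {
      cand <- ev[!is.na(ev$origin_pos_kb) &
                   abs(ev$origin_pos_kb - o$origin_pos_kb) <= tol_kb, ,
                 drop = FALSE]
      if (nrow(cand)) {
        j <- which.min(abs(cand$origin_pos_kb - o$origin_pos_kb))
        got <- cand$kind[j]
        pos_err <- cand$origin_pos_kb[j] - o$origin_pos_kb
      }
    }
    data.frame(molecule_id = o$molecule_id,
               origin_pos_kb = o$origin_pos_kb,
               kind_truth = o$kind_truth, kind_classified = got,
               pos_error_kb = pos_err, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  matched <- !is.na(tab$kind_classified) &
    tab$kind_classified == tab$kind_truth
  list(n_eval = nrow(tab), n_matched = sum(matched),
       kind_match_frac = mean(matched), table = tab)
}

# Which ground-truth origins have a pattern that the reading rules can
# decide at all? (computed from kinematics, not from the classifier)
truth_decidable <- function(truth, gap_tol_kb = 3, min_track_kb = 0.3225,
                            max_pair_gap_kb = 250) {
  orgs <- truth$origins
  arms <- truth$arms
  if (!nrow(orgs)) return(logical(0))
  key_o <- paste(orgs$molecule_id, signif(orgs$origin_pos_kb, 10))
  key_a <- paste(arms$molecule_id, signif(arms$origin_pos_kb, 10))
  n_vis <- table(orgs$molecule_id[orgs$kind_truth != "UNOBSERVABLE"])
  # closest approach of another origin's span (including the unlabeled
  # trails) on the same molecule; overlapping events cannot be read apart
  span_sep <- vapply(seq_len(nrow(orgs)), function(i) {
    o <- orgs[i, ]
    oth <- orgs[orgs$molecule_id == o$molecule_id, , drop = FALSE]
    oth <- oth[oth$origin_pos_kb != o$origin_pos_kb, , drop = FALSE]
    if (!nrow(oth)) return(Inf)
    min(pmax(oth$span_start_kb - o$span_end_kb,
             o$span_start_kb - oth$span_end_kb))
  }, numeric(1))
  vapply(seq_len(nrow(orgs)), function(i) {
    o <- orgs[i, ]
    a <- arms[key_a == key_o[i], ]
    la <- a[a$side == "left", ]
    ra <- a[a$side == "right", ]
    others <- (n_vis[o$molecule_id] %||% 0) - 1L
    switch(o$kind_truth,
      BIDIRECTIONAL = ,
      ASYNCHRONOUS = {
        # both arms must be anchored to the origin by a visible P1 (an arm
        # whose P1 was erased by a pause leaves an orphan red track); when
        # the origin center is unlabeled, the facing P1s and the silent
        # trails must both be comparable, or the center midpoint does not
        # map the origin; and the event must stand clear of its neighbours
        center <- la$p0_len_kb + ra$p0_len_kb
        p1s <- c(la$p1_len_kb, ra$p1_len_kb)
        all(p1s >= min_track_kb) && span_sep[i] > gap_tol_kb + 0.5 &&
          (center <= gap_tol_kb + 0.5 ||
             (max(p1s) / min(p1s) <= 2.5 && .trail_ok(la, ra)))
      },
      PAUSED_UNILATERAL = {
        # the paused arm's P1 must be separately visible and comparable in
        # length to its sister's (a pause that already ate into pulse 1
        # leaves a stub that cannot be paired), and the unlabeled center
        # must be wide enough to split the structures but symmetric enough
        # to map the origin
        center <- la$p0_len_kb + ra$p0_len_kb
        p1s <- c(la$p1_len_kb, ra$p1_len_kb)
        all(p1s >= min_track_kb) && center > gap_tol_kb + 0.5 &&
          max(p1s) / min(p1s) <= 2.5 && .trail_ok(la, ra) &&
          span_sep[i] > gap_tol_kb + 0.5
      },
      PAUSED_BILATERAL = {
        center <- la$p0_len_kb + ra$p0_len_kb
        p1s <- c(la$p1_len_kb, ra$p1_len_kb)
        if (center > gap_tol_kb + 0.5) {
          all(p1s >= min_track_kb) && max(p1s) / min(p1s) <= 2.5 &&
            .trail_ok(la, ra) && span_sep[i] > gap_tol_kb + 0.5
        } else {
          others >= 1L
        }
      },
      UNIDIRECTIONAL = {
        # needs a same-direction arm elsewhere on the fiber (the reading
        # rule for unidirectional forks); its structure (with the
        # unlabeled trail) must stand clear of every other event's span;
        # and no other event may face its silent trailing side within
        # pairing distance (two diverging trails read as one origin)
        mv <- if (la$stalled) ra else la
        same_dir <- {
          oth_arms <- arms[arms$molecule_id == o$molecule_id &
                             arms$origin_pos_kb != o$origin_pos_kb, ,
                           drop = FALSE]
          # direction is only readable from an arm showing both labels
          any(oth_arms$side == mv$side & !oth_arms$stalled &
                oth_arms$p1_len_kb >= min_track_kb &
                oth_arms$p2_len_kb >= min_track_kb)
        }
        oth <- orgs[orgs$molecule_id == o$molecule_id &
                      orgs$origin_pos_kb != o$origin_pos_kb, , drop = FALSE]
        trail_clear <- if (!nrow(oth)) TRUE else if (mv$side == "right") {
          # trailing silent side is the left
          !any(oth$origin_pos_kb < o$origin_pos_kb &
                 o$span_start_kb - oth$span_end_kb <= max_pair_gap_kb)
        } else {
          !any(oth$origin_pos_kb > o$origin_pos_kb &
                 oth$span_start_kb - o$span_end_kb <= max_pair_gap_kb)
        }
        others >= 1L && same_dir && span_sep[i] > gap_tol_kb + 0.5 &&
          trail_clear
      },
      FALSE
    )
  }, logical(1))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# silent trails of a pre-pulse origin must be comparable for the center
# midpoint to map the origin (a pause frozen near the origin breaks this)
.trail_ok <- function(la, ra) {
  p0 <- c(la$p0_len_kb, ra$p0_len_kb)
  if (max(p0) <= 3.5) return(TRUE)
  max(p0) / max(min(p0), 1e-6) <= 2.5
}
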