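#' Default candidate origin sites for a locus
#'
#' Candidate initiation sites are laid out on a regular grid across the
#' region, excluding the gene interval (on the normal allele the gene body
#' is replicated passively; intragenic initiation is modeled separately as
#' the dormant origin of the expanded allele).
#'
#' @param locus A [locus_map()].
#' @param spacing_kb Distance between candidate sites.
#' @param efficiency Per-cell-cycle firing probability of each site. With
#'   60 kb spacing and efficiency 0.4 the mean spacing of fired origins is
#'   150 kb, in the range observed for lymphoblastoid cells, while keeping
#'   licensed sites tens of kb apart.
#' @return Data frame `pos_kb`, `efficiency`.
#' @export
default_origin_sites <- function(locus, spacing_kb = 60, efficiency = 0.4) {
  pos <- seq(spacing_kb / 2, locus$region_len_kb - spacing_kb / 2,
             by = spacing_kb)
  gi <- locus$gene_interval_kb
  pos <- pos[pos < gi[1] | pos > gi[2]]
  data.frame(pos_kb = pos, efficiency = efficiency)
}

#' Simulation parameters for two-pulse combing experiments
#'
#' The forward model: molecules are random fragments of the locus; candidate
#' origins fire stochastically in time; each fork arm progresses at its own
#' rate, freezing during pause events, until it merges with a converging
#' fork or reaches the fragment end; DNA synthesised during the first and
#' second 30-minute pulse is labeled `P1` (IdU) and `P2` (CldU); finally the
#' fiber is measured with Gaussian endpoint noise and probes may drop out.
#' Time 0 is the start of pulse 1 and the fiber is a snapshot at the end of
#' pulse 2.
#'
#' @param locus A [locus_map()].
#' @param n_molecules Number of molecules to simulate.
#' @param origin_sites Data frame `pos_kb`, `efficiency`
#'   (default [default_origin_sites()]).
#' @param dormant_gene_origin_prob Per-molecule probability that a dormant
#'   origin fires inside the gene interval, uniform in position. Active only
#'   when `locus$expanded`, and only for molecules whose fragment covers the
#'   whole gene interval (so the probability is the estimand among
#'   gene-covering molecules).
#' @param fork_rate_mean_kb_min,fork_rate_cv Log-normal fork-level rate
#'   (mean 1.4 kb/min, CV 0.4 by default, spanning the observed range).
#' @param arm_jitter_cv Log-normal multiplicative jitter of the two sister
#'   arms around the fork rate (CV 0.05 by default): sister forks are
#'   nearly synchronous, so grossly asynchronous arms stay rare and origin
#'   midpoints stay accurate, as observed.
#' @param pause_rate_per_kb Poisson rate of pause events per kb traveled.
#' @param pause_duration_mean_min Mean of the exponential pause duration.
#'   The defaults model arrest-like blocks (long pauses at a low rate)
#'   whose signature is a missing second-pulse segment, the pattern scored
#'   as paused/arrested on fibers.
#' @param pause_hotspot_weight Probability that an arm whose path crosses
#'   the repeat position acquires an extra pause there (default 0).
#' @param unidirectional_prob Per fired origin, probability that one arm is
#'   permanently stalled from firing time (the minimal generative model of
#'   unidirectional forks, whose biology is unresolved).
#' @param pulse1_min,pulse2_min Pulse durations in minutes.
#' @param firing_window_min Length-2 window (minutes, relative to pulse-1
#'   start) over which replicon-cluster firing times are uniform. The
#'   default `c(-60, 30)` produces terminations, blue-only tracks and
#'   ongoing forks alike.
#' @param cluster_span_kb,firing_sync_sd_min Origins fire in locally
#'   synchronized replicon clusters: the region is tiled (with a random
#'   per-molecule phase) into blocks of `cluster_span_kb`, each block draws
#'   one firing time from `firing_window_min`, and origins within the block
#'   fire at that time plus independent Gaussian jitter of
#'   `firing_sync_sd_min` minutes. Set `firing_sync_sd_min` large to
#'   approach independent firing.
#' @param fragment_mean_kb,fragment_sd_kb,fragment_min_kb Normal fragment
#'   length distribution truncated at `fragment_min_kb`.
#' @param probe_dropout_prob Independent probability of losing each probe
#'   signal.
#' @param measurement_noise_sd_kb Gaussian noise added to every measured
#'   interval endpoint.
#' @param min_track_kb Shortest detectable track (1 pixel = 0.3225 kb by
#'   default); shorter synthesised segments are invisible.
#' @param min_probe_signal_kb Shortest recognisable probe signal; probe
#'   portions clipped at fragment ends below this length are lost.
#' @param seed Integer root seed; each molecule uses an independent
#'   deterministic substream so earlier molecules are unchanged when
#'   `n_molecules` grows.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(locus,
                       n_molecules = 200,
                       origin_sites = default_origin_sites(locus),
                       dormant_gene_origin_prob = 0.2,
                       fork_rate_mean_kb_min = 1.4,
                       fork_rate_cv = 0.4,
                       arm_jitter_cv = 0.05,
                       pause_rate_per_kb = 8e-4,
                       pause_duration_mean_min = 40,
                       pause_hotspot_weight = 0,
                       unidirectional_prob = 0.15,
                       pulse1_min = 30,
                       pulse2_min = 30,
                       firing_window_min = c(-60, 30),
                       cluster_span_kb = 300,
                       firing_sync_sd_min = 8,
                       fragment_mean_kb = 450,
                       fragment_sd_kb = 150,
                       fragment_min_kb = 50,
                       probe_dropout_prob = 0.05,
                       measurement_noise_sd_kb = 1,
                       min_track_kb = 0.3225,
                       min_probe_signal_kb = 10,
                       seed = 1L) {
  stopifnot(inherits(locus, "locus_map"))
  probs <- c(dormant_gene_origin_prob, unidirectional_prob,
             probe_dropout_prob, origin_sites$efficiency,
             pause_hotspot_weight)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (pulse1_min <= 0 || pulse2_min <= 0) {
    stop("pulse durations must be positive", call. = FALSE)
  }
  if (fork_rate_mean_kb_min <= 0) {
    stop("fork rate mean must be positive", call. = FALSE)
  }
  if (fragment_mean_kb <= 0 || fragment_min_kb <= 0) {
    stop("fragment length distribution must have positive support",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_params")
}

# lognormal meanlog/sdlog for a given mean and CV
.lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# distance traveled by an arm `t_abs` minutes into the experiment, given
# firing time t0, rate, and pauses (distances from origin, durations)
.arm_distance <- function(t_abs, t0, rate, pause_d, pause_dur) {
  tau <- t_abs - t0
  if (tau <= 0 || rate <= 0) return(0)
  d <- 0
  if (length(pause_d)) {
    o <- order(pause_d)
    pause_d <- pause_d[o]
    pause_dur <- pause_dur[o]
    for (k in seq_along(pause_d)) {
      step <- (pause_d[k] - d) / rate
      if (tau < step) return(d + rate * tau)
      tau <- tau - step
      d <- pause_d[k]
      if (tau < pause_dur[k]) return(d)
      tau <- tau - pause_dur[k]
    }
  }
  d + rate * tau
}

#' Simulate two-pulse labeled combed molecules
#'
#' Runs the forward model described in [sim_params()] and returns the
#' measured molecules alongside the full ground truth, so every analysis
#' stage can be validated against known origin positions, firing times,
#' fork rates and pause events.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements:
#'   * `molecules`: list of [molecule()] objects (kb units, unoriented,
#'     randomly flipped),
#'   * `truth`: a `ground_truth` object with data frames `origins`, `arms`,
#'     `fragments` plus the parameter set.
#' @export
simulate_molecules <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  locus <- p$locus
  t_end <- p$pulse1_min + p$pulse2_min
  mols <- vector("list", p$n_molecules)
  org_rows <- list()
  arm_rows <- list()
  frag_rows <- list()

  for (i in seq_len(p$n_molecules)) {
    # independent deterministic substream per molecule
    sub_seed <- (as.numeric(p$seed) * 7919 + i * 104729) %% 2147483647
    set.seed(as.integer(sub_seed))
    id <- sprintf("mol%04d", i)

    ## fragment
    L <- Inf
    while (!is.finite(L) || L < p$fragment_min_kb) {
      L <- stats::rnorm(1, p$fragment_mean_kb, p$fragment_sd_kb)
    }
    frag_start <- stats::runif(1, -L + 20, locus$region_len_kb - 20)
    frag_end <- frag_start + L
    covers_gene <- frag_start <= locus$gene_interval_kb[1] &&
      frag_end >= locus$gene_interval_kb[2]

    ## origin firing
    fired <- stats::runif(nrow(p$origin_sites)) < p$origin_sites$efficiency
    o_pos <- p$origin_sites$pos_kb[fired]
    o_pos <- o_pos[o_pos > frag_start & o_pos < frag_end]
    o_dormant <- rep(FALSE, length(o_pos))
    if (locus$expanded && covers_gene &&
        stats::runif(1) < p$dormant_gene_origin_prob) {
      dpos <- stats::runif(1, locus$gene_interval_kb[1],
                           locus$gene_interval_kb[2])
      o_pos <- c(o_pos, dpos)
      o_dormant <- c(o_dormant, TRUE)
    }
    ord <- order(o_pos)
    o_pos <- o_pos[ord]
    o_dormant <- o_dormant[ord]
    n_org <- length(o_pos)
    ## locally synchronized firing: one cluster time per block
    phase <- stats::runif(1, 0, p$cluster_span_kb)
    block <- floor((o_pos + phase) / p$cluster_span_kb)
    o_t0 <- numeric(n_org)
    for (b in unique(block)) {
      tb <- stats::runif(1, p$firing_window_min[1], p$firing_window_min[2])
      sel <- block == b & !o_dormant
      o_t0[sel] <- tb + stats::rnorm(sum(sel), 0, p$firing_sync_sd_min)
    }
    ## a dormant origin is a rescue origin: its firing is triggered by the
    ## approach of incoming forks, so it fires within the ~45 minutes
    ## before its position would be replicated passively (never after)
    for (j in which(o_dormant)) {
      cover <- Inf
      for (k in seq_len(n_org)) {
        if (k == j || o_dormant[k]) next
        cover <- min(cover, o_t0[k] +
                       abs(o_pos[j] - o_pos[k]) / p$fork_rate_mean_kb_min)
      }
      hi <- min(p$firing_window_min[2], cover - 1)
      hi <- max(hi, p$firing_window_min[1] + 0.5)
      lo <- max(p$firing_window_min[1], hi - 45)
      o_t0[j] <- stats::runif(1, lo, hi)
    }

    ## passive-replication suppression: an origin does not fire if an
    ## earlier-firing neighbour's fork has already passed over it
    if (n_org > 1L) {
      keep <- rep(TRUE, n_org)
      for (j in order(o_t0)) {
        if (o_dormant[j]) next   # fired before coverage by construction
        for (k in seq_len(n_org)) {
          if (k == j || !keep[k] || o_t0[k] >= o_t0[j]) next
          # crude bound: neighbour k travels unimpeded at the mean rate
          reach <- p$fork_rate_mean_kb_min * (o_t0[j] - o_t0[k])
          if (abs(o_pos[j] - o_pos[k]) < reach) {
            keep[j] <- FALSE
            break
          }
        }
      }
      o_pos <- o_pos[keep]
      o_dormant <- o_dormant[keep]
      o_t0 <- o_t0[keep]
      n_org <- length(o_pos)
    }

    ## per-origin kinematics
    rate_f <- .lnorm_pars(p$fork_rate_mean_kb_min, p$fork_rate_cv)
    jit <- .lnorm_pars(1, p$arm_jitter_cv)
    arms <- vector("list", n_org)   # each: list(left=..., right=...)
    o_unidir <- rep(FALSE, n_org)
    for (j in seq_len(n_org)) {
      fr <- stats::rlnorm(1, rate_f$meanlog, rate_f$sdlog)
      o_unidir[j] <- stats::runif(1) < p$unidirectional_prob
      stalled_side <- if (o_unidir[j]) sample(c("left", "right"), 1) else ""
      mk_arm <- function(side) {
        rate <- fr * stats::rlnorm(1, jit$meanlog, jit$sdlog)
        stalled <- identical(side, stalled_side)
        max_d <- if (stalled) 0 else max(0, rate * (t_end - o_t0[j]))
        n_pause <- if (stalled) 0L else stats::rpois(1, p$pause_rate_per_kb * max_d)
        pause_d <- if (n_pause) stats::runif(n_pause, 0, max_d) else numeric(0)
        pause_dur <- if (n_pause) {
          stats::rexp(n_pause, 1 / p$pause_duration_mean_min)
        } else {
          numeric(0)
        }
        if (!stalled && p$pause_hotspot_weight > 0) {
          hd <- if (side == "right") locus$repeat_pos_kb - o_pos[j]
                else o_pos[j] - locus$repeat_pos_kb
          if (hd > 0 && hd < max_d &&
              stats::runif(1) < p$pause_hotspot_weight) {
            pause_d <- c(pause_d, hd)
            pause_dur <- c(pause_dur,
                           stats::rexp(1, 1 / p$pause_duration_mean_min))
          }
        }
        list(side = side, rate = rate, stalled = stalled,
             pause_d = pause_d, pause_dur = pause_dur)
      }
      arms[[j]] <- list(left = mk_arm("left"), right = mk_arm("right"))
    }

    ## arm travel limits: fragment ends and fork merges
    dist_at <- function(arm, j, t) {
      if (arm$stalled) 0
      else .arm_distance(t, o_t0[j], arm$rate, arm$pause_d, arm$pause_dur)
    }
    lim_left <- if (n_org) o_pos - frag_start else numeric(0)
    lim_right <- if (n_org) frag_end - o_pos else numeric(0)
    if (n_org > 1L) {
      for (j in seq_len(n_org - 1L)) {
        gap <- o_pos[j + 1L] - o_pos[j]
        g <- function(t) {
          dist_at(arms[[j]]$right, j, t) +
            dist_at(arms[[j + 1L]]$left, j + 1L, t) - gap
        }
        if (g(t_end) > 0) {
          tm <- stats::uniroot(g, c(min(o_t0[j], o_t0[j + 1L]), t_end),
                               tol = 1e-8)$root
          dr <- dist_at(arms[[j]]$right, j, tm)
          lim_right[j] <- min(lim_right[j], dr)
          lim_left[j + 1L] <- min(lim_left[j + 1L], gap - dr)
        }
      }
    }

    ## labeled segments per arm
    segs <- list()
    for (j in seq_len(n_org)) {
      for (side in c("left", "right")) {
        arm <- arms[[j]][[side]]
        lim <- if (side == "left") lim_left[j] else lim_right[j]
        d0 <- min(dist_at(arm, j, 0), lim)
        d1 <- min(dist_at(arm, j, p$pulse1_min), lim)
        d2 <- min(dist_at(arm, j, t_end), lim)
        sgn <- if (side == "right") 1 else -1
        add <- function(a, b, lab) {
          if (b - a >= p$min_track_kb) {
            lo <- o_pos[j] + sgn * a
            hi <- o_pos[j] + sgn * b
            segs[[length(segs) + 1L]] <<-
              data.frame(start = min(lo, hi), end = max(lo, hi), label = lab,
                         stringsAsFactors = FALSE)
          }
        }
        add(d0, d1, "P1")
        add(d1, d2, "P2")
        hit_lim <- !arm$stalled && abs(d2 - lim) < 1e-9
        arm_rows[[length(arm_rows) + 1L]] <- data.frame(
          molecule_id = id, origin_index = j, origin_pos_kb = o_pos[j],
          side = side, rate_kb_min = arm$rate, stalled = arm$stalled,
          p0_len_kb = d0, p1_len_kb = d1 - d0, p2_len_kb = d2 - d1,
          n_pauses = length(arm$pause_d), hit_limit = hit_lim,
          stringsAsFactors = FALSE
        )
      }
    }

    ## merge adjacent same-label segments (e.g. P1 running through an origin)
    tracks <- empty_tracks()
    if (length(segs)) {
      seg <- do.call(rbind, segs)
      seg <- seg[order(seg$start, seg$end), , drop = FALSE]
      merged <- list()
      for (r in seq_len(nrow(seg))) {
        n <- length(merged)
        if (n > 0L && merged[[n]]$label == seg$label[r] &&
            seg$start[r] <= merged[[n]]$end + 1e-6) {
          merged[[n]]$end <- max(merged[[n]]$end, seg$end[r])
        } else {
          merged[[n + 1L]] <- seg[r, ]
        }
      }
      tracks <- do.call(rbind, merged)
    }

    ## truth kind per origin, from kinematics
    if (n_org) {
      arm_tab <- do.call(rbind, arm_rows[(length(arm_rows) - 2L * n_org + 1L):
                                           length(arm_rows)])
      for (j in seq_len(n_org)) {
        a <- arm_tab[arm_tab$origin_index == j, ]
        la <- a[a$side == "left", ]
        ra <- a[a$side == "right", ]
        kt <- .truth_kind(la, ra, p$min_track_kb, async_ratio = 2.0)
        span_lo <- o_pos[j] - (la$p0_len_kb + la$p1_len_kb + la$p2_len_kb)
        span_hi <- o_pos[j] + (ra$p0_len_kb + ra$p1_len_kb + ra$p2_len_kb)
        interior <- !la$hit_limit && !ra$hit_limit
        org_rows[[length(org_rows) + 1L]] <- data.frame(
          molecule_id = id, origin_pos_kb = o_pos[j],
          fire_time_min = o_t0[j], dormant = o_dormant[j],
          in_gene = o_pos[j] >= locus$gene_interval_kb[1] &
            o_pos[j] <= locus$gene_interval_kb[2],
          unidirectional = o_unidir[j], kind_truth = kt,
          span_start_kb = span_lo, span_end_kb = span_hi,
          interior = interior, stringsAsFactors = FALSE
        )
      }
    }

    ## probe signals: emitted when the fragment covers (nearly) the whole
    ## probe; partial hybridizations at fragment ends are treated as lost
    ## probe signals: clipped to the fragment; slivers shorter than
    ## min_probe_signal_kb are unrecognisable and treated as lost
    pr <- locus$probes
    ps_start <- pmax(pr$start_kb, frag_start)
    ps_end <- pmin(pr$end_kb, frag_end)
    visible <- ps_end - ps_start >= p$min_probe_signal_kb
    kept <- visible & stats::runif(nrow(pr)) >= p$probe_dropout_prob
    probe_sig <- data.frame(
      start = ps_start[kept], end = ps_end[kept],
      flag = pr$orientation_flag[kept]
    )
    framed <- if (sum(kept) >= 2L) {
      c(min(ps_start[kept]), max(ps_end[kept]))
    } else {
      c(NA_real_, NA_real_)
    }

    ## to molecule-local coordinates, random reading direction, noise
    flipped <- stats::runif(1) < 0.5
    localize <- function(df) {
      if (nrow(df) == 0L) return(df)
      s <- df$start - frag_start
      e <- df$end - frag_start
      if (flipped) {
        s2 <- L - e
        e2 <- L - s
        s <- s2
        e <- e2
      }
      if (p$measurement_noise_sd_kb > 0) {
        s <- s + stats::rnorm(length(s), 0, p$measurement_noise_sd_kb)
        e <- e + stats::rnorm(length(e), 0, p$measurement_noise_sd_kb)
        bad <- e <= s
        e[bad] <- s[bad] + p$min_track_kb
      }
      df$start <- s
      df$end <- e
      df[order(df$start), , drop = FALSE]
    }
    tr_loc <- localize(tracks)
    # endpoint noise can make neighbouring same-label tracks overlap; nudge
    if (nrow(tr_loc) > 1L) {
      for (lab in c("P1", "P2")) {
        ix <- which(tr_loc$label == lab)
        if (length(ix) > 1L) {
          for (q in seq_len(length(ix) - 1L)) {
            a <- ix[q]; b <- ix[q + 1L]
            if (tr_loc$end[a] > tr_loc$start[b]) {
              mid <- (tr_loc$end[a] + tr_loc$start[b]) / 2
              tr_loc$end[a] <- mid - 1e-4
              tr_loc$start[b] <- mid + 1e-4
            }
          }
        }
      }
    }
    mols[[i]] <- molecule(id, tracks = tr_loc,
                          probe_signals = localize(probe_sig),
                          units = "kb")
    frag_rows[[length(frag_rows) + 1L]] <- data.frame(
      molecule_id = id, frag_start_kb = frag_start, frag_end_kb = frag_end,
      length_kb = L, flipped = flipped, covers_gene = covers_gene,
      replicating = n_org > 0L, informative = sum(kept) >= 2L,
      framed_start_kb = framed[1], framed_end_kb = framed[2],
      stringsAsFactors = FALSE
    )
  }

  truth <- structure(
    list(
      origins = if (length(org_rows)) do.call(rbind, org_rows) else
        data.frame(),
      arms = if (length(arm_rows)) do.call(rbind, arm_rows) else data.frame(),
      fragments = do.call(rbind, frag_rows),
      params = params
    ),
    class = "ground_truth"
  )
  list(molecules = mols, truth = truth)
}

# expected event class from true arm kinematics (independent of the track
# classifier: uses synthesised segment lengths, not parsed track patterns)
.truth_kind <- function(left, right, min_track, async_ratio) {
  p1l <- left$p1_len_kb >= min_track
  p2l <- left$p2_len_kb >= min_track
  p1r <- right$p1_len_kb >= min_track
  p2r <- right$p2_len_kb >= min_track
  if (left$stalled || right$stalled) {
    mv <- if (left$stalled) right else left
    if (mv$p1_len_kb >= min_track && mv$p2_len_kb >= min_track) {
      return("UNIDIRECTIONAL")
    }
    return("UNOBSERVABLE")
  }
  if (!p1l && !p1r) return("UNOBSERVABLE")
  if (p2l && p2r) {
    ratio <- max(left$p2_len_kb, right$p2_len_kb) /
      min(left$p2_len_kb, right$p2_len_kb)
    return(if (ratio > async_ratio) "ASYNCHRONOUS" else "BIDIRECTIONAL")
  }
  if (p2l || p2r) return("PAUSED_UNILATERAL")
  "PAUSED_BILATERAL"
}

#' Summaries of simulation ground truth
#'
#' All quantities are computed from the ground truth (never from the
#' measured tracks): the replicating fraction, the true per-arm fork rates
#' of bidirectional origins, the true inter-origin distances (consecutive
#' fired origins along each molecule) and the dormant-origin frequency.
#'
#' @param truth The `truth` element returned by [simulate_molecules()].
#' @param locus A [locus_map()] (defaults to the one in the parameters).
#' @return A list with `n_molecules`, `replicating_fraction_pct`,
#'   `fork_rates` (per-arm, non-stalled arms of bidirectional origins),
#'   `iods_kb`, `dormant_freq` (gene-origin molecules over replicating
#'   molecules that cover the gene), `dormant_freq_all_replicating`, and
#'   per-molecule origin counts.
#' @export
truth_summary <- function(truth, locus = truth$params$locus) {
  stopifnot(inherits(truth, "ground_truth"))
  frags <- truth$fragments
  orgs <- truth$origins
  n_rep <- sum(frags$replicating)
  # true IODs are taken over origins active during the labeling window
  # (those leaving any labeled segment); an origin whose forks fully merged
  # before the first pulse is invisible to any labeling assay
  vis <- if (nrow(orgs)) {
    orgs[orgs$kind_truth != "UNOBSERVABLE", , drop = FALSE]
  } else {
    orgs
  }
  iods <- numeric(0)
  if (nrow(vis)) {
    for (id in unique(vis$molecule_id)) {
      pos <- sort(vis$origin_pos_kb[vis$molecule_id == id])
      if (length(pos) > 1L) iods <- c(iods, diff(pos))
    }
  }
  gene_mols <- if (nrow(orgs)) {
    unique(orgs$molecule_id[orgs$in_gene])
  } else {
    character(0)
  }
  cover_rep <- frags$molecule_id[frags$covers_gene & frags$replicating]
  arms <- truth$arms
  bidir <- if (nrow(orgs)) {
    orgs[orgs$kind_truth == "BIDIRECTIONAL", c("molecule_id", "origin_pos_kb")]
  } else {
    data.frame()
  }
  rates <- numeric(0)
  if (nrow(bidir) && nrow(arms)) {
    key_a <- paste(arms$molecule_id, signif(arms$origin_pos_kb, 10))
    key_b <- paste(bidir$molecule_id, signif(bidir$origin_pos_kb, 10))
    rates <- arms$rate_kb_min[key_a %in% key_b & !arms$stalled]
  }
  counts <- if (nrow(orgs)) {
    as.data.frame(table(molecule_id = orgs$molecule_id),
                  responseName = "n_origins")
  } else {
    data.frame(molecule_id = character(0), n_origins = integer(0))
  }
  list(
    n_molecules = nrow(frags),
    replicating_fraction_pct = if (nrow(frags)) 100 * n_rep / nrow(frags)
      else NA_real_,
    fork_rates = rates,
    iods_kb = iods,
    dormant_freq = if (length(cover_rep)) {
      length(intersect(gene_mols, cover_rep)) / length(cover_rep)
    } else {
      NA_real_
    },
    dormant_freq_all_replicating = if (n_rep) {
      length(gene_mols) / n_rep
    } else {
      NA_real_
    },
    origin_counts = counts
  )
}

#' Write the ground-truth origin table as TSV
#'
#' The seed is echoed in a `#` header line.
#'
#' @param truth A `ground_truth` object.
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", truth$params$seed), con)
  utils::write.table(truth$origins, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
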