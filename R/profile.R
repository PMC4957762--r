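ORIGIN_KINDS <- c("BIDIRECTIONAL", "ASYNCHRONOUS",
                  "PAUSED_UNILATERAL", "PAUSED_BILATERAL")
FORK_KINDS <- c(ORIGIN_KINDS, "UNIDIRECTIONAL")

#' Fork rate of a complete bidirectional event
#'
#' Rates are computed from complete bidirectional forks only: each arm's
#' rate is its second-pulse (P2) segment length divided by the pulse-2
#' duration, and the event rate is the mean of the two arm rates.
#'
#' @param ev A single event row (from [classify_molecule()]).
#' @param pulse2_min Second pulse duration in minutes.
#' @return A list with `arms` (left, right rates in kb/min) and `event`
#'   (their mean).
#' @export
fork_rate <- function(ev, pulse2_min = 30) {
  if (nrow(ev) != 1L) stop("`ev` must be a single event row", call. = FALSE)
  if (ev$kind != "BIDIRECTIONAL" || is.na(ev$left_p2_kb) ||
      is.na(ev$right_p2_kb) || is.na(ev$rate_kb_min)) {
    stop("fork_rate() requires a complete, synchronous bidirectional event",
         call. = FALSE)
  }
  arms <- c(left = ev$left_p2_kb, right = ev$right_p2_kb) / pulse2_min
  list(arms = arms, event = mean(arms))
}

#' Fork-rate estimates from classified events
#'
#' Per-arm rates (P2 length / pulse-2 duration) of bidirectional events.
#' Arms whose distal P2 tip ends at the visible edge of the fiber may be
#' cut by the invisible fragment end: their measured rate is a lower bound
#' (a right-censored observation). Two estimates of the mean rate are
#' returned: the plain mean over complete arms, and a Kaplan-Meier
#' (censoring-aware) restricted mean that also uses the censored arms —
#' censoring depends on where the fork sits on the fragment, not on how
#' fast it moves, so it is independent of the rate.
#'
#' A third estimate uses the first-pulse segments of paired origins (those
#' that fired before pulse 1): an intact P1 arm spans exactly
#' rate x pulse-1 duration, so it is unaffected by the later fate of the
#' fork (merging with a converging fork, or running off the fragment) that
#' right-censors P2-based measurements; P1 arms truncated at a merge or by
#' a pause enter as right-censored observations. The censored log-normal
#' maximum-likelihood mean over these P1 observations (`mean_p1_mle`) is
#' the preferred estimator of the population mean rate.
#'
#' @param events Event table from [classify_molecules()].
#' @return List with `rates_complete`, `mean_complete`, `n_complete`,
#'   `mean_km`, `n_total` (complete plus censored arms), and `rates_p1`
#'   (exact P1-based rates), `mean_p1`, `n_p1`, `mean_p1_mle`,
#'   `n_p1_total`.
#' @export
fork_rate_estimate <- function(events) {
  bid <- events[events$kind == "BIDIRECTIONAL", , drop = FALSE]
  val <- c(bid$left_arm_rate, bid$right_arm_rate)
  done <- c(bid$left_arm_complete, bid$right_arm_complete)
  ok_p1 <- events$kind %in% c("BIDIRECTIONAL", "PAUSED_UNILATERAL",
                              "PAUSED_BILATERAL")
  p1v <- c(events$left_p1_rate[ok_p1], events$right_p1_rate[ok_p1])
  p1e <- c(events$left_p1_exact[ok_p1], events$right_p1_exact[ok_p1])
  p1e <- p1e[!is.na(p1v)] %in% TRUE
  p1v <- p1v[!is.na(p1v)]
  mean_p1_mle <- NA_real_
  if (sum(p1e) >= 5L) {
    fit <- tryCatch(
      survival::survreg(survival::Surv(p1v, p1e) ~ 1, dist = "lognormal"),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$scale)) {
      mean_p1_mle <- unname(exp(fit$coefficients[1L] + fit$scale^2 / 2))
    }
  }
  keep <- !is.na(val)
  val <- val[keep]
  done <- done[keep] %in% TRUE
  comp <- val[done]
  mean_km <- NA_real_
  if (any(done)) {
    # Kaplan-Meier restricted mean on (rate, observed) pairs
    ord <- order(val)
    v <- val[ord]
    d <- done[ord]
    n <- length(v)
    surv <- 1
    mean_km <- 0
    prev <- 0
    for (i in seq_len(n)) {
      if (d[i]) {
        mean_km <- mean_km + surv * (v[i] - prev)
        prev <- v[i]
        surv <- surv * (1 - 1 / (n - i + 1))
      }
    }
  }
  list(rates_complete = comp, mean_complete = mean(comp),
       n_complete = length(comp), mean_km = mean_km, n_total = length(val),
       rates_p1 = p1v[p1e], mean_p1 = mean(p1v[p1e]), n_p1 = sum(p1e),
       mean_p1_mle = mean_p1_mle, n_p1_total = length(p1v))
}

#' Inter-origin distances along molecules
#'
#' Distances between consecutive origin positions on each molecule, using
#' all origin-generating event kinds (bidirectional, asynchronous and
#' paused events each reflect the firing of one origin). Origins on
#' different molecules are never paired. An interval containing a
#' replication structure whose origin could not be placed (a unidirectional
#' fork or an excluded ambiguous structure) is not measured: an unmapped
#' origin could hide there and the distance would span more than one
#' replicon.
#'
#' @param events Event table.
#' @param strict Drop intervals contaminated by unplaceable structures
#'   (default TRUE).
#' @return Numeric vector of distances in kb.
#' @export
inter_origin_distances <- function(events, strict = TRUE) {
  ev <- events[events$kind %in% ORIGIN_KINDS & !is.na(events$origin_pos_kb), ,
               drop = FALSE]
  out <- numeric(0)
  for (id in unique(ev$molecule_id)) {
    pos <- sort(ev$origin_pos_kb[ev$molecule_id == id])
    if (length(pos) < 2L) next
    d <- diff(pos)
    if (strict) {
      blocker <- events[events$molecule_id == id &
                          events$kind %in% c("UNIDIRECTIONAL",
                                             "AMBIGUOUS_EXCLUDED") &
                          !is.na(events$pos_kb), , drop = FALSE]
      if (nrow(blocker)) {
        ok <- vapply(seq_len(length(pos) - 1L), function(i) {
          !any(blocker$pos_kb > pos[i] & blocker$pos_kb < pos[i + 1L])
        }, logical(1))
        d <- d[ok]
      }
    }
    out <- c(out, d)
  }
  out
}

#' Fraction of replicating molecules
#'
#' The ratio between the number of molecules displaying replication signals
#' and the total number of informative molecules (those hybridizing at
#' least two probes), as a percentage to one decimal.
#'
#' @param x Either a list of [molecule()] objects, or the count of
#'   replicating molecules (with `n` the informative total).
#' @param n Informative-molecule total when `x` is a count.
#' @return Percentage (1 decimal).
#' @export
replicating_fraction <- function(x, n = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    info <- Filter(is_informative, x)
    if (length(info) == 0L) {
      stop("no informative molecules: replicating fraction undefined",
           call. = FALSE)
    }
    k <- sum(vapply(info, function(m) nrow(m$tracks) > 0L, logical(1)))
    n <- length(info)
  } else {
    k <- x
    if (is.null(n) || n <= 0) {
      stop("replicating fraction undefined for zero informative molecules",
           call. = FALSE)
    }
  }
  round(100 * k / n, 1)
}

#' Origin counts in the gene and central probe region
#'
#' Counts bidirectional origins mapped inside the gene interval, the
#' molecules carrying at least one of them, and the number of bidirectional
#' origins per origin-bearing molecule within the central probe region
#' (ratio to 2 decimals).
#'
#' @param events Event table.
#' @param locus A [locus_map()].
#' @param kinds Event kinds counted as mapped bidirectional origins.
#' @return A list with `origins_in_gene`, `molecules_with_gene_origin`,
#'   `origins_central`, `molecules_central`,
#'   `origins_per_origin_molecule` (0 with `undefined = TRUE` when no
#'   origin fell in the central region).
#' @export
gene_origin_stats <- function(events, locus,
                              kinds = c("BIDIRECTIONAL", "ASYNCHRONOUS")) {
  ev <- events[events$kind %in% kinds & !is.na(events$origin_pos_kb), ,
               drop = FALSE]
  gi <- locus$gene_interval_kb
  cp <- locus$probes[locus$probes$name == locus$central_probe, ]
  in_gene <- ev$origin_pos_kb >= gi[1] & ev$origin_pos_kb <= gi[2]
  in_central <- ev$origin_pos_kb >= cp$start_kb & ev$origin_pos_kb <= cp$end_kb
  n_central_mol <- length(unique(ev$molecule_id[in_central]))
  ratio <- if (n_central_mol > 0L) {
    round(sum(in_central) / n_central_mol, 2)
  } else {
    0
  }
  list(
    origins_in_gene = sum(in_gene),
    molecules_with_gene_origin = length(unique(ev$molecule_id[in_gene])),
    origins_central = sum(in_central),
    molecules_central = n_central_mol,
    origins_per_origin_molecule = ratio,
    undefined = n_central_mol == 0L
  )
}

#' Dormant-origin frequency estimate
#'
#' Fraction of replicating molecules whose observed span covers the whole
#' gene interval and that carry at least one origin-generating event mapped
#' inside the gene.
#'
#' @param events Event table.
#' @param molecules Oriented molecules that were classified.
#' @param locus A [locus_map()].
#' @return List with `k` (gene-origin molecules), `n` (gene-covering
#'   replicating molecules) and `freq`.
#' @export
dormant_origin_frequency <- function(events, molecules, locus) {
  gi <- locus$gene_interval_kb
  covering <- vapply(molecules, function(m) {
    if (!isTRUE(m$oriented)) return(FALSE)
    lo <- to_region(m, min(m$probe_signals$start, m$tracks$start, Inf))
    hi <- to_region(m, max(m$probe_signals$end, m$tracks$end, -Inf))
    lo <= gi[1] && hi >= gi[2]
  }, logical(1))
  ids_cov <- vapply(molecules, `[[`, character(1), "molecule_id")[covering]
  replicating <- unique(events$molecule_id[events$kind %in% FORK_KINDS])
  denom <- intersect(ids_cov, replicating)
  ev <- events[events$kind %in% ORIGIN_KINDS & !is.na(events$origin_pos_kb), ,
               drop = FALSE]
  gene_ids <- unique(ev$molecule_id[ev$origin_pos_kb >= gi[1] &
                                      ev$origin_pos_kb <= gi[2]])
  k <- length(intersect(gene_ids, denom))
  n <- length(denom)
  list(k = k, n = n, freq = if (n > 0) k / n else NA_real_)
}

#' Template strand of the repeat for each crossing fork
#'
#' For every fork arm whose trajectory crosses the repeat position, reports
#' whether the repeat-carrying strand served as lagging- or leading-strand
#' template: a fork traveling in the direction of gene transcription
#' (arriving from upstream of the gene) places the repeat on the lagging
#' template; a fork from downstream places it on the leading template.
#'
#' @param events Event table.
#' @param locus A [locus_map()].
#' @return List with `lagging`, `leading` counts and `prop_leading`.
#' @export
repeat_template_orientation <- function(events, locus) {
  rp <- locus$repeat_pos_kb
  arms <- list()
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$kind %in% ORIGIN_KINDS && !is.na(e$origin_pos_kb)) {
      lext <- sum(c(e$left_p1_kb, e$left_p2_kb), na.rm = TRUE)
      rext <- sum(c(e$right_p1_kb, e$right_p2_kb), na.rm = TRUE)
      if (lext > 0 && e$origin_pos_kb - lext < rp && rp < e$origin_pos_kb) {
        arms[[length(arms) + 1L]] <- "left"
      }
      if (rext > 0 && e$origin_pos_kb < rp && rp < e$origin_pos_kb + rext) {
        arms[[length(arms) + 1L]] <- "right"
      }
    } else if (e$kind == "UNIDIRECTIONAL" && !is.na(e$span_start_kb)) {
      if (e$span_start_kb < rp && rp < e$span_end_kb) {
        arms[[length(arms) + 1L]] <- e$direction
      }
    }
  }
  dirs <- unlist(arms)
  if (is.null(dirs)) dirs <- character(0)
  # "+" strand: transcription runs left to right in the region frame
  downstream_dir <- if (locus$gene_strand == "+") "left" else "right"
  leading <- sum(dirs == downstream_dir)
  lagging <- sum(dirs != downstream_dir)
  list(lagging = lagging, leading = leading,
       prop_leading = if (length(dirs)) leading / length(dirs) else NA_real_)
}

#' Unidirectional fork length statistics
#'
#' Lengths (total P1+P2 extent) of unidirectional structures, either over
#' the whole region or restricted to the central window — from the right
#' edge of the leftmost probe to the left edge of the rightmost probe
#' (the central probe plus the two probe-to-probe distances).
#'
#' @param events Event table.
#' @param locus A [locus_map()] (needed for `region_filter = "central"`).
#' @param region_filter `"all"` or `"central"`.
#' @return List with `lengths`, `n`, `mean`, `se`, `cv_pct` (CV uses the
#'   population standard deviation).
#' @export
unidirectional_length_stats <- function(events, locus = NULL,
                                        region_filter = c("all", "central")) {
  region_filter <- match.arg(region_filter)
  ev <- events[events$kind == "UNIDIRECTIONAL" & !is.na(events$length_kb), ,
               drop = FALSE]
  if (region_filter == "central") {
    stopifnot(inherits(locus, "locus_map"))
    win <- c(locus$probes$end_kb[1L],
             locus$probes$start_kb[nrow(locus$probes)])
    ev <- ev[ev$span_start_kb >= win[1] & ev$span_end_kb <= win[2], ,
             drop = FALSE]
  }
  x <- ev$length_kb
  n <- length(x)
  if (n == 0L) {
    return(list(lengths = numeric(0), n = 0L, mean = NA_real_, se = NA_real_,
                cv_pct = NA_real_))
  }
  m <- mean(x)
  sd_pop <- sqrt(mean((x - m)^2))
  list(
    lengths = x, n = n, mean = m,
    se = if (n > 1L) stats::sd(x) / sqrt(n) else 0,
    cv_pct = if (m > 0) 100 * sd_pop / m else NA_real_
  )
}

#' Summarize a sample's replication profile
#'
#' Aggregates classified events into the summary used to describe a
#' sample's replication profile: replicating fraction, fork counts and
#' percentages by kind, fork-rate and inter-origin-distance statistics,
#' unidirectional-fork lengths and gene-origin counts. Because it is not
#' stated whether fork-rate N counts forks or arms, both are reported.
#'
#' @param sample_name Sample label.
#' @param molecules Oriented molecules that were classified.
#' @param events Event table for those molecules.
#' @param locus A [locus_map()].
#' @param n_total_molecules Total observed informative molecules (defaults
#'   to `length(molecules)`).
#' @return An object of class `replication_profile`.
#' @export
summarize_profile <- function(sample_name, molecules, events, locus,
                              n_total_molecules = length(molecules)) {
  replicating_ids <- unique(events$molecule_id[events$kind %in% FORK_KINDS])
  n_rep <- length(replicating_ids)
  forks <- events[events$kind %in% FORK_KINDS, , drop = FALSE]
  n_forks <- nrow(forks)
  kind_counts <- vapply(FORK_KINDS, function(k) sum(forks$kind == k),
                        integer(1))
  fre <- fork_rate_estimate(events)
  rates <- fre$rates_complete
  n_rate_events <- sum(!is.na(forks$rate_kb_min[forks$kind ==
                                                  "BIDIRECTIONAL"]))
  iods <- inter_origin_distances(events)
  stat5 <- function(x) {
    n <- length(x)
    if (n == 0L) {
      return(list(mean = NA_real_, se = NA_real_, median = NA_real_,
                  n = 0L, min = NA_real_, max = NA_real_))
    }
    list(mean = mean(x), se = if (n > 1) stats::sd(x) / sqrt(n) else 0,
         median = stats::median(x), n = n, min = min(x), max = max(x))
  }
  gos <- gene_origin_stats(events, locus)
  structure(
    list(
      sample = sample_name,
      total_molecules = n_total_molecules,
      replicating_molecules = n_rep,
      replicating_fraction_pct = if (n_total_molecules > 0)
        replicating_fraction(n_rep, n_total_molecules) else NA_real_,
      total_forks = n_forks,
      fork_counts = kind_counts,
      fork_pct = if (n_forks > 0) round(100 * kind_counts / n_forks, 1)
        else kind_counts * NA_real_,
      fork_rate = c(stat5(rates), n_events = n_rate_events),
      iod = stat5(iods),
      unidirectional_all = unidirectional_length_stats(events, locus, "all"),
      unidirectional_central =
        unidirectional_length_stats(events, locus, "central"),
      origin_positions_kb = sort(events$origin_pos_kb[
        events$kind %in% ORIGIN_KINDS & !is.na(events$origin_pos_kb)]),
      pause_positions_kb = sort(c(
        events$pause_pos_kb[!is.na(events$pause_pos_kb)],
        events$pause_pos2_kb[!is.na(events$pause_pos2_kb)])),
      gene_origins = gos,
      excluded = sum(events$kind == "AMBIGUOUS_EXCLUDED"),
      terminations = sum(events$kind == "TERMINATION")
    ),
    class = "replication_profile"
  )
}

#' @export
print.replication_profile <- function(x, ...) {
  cat(sprintf("Replication profile: %s\n", x$sample))
  cat(sprintf("  molecules: %d total, %d replicating (%.1f%%)\n",
              x$total_molecules, x$replicating_molecules,
              x$replicating_fraction_pct))
  cat(sprintf("  forks: %d total\n", x$total_forks))
  for (k in names(x$fork_counts)) {
    cat(sprintf("    %-18s %3d (%.1f%%)\n", k, x$fork_counts[[k]],
                x$fork_pct[[k]]))
  }
  fr <- x$fork_rate
  if (fr$n > 0) {
    cat(sprintf("  fork rate: mean %.2f +/- %.3f kb/min, median %.2f (N=%d arms / %d complete events)\n",
                fr$mean, fr$se, fr$median, fr$n, fr$n_events))
  }
  io <- x$iod
  if (io$n > 0) {
    cat(sprintf("  IOD: mean %.1f +/- %.2f kb, median %.1f (N=%d)\n",
                io$mean, io$se, io$median, io$n))
  }
  cat(sprintf("  origins in gene: %d (on %d molecules)\n",
              x$gene_origins$origins_in_gene,
              x$gene_origins$molecules_with_gene_origin))
  invisible(x)
}

#' Compare samples' distributions by the Kruskal-Wallis test
#'
#' @param values A named list of numeric vectors (one per sample):
#'   fork rates, inter-origin distances or unidirectional fork lengths.
#' @return List with `H` (tie-corrected statistic), `df` and `p`.
#' @export
compare_profiles <- function(values) {
  if (length(values) < 2L) {
    stop("need at least two samples to compare", call. = FALSE)
  }
  if (any(!vapply(values, length, integer(1)))) {
    stop("empty sample in comparison", call. = FALSE)
  }
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), vapply(values, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
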