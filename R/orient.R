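#' Orient a molecule against the locus probe template
#'
#' Matches the observed probe signals (lengths and inter-signal gaps) to the
#' locus map's probe template, in both reading directions, within a relative
#' tolerance. Because the two inter-probe gaps of the template are unequal,
#' a fiber showing at least two probe signals can usually be oriented from
#' geometry alone; when both readings fit, the far-red co-label on the
#' central probe decides, and if it was not observed the molecule is
#' rejected rather than guessed.
#'
#' The anchor (region-relative kb of molecule coordinate 0) is fit by least
#' squares on the matched probe midpoints, which is robust to partial probe
#' hybridization at fragment ends.
#'
#' @param m A [molecule()] in kb units.
#' @param locus A [locus_map()].
#' @param tol_frac Relative tolerance on probe lengths and gaps (in (0,
#'   0.5)); default 0.10, reflecting typical combing stretch variability.
#' @return The oriented molecule (flipped if needed, `oriented = TRUE`,
#'   `anchor_offset_kb` set), or a `non_informative` object carrying a
#'   `reason` (one of `"too_few_probes"`, `"no_template_match"`,
#'   `"ambiguous_orientation"`).
#' @export
orient_molecule <- function(m, locus, tol_frac = 0.10) {
  stopifnot(inherits(m, "molecule"), inherits(locus, "locus_map"))
  if (m$units != "kb") {
    stop("orient_molecule() expects a molecule in kb units", call. = FALSE)
  }
  if (!(tol_frac > 0 && tol_frac < 0.5)) {
    stop("`tol_frac` must be in (0, 0.5)", call. = FALSE)
  }
  if (nrow(m$probe_signals) < 2L) {
    return(non_informative(m$molecule_id, "too_few_probes"))
  }

  fwd <- match_probe_template(m, locus, tol_frac)
  m_rev <- reverse_molecule(m)
  rev <- match_probe_template(m_rev, locus, tol_frac)

  if (is.null(fwd) && is.null(rev)) {
    return(non_informative(m$molecule_id, "no_template_match"))
  }
  if (!is.null(fwd) && !is.null(rev)) {
    # both readings fit geometrically: decide by the far-red flag
    fwd_ok <- flag_consistent(m, locus, fwd)
    rev_ok <- flag_consistent(m_rev, locus, rev)
    if (fwd_ok && !rev_ok) {
      rev <- NULL
    } else if (rev_ok && !fwd_ok) {
      fwd <- NULL
    } else {
      return(non_informative(m$molecule_id, "ambiguous_orientation"))
    }
  }
  if (!is.null(fwd)) {
    out <- m
    fit <- fwd
  } else {
    out <- m_rev
    fit <- rev
  }
  out$oriented <- TRUE
  out$anchor_offset_kb <- fit$offset
  out
}

# Match the (sorted) observed probe signals of `m` against a contiguous
# window of the template probes. The first and last observed signal may be
# truncated at a fragment end (and fragment ends are invisible without a
# counterstain), so terminal signals are only required not to EXCEED the
# template probe length; interior signals and all inter-signal gaps must
# match within the relative tolerance. The anchor is fit by least squares
# on reliable landmarks: the midpoints of interior signals and the inner
# edges of the terminal signals (which truncation cannot move).
# Returns NULL or list(offset, rss, window).
match_probe_template <- function(m, locus, tol_frac) {
  obs <- m$probe_signals
  k <- nrow(obs)
  tmpl <- locus$probes
  n <- nrow(tmpl)
  if (k > n) return(NULL)
  obs_len <- obs$end - obs$start
  obs_gap <- if (k > 1L) obs$start[-1L] - obs$end[-k] else numeric(0)
  tmpl_len <- tmpl$end_kb - tmpl$start_kb
  tmpl_gap <- probe_gaps(locus)

  best <- NULL
  for (w in seq_len(n - k + 1L)) {
    idx <- w:(w + k - 1L)
    terminal <- seq_len(k) %in% c(1L, k)
    len_ok <- all(ifelse(
      terminal,
      obs_len <= (1 + tol_frac) * tmpl_len[idx],
      abs(obs_len - tmpl_len[idx]) <= tol_frac * tmpl_len[idx]
    ))
    gidx <- if (k > 1L) idx[-k] else integer(0)
    gap_ok <- all(abs(obs_gap - tmpl_gap[gidx]) <= tol_frac * tmpl_gap[gidx])
    if (len_ok && gap_ok) {
      # landmarks: inner edge of first/last signal, midpoint of the rest
      obs_pt <- (obs$start + obs$end) / 2
      tmpl_pt <- (tmpl$start_kb[idx] + tmpl$end_kb[idx]) / 2
      obs_pt[1L] <- obs$end[1L]
      tmpl_pt[1L] <- tmpl$end_kb[idx[1L]]
      obs_pt[k] <- obs$start[k]
      tmpl_pt[k] <- tmpl$start_kb[idx[k]]
      offset <- mean(tmpl_pt - obs_pt)
      rss <- sum((tmpl_pt - (obs_pt + offset))^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(offset = offset, rss = rss, window = idx)
      }
    }
  }
  best
}

# Does the observed far-red flag fall on the template probe that carries it?
flag_consistent <- function(m, locus, fit) {
  obs_flag <- which(m$probe_signals$flag)
  if (length(obs_flag) != 1L) return(FALSE)
  tmpl_flag <- which(locus$probes$orientation_flag)
  if (length(tmpl_flag) != 1L) return(FALSE)
  fit$window[obs_flag] == tmpl_flag
}

non_informative <- function(molecule_id, reason) {
  structure(list(molecule_id = molecule_id, reason = reason),
            class = "non_informative")
}

#' @rdname orient_molecule
#' @param x An object.
#' @export
is_non_informative <- function(x) inherits(x, "non_informative")

#' Orient a set of molecules
#'
#' Applies [orient_molecule()] to each molecule; molecules already oriented
#' are passed through unchanged.
#'
#' @inheritParams orient_molecule
#' @param molecules A list of [molecule()] objects.
#' @return A list with elements `oriented` (list of oriented molecules) and
#'   `rejected` (data frame `molecule_id`, `reason`).
#' @export
orient_molecules <- function(molecules, locus, tol_frac = 0.10) {
  res <- lapply(molecules, function(m) {
    if (isTRUE(m$oriented)) m else orient_molecule(m, locus, tol_frac)
  })
  bad <- vapply(res, is_non_informative, logical(1))
  rejected <- if (any(bad)) {
    data.frame(
      molecule_id = vapply(res[bad], `[[`, character(1), "molecule_id"),
      reason = vapply(res[bad], `[[`, character(1), "reason"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(molecule_id = character(0), reason = character(0))
  }
  list(oriented = res[!bad], rejected = rejected)
}
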