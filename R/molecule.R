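#' A combed DNA molecule with labeled tracks and probe signals
#'
#' One stretched fiber as measured on the image: intervals of first-pulse
#' (`"P1"`, IdU, blue) and second-pulse (`"P2"`, CldU, red) incorporation,
#' plus the observed probe hybridization signals. Coordinates are molecule-
#' local (0 near one fragment end) in the declared units; after
#' [orient_molecule()] the molecule is flagged `oriented` and carries
#' `anchor_offset_kb`, the region-relative kb position of molecule
#' coordinate 0.
#'
#' @param molecule_id Molecule identifier (string).
#' @param tracks Data frame with columns `start`, `end`, `label`
#'   (`"P1"`/`"P2"`). May have zero rows.
#' @param probe_signals Data frame with columns `start`, `end`, `flag`
#'   (logical: far-red orientation co-label observed). May have zero rows.
#' @param units One of `"px"`, `"um"`, `"kb"`.
#' @param oriented Logical; set by [orient_molecule()].
#' @param anchor_offset_kb Region-relative kb of molecule coordinate 0
#'   (only meaningful when `oriented`).
#' @return An object of class `molecule`.
#' @export
molecule <- function(molecule_id, tracks = empty_tracks(),
                     probe_signals = empty_probe_signals(),
                     units = c("kb", "um", "px"),
                     oriented = FALSE, anchor_offset_kb = NA_real_) {
  units <- match.arg(units)
  tracks <- validate_tracks(tracks, molecule_id)
  probe_signals <- validate_probe_signals(probe_signals, molecule_id)
  structure(
    list(
      molecule_id = as.character(molecule_id),
      tracks = tracks,
      probe_signals = probe_signals,
      units = units,
      oriented = isTRUE(oriented),
      anchor_offset_kb = anchor_offset_kb
    ),
    class = "molecule"
  )
}

#' @rdname molecule
#' @export
empty_tracks <- function() {
  data.frame(start = numeric(0), end = numeric(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' @rdname molecule
#' @export
empty_probe_signals <- function() {
  data.frame(start = numeric(0), end = numeric(0), flag = logical(0))
}

validate_tracks <- function(tracks, id) {
  stopifnot(is.data.frame(tracks),
            all(c("start", "end", "label") %in% names(tracks)))
  tracks <- tracks[, c("start", "end", "label")]
  if (nrow(tracks) == 0L) return(empty_tracks())
  if (!all(tracks$label %in% c("P1", "P2"))) {
    stop(sprintf("molecule '%s': unknown track label (expected P1 or P2)", id),
         call. = FALSE)
  }
  if (any(tracks$end <= tracks$start)) {
    stop(sprintf("molecule '%s': track interval with start >= end", id),
         call. = FALSE)
  }
  tracks <- tracks[order(tracks$start), , drop = FALSE]
  for (lab in c("P1", "P2")) {
    tl <- tracks[tracks$label == lab, , drop = FALSE]
    if (nrow(tl) > 1L && any(tl$end[-nrow(tl)] > tl$start[-1L] + 1e-9)) {
      stop(sprintf("molecule '%s': overlapping %s tracks", id, lab),
           call. = FALSE)
    }
  }
  rownames(tracks) <- NULL
  tracks
}

validate_probe_signals <- function(ps, id) {
  stopifnot(is.data.frame(ps), all(c("start", "end", "flag") %in% names(ps)))
  ps <- ps[, c("start", "end", "flag")]
  if (nrow(ps) == 0L) return(empty_probe_signals())
  if (any(ps$end <= ps$start)) {
    stop(sprintf("molecule '%s': probe signal with start >= end", id),
         call. = FALSE)
  }
  ps <- ps[order(ps$start), , drop = FALSE]
  ps$flag <- as.logical(ps$flag)
  rownames(ps) <- NULL
  ps
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("Molecule '%s' (%s)%s\n", x$molecule_id, x$units,
              if (x$oriented)
                sprintf(", oriented, anchor %.1f kb", x$anchor_offset_kb)
              else ""))
  cat(sprintf("  %d probe signal(s), %d labeled track(s)\n",
              nrow(x$probe_signals), nrow(x$tracks)))
  invisible(x)
}

#' Convert a molecule's coordinates to kb
#'
#' @param m A [molecule()].
#' @param cal A [calibration()] used when the molecule is in `px` or `um`.
#' @return The molecule with all coordinates in kb.
#' @export
molecule_to_kb <- function(m, cal = calibration()) {
  stopifnot(inherits(m, "molecule"))
  if (m$units == "kb") return(m)
  m$tracks$start <- .to_kb(m$tracks$start, m$units, cal)
  m$tracks$end <- .to_kb(m$tracks$end, m$units, cal)
  m$probe_signals$start <- .to_kb(m$probe_signals$start, m$units, cal)
  m$probe_signals$end <- .to_kb(m$probe_signals$end, m$units, cal)
  m$units <- "kb"
  m
}

#' Reverse a molecule's coordinate axis
#'
#' Mirrors all intervals about the molecule extent (reading the fiber from
#' the other end). Orientation state is reset.
#'
#' @param m A [molecule()].
#' @return The reversed, unoriented molecule.
#' @export
reverse_molecule <- function(m) {
  stopifnot(inherits(m, "molecule"))
  hi <- suppressWarnings(max(m$tracks$end, m$probe_signals$end, 0))
  lo <- suppressWarnings(min(m$tracks$start, m$probe_signals$start, hi))
  flip <- function(df) {
    if (nrow(df) == 0L) return(df)
    s <- lo + hi - df$end
    e <- lo + hi - df$start
    df$start <- s
    df$end <- e
    df[order(df$start), , drop = FALSE]
  }
  m$tracks <- flip(m$tracks)
  m$probe_signals <- flip(m$probe_signals)
  rownames(m$tracks) <- rownames(m$probe_signals) <- NULL
  m$oriented <- FALSE
  m$anchor_offset_kb <- NA_real_
  m
}

# molecule-local -> region-relative kb (requires orientation)
to_region <- function(m, x) {
  if (!isTRUE(m$oriented)) {
    stop(sprintf("molecule '%s' is not oriented", m$molecule_id),
         call. = FALSE)
  }
  x + m$anchor_offset_kb
}

#' Is a molecule informative?
#'
#' A molecule is informative when it shows at least two probe hybridization
#' signals, so that it can be recognised and oriented against the locus map.
#'
#' @param m A [molecule()].
#' @return Logical.
#' @export
is_informative <- function(m) {
  stopifnot(inherits(m, "molecule"))
  nrow(m$probe_signals) >= 2L
}
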