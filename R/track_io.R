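#' Read and write molecule-track tables
#'
#' The molecule-track TSV is the on-disk interchange format shared by the
#' simulator and the analyzer. Columns:
#' `molecule_id  record_type{PROBE|TRACK}  start  end  label  flag  units`,
#' where `label` is `P1`/`P2` for tracks and a probe name (or `"?"` when the
#' probe identity is unknown) for probe signals, `flag` is `0`/`1` (far-red
#' orientation co-label observed on a probe signal), and `units` is one of
#' `px`, `um`, `kb`. `#`-prefixed header lines carry the calibration and
#' locus name. All coordinates are converted to kb at load time using the
#' header calibration.
#'
#' @param path File path.
#' @param cal A [calibration()] used when the header carries none.
#' @return `read_track_table`: a list of [molecule()] objects (in kb), with
#'   attributes `locus_name` and `calibration`. `write_track_table`:
#'   invisibly, `path`.
#' @export
read_track_table <- function(path, cal = calibration()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    if (grepl("=", kv, fixed = TRUE)) {
      k <- sub("=.*$", "", kv)
      v <- sub("^[^=]*=", "", kv)
      meta[[trimws(k)]] <- trimws(v)
    }
  }
  if (!is.null(meta$stretch_kb_per_um) && !is.null(meta$pixel_um)) {
    cal <- calibration(as.numeric(meta$stretch_kb_per_um),
                       as.numeric(meta$pixel_um))
  }
  body_idx <- setdiff(seq_along(lines), hdr)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) == 0L) {
    return(structure(list(), locus_name = meta$locus,
                     calibration = cal, class = "molecule_set"))
  }
  first <- body_idx[1L]
  cols <- strsplit(lines[first], "\t", fixed = TRUE)[[1L]]
  expected <- c("molecule_id", "record_type", "start", "end",
                "label", "flag", "units")
  if (!identical(cols, expected)) {
    stop(sprintf("%s:%d: bad header (expected '%s')",
                 path, first, paste(expected, collapse = "\t")),
         call. = FALSE)
  }
  rows <- lapply(body_idx[-1L], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 7L) {
      stop(sprintf("%s:%d: expected 7 fields, got %d", path, i, length(f)),
           call. = FALSE)
    }
    st <- suppressWarnings(as.numeric(f[3L]))
    en <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(st) || is.na(en)) {
      stop(sprintf("%s:%d: non-numeric interval", path, i), call. = FALSE)
    }
    if (en <= st) {
      stop(sprintf("%s:%d: molecule '%s': interval start >= end",
                   path, i, f[1L]), call. = FALSE)
    }
    if (!f[2L] %in% c("PROBE", "TRACK")) {
      stop(sprintf("%s:%d: unknown record_type '%s'", path, i, f[2L]),
           call. = FALSE)
    }
    if (f[2L] == "TRACK" && !f[5L] %in% c("P1", "P2")) {
      stop(sprintf("%s:%d: molecule '%s': unknown track label '%s'",
                   path, i, f[1L], f[5L]), call. = FALSE)
    }
    if (!f[7L] %in% c("px", "um", "kb")) {
      stop(sprintf("%s:%d: unknown units '%s'", path, i, f[7L]),
           call. = FALSE)
    }
    data.frame(molecule_id = f[1L], record_type = f[2L], start = st, end = en,
               label = f[5L], flag = f[6L] == "1", units = f[7L],
               line = i, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mols <- lapply(unique(tab$molecule_id), function(id) {
    sub <- tab[tab$molecule_id == id, , drop = FALSE]
    u <- unique(sub$units)
    if (length(u) != 1L) {
      stop(sprintf("%s: molecule '%s': mixed units within one molecule",
                   path, id), call. = FALSE)
    }
    tr <- sub[sub$record_type == "TRACK", , drop = FALSE]
    pr <- sub[sub$record_type == "PROBE", , drop = FALSE]
    m <- molecule(
      id,
      tracks = data.frame(start = tr$start, end = tr$end, label = tr$label,
                          stringsAsFactors = FALSE),
      probe_signals = data.frame(start = pr$start, end = pr$end,
                                 flag = pr$flag),
      units = u
    )
    molecule_to_kb(m, cal)
  })
  structure(mols, locus_name = meta$locus, calibration = cal,
            class = "molecule_set")
}

#' @rdname read_track_table
#' @param molecules A list of [molecule()] objects.
#' @param locus_name Locus name written to the header.
#' @export
write_track_table <- function(molecules, path, cal = calibration(),
                              locus_name = "unknown") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# locus=%s", locus_name),
    sprintf("# stretch_kb_per_um=%g", cal$stretch_kb_per_um),
    sprintf("# pixel_um=%g", cal$pixel_um),
    paste(c("molecule_id", "record_type", "start", "end",
            "label", "flag", "units"), collapse = "\t")
  ), con)
  fmt <- function(x) sprintf("%.4f", x)
  for (m in molecules) {
    ps <- m$probe_signals
    for (i in seq_len(nrow(ps))) {
      writeLines(paste(m$molecule_id, "PROBE", fmt(ps$start[i]),
                       fmt(ps$end[i]), "?",
                       if (ps$flag[i]) "1" else "0", m$units, sep = "\t"),
                 con)
    }
    tr <- m$tracks
    for (i in seq_len(nrow(tr))) {
      writeLines(paste(m$molecule_id, "TRACK", fmt(tr$start[i]),
                       fmt(tr$end[i]), tr$label[i], "0", m$units, sep = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Export mapped positions as BED
#'
#' Writes origin (or pause) positions as 1-bp BED features in genomic
#' coordinates (0-based, half-open) for genome-browser viewing.
#'
#' @param events An event table from [classify_molecules()].
#' @param locus A [locus_map()] giving the genomic anchor.
#' @param path Output path.
#' @param what `"origin"` or `"pause"` positions.
#' @return Invisibly, `path`.
#' @export
write_positions_bed <- function(events, locus, path,
                                what = c("origin", "pause")) {
  what <- match.arg(what)
  col <- if (what == "origin") "origin_pos_kb" else "pause_pos_kb"
  ev <- events[!is.na(events[[col]]), , drop = FALSE]
  pos_bp <- as.integer(round(locus$region_start_bp + ev[[col]] * 1000))
  bed <- data.frame(
    chrom = rep(locus$chrom, nrow(ev)),
    start = pos_bp,
    end = pos_bp + 1L,
    name = paste0(ev$molecule_id, ":", tolower(ev$kind))
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
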