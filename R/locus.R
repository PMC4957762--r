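#' Probe specification
#'
#' One FISH probe (typically a BAC clone) hybridized along the combed locus,
#' given in region-relative kb. At most one probe of a locus map carries the
#' far-red orientation flag (a spectrally distinct co-label that identifies
#' the central probe even when only two of the three hybridization signals
#' are visible on a fiber).
#'
#' @param name Probe name (e.g. a BAC clone identifier).
#' @param start_kb,end_kb Region-relative interval in kb (0-based, half-open).
#' @param orientation_flag Logical; whether this probe carries the far-red
#'   co-label.
#' @return A one-row data frame with columns `name`, `start_kb`, `end_kb`,
#'   `orientation_flag`.
#' @export
probe_spec <- function(name, start_kb, end_kb, orientation_flag = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("probe `name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(start_kb) || !is.numeric(end_kb) ||
      !is.finite(start_kb) || !is.finite(end_kb) || end_kb <= start_kb) {
    stop(sprintf("probe '%s': interval must satisfy start < end", name),
         call. = FALSE)
  }
  data.frame(
    name = name, start_kb = as.numeric(start_kb), end_kb = as.numeric(end_kb),
    orientation_flag = isTRUE(orientation_flag),
    stringsAsFactors = FALSE
  )
}

#' Locus map: the genomic coordinate frame of a combed region
#'
#' Describes the region analysed on single fibers: its genomic anchor, the
#' FISH probes used to recognise and orient molecules, the gene interval of
#' interest and the position of the repeat tract inside it. All working
#' coordinates are region-relative kb (0-based, half-open); the genomic
#' anchor is kept symbolically so any locus can be described.
#'
#' The probe layout must be asymmetric: the two inter-probe gaps must differ
#' by more than the matching tolerance, otherwise fiber orientation from the
#' probe pattern alone would be ambiguous.
#'
#' @param region_name Name of the region (free text).
#' @param chrom Chromosome name.
#' @param region_start_bp,region_end_bp Genomic anchor in bp (0-based,
#'   half-open).
#' @param probes A data frame of [probe_spec()] rows (use `rbind`).
#' @param gene_interval_kb Length-2 numeric: the gene interval in
#'   region-relative kb. Must lie within the central probe.
#' @param repeat_pos_kb Position of the repeat tract in region-relative kb.
#'   Must lie within `gene_interval_kb`.
#' @param expanded Logical; `TRUE` models the mutant (repeat-expanded)
#'   allele, which licenses a dormant intragenic origin in the simulator.
#' @param gene_strand `"+"` or `"-"`: strand of the gene relative to the
#'   region frame (left-to-right is `"+"`).
#' @return An object of class `locus_map`.
#' @seealso [fxn_locus()] for the default 850 kb frataxin-region map.
#' @export
locus_map <- function(region_name, chrom, region_start_bp, region_end_bp,
                      probes, gene_interval_kb, repeat_pos_kb,
                      expanded = FALSE, gene_strand = c("+", "-")) {
  gene_strand <- match.arg(gene_strand)
  stopifnot(is.data.frame(probes),
            all(c("name", "start_kb", "end_kb", "orientation_flag") %in%
                  names(probes)))
  if (region_end_bp <= region_start_bp) {
    stop("region end must exceed region start", call. = FALSE)
  }
  probes <- probes[order(probes$start_kb), , drop = FALSE]
  rownames(probes) <- NULL
  n <- nrow(probes)
  if (n < 2L) stop("a locus map needs at least two probes", call. = FALSE)
  if (any(probes$end_kb[-n] > probes$start_kb[-1L])) {
    stop("probes must be non-overlapping and ordered left to right",
         call. = FALSE)
  }
  if (sum(probes$orientation_flag) > 1L) {
    stop("at most one probe may carry the orientation flag", call. = FALSE)
  }
  region_len_kb <- (region_end_bp - region_start_bp) / 1000
  if (any(probes$start_kb < 0) || any(probes$end_kb > region_len_kb)) {
    stop("probe intervals must lie within the region", call. = FALSE)
  }
  if (length(gene_interval_kb) != 2L || diff(gene_interval_kb) <= 0) {
    stop("`gene_interval_kb` must be an increasing length-2 interval",
         call. = FALSE)
  }
  if (repeat_pos_kb < gene_interval_kb[1] || repeat_pos_kb > gene_interval_kb[2]) {
    stop("`repeat_pos_kb` must lie within `gene_interval_kb`", call. = FALSE)
  }
  # the gene interval must fall inside one probe ('the central probe')
  host <- which(probes$start_kb <= gene_interval_kb[1] &
                probes$end_kb >= gene_interval_kb[2])
  if (length(host) != 1L) {
    stop("`gene_interval_kb` must lie within exactly one probe interval",
         call. = FALSE)
  }
  structure(
    list(
      region_name = region_name, chrom = chrom,
      region_start_bp = region_start_bp, region_end_bp = region_end_bp,
      region_len_kb = region_len_kb,
      probes = probes,
      gene_interval_kb = as.numeric(gene_interval_kb),
      repeat_pos_kb = as.numeric(repeat_pos_kb),
      expanded = isTRUE(expanded),
      gene_strand = gene_strand,
      central_probe = probes$name[host]
    ),
    class = "locus_map"
  )
}

#' @export
print.locus_map <- function(x, ...) {
  cat(sprintf("Locus map '%s' (%s:%d-%d, %.1f kb)%s\n",
              x$region_name, x$chrom, x$region_start_bp, x$region_end_bp,
              x$region_len_kb,
              if (x$expanded) " [expanded allele]" else ""))
  for (i in seq_len(nrow(x$probes))) {
    p <- x$probes[i, ]
    cat(sprintf("  probe %-12s [%7.1f, %7.1f) kb%s\n", p$name,
                p$start_kb, p$end_kb,
                if (p$orientation_flag) "  <far-red flag>" else ""))
  }
  cat(sprintf("  gene  [%0.1f, %0.1f) kb (%s strand), repeat at %.1f kb\n",
              x$gene_interval_kb[1], x$gene_interval_kb[2], x$gene_strand,
              x$repeat_pos_kb))
  invisible(x)
}

# inter-probe gaps, left to right
probe_gaps <- function(locus) {
  p <- locus$probes
  p$start_kb[-1L] - p$end_kb[-nrow(p)]
}

#' Default locus map of the 850 kb frataxin region
#'
#' Three differentially spaced BAC probes cover about 850 kb at 9q21 around
#' the FXN gene; the central probe carries the far-red orientation flag and
#' harbors the gene, whose intron-1 GAA repeat sits near the gene 5' end.
#' Probe extents are configuration values derived from BAC end coordinates
#' (they are not measured quantities); edit the YAML config to refine them.
#'
#' @param expanded Logical; model the mutant (GAA-expanded) allele.
#' @return A [locus_map()].
#' @export
fxn_locus <- function(expanded = FALSE) {
  locus_map(
    region_name = "FXN_850kb",
    chrom = "chr9",
    region_start_bp = 68643187L,
    region_end_bp = 69477097L,
    probes = rbind(
      probe_spec("RP11-203L2", 5, 175),
      probe_spec("RP11-265B8", 330, 505, orientation_flag = TRUE),
      probe_spec("RP11-548B3", 620, 800)
    ),
    gene_interval_kb = c(390, 430),
    repeat_pos_kb = 395,
    expanded = expanded,
    gene_strand = "+"
  )
}

#' Read / write a locus map as YAML
#'
#' Probe intervals are stored in bp relative to the genomic anchor so the
#' config can be lifted straight from BAC end coordinates.
#'
#' @param path Path to a YAML file.
#' @return `read_locus_yaml` returns a [locus_map()];
#'   `write_locus_yaml` invisibly returns `path`.
#' @export
read_locus_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("region_name", "chrom", "region_start_bp", "region_end_bp",
            "probes", "gene_interval_bp", "repeat_pos_bp")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop("locus config missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rel_kb <- function(bp) (bp - y$region_start_bp) / 1000
  probes <- do.call(rbind, lapply(y$probes, function(p) {
    probe_spec(p$name, rel_kb(p$start_bp), rel_kb(p$end_bp),
               isTRUE(p$orientation_flag))
  }))
  locus_map(
    region_name = y$region_name, chrom = y$chrom,
    region_start_bp = y$region_start_bp, region_end_bp = y$region_end_bp,
    probes = probes,
    gene_interval_kb = rel_kb(unlist(y$gene_interval_bp)),
    repeat_pos_kb = rel_kb(y$repeat_pos_bp),
    expanded = isTRUE(y$expanded),
    gene_strand = if (is.null(y$gene_strand)) "+" else y$gene_strand
  )
}

#' @rdname read_locus_yaml
#' @param locus A [locus_map()].
#' @export
write_locus_yaml <- function(locus, path) {
  abs_bp <- function(kb) as.integer(round(locus$region_start_bp + kb * 1000))
  y <- list(
    region_name = locus$region_name,
    chrom = locus$chrom,
    region_start_bp = locus$region_start_bp,
    region_end_bp = locus$region_end_bp,
    probes = lapply(seq_len(nrow(locus$probes)), function(i) {
      p <- locus$probes[i, ]
      list(name = p$name, start_bp = abs_bp(p$start_kb),
           end_bp = abs_bp(p$end_kb),
           orientation_flag = p$orientation_flag)
    }),
    gene_interval_bp = as.list(abs_bp(locus$gene_interval_kb)),
    repeat_pos_bp = abs_bp(locus$repeat_pos_kb),
    expanded = locus$expanded,
    gene_strand = locus$gene_strand
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
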