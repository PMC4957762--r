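#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Ct = slope * log10(copies) + intercept` over the
#' dilution series, with amplification efficiency
#' `100 * (10^(-1/slope) - 1)`.
#'
#' @param copies Vector of nominal copy numbers (>= 2 distinct levels).
#' @param ct Matching Ct values.
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `efficiency_pct`, `r_squared` and the range of interpolable Ct.
#' @export
fit_standard_curve <- function(copies, ct) {
  stopifnot(length(copies) == length(ct), all(copies > 0))
  if (length(unique(copies)) < 2L) {
    stop("need at least two distinct copy levels", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10(copies))
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    stop("assay failure: standard-curve slope is not negative",
         call. = FALSE)
  }
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1L]),
      efficiency_pct = 100 * (10^(-1 / slope) - 1),
      r_squared = stats::cor(ct, stats::fitted(fit))^2,
      ct_range = range(stats::fitted(fit)),
      points = data.frame(copies = copies, ct = ct)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.4f * log10(copies) + %.3f\n",
              x$slope, x$intercept))
  cat(sprintf("  efficiency %.1f%%, R^2 = %.4f\n", x$efficiency_pct,
              x$r_squared))
  invisible(x)
}

#' Quantify a Ct value against a standard curve
#'
#' @param ct Ct value(s); must fall within the curve's interpolable range
#'   extended by `extrapolate_ct` cycles.
#' @param curve A [fit_standard_curve()] object.
#' @param extrapolate_ct Allowed extrapolation in cycles.
#' @return Copy number(s) of genomic equivalents.
#' @export
quantify <- function(ct, curve, extrapolate_ct = 2) {
  stopifnot(inherits(curve, "standard_curve"))
  lo <- min(curve$ct_range) - extrapolate_ct
  hi <- max(curve$ct_range) + extrapolate_ct
  if (any(ct < lo | ct > hi)) {
    stop(sprintf("Ct outside interpolable range [%.2f, %.2f]", lo, hi),
         call. = FALSE)
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' The 1:3 serial-dilution copy levels of the standard curve
#'
#' @param start_copies Copies of genomic equivalents in the first point.
#' @param n_points Number of dilution points.
#' @param dilution Dilution factor between consecutive points.
#' @return Numeric vector of copy levels.
#' @export
dilution_series <- function(start_copies = 4.5e4, n_points = 6,
                            dilution = 3) {
  start_copies / dilution^(seq_len(n_points) - 1L)
}

#' Mean nascent-strand quantities per primer set
#'
#' Averages replicate quantities (genomic equivalents, from [quantify()])
#' per primer set for one sample.
#'
#' @param quantities Data frame with columns `primer_set`, `quantity`.
#' @return Named numeric vector of mean quantities.
#' @export
mean_quantities <- function(quantities) {
  stopifnot(all(c("primer_set", "quantity") %in% names(quantities)))
  if (any(quantities$quantity < 0)) {
    stop("quantities must be non-negative", call. = FALSE)
  }
  tapply(quantities$quantity, quantities$primer_set, mean)
}

#' Enrichment scheme A: normalization to the chromosome-9 control sites
#'
#' Each primer set's mean quantity is divided by the mean quantity over the
#' control primer sets (C1-C3). By construction the normalized control
#' values average exactly 1.
#'
#' @param q Named numeric vector of mean quantities per primer set.
#' @param control_sets Names of the control primer sets.
#' @return Named numeric vector of enrichment ratios.
#' @export
enrich_scheme_a <- function(q, control_sets = c("C1", "C2", "C3")) {
  miss <- setdiff(control_sets, names(q))
  if (length(miss)) {
    stop("missing control primer sets: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cm <- mean(q[control_sets])
  if (!is.finite(cm) || cm <= 0) {
    stop("control mean is zero: scheme A undefined", call. = FALSE)
  }
  q / cm
}

#' Enrichment scheme B: normalization to a non-origin site with an
#' origin-enrichment threshold
#'
#' Each primer set's quantity is divided by the quantity at the non-origin
#' reference site (LB2C1), then corrected by the enrichment fold measured
#' at the LAMIN B2 origin, which acts as the threshold: a corrected value
#' of 1 means the primer set is exactly as enriched as a bona fide origin.
#'
#' @param q Named numeric vector of mean quantities per primer set.
#' @param lb2_origin_enrichment_fold Mean LAMIN B2 origin enrichment
#'   (LB2 origin / LB2C1) for the cell line.
#' @param nonorigin_set Name of the non-origin reference primer set.
#' @param plausible_fold_range Quality-control range for the fold; a value
#'   outside it triggers a warning.
#' @return Named numeric vector of threshold-corrected values.
#' @export
enrich_scheme_b <- function(q, lb2_origin_enrichment_fold,
                            nonorigin_set = "LB2C1",
                            plausible_fold_range = c(5, 119)) {
  if (!is.finite(lb2_origin_enrichment_fold) ||
      lb2_origin_enrichment_fold <= 0) {
    stop("LAMIN B2 origin enrichment fold must be positive", call. = FALSE)
  }
  if (!nonorigin_set %in% names(q)) {
    stop("missing non-origin reference set: ", nonorigin_set, call. = FALSE)
  }
  if (q[[nonorigin_set]] <= 0) {
    stop("non-origin reference quantity must be positive", call. = FALSE)
  }
  if (lb2_origin_enrichment_fold < plausible_fold_range[1] ||
      lb2_origin_enrichment_fold > plausible_fold_range[2]) {
    warning(sprintf(
      "LAMIN B2 enrichment fold %.2f outside the plausible range [%g, %g]",
      lb2_origin_enrichment_fold, plausible_fold_range[1],
      plausible_fold_range[2]), call. = FALSE)
  }
  (q / q[[nonorigin_set]]) / lb2_origin_enrichment_fold
}

#' LAMIN B2 origin enrichment fold from one plate
#'
#' @param q Named numeric vector of mean quantities per primer set.
#' @param origin_set,nonorigin_set Primer set names.
#' @return Enrichment fold (origin / non-origin).
#' @export
lb2_enrichment_fold <- function(q, origin_set = "LB2_origin",
                                nonorigin_set = "LB2C1") {
  if (!all(c(origin_set, nonorigin_set) %in% names(q))) {
    stop("missing LAMIN B2 primer sets", call. = FALSE)
  }
  unname(q[[origin_set]] / q[[nonorigin_set]])
}

#' Pool enrichment values across cell lines or experiments
#'
#' Arithmetic mean and standard error of the per-sample enrichment values
#' for each primer set within each group.
#'
#' @param enrichments A list of named numeric vectors (one per sample),
#'   grouped by a `groups` factor of the same length.
#' @param groups Character/factor of group labels (e.g. "FRDA", "control").
#' @return Data frame `group`, `primer_set`, `mean`, `se`, `n`
#'   (`se` is 0, flagged by `se_defined = FALSE`, for single samples).
#' @export
pool_enrichments <- function(enrichments, groups) {
  stopifnot(length(enrichments) == length(groups), length(enrichments) > 0)
  groups <- as.character(groups)
  rows <- list()
  for (g in unique(groups)) {
    vs <- enrichments[groups == g]
    if (length(vs) == 0L) stop("empty group: ", g, call. = FALSE)
    sets <- unique(unlist(lapply(vs, names)))
    for (s in sets) {
      vals <- unlist(lapply(vs, function(v) v[[s]]))
      n <- length(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, primer_set = s, mean = mean(vals),
        se = if (n > 1L) stats::sd(vals) / sqrt(n) else 0,
        se_defined = n > 1L, n = n, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a qPCR plate table
#'
#' CSV columns: `sample, primer_set, well_type` (`standard`/`unknown`),
#' `copies_nominal` (standards only), `Ct`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_plate_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "primer_set", "well_type", "copies_nominal", "Ct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("plate table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$well_type %in% c("standard", "unknown"))) {
    stop("well_type must be 'standard' or 'unknown'", call. = FALSE)
  }
  tab
}

#' Quantify all unknowns on a plate against per-primer standard curves
#'
#' @param plate Data frame from [read_plate_table()].
#' @return Named numeric vector of mean quantities per primer set.
#' @export
quantify_plate <- function(plate) {
  sets <- unique(plate$primer_set)
  q <- lapply(sets, function(s) {
    std <- plate[plate$primer_set == s & plate$well_type == "standard", ]
    unk <- plate[plate$primer_set == s & plate$well_type == "unknown", ]
    if (nrow(std) < 2L || nrow(unk) == 0L) return(NA_real_)
    curve <- fit_standard_curve(std$copies_nominal, std$Ct)
    mean(quantify(unk$Ct, curve))
  })
  stats::setNames(unlist(q), sets)
}

#' Simulate a short-nascent-strand qPCR plate
#'
#' Generates a plate table for one sample: triplicate 1:3 standard curves
#' per primer set and replicate unknown wells whose Ct values follow the
#' true nascent-strand quantities with additive normal Ct noise.
#'
#' @param true_quantities Named numeric vector of true genomic-equivalent
#'   quantities per primer set.
#' @param sample_name Sample label.
#' @param n_replicates Replicate unknown wells per primer set.
#' @param ct_sd Additive Ct noise (cycles); standards get the same noise.
#' @param slope,intercept True amplification line. The default slope
#'   `-1/log10(2) = -3.3219` cycles per 10-fold dilution corresponds to
#'   100% amplification efficiency.
#' @param start_copies,n_points Standard-series layout.
#' @param seed Integer seed.
#' @return A plate data frame (see [read_plate_table()]).
#' @export
simulate_sns_plate <- function(true_quantities, sample_name = "sample",
                               n_replicates = 6, ct_sd = 0.25,
                               slope = -1 / log10(2), intercept = 35,
                               start_copies = 4.5e4, n_points = 6,
                               seed = 1L) {
  set.seed(seed)
  rows <- list()
  levels <- dilution_series(start_copies, n_points)
  for (s in names(true_quantities)) {
    for (rep_i in 1:3) {
      ct <- intercept + slope * log10(levels) +
        stats::rnorm(length(levels), 0, ct_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_name, primer_set = s, well_type = "standard",
        copies_nominal = levels, Ct = ct, stringsAsFactors = FALSE
      )
    }
    ct_u <- intercept + slope * log10(true_quantities[[s]]) +
      stats::rnorm(n_replicates, 0, ct_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample_name, primer_set = s, well_type = "unknown",
      copies_nominal = NA_real_, Ct = ct_u, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
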