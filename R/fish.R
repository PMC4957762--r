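FISH_PATTERNS <- c("SS", "SD", "DD", "OTHER")
FISH_SUBSTAGES <- c("early", "mid", "late")

#' Percentage and standard error of a proportion
#'
#' Binomial (Wald) standard error: `100 * sqrt(p(1-p)/n)` with `p = k/n`.
#' The percentage is reported to 1 decimal and the SE to 2 decimals.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (> 0).
#' @return List with `pct` and `se`.
#' @examples
#' proportion_se(67, 259)   # 25.9 +/- 2.72
#' @export
proportion_se <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n)) {
    stop("`k` and `n` must be single numbers", call. = FALSE)
  }
  if (n <= 0) stop("proportion undefined for n = 0", call. = FALSE)
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  p <- k / n
  list(pct = round(100 * p, 1), se = round(100 * sqrt(p * (1 - p) / n), 2))
}

#' Tabulate nucleus records into a replication-timing table
#'
#' Counts nuclei by FISH pattern (SS both alleles unreplicated, SD one
#' replicated, DD both replicated, OTHER) and S-phase substage (from the
#' CldU labeling pattern). Percentages and their SEs are reported per
#' substage column only when the substage total exceeds `min_cells`
#' (columns with 10 or fewer cells show bare counts).
#'
#' @param records Data frame with columns `pattern` and `substage`
#'   (and optionally `sample`, `fraction`).
#' @param min_cells Substage total above which percentages are reported.
#' @return An object of class `timing_table`: counts matrix
#'   (pattern x substage), `totals`, `pct` and `se` matrices (NA where
#'   suppressed), `s_phase_n` per pattern.
#' @export
build_timing_table <- function(records, min_cells = 10) {
  stopifnot(is.data.frame(records),
            all(c("pattern", "substage") %in% names(records)))
  bad_p <- setdiff(unique(records$pattern), FISH_PATTERNS)
  if (length(bad_p)) {
    stop("unknown pattern(s): ", paste(bad_p, collapse = ", "), call. = FALSE)
  }
  bad_s <- setdiff(unique(records$substage),
                   c(FISH_SUBSTAGES, "CldU_negative"))
  if (length(bad_s)) {
    stop("unknown substage(s): ", paste(bad_s, collapse = ", "),
         call. = FALSE)
  }
  s_rec <- records[records$substage %in% FISH_SUBSTAGES, , drop = FALSE]
  counts <- table(
    factor(s_rec$pattern, levels = FISH_PATTERNS),
    factor(s_rec$substage, levels = FISH_SUBSTAGES)
  )
  counts <- matrix(as.integer(counts), nrow = length(FISH_PATTERNS),
                   dimnames = list(FISH_PATTERNS, FISH_SUBSTAGES))
  timing_table_from_counts(counts,
                           total_cells = nrow(records),
                           min_cells = min_cells)
}

#' @rdname build_timing_table
#' @param counts Integer matrix pattern x substage (rows SS, SD, DD, OTHER;
#'   columns early, mid, late).
#' @param total_cells Total scored nuclei (defaults to the S-phase sum).
#' @export
timing_table_from_counts <- function(counts, total_cells = sum(counts),
                                     min_cells = 10) {
  stopifnot(is.matrix(counts), nrow(counts) == length(FISH_PATTERNS))
  dimnames(counts) <- list(FISH_PATTERNS, FISH_SUBSTAGES)
  totals <- colSums(counts)
  pct <- se <- matrix(NA_real_, nrow(counts), ncol(counts),
                      dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    if (totals[j] > min_cells) {
      for (i in seq_len(nrow(counts))) {
        ps <- proportion_se(counts[i, j], totals[j])
        pct[i, j] <- ps$pct
        se[i, j] <- ps$se
      }
    }
  }
  structure(
    list(counts = counts, totals = totals, pct = pct, se = se,
         s_phase_n = rowSums(counts), total_cells = total_cells,
         min_cells = min_cells),
    class = "timing_table"
  )
}

#' @export
print.timing_table <- function(x, ...) {
  cat("Replication-timing table (N, % +/- SE; bare N when substage total <=",
      x$min_cells, "cells)\n")
  for (i in rownames(x$counts)) {
    cells <- vapply(colnames(x$counts), function(j) {
      if (is.na(x$pct[i, j])) {
        sprintf("%d", x$counts[i, j])
      } else {
        sprintf("%d (%.1f +/- %.2f)", x$counts[i, j], x$pct[i, j],
                x$se[i, j])
      }
    }, character(1))
    cat(sprintf("  %-6s %s\n", i, paste(sprintf("%-22s", cells),
                                        collapse = " ")))
  }
  cat(sprintf("  totals %s\n",
              paste(sprintf("%-22d", x$totals), collapse = " ")))
  invisible(x)
}

#' FISH hybridization efficiency
#'
#' `100 * (SS + SD + DD + (S_single + D_single)/2) / total`, where
#' `S_single`/`D_single` are nuclei showing only one (single or duplicated)
#' signal.
#'
#' @param SS,SD,DD Counts of fully scored nuclei by pattern.
#' @param S_single,D_single Counts of one-signal nuclei.
#' @param total Total scored nuclei.
#' @return Efficiency percentage.
#' @export
hybridization_efficiency <- function(SS, SD, DD, S_single, D_single, total) {
  counts <- c(SS, SD, DD, S_single, D_single)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (total <= 0) {
    stop("hybridization efficiency undefined for total = 0", call. = FALSE)
  }
  if (total < SS + SD + DD + S_single + D_single) {
    stop("total must be at least the sum of categorized nuclei",
         call. = FALSE)
  }
  100 * (SS + SD + DD + (S_single + D_single) / 2) / total
}

#' Chi-square comparison of replication patterns between two samples
#'
#' Pearson chi-square (no continuity correction) on the 2 x k contingency
#' table of nucleus counts for one substage, restricted to the requested
#' pattern categories. A warning is issued when any expected cell count is
#' below 5.
#'
#' @param tableA,tableB [build_timing_table()] objects (or count matrices).
#' @param substage One of `"early"`, `"mid"`, `"late"`.
#' @param categories Pattern categories to include (with or without
#'   `"OTHER"`; which set was used for the published bounds is not stated,
#'   so both options are available).
#' @return List with `chi2`, `df`, `p`, `expected`.
#' @export
compare_patterns <- function(tableA, tableB, substage = "mid",
                             categories = c("SS", "SD", "DD", "OTHER")) {
  get_col <- function(tt) {
    cm <- if (inherits(tt, "timing_table")) tt$counts else tt
    cm[categories, substage]
  }
  m <- rbind(A = get_col(tableA), B = get_col(tableB))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    # drop all-zero categories; a zero margin otherwise is degenerate
    keep <- colSums(m) > 0
    m <- m[, keep, drop = FALSE]
    if (ncol(m) < 2L || any(rowSums(m) == 0)) {
      stop("degenerate contingency table (zero margin)", call. = FALSE)
    }
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(ct$expected < 5)) {
    warning("expected cell count below 5; chi-square approximation is weak",
            call. = FALSE)
  }
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Simulation parameters for sorted-nuclei FISH scoring
#'
#' Each nucleus carries two alleles that complete replication independently
#' with a per-fraction probability `p_complete[f]` (the locus replication
#' curve); the FISH pattern follows from the two allele states (SS, SD,
#' DD), a detection failure turns the nucleus into OTHER, and the CldU
#' substage is drawn from the fraction's substage row (modeling sorting
#' contamination).
#'
#' @param p_complete Named numeric: probability an allele has completed
#'   replication, per fraction (e.g. S1..S4).
#' @param substage_probs Matrix fractions x substages (rows sum to 1).
#' @param n_per_fraction Named integer vector of nuclei per fraction.
#' @param detection_failure_prob Probability a nucleus scores as OTHER.
#' @param seed Integer seed.
#' @return An object of class `timing_sim_params`.
#' @export
timing_sim_params <- function(p_complete,
                              substage_probs,
                              n_per_fraction,
                              detection_failure_prob = 0.05,
                              seed = 1L) {
  stopifnot(all(p_complete >= 0 & p_complete <= 1),
            detection_failure_prob >= 0, detection_failure_prob <= 1)
  substage_probs <- as.matrix(substage_probs)
  if (!all(abs(rowSums(substage_probs) - 1) < 1e-8)) {
    stop("substage probability rows must sum to 1", call. = FALSE)
  }
  if (!identical(sort(names(p_complete)), sort(rownames(substage_probs))) ||
      !identical(sort(names(p_complete)), sort(names(n_per_fraction)))) {
    stop("fraction names must agree across parameters", call. = FALSE)
  }
  structure(
    list(p_complete = p_complete, substage_probs = substage_probs,
         n_per_fraction = n_per_fraction,
         detection_failure_prob = detection_failure_prob, seed = seed),
    class = "timing_sim_params"
  )
}

#' Simulate sorted-nuclei FISH records
#'
#' @param params A [timing_sim_params()].
#' @return Data frame with columns `fraction`, `pattern`, `substage`.
#' @export
simulate_nuclei <- function(params) {
  stopifnot(inherits(params, "timing_sim_params"))
  set.seed(params$seed)
  out <- list()
  for (f in names(params$p_complete)) {
    n <- params$n_per_fraction[[f]]
    if (n == 0L) next
    p <- params$p_complete[[f]]
    done <- matrix(stats::runif(2L * n) < p, ncol = 2L)
    n_done <- rowSums(done)
    pattern <- c("SS", "SD", "DD")[n_done + 1L]
    fail <- stats::runif(n) < params$detection_failure_prob
    pattern[fail] <- "OTHER"
    sub <- sample(colnames(params$substage_probs), n, replace = TRUE,
                  prob = params$substage_probs[f, ])
    out[[f]] <- data.frame(fraction = f, pattern = pattern, substage = sub,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Published-style replication-timing counts for the FXN locus
#'
#' Loads the shipped fixture of raw nucleus counts by sample (control vs
#' FRDA pool), sorted fraction (S1-S4), FISH pattern and CldU substage.
#'
#' @return Data frame with columns `sample`, `fraction`, `pattern`,
#'   `substage`, `n`.
#' @export
fxn_timing_counts <- function() {
  path <- system.file("extdata", "fxn_timing_counts.tsv",
                      package = "replicomb", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Timing table for one sample and fraction from a counts data frame
#'
#' @param counts_df Data frame as returned by [fxn_timing_counts()].
#' @param sample_name,fraction Sample and fraction to tabulate.
#' @inheritParams build_timing_table
#' @return A [build_timing_table()] object.
#' @export
timing_table_for <- function(counts_df, sample_name, fraction,
                             min_cells = 10) {
  sub <- counts_df[counts_df$sample == sample_name &
                     counts_df$fraction == fraction, , drop = FALSE]
  m <- matrix(0L, length(FISH_PATTERNS), length(FISH_SUBSTAGES),
              dimnames = list(FISH_PATTERNS, FISH_SUBSTAGES))
  for (r in seq_len(nrow(sub))) {
    if (sub$substage[r] %in% FISH_SUBSTAGES) {
      m[sub$pattern[r], sub$substage[r]] <- sub$n[r]
    }
  }
  timing_table_from_counts(m, min_cells = min_cells)
}
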