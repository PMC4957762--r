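#' Published-style single-molecule profile counts for the FXN region
#'
#' Loads the shipped fixture of per-sample molecule and fork counts
#' (informative molecules, replicating molecules, forks by kind, and
#' bidirectional-origin counts within the central probe region) for the
#' four lymphoblastoid cell lines.
#'
#' @return Data frame, one row per cell line.
#' @export
fxn_combing_counts <- function() {
  path <- system.file("extdata", "fxn_combing_counts.tsv",
                      package = "replicomb", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Summary ratios from profile count data
#'
#' Computes, from raw per-sample counts, the printed summary ratios of a
#' replication profile: the replicating-molecule fraction, fork-kind
#' percentages and the number of bidirectional origins per origin-bearing
#' molecule in the central probe region.
#'
#' @param counts Data frame as from [fxn_combing_counts()].
#' @return The data frame with added columns `replicating_fraction_pct`,
#'   `unidirectional_pct`, `paused_pct`, `asynchronous_pct`,
#'   `origins_per_origin_molecule`.
#' @export
profile_count_ratios <- function(counts = fxn_combing_counts()) {
  counts$replicating_fraction_pct <-
    round(100 * counts$replicating_molecules / counts$total_molecules, 1)
  counts$unidirectional_pct <-
    round(100 * counts$unidirectional_n / counts$total_forks, 1)
  counts$paused_pct <- round(100 * counts$paused_n / counts$total_forks, 1)
  counts$asynchronous_pct <-
    round(100 * counts$asynchronous_n / counts$total_forks, 1)
  counts$origins_per_origin_molecule <-
    round(counts$central_origins / counts$central_origin_molecules, 2)
  counts
}

#' Write a profile summary as a text report
#'
#' @param profiles A list of `replication_profile` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_profile_report <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  on.exit(sink(), add = TRUE, after = FALSE)
  for (p in profiles) print(p)
  invisible(path)
}

#' Export a replication profile as JSON
#'
#' @param profile A `replication_profile`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_profile_json <- function(profile, path) {
  x <- unclass(profile)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
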