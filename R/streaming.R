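#' Streaming membership queries
#'
#' Looks up every consecutive k-mer window of each pattern, window by window
#' identical to independent [dict_lookup()] calls, but with cached state:
#' the previous window's minimizer and bucket are reused while the minimizer
#' is unchanged (including the definitive skip when it is not a stored
#' minimizer at all), and a confirmed match is first extended to the
#' adjacent position in the stored strings -- forward after a forward-strand
#' match, backward after a reverse-complement match, which is what keeps
#' reverse-complemented patterns from rescanning their bucket once per
#' window. Every fast path re-verifies the k-mer against the strings and
#' endpoints before acceptance. State is reset at pattern boundaries and at
#' windows containing non-ACGT characters (reported absent).
#'
#' @param d A `kmer_dict`.
#' @param patterns Character vector of patterns, each of length >= k
#'   (shorter patterns contribute no windows).
#' @param orientation_cache Keep the orientation of the last match and
#'   extend in that direction; `FALSE` always extends forward (exposed only
#'   to measure what the orientation cache buys).
#' @return A data.frame with one row per window: `pattern` (1-based index
#'   into `patterns`), `window` (0-based start), `id`, `orientation`. The
#'   `counters` attribute aggregates instrumentation: `f_evals`,
#'   `skew_evals`, `bucket_scans`, `superkmers_scanned`,
#'   `kmer_comparisons`, `extension_attempts`, `extensions`.
#' @seealso [stream_stats()]
#' @export
stream_query <- function(d, patterns, orientation_cache = TRUE) {
  stopifnot(inherits(d, "kmer_dict"))
  res <- cpp_stream_query(d$ptr, toupper(as.character(patterns)),
                          isTRUE(orientation_cache))
  out <- res$results
  attr(out, "counters") <- res$counters
  out
}

#' Summarize a streaming run
#'
#' @param results The data.frame returned by [stream_query()].
#' @return A list: `windows`, `hits`, `misses`, `hit_fraction`, plus the
#'   instrumentation counters of the run. Totals are recomputed from the
#'   per-window rows, so `hits + misses == windows` by construction.
#' @export
stream_stats <- function(results) {
  counters <- attr(results, "counters")
  hits <- sum(results$id >= 0)
  windows <- nrow(results)
  c(list(windows = windows, hits = hits, misses = windows - hits,
         hit_fraction = if (windows) hits / windows else NA_real_),
    counters)
}
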