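#' Seeded hash of m-mers
#'
#' The 64-bit hash h defining the random minimizer order. Operates on the
#' 2-bit packing of the m-mer, not its text; deterministic for a fixed seed.
#'
#' @param mmers Character vector of m-mers (length at most 32).
#' @param seed Integer seed.
#' @return Character vector of 16-digit lower-case hex hash values (64 bits
#'   do not fit exactly in a double, so the full value is returned as text;
#'   lexicographic order on the hex strings equals numeric order).
#' @export
mmer_hash <- function(mmers, seed = 1) {
  cpp_mmer_hash(as.character(mmers), seed)
}

#' Minimizer of k-mers
#'
#' The minimizer of a k-mer g is the m-mer of g smallest under the random
#' order induced by the seeded hash [mmer_hash()]; ties within a window are
#' broken towards the leftmost position. In canonical modality the minimizer
#' is the smaller of the minimizer of g and that of `revcomp(g)` under the
#' same order (the reverse strand is read in its own left-to-right
#' direction), which guarantees that g and its reverse complement share one
#' minimizer and hence one dictionary bucket.
#'
#' @param kmers Character vector of k-mers (all of one length k >= m).
#' @param m Minimizer length (1 <= m <= min(k, 32)).
#' @param seed Integer seed of the hash order.
#' @param canonical Use the double-strand (canonical) selection rule.
#' @return A data.frame with one row per k-mer: `mmer` (the minimizer, in
#'   its winning orientation), `pos` (0-based start of the m-mer within the
#'   k-mer, forward coordinates), `strand` ("forward" or "reverse").
#' @examples
#' kmer_minimizer("ACGTACGTACGT", m = 4)
#' @export
kmer_minimizer <- function(kmers, m, seed = 1, canonical = FALSE) {
  cpp_minimizer(as.character(kmers), as.integer(m), seed, isTRUE(canonical))
}

#' Parse super-k-mers
#'
#' Partitions the k-mers of each string, left to right, into maximal runs
#' sharing one minimizer -- the super-k-mers. A run is closed after
#' `k - m + 1` k-mers even if the minimizer value persists, so parse-time
#' windows and query-time scan windows coincide. Consecutive super-k-mers of
#' one string overlap by exactly `k - 1` bases and together tile all its
#' k-mers.
#'
#' @param strings Character vector of DNA strings, each of length >= k.
#' @param k K-mer length.
#' @param m Minimizer length.
#' @param seed Hash seed.
#' @param canonical Canonical (double-strand) minimizer selection.
#' @return A data.frame with one row per super-k-mer: `string_index`
#'   (0-based), `offset` (0-based absolute position of its first base in the
#'   concatenated strings), `length` (bases), `n_kmers`, `minimizer`.
#' @examples
#' parse_super_kmers("ACGTACGTACGTACGT", k = 8, m = 4)
#' @export
parse_super_kmers <- function(strings, k, m, seed = 1, canonical = FALSE) {
  cpp_parse_super_kmers(as.character(strings), as.integer(k), as.integer(m),
                        seed, isTRUE(canonical))
}

#' Count super-k-mers of a single string
#'
#' Cheap variant of [parse_super_kmers()] that returns only the run count,
#' used for density measurements on long random strings.
#'
#' @inheritParams parse_super_kmers
#' @param s A single DNA string.
#' @return The number of super-k-mers (scalar).
#' @export
count_super_kmers <- function(s, k, m, seed = 1, canonical = FALSE) {
  stopifnot(length(s) == 1L)
  cpp_count_super_kmers(s, as.integer(k), as.integer(m), seed, isTRUE(canonical))
}
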