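#' Generate a synthetic path cover
#'
#' Deterministic random cover strings with no duplicate canonical k-mers
#' (strings that would introduce one are regenerated, mimicking the
#' disjoint-node guarantee of a real path cover). An optional heavy-bucket
#' motif is implanted every `heavy_every` bases of every string: its m-mers
#' then recur throughout the collection and the minimizer they win lands
#' many super-k-mers in one bucket, which is how the skew-index code paths
#' are exercised without genome-scale data.
#'
#' @param p Number of strings.
#' @param len_range Length range `c(min, max)` per string (min >= k).
#' @param k K-mer length (used for the duplicate check).
#' @param seed Integer seed; identical seeds give identical covers.
#' @param heavy_motif Optional motif (length >= the minimizer length you
#'   will index with) to implant.
#' @param heavy_every Implant stride in bases (0 = no implant).
#' @return Character vector of `p` strings, with attributes `n`, `p`, `N`.
#' @examples
#' cover <- gen_cover(p = 4, len_range = c(101, 102), k = 31, seed = 1)
#' attr(cover, "n")  # sum(nchar(cover)) - 4 * 30
#' @export
gen_cover <- function(p, len_range, k = 31L, seed = 1,
                      heavy_motif = NULL, heavy_every = 0) {
  stopifnot(length(len_range) == 2L, len_range[1] >= k)
  out <- cpp_gen_cover(p, len_range[1], len_range[2], as.integer(k), seed,
                       if (is.null(heavy_motif)) "" else toupper(heavy_motif),
                       heavy_every)
  N <- sum(nchar(out))
  structure(out, n = N - p * (k - 1), p = p, N = N)
}

#' Uniform random DNA
#'
#' @param len Number of bases.
#' @param seed Integer seed.
#' @return A single ACGT string.
#' @export
random_dna <- function(len, seed = 1) {
  cpp_random_dna(len, seed)
}

#' Generate query workloads
#'
#' Patterns for benchmarking and testing the dictionary. `high_hit` mixes
#' positive patterns (substrings sampled uniformly from the cover, half of
#' them reverse-complemented) with random patterns so that at least 70% of
#' all query windows are stored; `low_hit` uses random patterns only, for a
#' hit fraction below 1%.
#'
#' @param cover Character vector of cover strings.
#' @param workload `"high_hit"` or `"low_hit"`.
#' @param n_queries Number of patterns.
#' @param pattern_len Pattern length (capped at the sampled string's
#'   length).
#' @param seed Integer seed.
#' @param frac_positive Fraction of positive patterns in the `high_hit`
#'   workload.
#' @return Character vector of patterns.
#' @export
gen_queries <- function(cover, workload = c("high_hit", "low_hit"),
                        n_queries = 100, pattern_len = 100, seed = 1,
                        frac_positive = 0.85) {
  workload <- match.arg(workload)
  stopifnot(length(cover) > 0)
  if (n_queries == 0) return(character(0))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  n_pos <- if (workload == "high_hit") round(frac_positive * n_queries) else 0L
  pos <- character(0)
  if (n_pos > 0) {
    js <- sample.int(length(cover), n_pos, replace = TRUE,
                     prob = nchar(cover))
    pos <- vapply(js, function(j) {
      len <- min(pattern_len, nchar(cover[j]))
      at <- sample.int(nchar(cover[j]) - len + 1L, 1L)
      substr(cover[j], at, at + len - 1L)
    }, character(1))
    flip <- sample.int(n_pos) <= n_pos / 2  # half on the reverse strand
    pos[flip] <- revcomp(pos[flip])
  }
  neg <- vapply(seq_len(n_queries - n_pos),
                function(i) cpp_random_dna(pattern_len, seed + 7919 * i),
                character(1))
  out <- c(pos, neg)
  out[sample.int(length(out))]
}
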