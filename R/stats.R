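#' Space accounting and bucket-size distribution
#'
#' Per-component space report: 2N bits for the packed strings, the
#' Elias-Fano payloads of the endpoints and prefix-summed bucket sizes, the
#' minimizer MPHF, `z * ceiling(log2(N))` bits of offsets and the skew index
#' (per partition, MPHF plus compact vector), each also expressed per
#' k-mer. The report includes the bucket-size histogram (counts and
#' percentages, which sum to 100 up to rounding) and, for comparison, what
#' partitioning the strings *by super-k-mer* instead of addressing them by
#' absolute offset would cost: at least `2 + 2*z*(k-1)/n` bits/k-mer,
#' because every super-k-mer would then pay its k-1 tail bases again (see
#' [superkmer_partition_cost()]).
#'
#' @param d A `kmer_dict`.
#' @return An object of class `kmer_dict_stats`: a list with `components`
#'   (data.frame of bits and bits/k-mer), `total_bits`,
#'   `total_bits_per_kmer`, `superkmer_partition_bpk`, `skew_partitions`
#'   and `bucket_histogram` (with `percent`), plus the dictionary counts.
#' @export
dict_stats <- function(d) {
  stopifnot(inherits(d, "kmer_dict"))
  p <- cpp_dict_params(d$ptr)
  s <- cpp_dict_stats(d$ptr)
  comp <- data.frame(
    component = c("strings", "endpoints", "minimizer_mphf", "sizes",
                  "offsets", "skew_index"),
    bits = c(s$strings_bits, s$endpoints_bits, s$minimizer_mphf_bits,
             s$sizes_bits, s$offsets_bits, s$skew_bits),
    stringsAsFactors = FALSE)
  comp$bits_per_kmer <- comp$bits / p$n
  hist <- s$bucket_histogram
  hist$percent <- 100 * hist$count / sum(hist$count)
  structure(list(
    params = p,
    components = comp,
    total_bits = sum(comp$bits),
    total_bits_per_kmer = sum(comp$bits) / p$n,
    superkmer_partition_bpk = superkmer_partition_cost(p$z, p$n, p$k),
    offsets_width = s$offsets_width,
    skew_partitions = s$skew_partitions,
    bucket_histogram = hist,
    heavy_bucket_percent = heavy_bucket_fraction(hist$size, hist$percent, p$l)
  ), class = "kmer_dict_stats")
}

#' @export
print.kmer_dict_stats <- function(x, ...) {
  p <- x$params
  cat(sprintf("Space accounting: n = %g k-mers, z = %g super-k-mers, M = %g minimizers\n",
              p$n, p$z, p$M))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  %-15s %12.0f bits  (%6.3f bits/k-mer)\n",
                comp$component[i], comp$bits[i], comp$bits_per_kmer[i]))
  cat(sprintf("  %-15s %12.0f bits  (%6.3f bits/k-mer)\n", "total",
              x$total_bits, x$total_bits_per_kmer))
  cat(sprintf("  super-k-mer partitioning would cost >= %.2f bits/k-mer\n",
              x$superkmer_partition_bpk))
  h <- x$bucket_histogram
  show <- head(h[order(h$size), ], 5)
  cat("Bucket size distribution (%):",
      paste(sprintf("%g: %.1f", show$size, show$percent), collapse = ", "),
      sprintf("| > 2^%d: %.1f%%\n", p$l, x$heavy_bucket_percent))
  invisible(x)
}

#' Cost of the super-k-mer-partitioned layout
#'
#' The lower bound `2 + 2*z*(k-1)/n` bits/k-mer paid by a layout that stores
#' each super-k-mer as its own string: 2 bits/base for the k-mers plus the
#' duplicated `k-1`-base tail of each of the z super-k-mers. Addressing
#' super-k-mers by absolute offset into unbroken strings avoids the second
#' term, which is the point of the offsets array.
#'
#' @param z Number of super-k-mers.
#' @param n Number of k-mers.
#' @param k K-mer length.
#' @return Bits per k-mer (scalar).
#' @examples
#' superkmer_partition_cost(z = 28, n = 285, k = 31)
#' @export
superkmer_partition_cost <- function(z, n, k) {
  2 + 2 * z * (k - 1) / n
}

#' Fraction of buckets larger than 2^l
#'
#' Given a bucket-size distribution in percent, the percentage of buckets
#' with more than `2^l` super-k-mers, i.e. 100 minus the percentages of all
#' sizes up to `2^l` (which must all be present in `size`).
#'
#' @param size Bucket sizes.
#' @param percent Percentage of buckets of each size.
#' @param l Threshold exponent.
#' @return Percentage of heavy buckets.
#' @examples
#' # a sharply skewed distribution: sizes 1..4 cover 99.4% of buckets
#' heavy_bucket_fraction(1:4, c(97.1, 1.7, 0.4, 0.2), l = 2)
#' @export
heavy_bucket_fraction <- function(size, percent, l) {
  stopifnot(length(size) == length(percent))
  100 - sum(percent[size <= 2^l])
}
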