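#' Build a k-mer dictionary from a path cover
#'
#' Indexes a collection of DNA strings forming a de Bruijn graph path cover
#' (each string of length >= k, no duplicate k-mers across the collection
#' when a k-mer and its reverse complement are identified). The resulting
#' dictionary stores `n = N - p*(k-1)` k-mers, where `p` is the number of
#' strings and `N` their total length, and supports exact lookup, access,
#' iteration and streaming queries.
#'
#' The index comprises: the 2-bit packed `Strings` with Elias-Fano
#' `Endpoints`; a minimal perfect hash `f` over the `M` distinct minimizers;
#' prefix-summed Elias-Fano bucket `Sizes`; a `ceiling(log2(N))`-bit-wide
#' array of the `z` absolute super-k-mer `Offsets` laid out bucket by bucket
#' in the order of `f` (ascending within a bucket); and a skew index that
#' gives each k-mer of a bucket larger than `2^l` super-k-mers a direct
#' pointer to its super-k-mer, so a lookup never scans more than `2^l`
#' super-k-mers.
#'
#' @param strings Character vector: the cover strings (ACGT only, case
#'   normalized).
#' @param k K-mer length (2..63; 31 is the conventional default).
#' @param m Minimizer length; default `ceiling(log(N, 4)) + 1` clamped to
#'   `[1, min(k, 32)]`, so that there are at least as many possible
#'   minimizers as bases.
#' @param canonical Parsing modality. Regular (`FALSE`) buckets each strand
#'   separately and a lookup may inspect two buckets; canonical (`TRUE`)
#'   buckets by the double-strand minimizer so one bucket always suffices,
#'   at the price of more distinct minimizers.
#' @param l,L Skew-index thresholds, `0 <= l < L`: buckets with more than
#'   `2^l` super-k-mers are indexed by per-size-class minimal perfect hash
#'   functions, partitioned by `2^i < size <= 2^(i+1)` up to `2^L` (one top
#'   partition beyond).
#' @param seed Seed of every hash in the index (stored in the index header
#'   so query-time parsing matches build-time parsing).
#' @param skew Build the skew index (disable only to compare against full
#'   bucket scans).
#' @param verify Run a full duplicate-k-mer check on the input (the path
#'   cover contract already guarantees this, so it is off by default).
#' @return An object of class `kmer_dict`.
#' @examples
#' cover <- gen_cover(p = 4, len_range = c(60, 80), k = 31, seed = 7)
#' d <- dict_build(cover, k = 31, m = 8, seed = 7)
#' d
#' ids <- dict_lookup(d, substr(cover[1], 1, 31))
#' ids$id
#' @seealso [dict_lookup()], [dict_access()], [stream_query()], [dict_stats()]
#' @export
dict_build <- function(strings, k = 31L, m = NULL, canonical = FALSE,
                       l = 6L, L = 12L, seed = 1, skew = TRUE,
                       verify = FALSE) {
  strings <- toupper(as.character(strings))
  k <- as.integer(k)
  if (k < 2L || k > 63L) stop("k must be in 2..63")
  if (is.null(m)) m <- default_minimizer_length(sum(nchar(strings)), k)
  m <- as.integer(m)
  ptr <- cpp_dict_build(strings, k, m, isTRUE(canonical), as.integer(l),
                        as.integer(L), seed, isTRUE(skew), isTRUE(verify))
  structure(list(ptr = ptr), class = "kmer_dict")
}

#' Default minimizer length for an input of N bases
#'
#' `ceiling(log4(N)) + 1`, clamped to `[1, min(k, 32)]`: the recommended
#' choice giving at least as many possible minimizers as input bases.
#'
#' @param N Total number of bases.
#' @param k K-mer length (clamp bound).
#' @return Integer minimizer length.
#' @export
default_minimizer_length <- function(N, k) {
  m <- as.integer(ceiling(log(max(N, 2), base = 4))) + 1L
  max(1L, min(m, as.integer(k), 32L))
}

#' Build a dictionary from a FASTA file
#'
#' Reads the path cover from a (optionally gzipped) FASTA file; headers are
#' ignored.
#'
#' @param path FASTA file of cover strings.
#' @inheritParams dict_build
#' @param ... Passed on to [dict_build()].
#' @return A `kmer_dict`.
#' @export
dict_build_fasta <- function(path, k = 31L, ...) {
  seqs <- read_sequences(path, format = "fasta")
  dict_build(seqs, k = k, ...)
}

#' Dictionary parameters and counts
#'
#' @param d A `kmer_dict`.
#' @return A list: configuration (`k`, `m`, `canonical`, `l`, `L`, `seed`,
#'   `skew_enabled`) and counts (`n` k-mers, `p` strings, `N` bases, `z`
#'   super-k-mers, `M` distinct minimizers, `max_bucket`).
#' @export
dict_params <- function(d) {
  stopifnot(inherits(d, "kmer_dict"))
  cpp_dict_params(d$ptr)
}

#' @export
print.kmer_dict <- function(x, ...) {
  p <- cpp_dict_params(x$ptr)
  cat(sprintf("kmer_dict (k = %d, m = %d, %s modality%s)\n", p$k, p$m,
              if (p$canonical) "canonical" else "regular",
              if (p$skew_enabled) "" else ", skew index disabled"))
  cat(sprintf("  %g k-mers in %g strings (%g bases), %g super-k-mers, %g minimizers\n",
              p$n, p$p, p$N, p$z, p$M))
  cat(sprintf("  largest bucket: %g super-k-mers (skew threshold 2^%d = %d)\n",
              p$max_bucket, p$l, 2^p$l))
  invisible(x)
}

#' Look up k-mers
#'
#' For each query k-mer g returns its unique identifier in `[0, n)` if g --
#' or, k-mers being identified with their reverse complements, `revcomp(g)`
#' -- is stored, and -1 otherwise. Absence is a result, not an error; query
#' windows containing non-ACGT characters are reported absent. In regular
#' modality the forward strand is searched first and the reverse complement
#' only on a miss; canonical modality inspects a single bucket.
#'
#' @param d A `kmer_dict`.
#' @param kmers Character vector of k-mers (each of the dictionary's k).
#' @param instrument Attach a `counters` attribute (hash evaluations, bucket
#'   scans, super-k-mers scanned, k-mer comparisons).
#' @return A data.frame with one row per query: `id` (-1 when absent),
#'   `orientation` ("forward", "reverse", "none"), the bucket window
#'   `begin`/`end` into the offsets array, and for hits the super-k-mer
#'   offset `t`, the match position `w` within it and the containing string
#'   index `j` (all 0-based; `id = t + w - j*(k-1)`).
#' @export
dict_lookup <- function(d, kmers, instrument = FALSE) {
  stopifnot(inherits(d, "kmer_dict"))
  res <- cpp_dict_lookup(d$ptr, as.character(kmers))
  out <- res$results
  if (isTRUE(instrument)) attr(out, "counters") <- res$counters
  out
}

#' Retrieve a k-mer by identifier
#'
#' Inverse of [dict_lookup()]: returns the k-mer whose identifier is `i`,
#' spelled as stored in the cover strings (so `dict_lookup()` of the result
#' returns `i` with forward orientation).
#'
#' @param d A `kmer_dict`.
#' @param ids Identifiers in `[0, n)`; out-of-range values are an error.
#' @return Character vector of k-mers.
#' @export
dict_access <- function(d, ids) {
  stopifnot(inherits(d, "kmer_dict"))
  p <- cpp_dict_params(d$ptr)
  ids <- as.numeric(ids)
  if (any(ids < 0 | ids >= p$n)) stop("identifiers must lie in [0, n)")
  cpp_dict_access(d$ptr, ids)
}

#' Enumerate all stored k-mers in identifier order
#'
#' Streams every k-mer exactly once, skipping the k-1 trailing alien windows
#' of each string; element `i + 1` of the result is `dict_access(d, i)`.
#'
#' @param d A `kmer_dict`.
#' @return Character vector of length n.
#' @export
dict_iterate <- function(d) {
  stopifnot(inherits(d, "kmer_dict"))
  cpp_dict_iterate(d$ptr)
}

#' Window validity at an absolute offset
#'
#' TRUE iff `[t, t+k)` lies within a single cover string, i.e. crosses no
#' string endpoint. Windows failing this are "alien": their bases are
#' adjacent only as a storage artifact and must never match a query.
#'
#' @param d A `kmer_dict`.
#' @param t Absolute 0-based offsets.
#' @return Logical vector.
#' @export
dict_is_valid_window <- function(d, t) {
  stopifnot(inherits(d, "kmer_dict"))
  cpp_dict_valid_window(d$ptr, as.numeric(t))
}

#' Save / load a dictionary
#'
#' The index is a single self-contained binary file: magic "SSHX", format
#' version, configuration, counts, then the serialized components
#' (little-endian throughout). Loading refuses files with a different magic
#' or version rather than answering queries from a misread layout.
#'
#' @param d A `kmer_dict`.
#' @param path File path.
#' @return `dict_load()` returns the reloaded `kmer_dict`; `dict_save()`
#'   returns `path` invisibly.
#' @export
dict_save <- function(d, path) {
  stopifnot(inherits(d, "kmer_dict"))
  cpp_dict_save(d$ptr, path.expand(path))
  invisible(path)
}

#' @rdname dict_save
#' @export
dict_load <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  structure(list(ptr = cpp_dict_load(path.expand(path))), class = "kmer_dict")
}

#' Skew-index partition of a bucket size
#'
#' A bucket of `s` super-k-mers is "small" (returned as `NA`) when
#' `ceiling(log2(s)) <= l` and is then scanned directly; otherwise it
#' belongs to the unique partition `i` with `2^i < s <= 2^(i+1)`, clamped
#' to `L`.
#'
#' @param s Bucket sizes (>= 1).
#' @param l,L Skew thresholds, `0 <= l < L`.
#' @return Integer partition indices, `NA` for small buckets.
#' @examples
#' skew_partition_of(13, l = 3, L = 12)  # 2^3 < 13 <= 2^4
#' skew_partition_of(2^6, l = 6, L = 12) # small
#' @export
skew_partition_of <- function(s, l = 6L, L = 12L) {
  if (l < 0 || L <= l) stop("need 0 <= l < L")
  out <- cpp_skew_partition_of(as.numeric(s), as.integer(l), as.integer(L))
  out[out < 0L] <- NA_integer_
  out
}

#' Bits per skew-index entry for a bucket size
#'
#' Entries of partition `i` store super-k-mer ranks below `2^(i+1)` and need
#' `i + 1` bits; the top occupied partition instead stores ranks up to the
#' largest bucket and needs `ceiling(log2(max_bucket))` bits.
#'
#' @param s Bucket size.
#' @param l,L Skew thresholds.
#' @param max_bucket Largest bucket size in the dictionary.
#' @return Bits per stored integer, `NA` for small buckets.
#' @examples
#' skew_value_width(13, l = 3, L = 12, max_bucket = 5000)   # 4 bits
#' skew_value_width(36000, l = 6, L = 12, max_bucket = 36000)  # 16 bits
#' @export
skew_value_width <- function(s, l = 6L, L = 12L, max_bucket) {
  i <- skew_partition_of(s, l, L)
  itop <- skew_partition_of(max_bucket, l, L)
  ifelse(is.na(i), NA_integer_,
         ifelse(i == itop, pmax(i + 1L, as.integer(ceiling(log2(max_bucket)))),
                i + 1L))
}
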