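#' Encode and decode DNA bases
#'
#' The fixed 2-bit alphabet mapping A=0, C=1, G=2, T=3, under which the
#' complement of a code is its XOR with 3. Lower-case input is accepted and
#' normalized; any other character is an error reporting the offending
#' position.
#'
#' @param s A single DNA string.
#' @param codes An integer vector of 2-bit codes in 0..3.
#' @return `encode_dna()` returns an integer vector of codes; `decode_dna()`
#'   the corresponding DNA string.
#' @examples
#' encode_dna("GATTACA")
#' decode_dna(encode_dna("GATTACA"))
#' @export
encode_dna <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  cpp_encode_bases(s)
}

#' @rdname encode_dna
#' @export
decode_dna <- function(codes) {
  cpp_decode_bases(as.integer(codes))
}

#' Reverse complement
#'
#' Vectorized reverse complement over `{A,C,G,T}` strings (any length).
#' An involution: `revcomp(revcomp(x))` is `x`.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "AAA"))
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x))
}

#' Pack a string collection into 2-bit form
#'
#' Concatenates the given strings into a vector of 2 bits per base (`2N` bits
#' for `N` total bases) and records the string endpoints
#' `E[0] = 0 < E[1] < ... < E[p] = N`, the structure every dictionary query
#' ultimately scans.
#'
#' @param strings Character vector of DNA strings.
#' @return An object of class `packed_dna`.
#' @examples
#' ps <- pack_dna(c("ACGTACGT", "GGGTTTAA"))
#' ps
#' unpack_dna(ps)
#' @export
pack_dna <- function(strings) {
  ptr <- cpp_pack_dna(as.character(strings))
  structure(list(ptr = ptr), class = "packed_dna")
}

#' @rdname pack_dna
#' @param ps A `packed_dna` object.
#' @export
unpack_dna <- function(ps) {
  stopifnot(inherits(ps, "packed_dna"))
  cpp_unpack_dna(ps$ptr)
}

#' @export
print.packed_dna <- function(x, ...) {
  info <- cpp_packed_info(x$ptr)
  cat(sprintf("packed_dna: %d strings, %d bases (%d bits)\n",
              info$p, info$N, 2 * info$N))
  invisible(x)
}

#' Endpoints of a packed collection
#'
#' @param ps A `packed_dna` object.
#' @return Numeric vector `E[0..p]` of cumulative string lengths (0-based
#'   offsets into the concatenation).
#' @export
dna_endpoints <- function(ps) {
  stopifnot(inherits(ps, "packed_dna"))
  cpp_packed_info(ps$ptr)$endpoints
}

#' Extract the k-mer at an absolute offset
#'
#' Decodes `Strings[t, t+k)`. The window must lie within a single string: a
#' window crossing a string endpoint is an "alien" window and raises an
#' error, as such windows never correspond to stored k-mers.
#'
#' @param ps A `packed_dna` object.
#' @param t Absolute 0-based offset into the concatenated strings.
#' @param k Window length.
#' @return The k bases starting at `t`, as a string.
#' @export
kmer_at <- function(ps, t, k) {
  stopifnot(inherits(ps, "packed_dna"))
  vapply(t, function(tt) cpp_kmer_at(ps$ptr, tt, as.integer(k)), character(1))
}
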