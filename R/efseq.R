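#' Elias-Fano encoding of a monotone sequence
#'
#' Encodes a non-decreasing integer sequence `S[0..n)` with known universe
#' `U >= S[n-1]` into `floor(log2(U/n))`-bit low parts plus a unary-coded
#' high-bit vector. The payload never exceeds `n*ceiling(log2(U/n)) + 2n`
#' bits (select support is o(n) on top and accounted separately); see
#' [ef_bits()]. Supports random access and successor queries.
#'
#' @param values Non-decreasing numeric vector of non-negative integers.
#' @param universe Upper bound `U` (defaults to the last value).
#' @return An object of class `ef_sequence`.
#' @examples
#' ef <- ef_build(c(10, 20, 30), 35)
#' ef_access(ef, 0:2)
#' ef_successor_rank(ef, c(0, 20, 21, 31))
#' @export
ef_build <- function(values, universe = NULL) {
  values <- as.numeric(values)
  if (is.null(universe)) universe <- if (length(values)) values[length(values)] else 0
  ptr <- cpp_ef_build(values, universe)
  structure(list(ptr = ptr), class = "ef_sequence")
}

#' @rdname ef_build
#' @param ef An `ef_sequence`.
#' @param i 0-based indices.
#' @export
ef_access <- function(ef, i) {
  stopifnot(inherits(ef, "ef_sequence"))
  cpp_ef_access(ef$ptr, as.numeric(i))
}

#' @rdname ef_build
#' @param x Query values; for each, the smallest index `i` with `S[i] >= x`
#'   is returned (`n` when no such element exists).
#' @export
ef_successor_rank <- function(ef, x) {
  stopifnot(inherits(ef, "ef_sequence"))
  cpp_ef_successor_rank(ef$ptr, as.numeric(x))
}

#' @rdname ef_build
#' @export
ef_size <- function(ef) {
  stopifnot(inherits(ef, "ef_sequence"))
  cpp_ef_info(ef$ptr)$n
}

#' Space of an Elias-Fano sequence
#'
#' @param ef An `ef_sequence`.
#' @return A list with `payload_bits` (low + high bit arrays as stored) and
#'   `bound_bits` (the `n*ceiling(log2(U/n)) + 2n` guarantee).
#' @export
ef_bits <- function(ef) {
  stopifnot(inherits(ef, "ef_sequence"))
  info <- cpp_ef_info(ef$ptr)
  list(payload_bits = info$payload_bits, bound_bits = info$bound_bits,
       low_width = info$low_width)
}

#' @export
print.ef_sequence <- function(x, ...) {
  info <- cpp_ef_info(x$ptr)
  cat(sprintf("ef_sequence: n = %d, universe = %g, %d-bit low parts, %g payload bits\n",
              info$n, info$universe, info$low_width, info$payload_bits))
  invisible(x)
}
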