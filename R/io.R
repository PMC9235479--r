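#' Read sequences from FASTA/FASTQ
#'
#' Thin wrapper over Biostrings that returns plain upper-case character
#' vectors; gzipped input is handled transparently. Format is sniffed from
#' the first non-blank character unless given.
#'
#' @param path Input file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- readLines(con, n = 1L)
    format <- if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Character vector (names become headers; unnamed sequences
#'   get `seq1`, `seq2`, ...).
#' @param path Output file (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Query a read set against a dictionary
#'
#' Runs every k-mer window of every read through the dictionary, either with
#' the streaming algorithm or as independent lookups (`mode = "single"`,
#' kept for equivalence checking), and tabulates per-read hit statistics.
#'
#' @param d A `kmer_dict`.
#' @param reads Character vector of reads, or a FASTA/FASTQ path.
#' @param mode `"streaming"` or `"single"`.
#' @param per_kmer Also return the per-window identifiers.
#' @return A data.frame with one row per read: `read`, `windows`, `hits`,
#'   `hit_fraction`. With `per_kmer = TRUE`, the window-level data.frame
#'   (as [stream_query()]) is attached as attribute `per_kmer`.
#' @export
query_reads <- function(d, reads, mode = c("streaming", "single"),
                        per_kmer = FALSE) {
  stopifnot(inherits(d, "kmer_dict"))
  mode <- match.arg(mode)
  if (length(reads) == 1L && file.exists(reads)) reads <- read_sequences(reads)
  ids <- if (is.null(names(reads))) sprintf("read%d", seq_along(reads)) else names(reads)
  k <- dict_params(d)$k
  if (mode == "streaming") {
    res <- stream_query(d, reads)
  } else {
    res <- do.call(rbind, lapply(seq_along(reads), function(i) {
      nw <- max(0L, nchar(reads[i]) - k + 1L)
      if (nw == 0L) return(NULL)
      wins <- substring(reads[i], seq_len(nw), seq_len(nw) + k - 1L)
      lk <- dict_lookup(d, wins)
      data.frame(pattern = i, window = seq_len(nw) - 1L, id = lk$id,
                 orientation = lk$orientation, stringsAsFactors = FALSE)
    }))
    if (is.null(res)) res <- data.frame(pattern = numeric(0), window = numeric(0),
                                        id = numeric(0), orientation = character(0))
  }
  per_read <- data.frame(read = ids, windows = rep(0L, length(reads)),
                         hits = rep(0L, length(reads)),
                         hit_fraction = rep(NA_real_, length(reads)),
                         stringsAsFactors = FALSE)
  if (nrow(res)) {
    tab <- tapply(res$id >= 0, factor(res$pattern, levels = seq_along(reads)),
                  function(h) c(length(h), sum(h)))
    for (i in seq_along(reads)) {
      if (!is.null(tab[[i]])) {
        per_read$windows[i] <- tab[[i]][1]
        per_read$hits[i] <- tab[[i]][2]
      }
    }
    per_read$hit_fraction <- ifelse(per_read$windows > 0,
                                    per_read$hits / per_read$windows, NA_real_)
  }
  if (isTRUE(per_kmer)) attr(per_read, "per_kmer") <- res
  per_read
}
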