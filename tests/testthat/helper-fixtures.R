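# shared oracles and fixture builders (everything generated in code)

# independent reverse complement: plain string reversal + per-base complement
rc_oracle <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# all k-mer windows of a string, by substring
windows_of <- function(s, k) {
  nw <- nchar(s) - k + 1L
  substring(s, seq_len(nw), seq_len(nw) + k - 1L)
}

# canonical k-mer set of a cover (membership oracle)
canonical_set <- function(cover, k) {
  w <- unlist(lapply(cover, windows_of, k = k))
  unique(pmin(w, rc_oracle(w)))
}

is_member <- function(kmers, canon_set) {
  pmin(kmers, rc_oracle(kmers)) %in% canon_set
}

# mutate one random base of each k-mer (negative-query generator)
mutate_kmers <- function(kmers, seed) {
  set.seed(seed)
  vapply(kmers, function(g) {
    i <- sample.int(nchar(g), 1)
    old <- substr(g, i, i)
    substr(g, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    g
  }, character(1), USE.NAMES = FALSE)
}

# a cover with N = 405 bases in p = 4 strings (lengths 101, 101, 101, 102)
cover_405 <- function(seed = 405) {
  cover <- c(gen_cover(3, c(101, 101), k = 31, seed = seed),
             gen_cover(1, c(102, 102), k = 31, seed = seed + 1))
  stopifnot(sum(nchar(cover)) == 405)
  cover
}

# cover engineered to contain heavy minimizer buckets: a fixed motif
# implanted every 45 bases makes its minimizers recur across all strings
heavy_cover <- function(seed = 11, p = 20) {
  gen_cover(p, c(300, 400), k = 31, seed = seed,
            heavy_motif = random_dna(16, seed = seed + 1), heavy_every = 45)
}
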