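test_that("counts follow the path-cover arithmetic", {
  cover <- gen_cover(7, c(60, 200), k = 31, seed = 14)
  d <- dict_build(cover, k = 31, m = 9, seed = 14, verify = TRUE)
  p <- dict_params(d)
  expect_equal(p$n, sum(nchar(cover)) - 7 * 30)  # n = N - p(k-1)
  sk <- parse_super_kmers(cover, k = 31, m = 9, seed = 14)
  expect_equal(p$z, nrow(sk))
  expect_equal(sum(sk$n_kmers), p$n)             # runs cover every k-mer once
  expect_equal(p$M, length(unique(sk$minimizer)))
  st <- dict_stats(d)
  expect_equal(sum(st$bucket_histogram$count * st$bucket_histogram$size), p$z)
})

test_that("a single-k-mer input builds a trivial dictionary", {
  s <- random_dna(31, seed = 5)
  d <- dict_build(s, k = 31, m = 8)
  p <- dict_params(d)
  expect_equal(c(p$n, p$z, p$M), c(1, 1, 1))
  expect_equal(dict_access(d, 0), s)
  expect_equal(dict_lookup(d, s)$id, 0)
  expect_equal(dict_lookup(d, revcomp(s))$id, 0)
})

test_that("lookup ids are a bijection and strand-invariant in both modalities", {
  for (seed in c(51, 52, 53)) {
    cover <- gen_cover(8, c(100, 250), k = 31, seed = seed)
    for (canonical in c(FALSE, TRUE)) {
      d <- dict_build(cover, k = 31, m = 10, canonical = canonical, seed = seed)
      stored <- dict_iterate(d)
      fw <- dict_lookup(d, stored)
      rv <- dict_lookup(d, revcomp(stored))
      expect_equal(sort(fw$id), as.numeric(seq_along(stored) - 1))
      expect_identical(fw$id, rv$id)
      expect_true(all(fw$orientation == "forward"))
      expect_true(all(rv$orientation == "reverse"))
    }
  }
})

test_that("the identifier arithmetic id = t + w - j(k-1) is exposed and consistent", {
  cover <- gen_cover(5, c(80, 150), k = 31, seed = 77)
  d <- dict_build(cover, k = 31, m = 9, seed = 77)
  ps <- pack_dna(cover)
  res <- dict_lookup(d, dict_iterate(d))
  expect_equal(res$id, res$t + res$w - res$j * 30)
  # the matched window really spells the query
  some <- res[sample.int(nrow(res), 50), ]
  expect_equal(kmer_at(ps, some$t + some$w, 31), dict_access(d, some$id))
})

test_that("lookup and access are mutually inverse", {
  cover <- gen_cover(6, c(90, 220), k = 31, seed = 19)
  for (canonical in c(FALSE, TRUE)) {
    d <- dict_build(cover, k = 31, m = 10, canonical = canonical, seed = 19)
    n <- dict_params(d)$n
    km <- dict_access(d, 0:(n - 1))
    expect_equal(dict_lookup(d, km)$id, as.numeric(0:(n - 1)))
    stored <- dict_iterate(d)
    expect_identical(dict_access(d, dict_lookup(d, stored)$id), stored)
  }
})

test_that("absent k-mers are exactly rejected", {
  cover <- gen_cover(5, c(100, 200), k = 31, seed = 23)
  d <- dict_build(cover, k = 31, m = 10, seed = 23)
  canon <- canonical_set(cover, 31)
  rand_neg <- vapply(1:5000, function(i) random_dna(31, seed = 5e4 + i), character(1))
  rand_neg <- rand_neg[!is_member(rand_neg, canon)]
  expect_true(all(dict_lookup(d, rand_neg)$id == -1))
  mut <- mutate_kmers(dict_iterate(d), seed = 1)
  mut <- mut[!is_member(mut, canon)]
  expect_true(all(dict_lookup(d, mut)$id == -1))
})

test_that("window validity matches the endpoint-interval oracle", {
  two <- c(random_dna(31, 1), random_dna(31, 2))
  d2 <- dict_build(two, k = 31, m = 8)
  expect_equal(dict_is_valid_window(d2, c(0, 1, 31)), c(TRUE, FALSE, TRUE))
  cover <- gen_cover(4, c(50, 120), k = 31, seed = 6)
  d <- dict_build(cover, k = 31, m = 8, seed = 6)
  ep <- cumsum(c(0, nchar(cover)))
  N <- sum(nchar(cover))
  t <- 0:(N - 31)
  oracle <- vapply(t, function(tt) {
    j <- findInterval(tt, ep, rightmost.closed = FALSE)  # 1-based string
    tt + 31 <= ep[j + 1]
  }, logical(1))
  expect_equal(dict_is_valid_window(d, t), oracle)
})

test_that("iteration emits each stored k-mer once, in identifier order", {
  cover <- gen_cover(5, c(60, 140), k = 31, seed = 33)
  d <- dict_build(cover, k = 31, m = 9, seed = 33)
  stored <- dict_iterate(d)
  expect_equal(length(stored), dict_params(d)$n)
  expect_equal(dict_lookup(d, stored)$id, as.numeric(seq_along(stored) - 1))
  # same canonical set as brute-force window extraction
  expect_setequal(pmin(stored, rc_oracle(stored)), canonical_set(cover, 31))
})

test_that("malformed inputs and queries are handled as specified", {
  cover <- gen_cover(3, c(60, 90), k = 31, seed = 40)
  d <- dict_build(cover, k = 31, m = 8, seed = 40)
  expect_error(dict_build(c(cover, "ACGT"), k = 31, m = 8), "shorter than k")
  expect_error(dict_build("ACGTNACGT", k = 5, m = 3), "invalid base")
  expect_error(dict_build(c(cover, cover[1]), k = 31, m = 8, verify = TRUE),
               "duplicate")
  expect_error(dict_access(d, dict_params(d)$n), "\\[0, n\\)")
  expect_error(dict_lookup(d, "ACGT"), "length")
  # non-ACGT query windows are absent, not errors
  expect_equal(dict_lookup(d, paste0(strrep("A", 15), "N", strrep("A", 15)))$id, -1)
})

test_that("the default minimizer length follows ceil(log4 N) + 1", {
  expect_equal(default_minimizer_length(405, k = 31), 6)
  expect_equal(default_minimizer_length(4^10, k = 31), 11)
  expect_equal(default_minimizer_length(1e9, k = 12), 12)  # clamped at k
  cover <- cover_405()
  d <- dict_build(cover, k = 31, seed = 1)  # m omitted
  expect_equal(dict_params(d)$m, 6)
})

test_that("offsets occupy ceil(log2 N) bits each", {
  cover <- gen_cover(5, c(80, 150), k = 31, seed = 61)
  d <- dict_build(cover, k = 31, m = 9, seed = 61)
  p <- dict_params(d)
  st <- dict_stats(d)
  expect_equal(st$offsets_width, ceiling(log2(p$N)))
  expect_equal(st$components$bits[st$components$component == "offsets"],
               p$z * ceiling(log2(p$N)))
})
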