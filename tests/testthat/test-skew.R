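test_that("partition_of matches the direct inequality scan", {
  expect_equal(skew_partition_of(13, l = 3, L = 12), 3)  # 2^3 < 13 <= 2^4
  expect_true(is.na(skew_partition_of(2^6, l = 6, L = 12)))  # boundary: small
  s <- 1:2^14
  got <- skew_partition_of(s, l = 6, L = 12)
  oracle <- vapply(s, function(x) {
    if (ceiling(log2(x)) <= 6) return(NA_integer_)
    for (i in 6:12) if (x > 2^i && (x <= 2^(i + 1) || i == 12)) return(i)
    12L
  }, integer(1))
  expect_equal(got, oracle)
})

test_that("partition value widths follow the size classes", {
  expect_equal(skew_value_width(13, l = 3, L = 12, max_bucket = 5000), 4)
  expect_equal(skew_value_width(36000, l = 6, L = 12, max_bucket = 36000), 16)
  expect_true(is.na(skew_value_width(4, l = 3, L = 12, max_bucket = 5000)))
})

test_that("the skew layout always has L - l + 1 partitions (empty ones as stubs)", {
  cover <- heavy_cover(seed = 11)
  d <- dict_build(cover, k = 31, m = 8, l = 2, L = 8, seed = 11)
  sp <- dict_stats(d)$skew_partitions
  expect_equal(nrow(sp), 8 - 2 + 1)
  expect_equal(sp$partition, 2:8)
  expect_true(any(sp$n_keys > 0))
  # heavy k-mers only: keys are exactly the k-mers of buckets larger than 2^l
  h <- dict_stats(d)$bucket_histogram
  expect_gt(dict_params(d)$max_bucket, 2^2)
})

test_that("skew-indexed lookup is equivalent to full bucket scans", {
  cover <- heavy_cover(seed = 12)
  for (canonical in c(FALSE, TRUE)) {
    d1 <- dict_build(cover, k = 31, m = 8, l = 2, L = 8, seed = 12,
                     canonical = canonical, skew = TRUE)
    d0 <- dict_build(cover, k = 31, m = 8, l = 2, L = 8, seed = 12,
                     canonical = canonical, skew = FALSE)
    expect_gt(dict_params(d1)$max_bucket, 2^2)
    stored <- dict_iterate(d1)
    expect_identical(dict_lookup(d1, stored)$id, dict_lookup(d0, stored)$id)
    neg <- vapply(1:10000, function(i) random_dna(31, seed = 9e5 + i), character(1))
    canon <- canonical_set(cover, 31)
    neg <- neg[!is_member(neg, canon)]
    r1 <- dict_lookup(d1, neg)$id
    expect_identical(r1, dict_lookup(d0, neg)$id)
    expect_true(all(r1 == -1))
  }
})

test_that("lookup work is bounded: <= 2^l super-k-mers for small buckets, one candidate for heavy", {
  cover <- heavy_cover(seed = 13)
  d <- dict_build(cover, k = 31, m = 8, l = 2, L = 8, seed = 13, canonical = TRUE)
  stored <- dict_iterate(d)
  probe <- c(sample(stored, 150),
             vapply(1:150, function(i) random_dna(31, seed = 7e5 + i), character(1)))
  for (g in probe) {
    cnt <- attr(dict_lookup(d, g, instrument = TRUE), "counters")
    expect_lte(cnt$superkmers_scanned, 2^2)  # canonical: one bucket per query
  }
})

test_that("skew space accounting is exact", {
  cover <- heavy_cover(seed = 14)
  d <- dict_build(cover, k = 31, m = 8, l = 2, L = 8, seed = 14)
  st <- dict_stats(d)
  sp <- st$skew_partitions
  expect_equal(st$components$bits[st$components$component == "skew_index"],
               sum(sp$mphf_bits + sp$vector_bits))
  occupied <- sp[sp$n_keys > 0, ]
  expect_equal(occupied$vector_bits, occupied$n_keys * occupied$width)
})
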