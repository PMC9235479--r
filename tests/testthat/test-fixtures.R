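test_that("covers are deterministic, sized as requested and duplicate-free", {
  a <- gen_cover(6, c(60, 120), k = 31, seed = 101)
  b <- gen_cover(6, c(60, 120), k = 31, seed = 101)
  expect_identical(as.character(a), as.character(b))
  expect_true(all(nchar(a) >= 60 & nchar(a) <= 120))
  expect_equal(attr(a, "N"), sum(nchar(a)))
  expect_equal(attr(a, "n"), attr(a, "N") - 6 * 30)
  # no duplicate canonical k-mers
  w <- unlist(lapply(a, windows_of, k = 31))
  expect_equal(length(unique(pmin(w, rc_oracle(w)))), length(w))
  # degenerate cover: one string of length k is a single k-mer
  one <- gen_cover(1, c(31, 31), k = 31, seed = 5)
  expect_equal(attr(one, "n"), 1)
})

test_that("the heavy-bucket knob forces buckets past the skew threshold", {
  for (seed in c(7, 8)) {
    cover <- heavy_cover(seed = seed)
    d <- dict_build(cover, k = 31, m = 8, l = 2, L = 8, seed = seed)
    expect_gt(dict_params(d)$max_bucket, 2^2)
  }
})

test_that("query workloads meet their hit-fraction contracts across seeds", {
  cover <- gen_cover(10, c(200, 400), k = 31, seed = 200)
  d <- dict_build(cover, k = 31, m = 10, canonical = TRUE, seed = 200)
  for (seed in 1:20) {
    hi <- gen_queries(cover, "high_hit", n_queries = 60, pattern_len = 90,
                      seed = seed)
    frac <- stream_stats(stream_query(d, hi))$hit_fraction
    expect_gte(frac, 0.70)
    lo <- gen_queries(cover, "low_hit", n_queries = 60, pattern_len = 90,
                      seed = seed)
    expect_lt(stream_stats(stream_query(d, lo))$hit_fraction, 0.01)
  }
  expect_length(gen_queries(cover, "high_hit", n_queries = 0), 0)
})

test_that("half of positive patterns are reverse-complemented", {
  cover <- gen_cover(6, c(200, 300), k = 31, seed = 300)
  qs <- gen_queries(cover, "high_hit", n_queries = 100, pattern_len = 60,
                    seed = 3, frac_positive = 1)
  on_forward <- vapply(qs, function(q) {
    any(vapply(cover, function(s) grepl(q, s, fixed = TRUE), logical(1)))
  }, logical(1))
  expect_true(all(on_forward | vapply(rc_oracle(qs), function(q) {
    any(vapply(cover, function(s) grepl(q, s, fixed = TRUE), logical(1)))
  }, logical(1))))
  expect_gte(sum(!on_forward), 35)  # about half flipped
  expect_lte(sum(!on_forward), 65)
})
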