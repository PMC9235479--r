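test_that("access and successor agree with plain-array oracles", {
  set.seed(1)
  for (case in 1:100) {
    n <- sample(1:200, 1)
    U <- sample(c(n, 10 * n, 1000 * n), 1)
    vals <- sort(sample(0:U, n, replace = TRUE))
    ef <- ef_build(vals, U)
    expect_equal(ef_access(ef, seq_len(n) - 1), as.numeric(vals))
    qs <- c(0, U, sample(0:U, 20, replace = TRUE))
    oracle <- vapply(qs, function(x) {
      i <- which(vals >= x)  # linear-scan successor
      if (length(i)) i[1] - 1 else n
    }, numeric(1))
    expect_equal(ef_successor_rank(ef, qs), oracle)
    b <- ef_bits(ef)
    expect_lte(b$payload_bits, b$bound_bits)  # n*ceil(log2(U/n)) + 2n
  }
})

test_that("edge sequences round-trip", {
  ef <- ef_build(0:999, 1000)          # identity
  expect_equal(ef_access(ef, c(0, 500, 999)), c(0, 500, 999))
  expect_equal(ef_successor_rank(ef, 3), 3)
  ef1 <- ef_build(12345, 12345)        # single element at the universe
  expect_equal(ef_access(ef1, 0), 12345)
  efd <- ef_build(c(5, 5, 5), 5)       # duplicates are legal
  expect_equal(ef_access(efd, 1), 5)
  expect_equal(ef_successor_rank(efd, 5), 0)
  expect_equal(ef_successor_rank(efd, 6), 3)  # past the end: n
})

test_that("invalid sequences are rejected", {
  expect_error(ef_build(c(3, 2, 5), 10), "non-decreasing")
  expect_error(ef_build(c(1, 11), 10), "universe")
})

test_that("the payload bound holds on dense draws", {
  set.seed(42)
  vals <- sort(sample(0:(1e6 - 1), 1e4, replace = TRUE))
  ef <- ef_build(vals, 1e6)
  b <- ef_bits(ef)
  expect_lte(b$payload_bits, 1e4 * ceiling(log2(100)) + 2e4)
  expect_equal(ef_access(ef, c(0, 5000, 9999)), vals[c(1, 5001, 10000)])
})
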