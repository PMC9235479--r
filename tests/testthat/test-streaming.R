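test_that("streaming is observationally equivalent to independent lookups", {
  cover <- gen_cover(6, c(150, 300), k = 31, seed = 81)
  patterns <- c(cover[1],                      # stored, forward
                revcomp(cover[2]),             # stored, reverse strand
                random_dna(200, seed = 4),     # all-miss
                paste0(substr(cover[3], 1, 80),
                       "NN", substr(cover[4], 1, 80)),  # invalid bases inside
                substr(cover[5], 10, 45))
  for (canonical in c(FALSE, TRUE)) {
    d <- dict_build(cover, k = 31, m = 9, canonical = canonical, seed = 81)
    sq <- stream_query(d, patterns)
    pk <- attr(query_reads(d, patterns, mode = "single", per_kmer = TRUE),
               "per_kmer")
    expect_identical(sq$id, pk$id)
    expect_identical(sq$orientation, pk$orientation)
  }
})

test_that("state resets at pattern boundaries: batched equals separate", {
  cover <- gen_cover(4, c(120, 200), k = 31, seed = 90)
  d <- dict_build(cover, k = 31, m = 9, seed = 90)
  p1 <- cover[1]; p2 <- revcomp(cover[2])
  both <- stream_query(d, c(p1, p2))
  sep <- rbind(stream_query(d, p1), stream_query(d, p2))
  sep$pattern <- both$pattern  # separate calls number patterns from 1
  expect_equal(both[c("window", "id", "orientation")],
               sep[c("window", "id", "orientation")],
               ignore_attr = TRUE)
})

test_that("a stored pattern is answered almost entirely by extensions", {
  cover <- gen_cover(4, c(250, 350), k = 31, seed = 95)
  d <- dict_build(cover, k = 31, m = 9, canonical = TRUE, seed = 95)
  st <- stream_stats(stream_query(d, cover[1]))
  expect_equal(st$hits, nchar(cover[1]) - 30)
  expect_equal(st$extensions, st$windows - 1)  # every window after the first
  expect_lte(st$f_evals, 2)
})

test_that("reverse-complement patterns extend backwards instead of rescanning", {
  cover <- heavy_cover(seed = 96, p = 12)
  d <- dict_build(cover, k = 31, m = 8, l = 2, L = 8, canonical = TRUE, seed = 96)
  pat <- revcomp(cover[1])
  with_cache <- stream_stats(stream_query(d, pat))
  no_cache <- stream_stats(stream_query(d, pat, orientation_cache = FALSE))
  expect_identical(with_cache$hits, no_cache$hits)  # results never change
  expect_equal(with_cache$extensions, with_cache$windows - 1)
  # the orientation cache removes the per-window bucket rescans: only the
  # first window (a bucket of at most 2^l super-k-mers, or one skew
  # candidate) is ever scanned
  expect_lte(with_cache$superkmers_scanned, 2^2)
  expect_gte(no_cache$superkmers_scanned, 5 * (with_cache$superkmers_scanned + 1))
  # scan work grows linearly in pattern length with the cache ...
  half <- substr(pat, 1, floor(nchar(pat) / 2))
  s_half <- stream_stats(stream_query(d, half))
  s_full <- with_cache
  expect_lte(s_full$superkmers_scanned + s_full$extension_attempts,
             2.5 * (s_half$superkmers_scanned + s_half$extension_attempts) + 2)
  # ... while without it the rescans scale with hits * bucket size
  n_half <- stream_stats(stream_query(d, half, orientation_cache = FALSE))
  expect_gte(no_cache$superkmers_scanned, 1.5 * n_half$superkmers_scanned)
})

test_that("an all-miss pattern costs at most one hash evaluation per minimizer run", {
  cover <- gen_cover(5, c(100, 200), k = 31, seed = 97)
  d <- dict_build(cover, k = 31, m = 12, canonical = TRUE, seed = 97)
  pat <- random_dna(600, seed = 55)
  res <- stream_query(d, pat)
  st <- stream_stats(res)
  if (st$hits == 0) {
    mins <- kmer_minimizer(windows_of(pat, 31), m = 12, seed = 97,
                           canonical = TRUE)$mmer
    runs <- 1 + sum(mins[-1] != mins[-length(mins)])
    expect_lte(st$f_evals, runs)
  }
  expect_equal(st$hits + st$misses, st$windows)
})

test_that("stream_stats totals recount the per-window results", {
  cover <- gen_cover(4, c(100, 180), k = 31, seed = 99)
  d <- dict_build(cover, k = 31, m = 9, seed = 99)
  res <- stream_query(d, c(cover[2], random_dna(120, 3)))
  st <- stream_stats(res)
  expect_equal(st$windows, nrow(res))
  expect_equal(st$hits, sum(res$id >= 0))
  expect_lte(st$extensions, st$hits)
  expect_true(all(unlist(st) >= 0))
  # patterns shorter than k contribute no windows
  expect_equal(nrow(stream_query(d, "ACGT")), 0)
})
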