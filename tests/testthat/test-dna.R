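test_that("2-bit encoding is a bijection with XOR-3 complement", {
  codes <- encode_dna("ACGT")
  expect_equal(codes, 0:3)
  # complementing the code must equal encoding the complementary base
  expect_equal(decode_dna(bitwXor(codes, 3L)), "TGCA")
  expect_equal(decode_dna(encode_dna("GATTACA")), "GATTACA")
  expect_equal(encode_dna("acgt"), encode_dna("ACGT"))  # case normalized
  expect_error(encode_dna("ACGNA"), "position 4")
})

test_that("revcomp matches the string-reversal oracle and is an involution", {
  expect_equal(revcomp("ACGT"), "ACGT")  # reverse-complement palindrome
  expect_equal(revcomp("AAA"), "TTT")
  kmers <- vapply(1:1000, function(i) random_dna(31, seed = i), character(1))
  expect_equal(revcomp(kmers), rc_oracle(kmers))
  expect_equal(revcomp(revcomp(kmers)), kmers)
  expect_error(revcomp("ACXT"), "invalid base")
})

test_that("packing round-trips and records endpoints", {
  strs <- gen_cover(5, c(40, 90), k = 31, seed = 2)
  ps <- pack_dna(strs)
  expect_equal(unpack_dna(ps), as.character(strs))
  ep <- dna_endpoints(ps)
  expect_equal(ep, cumsum(c(0, nchar(strs))))
  expect_true(all(diff(ep) >= 31))
})

test_that("kmer_at agrees with substring slicing at every valid offset", {
  strs <- gen_cover(3, c(35, 60), k = 31, seed = 9)
  ps <- pack_dna(strs)
  ep <- dna_endpoints(ps)
  for (j in seq_along(strs)) {
    for (off in 0:(nchar(strs[j]) - 8)) {
      expect_identical(kmer_at(ps, ep[j] + off, 8),
                       substr(strs[j], off + 1, off + 8))
    }
  }
})

test_that("windows crossing a string endpoint are rejected as alien", {
  strs <- c(random_dna(31, 1), random_dna(31, 2))
  ps <- pack_dna(strs)
  expect_equal(kmer_at(ps, 0, 31), strs[1])
  expect_equal(kmer_at(ps, 31, 31), strs[2])  # first k-mer of string 2
  expect_error(kmer_at(ps, 1, 31), "alien")
  expect_error(kmer_at(ps, 40, 31), "exceeds")
})
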