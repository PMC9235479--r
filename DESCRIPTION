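Package: kmerdict
Title: Exact Associative K-mer Dictionaries via Minimizer Bucketing and
    Perfect Hashing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A compressed, exact and associative dictionary for a set of n
    distinct k-mers given as a path cover of a de Bruijn graph (for example
    unitigs or stitched unitigs). Every k-mer is mapped to a unique integer
    identifier in [0, n) (lookup) and back (access), with support for
    stateful streaming membership queries over read sets. The index combines
    2-bit packed strings, minimizer-driven super-k-mer parsing, Elias-Fano
    encoded monotone sequences, minimal perfect hash functions over the
    minimizer set, and a skew index of per-size-class perfect hash functions
    that bounds worst-case lookup work on heavy minimizer buckets. Includes
    a deterministic synthetic path-cover and query-workload generator so the
    whole test suite runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
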