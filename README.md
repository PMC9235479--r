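# kmerdict

An exact, associative and compressed dictionary of k-mers for R, with a
C++ core. Given a *path cover* of a de Bruijn graph — a set of `p` strings
(unitigs / stitched unitigs) of total length `N` over `{A,C,G,T}` in which
every one of the `n = N − p(k−1)` distinct k-mers occurs exactly once — the
package builds an index that supports:

* **Lookup**: k-mer → unique identifier in `[0, n)`, or −1 if absent
  (a k-mer and its reverse complement are identical);
* **Access**: identifier → k-mer (the dictionary is a self-index);
* **Streaming queries**: membership of every consecutive window of a
  pattern or read set, with cached state that makes the common case
  (adjacent windows, shared minimizer, either strand) nearly free.

It is aimed at method developers and bioinformaticians who need exact
k-mer membership with stable integer handles — e.g. to attach abundances or
colors — without holding a hash table of all k-mers.

## The data structure

All k-mers of a window of a string sharing one *minimizer* (the m-mer
minimizing a seeded hash `h`) form a *super-k-mer*; on random sequence
there are about `(k−m+2)/2` k-mers per super-k-mer, so indexing
super-k-mers instead of k-mers sparsifies the dictionary by ~6.5× at
`k = 31, m = 20`. The index stores

* the cover strings, 2 bits/base, with Elias–Fano-encoded endpoints
  (`E[0..p]`) guarding against matches that straddle two strings;
* a minimal perfect hash `f` over the `M` distinct minimizers, prefix-summed
  bucket sizes `Sizes[0..M]` (Elias–Fano), and the `z` super-k-mer offsets
  (absolute, `⌈log2 N⌉` bits each) grouped by bucket in the order of `f`;
* a *skew index* for the heavy tail of the bucket-size distribution:
  buckets larger than `2^l` super-k-mers get per-size-class minimal perfect
  hashes mapping each of their k-mers straight to its super-k-mer, so a
  lookup never scans more than `2^l` super-k-mers — one, for heavy buckets.

`Lookup(g)` finds the bucket via `f(minimizer(g))`, scans at most
`k−m+1` windows per candidate super-k-mer comparing against `g` (and/or
`revcomp(g)`), and returns `id = t + w − j(k−1)` for a match at window `w`
of the super-k-mer at offset `t` in string `j`. Every candidate is verified
against the stored bases, so the structure is exact: zero false positives,
by construction.

## Worked example

```r
library(kmerdict)

cover <- gen_cover(p = 4, len_range = c(101, 102), k = 31, seed = 7)
d <- dict_build(cover, k = 31, m = 8, canonical = TRUE, seed = 7)
d
#> kmer_dict (k = 31, m = 8, canonical modality)
#>   286 k-mers in 4 strings (406 bases), 28 super-k-mers, 28 minimizers
#>   largest bucket: 1 super-k-mers (skew threshold 2^6 = 64)

g <- substr(cover[2], 11, 41)
dict_lookup(d, c(g, revcomp(g), strrep("A", 31)))
#>   id orientation begin end   t w j
#> 1 82     forward    11  12 112 0 1
#> 2 82     reverse    11  12 112 0 1
#> 3 -1        none     2   3   0 0 0
```

The k-mer starting at base 11 of the second string and its reverse
complement get the same identifier, 82 — which is its absolute position in
the concatenated strings (`t + w = 112`) minus the `j(k−1) = 30` alien
windows of the one string before it. Streaming a whole
reverse-complemented string touches the bucket machinery essentially once
and answers every other window by backward extension:

```r
st <- stream_stats(stream_query(d, revcomp(cover[3])))
st[c("windows", "hits", "extensions", "f_evals")]
#> $windows
#> [1] 71
#> $hits
#> [1] 71
#> $extensions
#> [1] 70
#> $f_evals
#> [1] 1

dict_stats(d)
#> Space accounting: n = 286 k-mers, z = 28 super-k-mers, M = 28 minimizers
#>   strings                  812 bits  ( 2.839 bits/k-mer)
#>   endpoints                 41 bits  ( 0.143 bits/k-mer)
#>   minimizer_mphf           275 bits  ( 0.962 bits/k-mer)
#>   sizes                     57 bits  ( 0.199 bits/k-mer)
#>   offsets                  252 bits  ( 0.881 bits/k-mer)
#>   skew_index                 0 bits  ( 0.000 bits/k-mer)
#>   total                   1437 bits  ( 5.024 bits/k-mer)
#>   super-k-mer partitioning would cost >= 7.87 bits/k-mer
#> Bucket size distribution (%): 1: 100.0 | > 2^6: 0.0%
```

Indexes serialize to a single versioned binary file (`dict_save()` /
`dict_load()`), and `inst/cli/kmerdict.R` wraps the same functions as a
command line tool (`build`, `query`, `access`, `iterate`, `stats`,
`fixtures`) for shell pipelines.

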