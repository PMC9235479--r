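---
title: "Minimizer-bucketed exact k-mer dictionaries: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizer-bucketed exact k-mer dictionaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerdict)
```

## The problem

Many sequence-analysis tasks reduce to exact membership queries over the set
$S$ of all distinct k-mers of a genome or pan-genome: given a k-mer $g$,
is it in $S$, and if so, under which stable integer identifier can satellite
data (abundances, colors, positions) be attached to it? `kmerdict`
implements a *compressed, associative and exact* dictionary for this
problem: `dict_lookup()` maps each stored k-mer bijectively onto
$\{0,\dots,n-1\}$ and returns $-1$ for everything else, `dict_access()`
inverts that map, and `stream_query()` answers membership for every
consecutive window of a pattern. A k-mer and its reverse complement are
considered identical throughout.

The input is not the raw genome but a *path cover* of its de Bruijn graph:
a set of $p$ strings (unitigs, stitched unitigs / simplitigs) of total
length $N$ in which every k-mer of $S$ occurs exactly once, so that
$n = N - p(k-1)$. Producing such covers is the job of established
assemblers/compacters and is out of scope here; the package ships a
synthetic generator (`gen_cover()`) instead, so that every test and example
runs from code alone.

## The index, component by component

**Strings and endpoints.** The cover strings are concatenated into $2N$
bits (2 bits per base, A=0, C=1, G=2, T=3, so complementing a code is
XOR 3). The cumulative string endpoints are kept as an Elias–Fano-encoded
monotone sequence: they delimit "alien" windows — windows that straddle two
strings and therefore spell k-mers that are storage artifacts, never
members.

**Minimizers and super-k-mers.** The minimizer of a k-mer is its smallest
m-mer under a seeded 64-bit hash order ("random minimizers"); ties within a
window go to the leftmost position. Runs of consecutive k-mers sharing a
minimizer — super-k-mers — are the unit of indexing: on random sequence one
expects $(k-m+2)/2$ k-mers per super-k-mer (6.5 for the conventional
$k=31, m=20$), so positional information is paid once per super-k-mer
rather than once per k-mer. That factor is exactly what
`scripts/acceptance.R` re-measures.

**Buckets.** A minimal perfect hash function $f$ over the $M$ distinct
minimizers gives every minimizer a bucket slot; prefix-summed bucket sizes
(Elias–Fano again) and a flat array of the $z$ super-k-mer offsets — each
$\lceil\log_2 N\rceil$ bits, absolute into the concatenation — locate all
super-k-mers of a bucket. Storing *absolute offsets into unbroken strings*
rather than materializing each super-k-mer separately avoids re-paying the
$k-1$ tail bases of every super-k-mer, which would cost at least
$2 + 2z(k-1)/n$ bits/k-mer (`superkmer_partition_cost()`); `dict_stats()`
prints both accountings.

**Lookup.** Compute the query's minimizer, evaluate $f$, scan the bucket's
super-k-mers comparing windows against the query (and, where applicable,
its reverse complement), and return $t + w - j(k-1)$ for a match at window
$w$ of the super-k-mer at offset $t$ in string $j$. Because an MPHF returns
*some* slot for any m-mer, a bucket is first validated by comparing the
query minimizer against the minimizer of the first k-mer stored in it; this
guard is what keeps the structure exact for queries whose minimizer was
never indexed. All matches are verified against the packed strings, so
false positives are structurally impossible.

**Double strandedness.** In *regular* modality the forward strand is
searched first and the reverse complement only on a miss — up to two
buckets per negative query. In *canonical* modality the minimizer is the
smaller of the two strands' minimizers, so a k-mer and its reverse
complement share a bucket by construction and one probe always suffices, at
the cost of a somewhat larger minimizer set on real genomes.

**Skew index.** Minimizer bucket sizes are heavily skewed: most buckets
hold one super-k-mer, a few hold thousands. Buckets larger than $2^\ell$
super-k-mers are covered by per-size-class MPHFs: partition $i$
($2^i < s \le 2^{i+1}$, clamped at $L$) stores, for each of its k-mers, the
rank of the containing super-k-mer in $(i+1)$-bit entries
($\lceil\log_2 \mathrm{max}\rceil$ for the top class). A heavy-bucket
lookup thus scans exactly one candidate super-k-mer, and any lookup scans
at most $2^\ell$; a retrieved rank $\ge$ the bucket size, or a failed
verifying scan, proves absence (entries for non-keys are arbitrary).

**Streaming.** Consecutive pattern windows usually share a minimizer, so
`stream_query()` caches the last minimizer, its bucket, whether it is a
stored minimizer at all, the position of the last confirmed match and its
orientation. The fast paths are: skip (same minimizer, known absent),
bucket reuse (same minimizer, no $f$ re-evaluation), and extension (try the
position adjacent to the last match first — the *next* position after a
forward match, the *previous* one after a reverse-complement match; the
latter is what prevents quadratic rescanning on reverse-complemented
patterns). Every fast path re-verifies bases and window validity before
accepting, which makes the optimization observationally invisible: the test
suite asserts window-by-window equality with independent lookups. The
cached state is a fixed handful of scalars, independent of pattern length.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 31 | k-mer length (2..63); odd values avoid self-reverse-complement palindromes |
| `m` | $\lceil\log_4 N\rceil + 1$ | minimizer length (≤ 32); smaller m → fewer, longer super-k-mers → smaller but slower index |
| `canonical` | `FALSE` | single-bucket double-strand lookups vs. smaller index |
| `l` | 6 | bucket-size exponent above which the skew index takes over ($2^\ell$ bounds the scan work) |
| `L` | 12 | last geometric size class; one top class covers $2^L <$ size $\le$ max |
| `seed` | 1 | seeds every hash (minimizer order, MPHF placement); stored in the index header so query parsing always matches build parsing |

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere, including in R return
  values: identifiers, offsets and window positions are index-domain
  quantities (`id = t + w - j*(k-1)` holds verbatim on the returned
  columns).
* **Super-k-mer cap.** A run is closed after $k-m+1$ k-mers even when the
  minimizer *value* persists (a nearby repeat of the minimizer m-mer).
  Parse-time runs and query-time scan windows then coincide exactly, so a
  bucket scan never needs run lengths — only offsets are stored.
* **Tie-breaks.** Within a window, equal hash values resolve to the
  leftmost position (on the reverse strand: leftmost in that strand's
  reading direction, i.e. rightmost in forward coordinates). Across
  strands in canonical modality the winner is decided by (hash, packed
  m-mer value) — a strand-symmetric rule, so the canonical minimizer of
  `g` and `revcomp(g)` is provably identical even in the astronomically
  unlikely event of two distinct m-mers sharing a hash value.
* **MPHF.** Any correct minimal perfect hash serves; the one here is a
  multi-level unique-cell construction (cells hit by exactly one key retire
  it; survivors cascade) at load factor 1/2, measured at ~3.5–3.8 bits/key
  — comfortably under the 4 bits/key engineering budget, if above what
  state-of-the-art pilot-based schemes reach in compiled tools.
* **Skew keys** are canonical (strand-minimum) packed k-mers, so in regular
  modality both strand searches of one query retrieve the same entry; for
  $k > 32$ a 64-bit fingerprint replaces the packing, and a fingerprint
  collision can only add a candidate that the verifying scan rejects.
* **Degenerate inputs.** Cover strings must be pure ACGT (hard error,
  with position) and at least k long; *query* windows containing other
  characters are reported absent and reset the streaming state. Duplicate
  k-mers in the cover violate the input contract; `verify = TRUE` runs an
  explicit hash-set check for untrusted inputs.
* **Empty skew partitions** are serialized as zero-length stubs so the
  on-disk layout is fixed ($L-\ell+1$ partitions, always).
* **Failed extensions** fall back to the cached bucket scan and then, if
  the minimizer changed, to a full lookup; only one directional extension
  is attempted per window (the cached orientation's direction).

## What the synthetic generator does and does not emulate

`gen_cover()` produces uniform-random strings, rejecting any string that
would duplicate a canonical k-mer — emulating the no-duplicates guarantee
of a real path cover. `gen_queries()` mirrors the two benchmark regimes
used for dictionaries of this kind: a high-hit workload (cover substrings,
half reverse-complemented, mixed with random patterns; ≥ 70% of windows
stored) and a low-hit workload (random patterns, < 1% stored). The
heavy-bucket knob implants a fixed motif periodically so that some
minimizers recur far more often than uniform sampling would produce,
forcing buckets past $2^\ell$ and exercising the skew index.

What passing tests on these fixtures *show* is the exactness, bijectivity,
equivalence and work-bound properties of the data structure, which are
combinatorial and hold regardless of input statistics. What they do *not*
show are genome-scale distributional effects: uniform-random covers have no
repeat structure, so bucket-size skew must be injected artificially, and
the canonical modality's inflation of the distinct-minimizer count observed
on real genomes does not reproduce here (on uniform covers the two
modalities use minimizer sets of similar size — measured both slightly
above and slightly below, scattering around zero). Space figures from
`dict_stats()` on synthetic fixtures are likewise not predictive of
genome-scale bits/k-mer.

## Problem sizes used by the tests

The suite builds dictionaries of $10^2$–$10^4$ k-mers (20-seed sweeps for
the bijection properties, both modalities), checks exactness against
$2\times10^5$ oracle-verified negative queries, and measures minimizer
density on $10^6$ uniform-random bases, where the $(k-m+2)/2$ law is
verified to within 5% (empirically it lands within ~0.3%). These sizes were
chosen so the whole suite re-runs from scratch in well under a minute of
single-core time while keeping every statistical check far from its
tolerance boundary.

## Known limitations

* Static: no insertions or deletions; rebuilding is the only update path.
* $k \le 63$, $m \le 32$; abundances/colors are not stored (identifiers
  are the hook for external satellite arrays).
* The R-facing API transports identifiers and offsets as doubles — exact
  below $2^{53}$, which bounds supported inputs far beyond anything a
  single R session would index anyway.
* Construction is in-memory and single-threaded.

## A worked example

```{r example}
cover <- gen_cover(p = 4, len_range = c(101, 102), k = 31, seed = 7)
d <- dict_build(cover, k = 31, m = 8, canonical = TRUE, seed = 7)
d

g <- substr(cover[2], 11, 41)
dict_lookup(d, c(g, revcomp(g)))

res <- stream_query(d, revcomp(cover[3]))
stream_stats(res)[c("windows", "hits", "extensions", "f_evals")]

dict_stats(d)
```
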