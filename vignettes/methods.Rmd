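---
title: "Methods: bit-packed adapter trimming for paired-end reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bit-packed adapter trimming for paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrim)
```

This vignette documents the model and the numerical decisions behind
`adaptrim`, in the order the pipeline applies them.  It makes no empirical
claims beyond what the package's test suite and the `scripts/acceptance.R`
benchmark script compute.

## Sequence representation

Bases are stored as 4-bit one-hot codes: `A = 0001`, `C = 0010`, `G = 0100`,
`T = 1000`.  Every IUPAC ambiguity code is the bitwise OR of its
constituents (`N = 1111`, `S = 0110`, ...), and a gap `-` is `0000`.  Two
bases are *compatible* exactly when their codes share a bit, so base
comparison is a bitwise AND, and reverse complementation is a reversal of
the nibble's bits (`A = 0001` maps to `T = 1000`, `S` and `N` map to
themselves).

Two bases are packed per byte (even index in the low nibble) and the buffer
is padded with eight zero bytes, so an unaligned 64-bit little-endian load
at byte `n` always yields a well-defined *word*: the 16 bases at positions
`2n .. 2n+15`, with positions past the end reading as gaps.  Because gaps
share no bits with anything, the padding can never fake a match
("bit-safe" padding).

```{r}
p <- packed_seq("ACGTN")
as.character(p)
word_at(p, 0)  # hex nibbles, base 0 in the lowest nibble
```

The number of mismatching positions between two 16-base words `a`, `b` is

```
K = max(0, 16 - popcount(a & b))
```

one AND plus one popcount per 16 bases.  Shared ambiguity codes can
contribute more than one bit to the popcount, slightly *under*-counting
mismatches for non-ACGT input; the clamp at zero keeps `K` well defined.
This is deliberate: ambiguity codes should err toward "compatible".

## The 16-mer head scan

All matching is anchored on the query's first 16 bases.  Two precomputed
head words are kept: `a0` (bases 0-15) and `a-` (bases 1-16).  Sliding by
one base is a 4-bit shift, so a byte-aligned load of the subject compared
against `a0` realises every even offset and against `a-` every odd offset
(at odd offsets the compared window is query bases 1-16 against subject
`o+1 .. o+16`).  The scan over all subject offsets therefore needs one load,
one AND and one popcount per offset.

`kmer_scan(query, subject, k)` returns the smallest offset achieving the
minimum `K`.  The hit is *found* when `K <= k` (default `k = 2`), but the
raw best `(offset, n_match = 16 - K)` is always reported: the loosening
logic below consumes raw counts even when no offset met the tolerance,
while scores treat unfound matches as absent (score 0).  Out-of-range
subject positions read as gaps, so a query overhanging the subject tail can
still match partially — this is what finds adapters whose remainder runs
off the read end.

## Quality-weighted scores

A Phred score `Q` maps to the probability the call is correct,
`P = 1 - 10^(-Q/10)`.  A match of `n` bases between regions with mean
16-mer accuracies `p_a`, `p_b` scores

```
S = n * p_a * p_b
```

For a user-supplied adapter `p = 1` on the adapter side.  The mean accuracy
is floored at 0.75 when used in scores, so abysmal qualities cannot erase
the evidence of a long match: a perfect 16-mer never scores below 12.  The
*unfloored* mean is used in exactly one place — the low-quality override
below compares it against 0.6 (roughly all-Q4 data), a condition the floor
would make unsatisfiable.  Windows truncated by the read end average only
the in-range bases.

## Four-way matching

For a pair `r1`, `r2` with adapters `A1`, `A2`, four scans run:

1. `A1` against `r1`, and `A2` against `r2`.  An adapter starting at offset
   `p` implies insert size `p`.
2. `r1`'s head against `reverse_complement(r2)`, and vice versa.  A match at
   offset `o` implies insert size `len(mate) - o`.

The paired-end insert-size mapping deserves a note.  Matching the *read
head* against the reverse-complemented mate locates the read's start inside
the mate, which corroborates an adapter position whenever the insert is no
longer than the read.  For inserts longer than the read (no adapter in
either read) this orientation presents only unrelated sequence to the scan,
so the paired-end channel deliberately contributes nothing there — and, at
a small rate, a 14/16 chance match can exceed the score threshold.  The
consequence is a measured fraction of roughly three in ten thousand
adapter-free reads trimmed by chance; the acceptance checks assert
adapter-free retention at one-decimal precision with a binomial sampling
allowance for exactly this reason.

Two refinements connect the four matches:

* **Loosened paired-end tolerance.**  When neither adapter match reaches
  `cutoff = 9` matched bases, the paired-end scans run at `k + 1`: with no
  adapter evidence the mate overlap is allowed to be slightly noisier.
* **Loosened re-evaluation.**  When the best of the four raw counts exceeds
  `cutoff` but another match's raw count is below it, that match is
  re-counted (threshold-free) at the single offset implied by the best
  match's insert size, and replaced when the recount exceeds `cutoff`.
  Implied offsets that are negative are skipped.

```{r}
set.seed(1)
insert <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
r1 <- fastq_read("demo/1", substr(paste0(insert, ADAPTER_R1, strrep("A", 20)), 1, 100),
                 strrep("I", 100))
r2 <- fastq_read("demo/2", substr(paste0(reverse_complement(insert), ADAPTER_R2,
                                         strrep("A", 20)), 1, 100),
                 strrep("I", 100))
four_way_match(r1, r2)
```

## Decision rules

Within each read the adapter and paired-end candidates are *reconciled*:
equal positions sum their scores, different positions keep the higher score
(ties keep the first operand — adapter over paired-end, read 1 over
read 2).  The two per-read results reconcile the same way into a single
`(position, score)`.

* **Low-quality override.**  When the reads disagree, one read's score
  exceeds the threshold, and the other read either cannot supply any base
  at that position or its unfloored mean accuracy there is below 0.6, the
  confident read wins outright and the tail filter is bypassed: an
  uninformative mate should not veto a convincing match.
* **Tail false-positive filter.**  Adapter hits confined to the last
  `tail_length = 12` bases with a nearby but disagreeing paired-end hit are
  characteristic of chance matches.  A read raises the flag when both its
  candidates fall in the tail; the pair is rejected when a flag is raised
  and in no read do the two candidates agree on the position.  The filter
  only ever converts trim into no-trim.  An alternative reading (adapter in
  the tail *without* a tail paired-end hit) is available as
  `tail_rule = "prose"` for experimentation; the default is the stricter
  conjunction rule.
* **Threshold.**  The pair is trimmed when the combined score strictly
  exceeds `trim_score = 10`.  At Q30, 14 matched bases score about 13.9 and
  pass; 10 cannot.
* **1-bp adjustment.**  Indels can shift the true adapter start by one
  base, so before cutting, the adapter's first four bases are compared at
  `s - 1`, `s`, `s + 1` and the best candidate wins (ties prefer `s`, then
  the smaller offset).  Positions within three bases of the read end skip
  the adjustment — too little adapter remains to check.  Kept lengths are
  clamped to each read's length.

## Overlap consensus

After adapter trimming, pairs that share an overlap get a second service:
disagreeing calls in the overlap are repaired using the mate as a replicate
measurement.

1. **Predict.**  If adapters were trimmed and the two kept lengths agree,
   the insert size is that length.  Otherwise two reverse-complement head
   scans run (mapping `s = offset + len(other)`), and the prediction holds
   only when both are found and agree.
2. **Assess.**  The whole overlap is compared base by base (read 1 position
   `i` against the complement of read 2 position `s - 1 - i`) with `N`
   treated as a mismatch; the overlap stands when the mismatch ratio is at
   most 0.28.  An empty overlap fails.
3. **Correct.**  At each disagreeing position the call with the higher
   Phred score wins and its quality is copied to both reads; ties keep
   read 1's call.  Lengths never change; afterwards the overlap regions are
   reverse-complement identical.

The tie rule means ties propagate read 1's call — including an `N` — into
read 2.  With informative qualities (the setting the rule is designed for)
the error is the lower-quality call and is repaired; the package's property
tests build exactly that setting.

## Remaining stages

The stage order is fixed: adapter trimming, consensus, sliding-window
quality trimming, optional N-trimming, optional hard clipping, length
filtering.  The quality trimmer slides a `window = 5` base window from the
front (tail windows truncate to the available bases) and cuts at the first
window whose mean Phred score falls below `quality_threshold = 15`.  The
length filter drops both mates together.  `trim_pairs()` runs the whole
pipeline in one compiled pass; `trim_pair()` composes the exported module
functions and is tested to agree with it row by row.

## The simulator

`simulate_read_pair()` mimics sequencing by synthesis.  A uniform random
ACGT insert of the requested size forms template 1 (`insert + adapter1`)
and template 2 (`reverse_complement(insert) + adapter2`).  Each template is
copied base by base: with `del_rate` the base is skipped, with `ins_rate` a
uniform random base is emitted first, with `sub_rate` a different base
replaces it; after the template, uniform random filler fills the read to
`read_length`.  The recorded truth is the position of the first surviving
adapter-derived base in the final read (`read_length` when none lands
inside), tracked through indels — so an insert of 100 with a deletion
produces a legitimately adapter-bearing read, which the evaluation
partitions accordingly.

The baseline error profile is 0.1% substitutions and 0.001% insertions and
deletions per base, scaled linearly by `baseline_error_profile(multiplier)`.
Qualities are a constant Phred score (default Q30): the simulator scopes
deliberately exclude quality decay, so the 0.6/0.75 quality machinery is
inert on simulated data unless `quality` is lowered explicitly.  All
randomness draws from R's RNG, so `set.seed()` (or the `seed` arguments)
makes every dataset reproducible.

`simulate_grid()` crosses profile multipliers, adapter prefix lengths and
insert sizes; the defaults describe a 100-bp benchmark in which even insert
sizes 66-98 carry adapter and 100-120 are adapter-free.

## Evaluation

`evaluate_trimming()` scores each read against the truth: adapter-bearing
reads (truth < read length) are true positives exactly when the trimmed
length equals the truth; adapter-free reads are true negatives exactly when
left at full length.  Signed differences additionally classify reads as
accurate, 1-bp, or multi-bp over-/under-trimmed.  The Matthews correlation
coefficient uses the convention that a zero denominator yields 0, and
computes in double precision to avoid integer overflow at realistic read
counts.

## Numerical and implementation notes

* All core loops run in C++ (via Rcpp) on the packed representation; the R
  functions are thin typed wrappers, and the batch driver reuses the same
  internals, so there is a single implementation of every rule.
* 64-bit words cross the R boundary as 16-digit hex strings, since R has no
  lossless 64-bit integer type.
* Adapters shorter than 16 bases are gap-padded with a warning; the padding
  nibbles count as permanent mismatches, so very short adapters
  systematically under-match.
* Degenerate inputs are defined, not errors: empty reads, empty overlaps
  and all-gap windows fail their respective checks; clip counts larger than
  the read yield empty reads; empty FASTQ files round-trip as zero pairs.

## Problem sizes

The unit and property tests run on reads of 10-120 bases and on simulated
grids of tens to hundreds of pairs per condition; the statistical
acceptance tests use 1,000 pairs per condition (tens of thousands of reads
per assertion) and three-sigma binomial allowances around the asserted
proportions.  `scripts/acceptance.R` recomputes the headline accuracy,
retention and 5x-error targets at 500 pairs per condition across the full
adapter-length grid in a few seconds.

## Limitations

* Single-end mode is a convenience (`trim_single()`), not a benchmarked
  procedure; the decision rules are inherently paired.
* The chance-match trimming of adapter-free reads described above is an
  inherent property of the head-against-mate orientation, bounded in
  practice by the score threshold to roughly three reads in ten thousand.
* Homopolymer trimming and complexity filtering are reserved CLI flags,
  not implemented features.
* The simulator's constant quality strings exercise the sequence machinery
  fully but the quality machinery only at its floors.
* Phred+33 is the only supported quality encoding, and `threads` is
  accepted for interface compatibility only — processing is single-threaded
  and deterministic.
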