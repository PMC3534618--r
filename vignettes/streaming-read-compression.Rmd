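---
title: "Streaming read compression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming read compression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readsqueeze)
```

## The method

Short-read libraries are often highly redundant: in RNA-Seq a handful of
highly expressed transcripts generate enormous numbers of identical reads,
and sequential aligners re-align every copy from scratch. `readsqueeze`
wraps such an aligner in three streaming stages:

1. **Compress.** Each read (or mate pair) is canonicalized and packed;
   a map from packed key to observation counts decides whether the
   sequence is new. First occurrences are written, in order, to a FASTA of
   unique sequences named by synthetic stable identifiers (`u0`, `u1`, ...);
   repeats only increment a forward or reverse counter.
2. **Align.** Any SAM-producing aligner consumes the unique-sequence
   FASTA. The wrapper assumes the aligner is deterministic and ignores
   quality strings — the unique sequences are aligned without qualities,
   exactly once each.
3. **Reconstitute.** Each SAM line for key `K` with counts `(f, r)` is
   re-emitted `f` times as-is and `r` times strand-flipped, restoring the
   full read multiset with corrected orientation.

The process deliberately sacrifices per-copy read names, quality strings
and the original read order; names and qualities can optionally be
preserved through a sorted sidecar file and re-attached per copy during
reconstitution.

## The packed sequence object

Sequences are held packed, not as text. N-free sequences use 2 bits per
base (`A=00, C=01, G=10, T=11`); the first N restarts packing at 3 bits
per base (`A=000 ... N=100`). Bases fill bytes left to right, first base
in the most significant bits, final byte zero-padded. A forced 2-bit mode
evaluates every N as an A (applied *before* canonicalization, so a read
and its reverse complement are compared post-substitution). Equality
short-circuits on the encoding and base count before comparing payload
bytes blockwise, and the bucket hash — 32-bit MurmurHash2, seed 0 — is
computed over payload bytes only.

One deliberate extension: the object stores the **base count**, not only
the byte count. Zero padding makes trailing-A sequences of different
lengths byte-identical (`AAAA` and `AAAAA` both pack to `00 00`), so a
byte count alone is not injective; the base count restores injectivity at
no observable cost. The 20-byte-per-entry memory model below still charges
the original accounting.

Choice of hash: the "modified" MurmurHash2 variant the original design
referred to is unspecified, so the published reference algorithm is used
with seed 0. Collisions are resolved by full packed comparison, so this
choice affects speed only, never correctness.

## Canonicalization

With reverse-complement collapsing on, a single-end read and its reverse
complement share one key: the **bytewise lexicographically smaller** of
the two (locale-independent). Which representative becomes the key is not
dictated by the method — any deterministic, order-independent choice
works — and the lexicographic minimum is the simplest such rule.
Palindromes tie and count as forward, in both observed orientations.

A forward-reverse mate pair sequenced from the opposite strand of its
fragment appears as the mate-swapped reverse complement:
`(s1, s2)` duplicates `(rc(s2), rc(s1))`. The candidate with the smaller
concatenation wins; the store key is the packed concatenation with the
mate-1 length recorded so the pair can be split exactly. Following the
concatenation rule, two pairs with equal concatenations but different
mate-length splits would share an entry; with fixed-length mates this
cannot arise.

## The store

An in-memory hash map keyed by the payload hash, buckets resolved by full
packed equality. Each entry carries forward and reverse counts, the
first-seen read name, and (only when restoration is enabled) the
first-seen quality. Counts are R doubles, exact to 2^53, rather than the
original 4-byte integers — overflow is detected, not wrapped.

An optional **singleton set** keeps first observations in a
membership-only set, promoting a key to the counting map on its second
observation; lookups synthesize a one-count entry for set members, so the
mode is externally indistinguishable (property-tested) while keeping the
counting map restricted to genuinely redundant sequences.

## Reconstitution semantics

A strand flip toggles flag bit 0x10, reverse complements the sequence
field, reverses the quality string and reverses the CIGAR element-wise;
unmapped records only have sequence and quality transformed. Three
documented approximations:

* **Position is kept unchanged.** For ungapped equal-length alignments the
  locus is identical; for gapped alignments the flip reverses the CIGAR
  only.
* **Alignment tags are copied verbatim** (NM, MD and friends are not
  recomputed for flipped copies).
* **Swapped-order pair copies** exchange mate flags 0x40/0x80 and flip
  both mates; `rnext`/`pnext`/`tlen` are left as reported.

Output is grouped by unique key in aligner-output order — original input
order is sacrificed — with a key's copies contiguous, forward copies
first. Without restoration, every copy carries the key's first-seen name;
with restoration, the i-th forward copy takes the i-th forward sidecar
line for that key (then reverse copies take reverse lines), and restored
qualities are reversed on flipped copies. Unmapped keys are expanded too
by default, which is what makes the pipeline lossless at the sequence
level.

## The toy aligner and what "lossless" means here

The built-in aligner scans every offset on both strands, ungapped, scored
by mismatch count. In **symmetric** mode the score is the plain Hamming
distance, so a read and its reverse complement receive strand-mirrored
hits and the wrapped pipeline reproduces direct alignment exactly. In
**left_seed** mode the first `seed_len` bases *of the read* must match
exactly — on the reverse strand that seed sits at the right end of the
forward projection — which reproduces the seed-handedness effect of real
left-seeded aligners: collapsing a read onto its reverse complement can
change the winning locus. The four-base worked construction (read `CAGT`
against loci `CATT` and `CCGT`, seed length 2, one mismatch allowed) is in
the test suite: the forward read wins the first locus, its reverse
complement the second.

Two design points needed care:

* **Tie-breaking is (fewest mismatches, leftmost position, forward
  strand), in that order.** Breaking ties by strand *before* position
  would destroy strand symmetry: if equal-score hits exist on opposite
  strands at different positions, a read and its reverse complement would
  pick different loci. Position-first is mirror-symmetric, because the
  mirror of a leftmost hit is still leftmost.
* **Concordance is compared on (reference, position, CIGAR, sequence,
  mate index, mapped status), excluding the strand bit.** When a locus
  matches a read and its reverse complement equally well *at the same
  position*, the wrapped and direct outputs legitimately differ only in
  flag 0x10 — the strand there is genuinely ambiguous. Mapping location
  is the natural accuracy currency; everything else is asserted exactly.

With a real aligner none of this is guaranteed: wrapped output differs
from direct output exactly where seed asymmetry (or tie randomization)
bites, which is why strand collapsing is optional in the first place.

## Cost models

The runtime predictor is `speed_ratio + n_compressed / n_input`, with
`speed_ratio = s_a / s_o` (aligner speed over wrapper speed). Shipped
reference ratios: Bowtie 0.079 (SE) / 0.023 (PE), BWA 0.017 / 0.015. The
break-even unique fraction is `1 − speed_ratio`; for slow, sensitive
aligners the ratio tends to zero and almost any redundancy pays.

The memory predictor charges `ceil(L/4) + 20` bytes per unique entry
(packed bases + two 4-byte counts, 4-byte hash, pointer, 2-byte size
field and heap overhead; the components sum to 22 but 20 is the operative
observed constant and is used as such). Pair entries store both mates
together, so `L` is the summed mate length and the overhead is charged
once per pair. Reports print both binary (2^30) and decimal gigabytes;
the headline projections (10^8 unique 80-mers ≈ 3.7 GiB; half as many ≈
1.85 GiB) use the binary convention. Lengths not divisible by 4 round up
to whole bytes.

## Redundancy profiling

`profile_depth()` draws seeded uniform subsets without replacement and
reports % unique reads per subset size; `profile_length()` fixes one
subset and trims reads to a series of lengths from the 3' end (suffix
removal). Subsetting uses in-memory seeded sampling — inputs here are R
vectors, so a streaming reservoir sampler would buy nothing — and never
perturbs the caller's RNG.

One property deserves a warning. "Longer reads are more unique" is a
theorem for exact-match canonicalization: trimming can only merge prefix
classes. Under reverse-complement collapsing it can **fail**: trimming the
3' end of a read trims the 5' end of its reverse complement, so two reads
collapsed at full length can separate when shortened (minimal
counterexample: `AC` and `GT` share a key at length 2 but not at length
1). The monotonicity guarantee is therefore asserted, and should only be
relied on, in exact-match mode; under rc collapsing it holds for typical
libraries but not pointwise. The same refinement logic applies to "pairs
are at least as unique as their mate-1 stream": guaranteed when the pair
key refines the mate-1 key (exact-match mode, or single-strand
libraries), violable under rc collapsing by order-swapped duplicates.

## The synthetic generator

`generate_library()` emulates the redundancy structure that makes
streaming compression worthwhile: a fixed template set (uniform random
DNA), power-law copy numbers (`rank^-skew`; every template gets at least
one copy, the remainder is multinomial), a strand mixture (`rc_fraction`),
optional per-base N injection, and forward-reverse pairing with an inner
distance. Defaults lean on desk-scale realism: read lengths 20–40, skew
around 1 for expression-like libraries and 0 for genome-like ones.
Qualities are a constant high-quality band — the mechanism under test
ignores them by design.

What it does **not** emulate: sequencing errors, platform quality
profiles, repeat structure or homology in the reference (decoy background
is uniform random), GC or coverage bias, and PCR-duplicate structure
beyond abundance skew. A green end-to-end test therefore establishes that
the compress–align–expand mechanics are exact — multisets conserved,
orientations corrected, counts conserved — not that any particular real
dataset will compress by a particular amount, nor that a real aligner's
wrapped output will be identical (with real left-seeded aligners it is
only nearly so, by the seed-handedness mechanism above).

## Degenerate inputs and numerical choices

Empty sequences, empty input streams and zero trim lengths are errors, not
silent no-ops. Non-ACGTN IUPAC codes are rejected by default; a permissive
flag maps them to N. Gzip is detected by magic bytes, never extension.
Mate files of unequal length fail at pairing. Corrupted pad bits in a
packed object are detected on unpacking. All RNG use is seeded and
restores the caller's RNG state; the toy aligner and the whole pipeline
are bit-deterministic given a seed.

## Known limitations

* Interleaved paired files, BAM/CRAM, and re-sorting output to input
  order are out of scope.
* Flipped copies keep the reported position and verbatim tags (above).
* The paired mate-swap correction approximates template-coordinate fields
  (`tlen` sign left as reported).
* The memory/runtime models predict the original C++ design's footprint
  and speed economics; they are not measurements of this implementation.
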