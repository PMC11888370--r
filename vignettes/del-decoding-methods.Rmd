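---
title: "Methods: barcode codes, decoding and enrichment statistics in delcube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode codes, decoding and enrichment statistics in delcube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delcube)
```

This vignette is the package's own account of the models and numerical
choices behind its three pillars: quaternary error-correcting barcodes,
read decoding, and enrichment statistics — together with what the built-in
simulator does and does not establish about real sequencing data.

## Quaternary Hamming codes

DNA tags live naturally over GF(4) = {0, 1, ω, ω²} with A=0, C=1, G=2,
T=3 (the symbol map is fixed and documented; nothing downstream depends
on the choice). Addition is XOR of the 2-bit values; multiplication
follows the cyclic group of order 3. A code of length $n$ is defined by a
parity-check matrix $H$ over GF(4); codewords are the null space, so the
message dimension is $k = n - \mathrm{rank}(H)$ and the code has $4^k$
barcodes.

**Distance-3 construction.** The columns of $H$ (3 rows) are the
projective representatives of $\mathrm{GF}(4)^3\setminus\{0\}$ — each
nonzero vector scaled so its first nonzero entry is 1 — in lexicographic
order, shortened to the first $n$ columns. No column is a scalar multiple
of another, which is exactly the certificate that the minimum distance is
at least 3, i.e. any single substitution is correctable: a corrupted tag
$r = c + \alpha e_j$ has syndrome $Hr^\top = \alpha h_j$, and the
$(j, \alpha)$ pair is recovered from a precomputed syndrome table. In a
shortened code some nonzero syndromes match no column; these decode to
`invalid` rather than guessing.

**Distance-4 (parity) construction.** A common recipe — append an
overall-sum row and a parity symbol to the distance-3 matrix — does not
in general preserve triple-wise column independence over GF(4), and a
greedy repair that swaps offending columns stalls well short of length
16 (we measured: 9 columns from the sum-row candidates, 14 when greedily
drawing from all of PG(3,4) in lexicographic order). delcube instead
takes the columns of the 4-row $H$ from the elliptic quadric
$x_1x_2 + x_3^2 + x_3x_4 + \omega x_4^2 = 0$ in PG(3,4): an ovoid of
$4^2+1 = 17$ points with *no three collinear*, so any three columns are
linearly independent and every shortening to $n \le 16$ has minimum
distance $\ge 4$. The first four columns are chosen to guarantee
rank 4 (an arbitrary quadric section can sit in a hyperplane), the rest
follow in lexicographic order. Both certificates — pairwise independence
for $d\ge3$, triple-wise for $d\ge4$ — are re-verified directly at build
time rather than assumed.

Decoding semantics in parity mode: a nonzero syndrome that matches
$\alpha h_j$ corrects position $j$; any other nonzero syndrome is
`detected_uncorrectable`. Because no three columns are dependent, a
double substitution can never produce a single-column syndrome, which is
the package's no-silent-miscorrection guarantee (verified exhaustively
for all $256 \times 252$ double corruptions at $n=8$ in the test suite).
In non-parity mode `detected_uncorrectable` is never reported — distance
3 cannot distinguish a double error from a correctable single — and
unmatched syndromes are `invalid`.

**Barcode sets** are sampled from the codeword space without replacement
under a user seed. No GC-content or homopolymer filtering is applied;
tags are optimal for the distance metric only.

**Lookup decoding.** Tag sets that follow no single code are decoded by
an associative map: each tag maps to itself, and a single-substitution
neighbour maps to a tag iff exactly one tag claims it and the neighbour
is not itself a tag. On a subset of Hamming codewords this coincides with
syndrome decoding wherever the corrected codeword is in the subset (a
property test in the suite).

## Read decoding

Reads are matched to libraries and then to the barcode schema by
semi-global alignment: the pattern must align end to end while read
overhangs are free. Scoring (match +1, mismatch −1, gap open −2, gap
extend −1) was chosen as the smallest integer scheme in which one
substitution (−2 swing) is cheaper than one gap (−3 opening swing), so
isolated sequencing substitutions are absorbed as mismatches while
indels still open gaps; the wildcard `N`, used at building-block tag, UMI
and index positions of the schema reference, scores 0 against every base
so variable regions neither attract nor repel the alignment — constant
regions do the anchoring. Errors are counted as non-wildcard mismatches
plus gap bases, and a hit is rejected when errors exceed
`max_error_rate × pattern length`; both stage tolerances default to 0.1
errors per reference base and are exposed in the selection's
`decode_settings` and on the CLI. Ties break toward the leftmost read
start, then fewest errors, making the traceback — and hence the
per-section read spans — deterministic. The aligner is a Gotoh
three-state DP in C++; the test suite checks score agreement against an
independent plain-R oracle on 1,000 random (read, reference) pairs, and
an insertion at a section boundary is attributed to the left, a
convention that only matters for pathological schemas with adjacent
variable sections.

Reads are tried in both orientations (amplicon libraries arrive in
either strand); the orientation with the better library-tag alignment
wins. The pipeline is strictly staged — library match, schema alignment,
per-cycle tag decode, UMI extraction — and the first failing stage
labels the read (`no_library_match`, `schema_align_failed`,
`bb_tag_invalid` with the failing cycle, `umi_missing`). Every read gets
exactly one label, so status counts always sum to the input read count
(a conservation invariant asserted in the tests).

**UMI handling.** UMI-corrected counts are distinct-UMI counts per
(condition, compound). The default is exact string identity; `cluster1`
additionally merges UMIs within Hamming distance 1, assigning greedily
in descending read-count order (ties by string), a standard
directional-style collapse for sequencing errors in the UMI itself.
Clustering is applied when the cube is built, not when shards are
written, so the shard/merge contract stays exact: states store raw UMI
strings with read tallies, merging sums tallies and unions sets, and any
partition of the reads reproduces the single-pass cube byte for byte.
Coordinates are 0-based half-open everywhere internally and in JSON.

## Enrichment statistics

The metric suite implements standard readings of the methods commonly
cited for DEL analysis; the exact normalisations vary across the
literature, so each formula is stated here and kept deliberately plain:

- *Sampling depth*: total raw reads in a condition divided by library
  diversity — reads available per compound.
- *Normalized sequence count*: counts per million within the condition.
- *z-score*: under a null sampling probability $p_0$ (default
  $1/\text{library size}$), $z = (c - np_0)/\sqrt{np_0(1-p_0)}$ with $n$
  the condition total. A configurable multiplier is deliberately *not*
  applied; users who want a depth-normalised variant can scale the
  column.
- *z vs control*: pooled two-proportion z between target and control
  arms; zero exactly when the proportions are equal.
- *MLE enrichment ratio*: Poisson rates proportional to condition
  totals; point estimate $((c_t+\tfrac12)/N_t)/((c_c+\tfrac12)/N_c)$
  (the half-count keeps zero-count compounds finite and shrinks extreme
  ratios), interval by the conditional-binomial argument — given
  $m = c_t + c_c$, $c_t \sim \mathrm{Bin}(m, p)$ with
  $p/(1-p) = \lambda_t N_t / (\lambda_c N_c)$ — transformed from a
  Clopper-Pearson interval for $p$. The interval is exact-conservative;
  a parametric simulation in the tests confirms ≥ nominal−2% coverage.

UMI-corrected counts are the default input (raw counts by flag): raw
counts double-count PCR duplicates, which is why the cube stores both.
No multiple-testing correction is applied by default — thresholds are
user-set, as is conventional for DEL feature nomination — and synthon
aggregation simply sums counts over the free cycles before the same
metrics are applied with the synthon count as the diversity.

The baseline-ML check undersamples the majority class to the minority
size (so the balanced set is twice the minority count), then
cross-validates a pluggable classifier (default: random forest) against
a majority-class dummy. Its purpose is diagnostic — on balanced data the
dummy pins 0.5, so the gap is a learnable-signal measure — not a
production model.

## The simulator, and what passing tests show

`simulate_selection()` draws compounds from a weight vector
(multinomial), renders each barcode exactly (constant sections verbatim,
sampled tags, uniform random UMI), adds 0–10 random flanking bases per
side to exercise the free end gaps, injects i.i.d. per-base
substitutions and single-base indels, and reverse-complements about half
the reads. `planted_enrichment_weights()` up-weights a seeded hit set
`fold`-fold; the expected hit read share is $fh/(fh+1-h)$.

This error model is deliberately simple. It is **not** a
sequencer-realistic profile: real nanopore data has correlated,
homopolymer-biased indels, quality-dependent substitutions and chimeric
reads, and PCR introduces amplification bias that the simulator does not
model. Passing the simulated decode-rate band therefore shows the
pipeline's *algorithmic* correctness (alignment, syndrome correction,
accounting) under calibrated noise, not a throughput or accuracy claim
for any particular instrument. Conversely the invariants — read
conservation, shard-merge identity, UMI ≤ raw, enumeration counts —
are model-free and transfer directly.

## Problem sizes and determinism

The test suite and the acceptance script use desk-scale sizes chosen to
exercise every code path while staying quick: exhaustive code checks at
$n=7$ (256×21 singles) and $n=8$ parity (256×252 doubles); full-codebook
distance verification wherever $4^k \le 10^5$ (using the
linear-code identity min-distance = min nonzero weight) and 500-codeword
samples above that; a 50,000-read, 24³-compound selection at 0.5%
substitution / 0.1% indel for the decode-rate band; 1,000 random triples
for the alignment oracle; and a 10×10×10 enumeration. Every stochastic
step takes an explicit seed, restores the caller's RNG state, and is
asserted byte-reproducible where files are written.

## Known limitations

- Reaction schemes are linear (A→AB→ABC); nonlinear or conditional
  schemes are rejected with a clear message. Multi-product reactions
  keep the first product in canonical-SMILES order and warn.
- Chemistry (SMIRKS application, canonicalization, descriptors) runs in
  an RDKit subprocess via `python`; no structure rendering.
- Insertion/deletion-*correcting* barcodes are out of scope; indels are
  handled at the alignment stage only.
- Sample-index demultiplexing is assumed done upstream (an `index`
  schema section is modelled but not used for demultiplexing).
- Quality scores are ignored; decoding is sequence-only.
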