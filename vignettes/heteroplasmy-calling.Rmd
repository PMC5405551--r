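---
title: "Quantifying mitochondrial heteroplasmy on a circular genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial heteroplasmy on a circular genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

## The problem

Mitochondrial DNA is present in hundreds to thousands of copies per cell, and
those copies need not be identical: a variant may be carried by 100% of the
molecules (homoplasmy) or by any smaller fraction (heteroplasmy). Deep
sequencing can in principle quantify a variant's frequency down to well below
1%, but two obstacles stand in the way:

* **Circularity.** The mitochondrial genome is a circle; a linear reference
  has an arbitrary origin, and fragments spanning that origin cannot align
  contiguously. Coverage collapses near position 1 and variants there are
  lost.
* **Noise.** At frequencies below ~1%, sequencing miscalls are of the same
  order as genuine low-level heteroplasmy, so calling must weigh each
  position's variant support against an explicit error model.

`mitohet` implements the downstream half of a heteroplasmy quantification
pipeline: it consumes alignments (SAM text) produced by any external aligner
against **both** the original reference and an origin-shifted copy, and
produces per-position reports, variant calls with heteroplasmy classes, an
N-masked consensus, and pedigree transmission screens. A built-in
two-haplotype mixture simulator generates ground-truth reads so every stage
is testable end to end without any external data.

## The pipeline

For each sample the same procedure runs twice, once per reference
orientation, and the results are merged:

1. **Pileup** (`build_pileup()`): strand-resolved allele and indel counts per
   position, after discarding records with mapping quality below `q = 50` and
   bases below quality `Q = 35`. Deletion spans count toward depth;
   insertions anchor at the preceding aligned base and are left-aligned
   against reference homopolymers before aggregation. Overlapping mates are
   counted independently, matching the behavior of the classical mpileup
   tool-chain that predates overlap clipping.
2. **Calling** (`call_positions()`): at every position the non-reference
   allele (SNV, insertion or deletion) with the highest qualified count is
   the candidate. Its significance is a one-sided Fisher exact test of the
   observed `(reads1, reads2)` against the counts expected from a fixed
   per-allele error rate `e = 0.001` at the same depth, computed as a
   hypergeometric right tail. A candidate passes when its frequency is at
   least `min_var_freq` (0.1%), it has at least 2 supporting reads, and
   `p <= 0.001`. Ties between co-maximal candidates break
   deterministically: A < C < G < T, SNV before insertion before deletion.
3. **Merge** (`merge_dual()`): shifted-orientation rows are re-coordinated
   with `unshift_position()` and, per position, the row with the larger
   coverage wins, all columns traveling together. Ties keep the
   original-orientation row, whose numbering is native.
4. **Flags and masking** (`relative_coverage()`, `flag_coverage()`): coverage
   is normalized by the genome-wide mean (all positions, zeros included) and
   flagged `GOOD` (>= 10%), `WARNING` (>= 1%) or `EXCLUDE` (< 1%). Excluded
   positions are masked: consensus `N`, frequency forced to 0, never
   reported as variants.
5. **Classification** (`classify_heteroplasmy()`): reported variants are
   homoplasmic (> 98%), high-frequency heteroplasmy (10-98%) or
   low-frequency heteroplasmy (1-10%); SNVs below 1% and indels below 10%
   are not reported, the indel floor reflecting the higher indel error floor
   of rolling-circle amplified libraries. By default only `GOOD`-flagged
   positions are reported; `report_flags` relaxes this.
6. **Transmission** (`transmission_table()`): given a pedigree, the union of
   reported variants is tabulated per sample, and two screens are derived:
   father-specific variants (absent in the corresponding mother) with their
   status in each offspring, and the mother's variants with offspring status.

### Why a null error rate of 0.001, and why Fisher?

The upstream caller that this package reconstructs delegates significance to
a Fisher exact test against expected counts at a fixed error rate; the exact
internals are not published, so the construction here — a 2x2 table
`[[reads1, reads2], [round(d(1-e)), round(d·e)]]` with `d = reads1 + reads2`,
right tail — is documented and parameterized (`error_rate` in
`call_params()`) rather than claimed identical. At 3,000X this threshold
requires roughly 11 variant reads (~0.37%) before a call can reach
`p < 0.001`, which is what makes the caller's false-positive rate negligible
while still detecting every engineered variant at 1.6% in the benchmark.

### Coordinate conventions

All coordinates are 1-based and fully closed. When the input reference
carries placeholder Ns (as the human rCRS does at position 3107), they are
deleted before alignment (`load_reference(strip_n = TRUE)`) and a coordinate
map preserves the input numbering in every report. The rule generalizes to
any number of Ns: each retained base reports its original position. The
origin shift is exactly `floor(L/2)` — deterministic and testable — and
`unshift_position(p) = ((p - 1 + s) mod L) + 1`.

### Indel frequency accounting

A read whose alignment terminates exactly at an indel's anchor cannot
witness the junction: it is uninformative rather than reference-supporting.
`reads1` for an indel candidate therefore excludes both indel-carrying reads
(which also match the reference base at the anchor) and junction-terminating
reads. Without this accounting, a fully homoplasmic insertion would plateau
near 98% instead of 100% simply because ~2% of anchor-covering reads end at
the junction.

## The simulator

`mixture_design()` + `simulate_reads()` emulate the benchmark that validated
the original method: two haplotypes of one circular genome, mixed at a
chosen ratio and sequenced as 2x150 paired reads.

* Haplotype A is the reference; haplotype B carries 88 homoplasmic SNVs at
  random positions plus two insertions — a `+G`, and a `+AA` placed
  immediately before an 8-A homopolymer, deliberately the hardest common
  indel context (the insertion is indistinguishable from the run except at
  its boundaries, and left-alignment must normalize it).
* Fragments of 300 bp are drawn uniformly on the circle; each fragment comes
  from haplotype B with probability `ratio/100`; mate 1 covers the first
  150 bases on the + strand, mate 2 the last 150 on the − strand.
* Errors: uniform per-base substitution at 0.1% and one-base indels at
  0.01%, emitted at phred 40 like every other base — they model miscalls,
  not low-confidence calls, so they are exactly the reads the quality
  filters cannot remove. The much larger empirical noise of rolling-circle
  amplification (substitutions up to ~0.4%, indels ~2% in homopolymers) is
  deliberately **not** included by default: it would confound the
  benchmark's interpretability, and the reporting thresholds (1% SNV / 10%
  indel) exist precisely to sit above it on real data.
* Every read is emitted, with its ground-truth alignment at mapping quality
  60, in each orientation where its mapping is contiguous; reads spanning
  the original origin appear only in the shifted SAM and vice versa.
* The default ratio grid is {0, 0.4, 0.8, 1.6, 3.2, 6.25, 12.5, 25, 50, 75,
  90, 100} — a two-fold series through the published sensitivity points
  (0.4, 0.8, 1.6) plus anchors; the published benchmark used 12 ratios
  without enumerating them. Coverage defaults to 3,000X, the published
  scale; one run of the full titration takes about a minute per mixture on
  one CPU.

What the simulator does *not* emulate: alignment ambiguity (truth alignments
are emitted directly, so mapping-quality degradation in variant-dense
regions — the main accuracy covariate on real data — does not occur),
GC/tagmentation coverage bias, quality-score profiles, NUMT contamination,
and amplification chimeras. Passing benchmarks here validate the counting,
testing, merging and reporting machinery, not robustness to aligner
artifacts. One visible consequence: truth alignments place an insertion's
bases explicitly even when a read ends inside a repeat where a real aligner
would simply match them to the reference; trailing insertions are
soft-clipped to keep alignments realistic at read boundaries.

## Benchmark metrics and calibration

`run_benchmark()` executes simulate → call → measure over the ratio grid.
Expected frequencies are calibrated from the 50/50 run,
`expected(r) = r × measured(50)/50`, mirroring the published procedure of
anchoring the titration on the measured mid-point (which absorbs any
constant proportionality between nominal input and realized fraction). The
headline metrics are the Pearson correlation and OLS slope between
calibrated expected and mean measured frequency across ratios. Because the
calibration anchor is itself an estimate, its sampling error is propagated
into the reported slope standard error; the OLS-only value is kept as
`slope_se_ols`.

Detection fractions use the full default filters. With the default design
the behavior reproduces the published pattern: partial detection at 0.4%,
most variants at 0.8%, and all 88 from 1.6% upward, with no false-positive
SNV at any ratio.

## Numerical and design choices

* Flag boundaries are inclusive at the lower edge (exactly 10% → `GOOD`,
  exactly 1% → `WARNING`); the homoplasmy bound is strict (exactly 98% →
  high-frequency). The class bounds at exactly 10% follow the same
  lower-edge convention (10% → high-frequency).
* Coverage ties in the dual merge keep the original-orientation row.
* `Covmp` counts every mapq-passing aligned base (and deletion spans)
  regardless of base quality; `QDepth` counts only bases passing `Q`.
* The samtools `-C 50` mapping-quality adjustment is version-specific and
  unpublished; the default here is the identity, with a documented
  mismatch-penalty hook (`adjusted_mapping_quality(hook = "mismatch")`)
  whose coefficient is the `C` parameter. Simulated reads carry truthful
  mapping qualities, so `q = 50` is the operative filter.
* The consensus is substitution-only by default (`FastA` column, length
  always `L`) so coordinates stay stable for downstream haplogroup tools;
  `consensus_seq(apply_indels = TRUE)` applies majority indels.
* The strand filter annotates calls (`StrandFilter` column) but does not
  remove them; `call_variants(hard_strand_filter = TRUE)` promotes it.
* Problem sizes in the test suite: unit tests run on 0.3-2 kb genomes at
  20-400X; the acceptance suite runs the full 16.6 kb / 3,000X design, a
  12-ratio titration, and five independent titration seeds for the
  specificity property.

## Known limitations

* Large structural variants and truncated-genome quantification are out of
  scope; reads are assumed to come from a single circular replicon.
* Only `M`, `I`, `D`, `S` CIGAR operations are supported; spliced or
  hard-clipped alignments are rejected.
* Indel left-alignment stops at position 1 rather than wrapping across the
  origin; an indel inside a homopolymer that itself spans the origin may
  anchor differently in the two orientations.
* The exact-test reconstruction is not guaranteed bit-identical to the
  historical caller it emulates; `error_rate` is exposed so the null can be
  tightened or relaxed.
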