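---
title: "Small RNA discovery and annotation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA discovery and annotation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`smrnakit` re-implements, at desk scale, the computational workflow used to
discover and annotate small regulatory RNAs in the coccolithophore
*Emiliania huxleyi* from a deep-sequenced small-RNA library: candidate miRNA
discovery from hairpin precursors, endogenous siRNA classification
(repeat-associated, phased trans-acting, natural-antisense, piRNA-like),
miRNA target prediction, and stem-loop RT-qPCR quantification arithmetic.
This vignette records the models, the tunable parameters, and the design
choices made where the design was genuinely open.

## The discovery model

A mature miRNA is a short (18–26 nt) RNA excised by a Dicer-family enzyme
from a fold-back (hairpin) precursor. Discovery from a sequenced library
proceeds locus by locus:

1. **Collapse and filter.** Raw reads are collapsed to unique sequences with
   counts (`collapse_reads()`). Reads outside the length window and reads
   perfectly matching tRNA/rRNA contaminants are removed (`filter_reads()`).
   Because sequenced small RNAs are *fragments* of structural RNAs, the
   default contaminant rule is substring containment, with whole-sequence
   equality available behind a flag; reverse-strand matches are also removed
   by default. Both choices are flags because the upstream convention is not
   observable from the data.
2. **Exact placement.** Unique reads are placed on both genome strands by
   exact match only (`build_index()`/`map_exact()`), a fixed-k seed table
   (k = 12) with full-length verification. Multi-mapping is preserved; reads
   mapping to more than 1,000 loci are flagged hyper-repetitive and excluded
   from miRNA discovery (they are repeat-derived by definition) while
   remaining available to the repeat-associated siRNA analysis.
3. **Window scan.** Around each hit, candidate precursor windows of 60 to
   300 nt in 20-nt increments are extracted (13 lengths), each in three
   placements: mature anchored 10 nt from the window 5' end, 10 nt from the
   3' end, and centered. Placements that would leave the scaffold are
   dropped. Three anchored placements cover both hairpin arms without a
   quadratic placement scan.
4. **Hairpin curation.** Each window is folded (`fold_mfe()`) and scored
   against the "good structure" rules (`evaluate_hairpin()`): exactly one
   terminal loop; at least 50% of window positions paired; at most four
   mismatched and at most two bulged runs (each ≤ 2 nt) in the mature
   region; and MFE below −0.35 × length kcal/mol (−35 kcal/mol for a 100-nt
   precursor; the comparison is strict, so −35.0 exactly fails).
5. **miRNA\* detection.** The expected star span is derived from the
   structure: the opposite-arm segment pairing with the mature, with both
   3' ends shifted by the 2-nt Dicer overhang. A star is reported only when
   a mapped read coincides with that span within ±1 nt at each end (the
   tolerance absorbs cleavage-position wobble) and the duplex carries at
   most four mismatches.
6. **Abundance rules.** A candidate needs either library count ≥ 3 *and* a
   star read, or count ≥ 100 with a good hairpin alone.
7. **Deduplication and context.** Among passing windows for one read the
   window preferred is: eligible under the abundance rule first, then lowest
   MFE, then shortest, then leftmost. Candidates whose precursors overlap by
   ≥ 50% of the shorter locus are merged, keeping the higher-abundance
   mature. Each candidate locus is classified strand-agnostically as exon
   (≥ 1 nt exon overlap), intron (inside a gene span), or intergenic.

### Mismatch and bulge accounting

The curation rules distinguish *mismatches* (mature positions unpaired but
facing nucleotides on the opposing strand) from *bulges* (mature positions
with no opposing nucleotide). For each maximal unpaired run in the mature,
the gap between the partners of its flanking paired positions gives the
opposing-side width g: min(run, g) positions count as mismatches, and any
excess beyond g forms one bulge run of that length. Terminal unpaired runs
with no paired flank count as mismatches — a strict, deterministic
convention.

## The folding engine

The MFE engine (`src/fold.cpp`) is a Zuker-style dynamic program over all
non-crossing structures with a 3-nt minimum hairpin loop, under a
deliberately small energy model:

* **Stacks** are additive pair stabilities, v(AU) = v(UA) = −1.1,
  v(GC) = v(CG) = −2.2, v(GU) = v(UG) = −0.8 kcal/mol; a stack of pair p on
  pair q contributes v(p) + v(q). Additivity makes the model exactly
  symmetric under reverse-complementation.
* **Hairpin loops** cost 4.5 + 0.3·(L − 3); **bulges/interior loops** cost
  2.0 + 0.5·u for u unpaired nt (interior size capped at 30 in the DP, a cap
  unreachable at oracle scale); **multiloops** cost 3.4 + 0.4·branch +
  0.1·unpaired. No dangles, no coaxial stacking.

The empty structure is always a candidate, so any reported structure with
pairs has energy ≤ 0. The same constants are implemented a second time in
pure R (`structure_energy()`), and `enumerate_min_energy()` exhaustively
enumerates all structures of sequences up to 18 nt; the test suite checks
the DP against this oracle on hundreds of random sequences, and
`duplex_energy()` (intermolecular-only pairing, used for animal-mode target
screens) against an independent recursive oracle.

Absolute energies from this model differ from full Turner-parameter folders.
That is acceptable by design: every energy screen in the pipeline
(−0.35 × length, duplex < −20, UPE ≤ 30) is threshold-relative and
calibrated against this engine, and the folding entry points are ordinary
functions that a caller can substitute with an external folder for
real-data work.

## Endogenous siRNA classes

* **ra-siRNA**: a hit is repeat-associated iff *fully contained* in a masked
  interval. Containment (not partial overlap) keeps the call unambiguous.
* **ta-siRNA**: phased loci are detected by anchoring a 231-nt window at
  each distinct 21-nt read start and counting distinct occupied start
  positions on both strands, the antisense register offset by +2 nt (the
  double-strand Dicer overhang geometry). The in-register occupancy k of n
  occupied positions among K = 2 × 11 in-register of N = 2 × 231 total is
  tested against the hypergeometric upper tail; windows at p ≤ 0.001 are
  reported, deduplicated by overlap. Because the anchoring read *defines*
  the register, it is not evidence of phasing: the p-value is computed
  conditionally on the anchor, as P[X ≥ k−1] for X ~ Hyp(N−1, K−1, n−1).
  Without this conditioning a read-anchored scan is anti-conservative and
  could not hold the nominal type-I error that the test suite verifies on
  10,000 uniform-placement windows. Whether a position occupied on both
  strands counts once or twice is a modelling choice; here each strand
  contributes its own position universe.
* **nat-siRNA**: hits antisense to annotated exons are flagged, and all
  opposite-strand gene pairs whose spans overlap by ≥ 25 nt are reported.
* **piRNA-like**: 26–30 nt reads are scored by a Fisher linear discriminant
  over normalized k-mer frequencies, k = 1..5 (4 + 16 + 64 + 256 + 1024 =
  1364 dimensions), with a ridge-regularized pooled covariance and the
  midpoint of projected class means as threshold. The classifier is trained
  on labelled sets supplied by the caller (published discriminant weights
  are not available); the 5'-U and position-10-A biases are reported as
  diagnostics (`positional_bias()`) and never used as filters, matching the
  negative ping-pong finding in this organism.

## Target prediction

*Plant mode* scans for near-perfect reverse complementarity: full mismatches
score 1, G:U wobbles 0.5, budget ≤ 3; surviving sites are screened by the
unpaired energy (UPE) needed to open the site, computed as
`fold_constrained(context, site) − fold_mfe(context)` over a 200-nt context
window centered on the site (clipped at transcript ends), keeping UPE ≤ 30.
The 200-nt window is a configurable choice — published accessibility
screens differ on this and the value is not recoverable from the original
analysis. *Animal mode* requires a perfect seed (miRNA positions 2–8) match
and an intermolecular duplex energy below −20 kcal/mol. In both modes
overlapping alignments for one miRNA–transcript pair merge to the
best-scoring site. GO level-2 clustering assigns a target gene to every
second-level term (direct child of a namespace root) that is an ancestor of,
or equal to, any of its annotations; genes may join multiple clusters.

## qPCR arithmetic

Relative expression is 2^−ΔCT against the reference small nuclear RNA;
differential expression between conditions is 2^−ΔΔCT; replicate CTs are
averaged before exponentiation (the Livak convention). Primer efficiency
from a dilution-series slope is E = 10^(−1/slope), reported both raw (2 at
perfect doubling) and as percent (E − 1) × 100 — the percent scale
reconciles the formula with efficiency ranges quoted as ~96–99. Because the
convention behind published "fold ± spread" values is ambiguous, both the
SD of per-replicate folds and the propagated ΔΔCT SD are emitted.

## The synthetic world

No read library is publicly deposited for this system, so the package ships
a truth-labelled generator (`synthesize_world()`) used by every
pipeline-level test. Its defaults are the stated test bed:

* a 6 × 30 kb genome at GC 0.65 (the organism's genome is strongly GC-rich);
* 30 planted miRNA hairpins: 10-nt lower stem + mature (19–23 nt) + 8–15 nt
  loop + the reverse complement of stem-plus-mature carrying 0–2
  substitutions, padded with an unpaired tail to the nearest scan-window
  width so that one 5'-anchored window reproduces the precursor exactly
  (precursors land at 80–100 nt, matching the reported median of ~93 nt).
  Construction is by rejection: each precursor is verified against
  `evaluate_hairpin()` and redrawn on failure, so planted positives are true
  positives under the package's own engine. Mature counts are log-normal
  with a floor of 3; star reads are emitted at the fold-derived star span
  with counts ≥ 1;
* 4 phased loci with 9 in-register 21-nt starts (antisense register +2);
* 2 repeat families of 6 identical copies; 4 overlapping antisense gene
  pairs; 4 tRNA/rRNA contaminant genes emitting fragment reads; 8 background
  multi-exon genes;
* noise reads as uniform genomic substrings of 15–30 nt at multiplicity 1;
  read multiplicities elsewhere are log-normal (μ = 0, σ = 2.5), giving the
  heavy-tailed count histogram (1 to ~10⁴) seen in real libraries.

What the generator does *not* emulate: sequencing errors, adapter remnants,
non-uniform coverage along precursors, isomiR end-heterogeneity beyond the
±1-nt star tolerance, and diverged repeat copies. A green recovery test
therefore establishes the pipeline's internal consistency
(generator-evaluator closure and correct bookkeeping), not performance on
real sequencing artifacts.

## Numerical choices and degenerate inputs

* MFE comparisons are strict (`<`); the DP breaks ties deterministically and
  the enumeration oracle breaks ties toward fewer pairs, then the
  lexicographically smallest dot-bracket. Only energies are asserted equal
  between the two.
* Medians of candidate summaries are lower medians (for even n, the n/2-th
  order statistic), consistent with a reported precursor median of 93 where
  the interpolated median would be 93.5.
* Empty inputs return typed empty results (empty candidate table, all-zero
  histograms); an empty candidate summary is an error.
* `phasing_pvalue` is computed by log-stable summation of exact terms;
  ties and degenerate windows (n < 2 occupied positions) are never reported.
* All genomic coordinates are 0-based half-open with explicit strand
  internally; GFF3 (1-based inclusive) and BED (0-based half-open) are
  converted only at the I/O boundary.
* `plant_feature()` returns a modified copy of the genome (R value
  semantics) rather than mutating its argument.

## Known limitations

* The energy model is intentionally minimal; absolute MFEs are not
  comparable to Turner-model folders, only orderings and threshold-relative
  screens are meaningful.
* Exact matching only: no mismatched or gapped alignment, so SNP-bearing
  reads are invisible.
* The window scan fixes three placements per length; a hairpin whose mature
  sits far from either arm terminus in every window geometry can be missed.
* Full-library statistics from the original deep-sequencing study (millions
  of reads against a 168-Mb genome and external databases) are out of desk
  scale; the tests assert in-table worked examples and parameter recovery on
  the synthetic world instead.
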