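---
title: "Methods: phased siRNA discovery, TAS locus characterization, and degradome validation"
author: "phasitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phased siRNA discovery, TAS locus characterization, and degradome validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind phasitrack, in the spirit of the methods sections of mature
differential-expression and genomics packages. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Biological model

Plant ta-siRNAs are phased 21-nt secondary siRNAs. In the two-hit
pathway, a non-coding transcript carries two binding sites for a 21-nt
trigger miRNA (miR390 for the *TAS3* family). Cleavage at the **3′**
site defines a register; RDR6/SGS3 convert the upstream RNA to a duplex
and DCL4 processes it 5′-ward of the cut into siRNAs spaced in exact
21-nt steps. Dicer leaves 2-nt 3′ overhangs, so the minus-strand member
of each duplex sits 2 nt to the left of its plus-strand partner. A
subset of these siRNAs, the tasiR-ARFs, guide cleavage of *ARF3*
transcripts. The pipeline's stages mirror that model: find genotype-
dependent siRNA windows, find phased clusters, locate dual trigger
sites, enumerate the phased products, and confirm predicted cleavage
with degradome (PARE) 5′-end tags.

## Coordinates and abundance

All coordinates are 0-based half-open. The strand-aware 5′ end of an
alignment is `start` on the plus strand and `start + length − 1` on the
minus strand. Abundance is reads per million (RPM): `copies × 1e6 /
genome_matched_total`, the denominator being all genome-matched reads of
the library **before** structural-RNA removal — "genome-matched" is the
stated unit, and the blacklist removes loci from analysis, not reads
from the sequencing depth. Multimapped alignments (up to 20 per read by
default) each contribute their full copy count; fractional 1/n weighting
is deliberately not applied in the small RNA stages, where excluding or
down-weighting repeated sequences would discard known multi-copy TAS
and miRNA families.

## Windowed differential abundance

Reads of each size class (21, 22, 24 nt) are counted in non-overlapping
500-nt windows tiling each sequence from coordinate 0 (the anchor is a
convention; windows are reported with explicit coordinates). A read
belongs to the window containing its strand-aware 5′ end, strands
pooled. Windows with fewer than 10 reads summed over all libraries are
dropped before testing.

Testing uses the exact negative-binomial test with a single common
dispersion shared across windows, estimated by quantile-adjusted
conditional maximum likelihood — the construction implemented in edgeR,
which backs `nb_test()`. With three replicates per genotype, a common
dispersion is the stable choice; trended/tagwise dispersions are out of
scope. A non-positive or undefined estimate falls back to a
method-of-moments estimate on size-factor-scaled counts and is clamped
to 1e-6 with a warning.

The reported `log2fc` is log2((mutant mean + 0.5) / (wild-type mean +
0.5)) on size-factor-normalized means; the 0.5 pseudo-count keeps
windows empty in one genotype finite. Positive values mean
`up_in_mutant`. The per-locus summary table reports the complementary
wild-type/mutant fold (the convention of published TAS locus tables).
P-values are Benjamini–Hochberg adjusted; calls require |log2fc| ≥ 1
and q < 0.05, and windows inside a supplied exclusion interval set
(e.g. an introgression interval around the mutant allele) are failed
with reason `excluded_region`.

Size-class totals (18–26 nt) are compared per class with a two-sided
Welch t-test; with millions of reads per class the totals are
approximately normal. Constant data across all libraries yields p = 1
when the group means agree (no evidence) and p = 0 otherwise.

## Phasing score and cluster scan

Strand merging maps a plus-strand read to its leftmost coordinate and a
minus-strand read to leftmost + 2, undoing the Dicer 2-nt 3′ overhang so
both strands of a duplex share one phase position. Wild-type libraries
are normalized, pooled, and scanned per size class k with 500-bp windows
sliding in 250-bp steps (half-window overlap; the slide step is a
package choice, window length is fixed by the method).

Within a window, a register is the residue class of position mod k —
an absolute convention, so translating all reads by k leaves scores and
registers invariant (a tested property). Each register is evaluated on
exactly C = ⌊500 / k⌋ phase-cycle positions counted from the window
start (C = 23, 22, 20 for k = 21, 22, 24): n is the number of occupied
cycle positions, P the summed RPM on them, U the remaining (off-register)
RPM of size-k reads in the window, and

score = (n − 2) · ln(1 + 10 · P / (1 + U)) for n ≥ 3, else 0.

This is the log-form phasing statistic of the Howell/De Paoli lineage
with constant 10; it is monotone in P and n and decreasing in U, and
requiring n ≥ 3 suppresses single-position (miRNA-like) peaks. The
best register per window is reported, ties broken toward the smaller
register. Candidacy requires ≥ 5 **raw** in-register reads (a read-count
condition), while the score itself is computed on normalized RPM;
qualification additionally requires score ≥ 25, a threshold stringent
enough to recover most confirmed *TAS* loci in published re-analyses
while rejecting diffuse background. Overlapping or abutting qualifying
windows of equal k merge into clusters; each cluster carries its
best-scoring constituent window's register, score, n, P and U — pooling
those statistics across overlapping sliding windows would double-count
reads. A cluster is mutant-dependent when it overlaps a same-size-class
window called significantly down in the mutant.

An occupied position falling inside the window but beyond the C-th
cycle of its register (possible because 500 is not a multiple of k)
counts toward U, keeping exactly C cycles per register as the statistic
defines.

## Target scoring and two-hit detection

Duplexes are scored with the Allen penalty scheme: mismatch 1, G:U
wobble 0.5, each bulged nucleotide 1, every penalty doubled at sRNA
positions 2–13 (the core), counted from the sRNA 5′ end. The predicted
cleavage position is the target nucleotide paired to sRNA position 10
(the cut falls between positions 10 and 11). T and U are equivalent on
input.

`find_sites()` slides the sRNA exhaustively along the transcript and
scores the ungapped duplex at every offset plus all variants with one
single-nucleotide bulge on either strand at internal positions (at most
one bulge per duplex, the practical regime of the classical search
tools; configurable). Two conventions are fixed and tested against an
independent enumerator: a bulged **target** nucleotide between sRNA
positions b and b+1 is charged at position b+1 for core doubling, and
when several configurations predict the same cleavage position only the
best-scoring one is kept, preferring fewer bulges, then the smaller
start. Hits are capped at score 4.5 by default; tasiR-ARF assignments
use 3.0, the ceiling observed for genuine tasiR-ARF:*ARF3* duplexes.
No per-sRNA hit cap is applied.

Complementing both strands of a duplex preserves Watson–Crick pairs but
maps G:U onto C:A (a mismatch), so score invariance under joint
complementation holds only for GU-free duplexes; the property test is
restricted accordingly.

`detect_two_hit()` returns the non-overlapping pair of qualifying sites
with the smallest combined score, ordered by coordinate; the register-
setting cleavage is taken from the 3′ site, since under the two-hit
model the 5′ site need not be cleaved.

## PARE validation

Degradome tags are pooled across PARE libraries onto per-transcript
5′-end counts. For a predicted cleavage position, W_S sums tags within
± 2 nt (5 positions) and W_L within ± 15 nt (31 positions); validation
requires W_S / W_L ≥ 0.75 and W_S ≥ 4 — thresholds on raw tag counts,
not RPM, because the floor guards against single-tag noise. Windows are
truncated at transcript boundaries (with a warning) and the truncated
sums are used as-is; W_L = 0 leaves the ratio undefined and the site
not validated.

## TAS locus characterization

D-indexing anchors at the 3′ cleavage site and counts 5′-ward: D1(+)
occupies [cleavage − 21, cleavage), D2(+) the next 21-mer, up to the
last complete cycle before the 5′ trigger site; each D_i(−) is the
duplex partner at a 2-nt left offset. (A 5′-anchored numbering exists in
parts of the literature; anchoring at the register-setting cut is the
convention used here because "in phase" is defined relative to that
cut.) A locus with an inter-site span of c complete cycles therefore
predicts 2c ta-siRNAs. Reads classify as in-phase when their
overhang-adjusted 5′ position is congruent to the cleavage position mod
21, regardless of read length; the size profile (18–26 nt) is reported
separately, so off-sized reads sitting on the register are visible as
such. The per-locus summary counts raw pooled wild-type reads of the
phase size class within the inter-site region (published locus tables
are ambiguous between raw and normalized totals; raw pooled totals are
used and the normalization is recoverable from the design table).

The package ships a reference summary of the nine maize *TAS3* family
loci (`tas3_reference()`), whose per-strand counts imply inter-site
spans; re-running those spans through the enumeration rule reproduces
the published total of 194 predicted ta-siRNAs — an internal
consistency check used by the acceptance suite.

## Synthetic data generator

The generator is first-class, tested code and defines the study
conditions the pipeline is validated under:

- toy genome: 2 chromosomes × 60 kb, loci placed on non-overlapping
  slots;
- 8 TAS-like loci with two exact trigger-complementary sites separated
  by 8–13 cycles of 21 nt (the range implied by published per-locus
  counts), a shared tasiR-ARF written at D7(+), mean 400 RPM in
  wild-type and a wild-type/mutant fold of 50 (within the published
  19–252× range), 10% out-of-phase and 10% off-size reads;
- 4 miRNA loci (single-position 21-nt peaks), 4 hairpin/antisense 22-nt
  loci, 3 LTR-repeat families × 3 identical copies whose reads are
  multimapped (`n_hits` = copy number) and gain 21/22-nt siRNAs 4× in
  the mutant, 6 heterochromatic 24-nt loci losing siRNAs (fold 0.3),
  and 50 null background loci;
- 3 replicates × 2 genotypes with NB replicate noise (dispersion 0.1)
  and a genome-matched total of 1e6, so RPM equals raw counts and hand
  checks are trivial;
- ARF3-like transcripts (2 × 1500 nt) with two tasiR-ARF-complementary
  sites whose cleavage positions are exactly 200 nt apart; PARE tags
  Poisson(20) at true cleavage sites over a uniform 0.02 tags/nt
  background, with uncleaved decoy positions recorded in the truth.

Minus-strand TAS reads are emitted at the exact duplex-partner
coordinates (leftmost = plus partner − 2), so strand merging is tested
against duplex geometry rather than against its own convention. All
outputs are byte-identical given the seed.

What the generator does **not** emulate: sequencing errors, adapter
artifacts, ligation biases, genome-scale repeat structure, transcript
isoforms, or partially complementary trigger sites. Passing tests
therefore demonstrate correctness of the statistics and conventions
under the stated generative model, not performance on real maize
libraries.

## Problem sizes and runtime choices

Test and acceptance runs use the default generator (≈ 120 kb genome,
≈ 50–60 k alignments across six libraries), 200 random toy windows for
the register oracle, 50-nt toys for the duplex-search oracle, and a
2000-window 3-vs-3 null simulation at dispersion 0.1 for NB
calibration — sizes at which every check runs in seconds to a couple of
minutes on one CPU while keeping binomial standard errors tight enough
to be informative.

## Known limitations

- Two-group designs only; no GLM layer over the NB test.
- One common dispersion; no trended or tagwise shrinkage.
- The duplex search allows at most one bulge and no G:U-aware
  thermodynamics; it is a penalty-table search, not a ΔG model.
- Cluster merging keeps the best window's statistics rather than
  re-scoring the merged interval.
- PARE validation is pooled across libraries; per-library validation is
  not implemented.
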