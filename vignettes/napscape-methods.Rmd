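---
title: "Methods: occupancy landscape analysis for a broad-binding bacterial NAP"
author: "napscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy landscape analysis for a broad-binding bacterial NAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napscape)
```

# The analysis in one paragraph

napscape analyses the genome-wide behaviour of a nucleoid-associated
protein (NAP) — a bacterial regulator that occupies long AT-rich tracts
rather than point sites — together with the point-binding sigma factors it
excludes, the temporal expression classes of the genes it covers, and the
3C-measured chromosomal contacts around its target operons. The package
covers the computational chain downstream of read mapping, peak calling
and differential-expression fitting: windowed binding signal and GC
content, replicate-consensus summits and broad regions, gene/TU occupancy
classification, temporal expression classification, 2x2 association
statistics, pairwise rank tests, and calibrated delta-delta-Ct
quantification. Every input can be generated by the package's synthetic
module with known ground truth, so each stage is testable end to end
without sequencing data.

# Coordinates and containers

All coordinates are 0-based, half-open, on every interface; GFF3
(1-based, inclusive) is converted at the file boundary. One convention
everywhere prevents off-by-one drift between tracks, intervals and
annotations. Interval sets are normalized by sorting and merging
overlapping *and bookended* intervals: a binding region is a genomic
footprint, and two fragments that touch base-to-base are one footprint.
Normalization is idempotent and preserves covered length. Strand is kept
on gene annotations but ignored by every overlap computation, since
ChIP-derived regions are strandless. Circular replicons affect only
*windows* (which may wrap across the origin); intervals never wrap — a
wrapping region would be stored as two intervals — which keeps the
interval algebra simple and testable.

# Windowed binding signal and GC content

The binding signal in each 100 bp bin is

$$S(w) = \frac{\mathrm{IP}_w}{\mathrm{Input}_w}
         \cdot \frac{\mathrm{TotalInput}}{\mathrm{TotalIP}},$$

the IP/input count ratio rescaled by the library totals. Two consequences
are used as test identities: multiplying either library (bin counts and
total together) by any constant leaves S unchanged, and the
Input-weighted mean of S over defined bins equals exactly 1 when the
totals are the genome-wide sums. Bins with zero input are *undefined* and
propagate as missing — never as zero or infinity — because a
division-by-zero bin is absence of data, not signal. Note that when the
enriched footprint is a sizable fraction of the genome, the library-total
rescaling lowers the absolute in-footprint signal below the fold
enrichment; the in/out signal *ratio* still recovers it.

GC content is computed in 500 bp windows anchored every 100 bp:
$100\,(G+C)/(A+C+G+T)$, with N bases excluded from numerator and
denominator, other ambiguity codes rejected, wrap-around on circular
replicons and truncated final windows on linear ones. Signal bins and GC
windows are paired by shared anchor start for the signal-GC correlation.
The pairing convention (anchor vs. window centre) is not forced by the
window definitions; anchor-start pairing was chosen because both grids are
anchored on the same 100 bp lattice, making the pairing exact rather than
interpolated. With a 500 bp window this offsets the GC window's centre
200 bp right of the bin's centre — immaterial for tract-scale (multi-kb)
structure, and the grids are configurable where it matters.

# Replicate consensus

Two biological replicates and one untagged control are the design assumed
throughout.

*Narrow summits.* Candidate summits from both replicates and the control
are pooled and single-linkage clustered per replicon with a 40 bp maximum
gap, so chains merge transitively. A cluster survives only if it contains
at least one summit from each replicate and none from the control; a
control summit anywhere in a chain poisons the whole cluster, the most
conservative reading of "in both replicates but not in the control". The
consensus position is the floor of the mean of the two replicate
positions — flooring makes the integer coordinate deterministic. When a
cluster holds several summits from one replicate the strongest-scored one
represents that replicate; this tie-break is the package's choice, not
asserted as the original protocol's, and single-summit clusters (the
overwhelming case at realistic summit densities) are unaffected.

*Broad regions.* The base-pair intersection of the two replicates'
broad peaks, after which any resulting interval overlapping a control
peak by at least 1 bp is removed whole — exclusion names peaks, not base
pairs. The minimum exclusion overlap is configurable as a fraction for
sensitivity analyses. Peak-caller q-value thresholds belong to the
(out-of-scope) caller and are carried only as configuration metadata.

# Occupancy and coverage

A gene's occupancy is the fraction of its bases covered by the union of
binding regions: `not_bound` (0), `partial` (0-1) or `entire` (1). Any
1 bp of overlap counts as bound by default, since no minimum is inherent
in the definition; a minimum-fraction toggle exists for sensitivity
analysis. A transcriptional unit (TU) is classified over its full span —
minimum gene start to maximum gene end, intergenic gaps included —
because a TU is one transcript unit. Genome coverage is merged region
length over the summed replicon lengths in scope. Whether plasmid
replicons belong in "the genome" for coverage denominators is a genuine
choice; the default includes all replicons, and `replicon_scope`
restricts it.

# Temporal expression classes

From per-gene log2 fold changes over a three-point time course (0, 1 and
4 h after the shift to dark, low-oxygen conditions):

* **up1**: log2FC(0 to 1 h) > 1 (strictly "more than twofold"; all
  thresholds are strict, so boundary genes are excluded).
* Among up1 genes: **transient** if log2FC(1 to 4 h) < -0.5,
  **continuous** if > +0.5, otherwise **plateau** (defined by exclusion,
  since only its neighbours have stated thresholds).
* Among non-up1 genes: **late** if log2FC(0 to 4 h) > 2 ("more than
  fourfold within 4 h but not upregulated within 1 h"); otherwise
  **none**.
* **all_upregulated** = up1 union late, the reference set for enrichment.

The early screen uses fold change only; an optional FDR gate
(`up1_fdr`) is available but off by default, mirroring a screen stated
without one. Differential expression *between strains* uses the separate
DEG rule |log2FC| > 1 with FDR < 0.05. The classes partition the gene set
and are monotone in the up1 threshold; both properties are tested.

# Association statistics

All 2x2 tests are Fisher's exact test: the two-sided p sums
hypergeometric probabilities no greater than the observed one (ties
included), via `stats::fisher.test`. The primary odds ratio is the
conditional MLE under the noncentral hypergeometric model — the
`fisher.test` convention — computed by solving the conditional score
equation $E[X \mid \psi] = x$ to near machine precision on the log-odds
scale, because the reference implementation's internal optimizer resolves
the estimate only to about 1e-4 (worse where the likelihood is flat). The
sample cross-product OR is reported alongside. Zero and infinite
estimates at degenerate margins are legitimate outputs. Families of tests
are adjusted by Benjamini-Hochberg (`p.adjust`, method `"fdr"`).

*Class enrichment* tests, for each temporal class, (class membership vs.
reference membership) against (overlapped vs. not). The reference row
counts every reference-set gene, including the tested class's own genes,
so a class identical to its reference gives OR exactly 1; an empty class
is an error, not a silent zero row.

*Summit/region anti-co-occurrence* discretizes the genome into 100 bp
bins (the signal bin width) and tests "bin contains a consensus summit"
against "bin midpoint lies in NAP-free space". The mosaic's counting unit
is not forced by the underlying data — summits, bins or base pairs are
all defensible — so bins at the signal resolution were chosen for
consistency with the signal layer, and the printed odds ratios of the
original study are treated as directional, not numeric, targets on
synthetic data. The OR is oriented so that values above 1 mean the point
binder avoids the broad binder's footprint.

*Occupancy-expression shift* runs pairwise two-sample Wilcoxon rank-sum
tests of a knockout-vs-wildtype log2 fold change across the three
occupancy classes, exact for small tie-free groups and
normal-approximated with tie correction otherwise (the `wilcox.test`
convention), BH-adjusted across the three pairs.

# 3C quantification

Each qPCR locus gets its own standard curve — least squares of Ct on
log10(relative concentration) over a dilution series of a randomly
ligated digest — because each primer pair has its own efficiency and its
own calibration template. The amplification efficiency is
$10^{-1/\mathrm{slope}}$; a slope of about -3.32 cycles per 10-fold step
is a perfect doubling assay. Quantification inverts the curve explicitly,
$c = 10^{(Ct - b)/m}$, which reduces to the familiar $2^{-\Delta\Delta
Ct}$ shortcut when the slope is exactly $-1/\log_{10} 2$. Interaction
frequencies divide each locus's abundance by the bait fragment's
abundance *in the same replicate* (per-replicate rather than per-sample
normalization propagates replicate variance honestly), and replicates are
aggregated as the arithmetic mean of frequencies, not of Cts. Replicates
missing a bait measurement are dropped with a warning; a locus with no
usable replicate is an error. Inverted dilution series (positive slope)
and single-concentration calibrations are rejected.

# The synthetic-data generator

The generator emulates the *structure* of the study's data, with defaults
fixed at the study's stated conditions where they exist:

* **Genome**: a 540 kb chromosome plus a 60 kb plasmid (a one-sixth-scale
  cyanobacterial genome), background GC 0.48; 13 planted AT tracts
  (GC 0.33) totalling 15.7% of the genome — the coverage the broad binder
  was measured to occupy is taken as the planted condition.
* **Genes**: 600 genes tiling the genome in operons of 1-7 genes with a
  published-map-like TU labelling, one gene left without a TU; 3.5%
  flagged as IS elements, 65% of them drawn from inside tracts (mirroring
  the measured 80/125).
* **Classes**: transient = 30, plateau = 90, continuous = 60, late = 20.
  Study-proportional class sizes at 600 genes would leave about 5
  transient genes — too few for any association statistic to resolve —
  so class sizes are scaled up while preserving the ordering
  plateau > continuous > transient ~ late. Transient genes are drawn from
  footprint-overlapping genes with probability 0.9 versus 0.3 for the
  other upregulated classes.
* **ChIP counts**: Poisson per 100 bp bin — the minimal count model,
  which keeps recovery analytic — at depth 50, fold enrichment 8 inside
  the footprint (scaled by each bin's covered fraction, so boundaries are
  soft), flat input and control. Candidate broad peaks are the planted
  footprint with endpoint jitter (sd 25 bp) per replicate; candidate
  summits are planted positions with 10 bp jitter plus a few
  replicate-specific false summits. Optional artifact regions are
  enriched in IP *and* control, so the consensus stage must remove them.
* **Sigma factors**: sigE 150 summits with exclusion probability 0.95,
  sigA 200 with 0.75 — each summit is forced into footprint-free space
  with that probability, otherwise placed uniformly — emulating the
  observed ordering of the two factors' free-region odds ratios.
* **Expression**: planted class-mean log2FCs (+e, -e, 0 / +e, 0, +e /
  +e, +e, +2e / 0, +2e, +2e / 0, 0, 0 for transient, plateau, continuous,
  late, none at effect e = 2), iid Gaussian noise (sd 0.2) per contrast.
  The 0-to-4 h contrast gets its own noise draw rather than the sum of
  the stage contrasts, keeping per-contrast errors independent. FDR
  columns are planted, not computed, because differential-expression
  fitting is out of scope.
* **3C**: Ct values generated by the exact inverse of the quantification
  model at efficiency 1.9 (realistic, and a steeper curve than perfect
  doubling, which is the accuracy-favourable direction), sample Ct noise
  sd 0.15 cycles, three replicates, 5-step 10-fold dilutions.
  Calibration records are generated noise-free, standing for averaged
  technical replicates of the dilution series.

What the generator does *not* emulate: read-level artifacts (mappability,
GC amplification bias, fragment-length effects), overdispersed counts,
correlated noise across contrasts, caller-specific peak-boundary
behaviour, or distance-dependent 3C background. Passing tests therefore
demonstrate that the analysis chain is correct and well calibrated on
data matching its own assumptions — not that those assumptions hold on
any particular sequencing run.

# Problem sizes and determinism

The shipped test suite and the acceptance script run the full pipeline on
the 600 kb / 600-gene default genome (6,000 signal bins), oracle checks
on 1,000 random summit instances and hundreds of random 2x2 tables, and
class-recovery checks on 500-gene expression tables; these sizes give
stable statistics while keeping a full run in tens of seconds on one
core. Every stochastic step takes an explicit seed; stage seeds are
derived from the master seed, the caller's RNG state is restored
afterwards, and identical seeds give byte-identical outputs, including
written files.

# Known limitations

* Consensus logic assumes exactly two replicates, as in the emulated
  design; the generator can produce more, but `merge_summits` and
  `intersect_broad` take pairs.
* The conditional-MLE OR is reported per test; no effect-size CI is
  computed (the original analysis reported OR and p only).
* The Wilcoxon layer tests location shift between occupancy classes; it
  does not model gene length or expression-level covariates.
* Interval algebra is exact but not streamed; genomes far beyond
  bacterial scale would want a different representation.
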