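---
title: "Methods: differential accessibility, GC-matched enrichment, and bias-corrected footprinting"
author: "footprintr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential accessibility, GC-matched enrichment, and bias-corrected footprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

footprintr implements the comparative ATAC-seq machinery used to nominate
transcription factors from differences in chromatin accessibility between two
cell states (e.g. adult bone-marrow-derived vs fetal cord-blood-derived
erythroblasts, or a knockdown vs its control): a universal peak atlas with
variance-stabilized scores, a negative-binomial Wald test with covariates,
GC-matched motif enrichment, and Tn5-bias-corrected transcription factor
footprinting. Every stage is exercisable on synthetic data with known ground
truth; this vignette records the models, the defaults, and the design
decisions that were genuinely open.

# Peak atlas and normalization

Per-sample peak calls are reduced to their top 50,000 peaks by caller score;
each retained peak is replaced by the 500 bp window centred on its summit and
the windows of all samples are union-merged (abutting windows merge) into a
sorted, disjoint atlas. The per-sample peak score is the number of cut sites
falling in each atlas interval. "Reads overlapping" is implemented as
single-base cut-site containment so the whole package has one coordinate
currency — the same cut positions drive counting and footprinting.

Counts are normalized by median-of-ratios size factors and transformed with
the closed-form negative-binomial variance-stabilizing transform

$$ g(n) = \log_2\!\left(\tfrac{n}{s} + \tfrac{1}{2\alpha} +
   \sqrt{\tfrac{n}{s}\!\left(\tfrac{n}{s}+\tfrac{1}{\alpha}\right) +
   \tfrac{1}{4\alpha^2}}\right), $$

with a single common dispersion $\hat\alpha$ fit by maximum likelihood. A
fitted mean–dispersion *trend* (as the reference implementation uses) is
deliberately not estimated: the downstream uses of the VST channel —
the 80th-percentile filter and clustering — are rank-driven, and the
closed-form transform is fully reproducible from this package alone. The
80th-percentile filter retains peaks whose maximum score across samples
reaches the interpolated 0.80 quantile of all per-peak maxima; it operates on
the VST channel by default (the raw-count channel is selectable), since the
filter's intent is to remove uniformly weak peaks on the scale where variance
is mean-independent.

# Differential accessibility

Within a population window (early = populations 1–2, mid = 3–5, late = 6–7),
each peak is fit with a negative-binomial log-link GLM, design
`~ source + population` (population as a categorical factor — it is ordinal,
but no trend model is assumed), with log size factors as offsets. Per-peak
dispersions are estimated by Cox–Reid adjusted profile likelihood — the
adjustment removes the downward bias the plain MLE incurs from the fitted
coefficients, which otherwise makes the Wald test visibly anti-conservative
at 12 samples and 4 coefficients — and shrunk toward the across-peak trend by
a 50/50 blend in log space. The trend centre is the *arithmetic* mean of the
per-peak estimates (a geometric mean is biased low by Jensen's inequality),
and the per-peak term is floored at trend/20 so that peaks whose dispersion
MLE collapses to zero are not treated as Poisson. The Wald statistic on the
source coefficient is referred to a standard normal; BH correction runs over
tested peaks only (all-zero peaks are excluded from the denominator).

Thresholds follow the standard scheme: differential per direction at
FDR < 0.1 and $|\log_2 FC| > \log_2 1.25$; background per direction at
p > 0.1 and $|\log_2 FC| < \log_2 1.25$. Both the 0.1 FDR used for motif
enrichment and a stricter 0.05 used for locus-level significance statements
are exposed as parameters rather than hard-coded, since the two appear in
different analysis passes.

No independent filtering and no log-fold-change shrinkage are applied; the
labels consume raw Wald output because only FDR and fold-change cutoffs
define the sets. Exact numerical parity with DESeq2 is a non-goal, but the
test suite cross-checks estimates and rankings against it on a shared
simulated matrix.

# Motif scanning and GC-matched enrichment

PWMs are scanned on both strands with the log-likelihood-ratio score
$\sum_j \log_2 (p_{b_j}/q_{b_j})$. Match p-values are exact: the null
distribution of the integer-discretized score (granularity 1/1000 bit) is
built by dynamic-programming convolution of the per-column score
distributions under the background model, and instances with $p \le 10^{-4}$
are retained, capped at the 500,000 best per motif. One consequence worth
knowing: a motif of width $W$ cannot score below $4^{-W}$ on a uniform
background, so hexamer-width motifs are invisible at $10^{-4}$; synthetic
validation runs that scan the width-5/6 half-site fixtures use $10^{-3}$,
the smallest round cutoff that retains a width-5 consensus match.

Enrichment per motif and direction is a one-sided Fisher exact test of motif
presence (≥ 1 overlapping instance) in differential vs background peaks,
with the sample odds ratio $(ad)/(bc)$ and BH correction across motifs
within a direction. The background is GC-matched: GC values are split into
20 equal-occupancy bins (read of "20 equally sized groups"; equal-width bins
are available by flag) whose edges come from the pooled differential +
background values, and 2500 background peaks are drawn without replacement
with inclusion probability proportional to (differential bin proportion /
background bin proportion). The draw is realized by stratified allocation —
largest-remainder bin targets, uniform sampling within each bin — because
sequential weighted draws without replacement measurably under-sample the
heaviest bins as they deplete, leaving residual GC confounding that the
stratified scheme removes.

# Hexamer bias model and footprinting

Tn5 prefers certain local sequences; left uncorrected, this preference
imprints on every cut profile. The correction uses three ingredients, all
with the same hexamer anchor — the 6-base window $[p-3, p+3)$ around the
insertion bond, reverse-complemented for minus-strand contexts (the window
itself is the same 6 bases either way):

1. **Genomic hexamer frequencies**, sliding windows outside the blacklist,
   N-containing windows dropped. Both strands are counted by default, so the
   frequencies describe the double-stranded genome and are exactly
   strand-symmetric — the natural reference for an enzyme that acts as a
   homodimer, and what makes the correction exact under pooled-strand
   counting.
2. **Positional hexamer frequencies** per motif: at each position −250..+250
   around motif centers (center = start + ⌊W/2⌋; instance strand orients the
   axis), the anchored hexamer is counted over all instances, and each
   position is normalized so the mean over the 4096 hexamers is 1.
3. **Cut hexamer factors** per sample: per-hexamer cut shares divided by
   genomic shares, renormalized to sum 1.

The expected profile is the positional frequencies weighted by the cut
factors, normalized to sum 1. Observed cuts around motif centers (pooling
both cut strands) and the expected profile are each scaled to mean 1 and the
footprint score is their per-position $\log_2$ ratio. The summary statistics
use regions derived from the motif width $W$: base $|pos| \le W/2+5$; flank
$\min(18, W/2+10) \le |pos| \le 50$; background $200 \le |pos| \le 250$.
$FPD = \text{trimmed mean}_{10\%}(\text{base}) - \text{mean}(\text{flank})$
and $FA = \text{mean}(\text{flank}) - \text{mean}(\text{background})$, where
the trimmed mean drops ⌊0.1k⌋ values from each tail. The literal `min()` in
the flank inner edge lets motifs wider than 26 bp overlap base and flank; it
is kept literally (a `max` variant is a flag) because the region formulas
are part of the published statistic. Between conditions,
$\Delta FA = FA_A - FA_B$ and $\Delta FPD = FPD_A - FPD_B$ rank motifs; a
protein bound in A only drives $\Delta FPD$ strongly negative.

The central correctness property is the *bias-only null*: when cuts are
generated purely from a hexamer bias model with no protection, the corrected
score must be flat. With the strand-symmetric bias table and double-stranded
genomic reference the expected profile is exactly proportional to the true
cut rate, so the mean |score| is pure counting noise,
$\approx \sqrt{2/\pi}\,/(\ln 2\,\sqrt{\lambda})$ for per-position count
$\lambda$ — the package verifies < 0.05 at $\lambda \gtrsim 500$.

# Synthetic data: what it emulates, and what it does not

The generators produce i.i.d. genomes with controllable GC, planted
*consensus* motif instances (consensus rather than PWM-sampled, so planted
instances always pass the scanner — a deterministic test surface), cut sites
drawn from a multinomial whose weights are the hexamer bias times a flat
protection factor across protected motif spans, and negative-binomial count
matrices with planted log2 fold-changes, sample-specific size factors, and
peak × population shifts so the population covariate carries real signal.
Cut strands are independent of position, matching the footprint math, which
never separates strands.

Deliberate simplifications: no read-level simulation (no fragments, no
duplicates), no shoulder effects around footprints (protection is flat
across the motif span only), no mean–dispersion trend (a single dispersion),
and no correlated peak structure. Passing tests therefore demonstrate that
the machinery is correct under its own model assumptions — they do not
demonstrate robustness to fragment-length confounding, dispersion trends, or
other features of real libraries.

Parameter choices in the validation experiments, fixed a priori:

* **Bias-null run** (2 Mb genome, 10^6 cuts): 1500 consensus instances are
  planted per motif so the per-position aggregate count
  (≈ n_inst × depth/genome length) keeps counting noise well below the 0.05
  band; the scan also picks up natural consensus occurrences (~2L/4^W).
* **Ranking run** (1 Mb, 5×10^5 cuts per condition, protection 0.2 on NFI
  instances in condition A, 20 decoys): footprints are computed from the
  planted instance lists, not scan output — for hexamer-width motifs the
  natural unprotected occurrences outnumber any plantable protected set and
  would dilute the aggregate profile toward zero, so a scan-fed version
  measures dilution rather than the statistics under test.
* **GC confound** (500 differential, 20,000-peak pool, +0.06 GC shift,
  presence logistic in GC): the pool must be much larger than the 2500-peak
  draw for *any* without-replacement matching to be feasible (a bin can be
  enriched at most pool/n-fold); real background pools are tens of
  thousands of peaks.
* **Recovery run**: planted effects are balanced (+2/−2 in equal numbers).
  One-directional planting of 20% of peaks shifts median-of-ratios size
  factors by the planted mass (measured −0.23 log2) and biases every
  estimate; that experiment would measure normalization contamination, not
  estimator recovery.

# Numerical and degenerate-input conventions

Coordinates are 0-based half-open everywhere (BED semantics, unshifted on
IO); narrowPeak summit offsets are applied on read, with a midpoint fallback
at offset −1. Zero PWM entries get a 10^-4 pseudo-probability before
log-ratios. Scan ties at the instance cap break by genomic coordinate;
top-k peak ties break by genomic order. Cuts within 5 bases of a contig end
are outside the simulation support; cut hexamers containing N are skipped
with a count. All-zero peaks are excluded from testing; all-N peaks have
undefined GC and are dropped from matching. Positions with zero expected
cuts are masked in the score and excluded from region means. All generators
and samplers are bit-reproducible under fixed seeds, and pipeline outputs
carry a config-hash + seed provenance header.

# Problem sizes used in the shipped experiments

The test suite and the acceptance script run the experiments at the sizes
given above (2 Mb / 10^6 cuts for the bias null; 1 Mb / 5×10^5 cuts × 10
seeds for the ranking; 100 repeats of the GC confound; 2000-peak null and
1000-peak recovery matrices for the Wald test). On one CPU the whole
acceptance script completes in roughly four minutes.
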