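---
title: "Methods: 4C-seq signal processing, Brick calling and differential analysis"
author: "fourcbricks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4C-seq signal processing, Brick calling and differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourcbricks)
```

## The measurement and its signal structure

4C-seq measures how often one genomic locus — the *viewpoint*, a single
restriction fragment — is in physical contact with every other fragment of
the genome. Reads are assigned to a virtual library of restriction fragments
(BglII, motif `AGATCT`, by default), so the fragment tiling is the coordinate
system of everything downstream. Three features dominate the cis signal:

1. a steep distance decay around the viewpoint, empirically close to a power
   law with exponent −1 (a straight line of slope −1 in log–log space);
2. a roughly uniform random-ligation floor that carries most of the
   chromosome-wide read mass far from the viewpoint;
3. localized contact enrichments — loops — sitting on top of both.

The pipeline recovers (3) by estimating and removing (1), and treating what
remains as a rank-ordered signal in which unusually high stretches are
called *Bricks* (significantly interacting windows) at multiple scales.

## Processing chain

Per replicate: counts are normalized to the total number of retained reads
(reads per million by default; reads on the viewpoint fragment and
`exclusion_k = 2` fragments per side are removed first as
self-ligation/undigested artifacts — the radius is not prescribed by any
published value, so it is configurable). Replicates are averaged pointwise
after smoothing.

**Running mean (`w` fragments, default 19).** Used for display and for the
log2 condition-ratio track. At chromosome edges the window shrinks
symmetrically rather than padding or reflecting, so the track length is
preserved and no signal is fabricated.

**Background model.** With the slope pinned at −1, only the intercept `a` of
`expected(d) = 10^a / d` is estimated: `a` is the median of
`log10(value) + log10(d)` over fragments in the fit range (a
least-absolute-deviation fit, robust against the very peaks we want to keep;
least squares is available). Zero and negative values are excluded from the
fit but stay in the track. Correction subtracts the expectation, keeping
*signed* residuals; division would make the corrected level grow with
distance wherever a uniform floor dominates, distorting the rank order that
all downstream calling relies on.

**Fit range.** The package default spans from the first fragment outside the
exclusion zone to 2.5 Mb. For data in which the distal signal is dominated
by a flat floor — including this package's generator — the fit must stay
inside the decay-dominated zone `d << c/beta` (about 330 kb under the
generator defaults): fitting a pure power law into the floor-dominated zone
biases the intercept upward and imprints a spurious rising trend on the
corrected track, which both breaks the two-fold deletion ratio and creates
rank artifacts at the chromosome ends. The analysis scripts and tests
therefore fit over 1–100 kb. With real data the choice should follow the
same rule: fit where the log–log profile is actually straight.

## The domainogram statistic

Corrected signals are ranked per chromosome (average ranks for ties, scaled
by the number of ranked fragments, `u = r/n`). For every start fragment and
width `w ≤ 200`, the mean rank `m` of the window is converted to an
upper-tail p-value by a normal approximation to its permutation null: a
window holds `w` of the `n` chromosome ranks drawn without replacement, so

$$E[m] = \frac{n+1}{2n}, \qquad
  \mathrm{Var}[m] = \Bigl(1 - \tfrac{1}{n^2}\Bigr)\frac{n-w}{n-1}\,\frac{1}{12w}.$$

At chromosome scale this is the familiar `z = (m - 1/2)\sqrt{12w}` for the
mean of `w` iid uniforms; the exact moments matter for wide windows
(`w/n` not small) and keep the approximation within 0.05 of exhaustive rank
enumeration already at `n = 7` (continuity-matched comparison; the tests
enumerate all subsets). Windows touching the viewpoint exclusion zone are
skipped. Cumulative sums make the whole scan O(n·Wmax).

**Tiers and selection.** Windows whose span lies inside the short-range
window (±2.5 Mb around the viewpoints by default; configurable coordinates)
form the short-range tier, called at FDR 0.1; all other windows — including
any straddling the border — form the long-range tier at FDR 0.001, because
long-range signal is more exposed to random ligation. Benjamini–Hochberg is
applied per tier over all (start, width) windows; surviving windows are
selected greedily by ascending p-value (ties to the smaller start) with
removal of overlaps, giving disjoint Bricks; consecutive Bricks separated by
at most one fragment merge into interacting regions.

## Why the calling branch is unsmoothed

The 19-fragment running mean makes adjacent fragments share 18/19 of their
averaging window, so the ranks fed to the window statistic are strongly
autocorrelated and its permutation null is violated: every noise excursion
then looks significant at every scale. On synthetic data this inflates false
regions roughly 80-fold (measured 1.6 per Mb smoothed vs 0.02 per Mb
unsmoothed at the same thresholds). Since the multi-scale window mean *is*
already a smoother, the calling branch runs the chain with `w = 1`
(smoothing is a parameter, and identity is a supported value), while the
ratio/display branch keeps `w = 19`. Both branches share normalization,
background fit and correction.

## What false-discovery control does and does not buy

BH at level *q* controls the expected false fraction *among discovery
windows*. On planted-peak simulations the discovery-window precision is
≈ 0.997 at FDR 0.1 and planted-peak recall is ≈ 1. After collapsing
discoveries to disjoint Bricks and regions, however, the hundreds of windows
covering one true peak count once, while scattered null windows that cleared
the adaptively raised BH threshold count individually: region-level
precision on the same simulations is ≈ 0.3–0.4. This is a structural
property of rank-scan methods, not an implementation artifact; users who
need region-level guarantees should tighten `fdr_short`/`fdr_long` or
validate regions with the read-count rank-sum test. A peak also needs to
span roughly 10+ fragments to be callable at all: the window z-score is
bounded by `sqrt(12w)/2`, so a 4-fragment enrichment can never clear
genome-wide BH, whatever its height.

## Differential (ratio) Bricks

The log2 ratio of case over control smoothed corrected signals is
stabilized with a pseudocount (5% of the pooled median positive corrected
signal by default; negative corrected values are floored at zero before the
ratio so the pseudocount sets the scale of "no signal"). Candidate positive
Bricks come from calling on the ratio track, candidate negatives from
calling on its negation — by construction, swapping the two conditions
exactly exchanges the two sets. Three filters follow: positive/negative
pairs overlapping by more than 5% of the shorter member are removed from
both sets (reciprocal mode available); assembly-gap intervals are subtracted,
splitting bisected Bricks; and Bricks that do not touch any selected Brick
of either condition are dropped. Selected regions are validated by
comparing, with a two-sided Wilcoxon rank-sum test (exact for
`min(nA, nB) ≤ 10` without ties), the per-region mean of log total read
counts against the same quantity for Bricks outside all regions.

The two-condition design carries no replicate-level dispersion model for the
ratio — deliberately, mirroring the study design this pipeline reimplements;
the rank-sum validation and the bootstrap interval summary are the
uncertainty statements. The interval summary reports the median per-fragment
log2 ratio over a window of interest with a percentile bootstrap CI
(fragment-level resampling, 1000 draws, fixed seed).

## Enrichment by interval shuffling

Interacting regions are compared against feature sets (genes, histone-mark
islands) by permutation: each region is placed uniformly at random on its
chromosome outside excluded (gap) intervals, length preserved, shuffled
regions free to overlap each other. Placement is exact-uniform over
admissible starts (gap-weighted sampling), avoiding rejection loops. The
empirical p-value uses plus-one smoothing and so is never zero. The default
statistic counts regions hitting at least one feature; `feature_hits` and
total intersection bp are alternatives (the bp statistic is the natural
choice when ties would otherwise dominate, e.g. in calibration studies).

## The synthetic generator

`sim_config()` encodes the minimal generative model the statistics assume —
it makes the pipeline testable offline, and every acceptance band derived
from it is a property of this model, not of any real dataset. Defaults,
chosen once as a realistic desk-scale instance: a 20 Mb chromosome at mean
fragment length 4096 bp (the expected spacing of a 6-bp cutter, drawn iid
exponential); viewpoint at 2 Mb; intensity
`(c/d + beta) * fold * allele`, with `c = 1`, `beta = 3e-6` per fragment, so
the decay term dominates within ~330 kb of the viewpoint while the floor
carries most chromosome-wide mass, as in real 4C; three planted 80 kb
peaks of fold 4 (two short-range, one long-range; ~20 fragments each, safely
above the ~10-fragment detectability floor and conservative relative to
Mb-scale real interacting regions); an optional 1.5 Mb deletion at
8.0–9.5 Mb whose case-condition intensity is exactly halved (one allele
lost; the case library is correspondingly smaller, which total-read
normalization absorbs); library 1e5 reads per replicate, two replicates,
Poisson counts (negative binomial, size 10, for overdispersion stress
tests). Deletion scenarios plant one peak inside the deleted interval, as a
rearrangement-flanking viewpoint contacts the critical region in the system
this emulates — without it, the lost-contact Brick would be discarded by
condition anchoring. `simulate_genome()` additionally realizes a DNA
sequence whose motif occurrences sit exactly at the fragment boundaries, so
digestion closure can be tested on sequence.

What the generator does *not* emulate: mappability and fragment-end biases,
trans contacts, polymer-physics contact correlations, replicate batch
effects, and sequencing error. Passing closure tests therefore demonstrates
the pipeline's statistical correctness under its own assumptions, not
robustness to those real-data artifacts.

## Numerical and design choices

- Coordinates are 0-based half-open throughout (BED convention); cuts are
  placed at the motif start — the analysis needs only a consistent tiling.
- Reads are assigned by 5′ position; boundary ties go to the fragment
  starting at that coordinate.
- p-values are floored at the smallest positive double, keeping them in
  (0, 1].
- The whole-chromosome window (`w = n`) carries no rank information and is
  assigned p = 1.
- Brick-calling problem sizes used in the tests and the acceptance script:
  1000-fragment chromosomes for null/planted studies (200 and 100 seeds),
  the 20 Mb generator default (~4900 fragments) for pipeline closure
  (10–50 seeds), permutation calibration at N = 199 with 100–200
  replicates. These sizes give binomial/KS resolution well inside the
  asserted bands.
- The expression report rounds half away from zero at 3 decimals, matching
  how published ratio tables are printed; two of the published rows (ASL,
  KCTD7) are inconsistent with division of their own printed means
  (presumably computed from unrounded inputs) and are not used as checks.

## Known limitations

Region-level FDP exceeds the window-level FDR by construction (above).
The slope of the background model is fixed at −1; data with a genuinely
different decay exponent will leave a residual trend (the
`diagnostic_slope` field of the fitted model flags this). Trans-chromosomal
interactions, fragment-end mappability correction and graphical domainogram
rendering are out of scope.
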