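---
title: "capnet: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capnet: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnet)
```

# The scientific problem

Capillary blood flow in the human parafovea is heterogeneous between
vessels for reasons that local vessel properties only partly explain.
`capnet` implements the network-level side of the question: given traced
vessel segments, their connectivity at junctions, OCTA slab stacks and
per-vessel velocity traces, it quantifies where each capillary sits in the
vascular tree and correlates those positional variables with its flow
parameters. This vignette documents the models behind each step, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic validation does and does not establish.

# The vascular graph

A network is a set of segments (id, length in µm, lumen diameter in µm,
optional depth) connected by three-way junctions. Each junction has a
*major* vessel and exactly two *minors*; its kind fixes the flow
direction — a **bifurcation** sends blood from the major to both minors, a
**confluence** collects both minors into the major. Crossings (segments
that overlap en face without connecting) are stored but never traversed.
This mirrors how such networks are traced in practice: flow direction is
established per junction from video data, so the kind plus the major/minor
roles carry the whole directed structure.

`validateNetwork()` is report-only. Besides multiple-inflow/outflow and
feeder-inflow checks, it includes a kind-consistency heuristic: a junction
whose labeled kind creates direction conflicts that relabeling would
remove, and which removes more conflicts than any other junction's flip,
is flagged as a probable kind mislabel. With symmetric evidence several
junctions can tie and all are flagged; the report never modifies the
network.

**Feeding arterioles** are segments with lumen diameter above 8 µm and no
upstream parent inside the field — the vessel that supplies the rest of
the system. The 8 µm threshold is the conventional upper bound of the
capillary calibre range and is exposed as `minDiameter`.

**Branch order** starts at 1 at the feeder and increments at every
bifurcation crossed; confluences do not increment it. The alternative —
counting every junction — was considered and rejected because the order is
defined by *branching* points; the choice is documented here rather than
hidden because the distinction only matters on the venular side.

**Feeder distance** is the along-flow distance from the upstream end of
the feeder to the *center* of the queried segment: the sum of full lengths
of all upstream path segments plus half the segment's own length (so the
feeder's own distance is half its length). Where several upstream paths
exist (multiple feeders, anastomoses) the path minimizing summed length is
used, with exact ties broken by the lexicographically smallest id
sequence so results are reproducible. Shortest-path computation is
delegated to igraph; tie enumeration uses all shortest paths.

# Capillary taxonomy

Classification uses only the kinds of the two end junctions:
bifurcation→bifurcation is an arteriolar capillary (AC),
confluence→confluence a venular capillary (VC),
bifurcation→confluence a terminal capillary (TC), and
confluence→bifurcation the rare "unorthodox" capillary (WC), where
collection is followed by re-distribution. A segment missing either end
junction is UNCLASSIFIED. The classification is total: every segment gets
exactly one label.

# Junction exponents

At a junction with parent (major) radius $R_p$ and daughter radii
$R_1, R_2$, the generalized Murray relation is

$$R_p^{\,x} = R_1^{\,x} + R_2^{\,x},$$

with Murray's law the special case $x = 3$. The exponent is estimated by
brute force: for each candidate $x$ on a grid the parent radius predicted
from the daughters, $(R_1^x + R_2^x)^{1/x}$, is compared to the measured
one, and the $x$ minimizing the squared error is chosen. Notes on the
numerics:

* **Grid**: $x \in \{0.01, 0.02, \dots, 10.00\}$. Zero is excluded (the
  $1/x$ root is undefined there) and the 0.01 step makes two-decimal
  exponents exactly representable. Ties go to the smallest candidate,
  which on an ascending grid is simply the first minimum.
* **Stability**: the prediction is evaluated as
  $m\,((R_1/m)^x + (R_2/m)^x)^{1/x}$ with $m = \max(R_1, R_2)$ so large
  exponents do not overflow; the large-$x$ limit is $\max(R_1, R_2)$.
* **Admissibility**: a junction is only fit when all three radii are
  available and the parent is *strictly* the widest vessel — the relation
  cannot support a major vessel narrower than its widest minor. Equality
  within the 0.01 µm measurement precision also counts as non-fittable.
  Non-fittable junctions are reported with an explicit status
  (missing-radius or parent-not-widest) rather than dropped.
* **Radii** are measured lumen diameters divided by two; no wall
  correction is applied because only the lumen is measured.
* No exclusion rule is applied at fit time to implausibly large exponents;
  high-exponent sensitivity is handled downstream by the outlier
  re-analysis (`outlierRerun`, default threshold 4).

Per vessel of interest, an UPSTREAM record is fit at the supplying
bifurcation (the VOI being one of the daughters) and a DOWNSTREAM record
at the collecting confluence (the VOI being one of the drained vessels);
these always correspond to arteriolar and venular junctions respectively,
so a vessel fed or drained by the opposite junction type contributes no
record on that side.

# Vessel depth from OCTA slabs

Depth is quantified against the PR1 reference band using a stack of
40-µm-thick en-face slabs, by default at 60–220 µm above PR1 in 20 µm
steps (the acquisition may be denser; the analysis grid is configurable).
For each vessel ROI the per-slab mean, min, max, sd and area are
extracted; the vessel's depth is the label of the slab with the highest
ROI mean intensity — a discrete argmax, with no sub-slab interpolation,
because a slab position is what the measurement physically selects.
Exact mean ties resolve to the smallest depth and are flagged ambiguous;
an all-flat profile is an error. The `peak_quality` (peak mean over
profile median) gives a per-vessel reliability handle.

`depthTable()` summarizes peak depths in 25-µm bins centered on multiples
of 25 µm. This off-grid binning is deliberate: a 20-µm slab grid spanning
60–220 µm has no slab at 150 µm, yet real parafoveal data concentrate
near 150 and 200 µm; with centered 25-µm bins, peaks at the 140 and
160 µm slabs both land in the 150-µm bin while 200 µm is on the grid, so
the expected bimodality is visible without interpolation.

# Lumen diameter

The diameter estimator models the straightened ("division") vessel image:
rows are cross-sections, columns run across the vessel, and the axis sits
at a known (possibly half-integer) column. The cross-sectional intensity
profile is modeled as a uniform chord on $[-D/2, D/2]$ convolved with a
Gaussian edge blur of sd $\sigma$ (a nuisance parameter), plus an
amplitude and background offset, and fit by maximum likelihood under
Gaussian noise — equivalently, least squares of the column-mean profile,
with the linear parameters profiled out and $(D, \sigma)$ optimized on a
log scale by Nelder–Mead. Two details matter:

* **Pixel-footprint integration.** The model integrates the blurred chord
  over each pixel's footprint rather than evaluating it at the pixel
  center. A noiseless sharp band then identifies $D$ exactly through its
  partially covered edge pixels, and sub-pixel width differences (a 6 µm
  vessel vs a 5 µm vessel, below the ~2 µm optical resolution) are
  resolved — a binary lumen mask alone cannot do this, because
  thresholding quantizes the band to whole pixels. The Otsu threshold
  (`thresholdLumen`, histogram split on the ROI, polarity selectable) is
  therefore used to localize the vessel and reject degenerate input, not
  as the data for the width fit. A full-width-at-half-maximum alternative
  (`method = "halfmax"`) is provided for comparison.
* **Bootstrap confidence limits.** Rows (cross-sections) are resampled
  with replacement and the diameter re-fit per resample; the 95 % limits
  are the 2.5/97.5 percentiles over `nBoot = 1000` resamples (percentile
  intervals chosen for simplicity; the interval is expanded, if needed, to
  contain the point estimate, so the reported triple is always
  internally consistent). The bootstrap runs under an explicit seed via
  `withSeed()`, which restores the caller's RNG state.

# Flow parameters

A velocity trace (mm/s at 200 or 300 Hz, at most 3.4 s) is summarized by
its raw extrema $V_{max}$, $V_{min}$, the arithmetic mean $V_{ave}$, and
the pulsatility $(V_{max} - V_{min})/(V_{max} + V_{min})$. Raw extrema are
the default because acquisitions are not cardiac-gated and no spike model
is assumed; an optional moving-median window (`smoothWindow`) is provided
but off by default, and when used, all four summaries are computed from
the same smoothed series so that $V_{min} \le V_{ave} \le V_{max}$ always
holds. Velocities are treated as mm/s throughout; this follows the
convention of the velocimetry literature the traces come from.

# Statistics

Correlations are two-tailed Pearson tests at a 0.05 significance level,
computed from the closed form with the p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom; complete-case
deletion is applied per variable pair, so every cell of the report can
have its own $n$. No multiple-testing correction is applied. Strength
categories bin $|r|$ into [0, 0.30) negligible, [0.30, 0.50) low,
[0.50, 0.70) moderate, [0.70, 0.90) high, and [0.90, 1] very high;
boundaries belong to the upper bin. `outlierRerun()` repeats the
downstream-exponent correlations with $V_{ave}$ and $V_{min}$ after
removing vessels with an exponent above 4, reporting how many were
removed.

# Synthetic data: what it emulates

Two generators cover two scales.

**Geometry scale** (`generateNetwork` and companions): per feeder, a
binary tree of `treeDepth` bifurcation generations ends in terminal
capillaries that drain pairwise through confluences into a single
collecting venule; optionally a fraction of terminal sibling pairs is
rewired into a confluence-then-bifurcation motif, planting unorthodox
(WC) segments. Junction radii are constructed to satisfy the generalized
Murray relation *exactly* at each junction's drawn exponent (truncated
normal, mean 2.2, sd 0.8 on [0.5, 6] by default — the range observed in
capillary-scale data). Because the relation is scale invariant, all radii
are rescaled so mean terminal capillary diameter is 4.33 µm (sd arising
from split asymmetry, drawn splits 0.35–0.65), while keeping the feeder
above 8 µm; in shallow trees the feeder constraint wins and capillaries
come out wider. Segment lengths are lognormal (~60 µm, feeder ~90 µm);
depths come from a two-component Gaussian mixture with means 150 and
200 µm (weights 35/52 and 17/52, sds 12 and 10 µm), matching the observed
bimodal depth distribution. Velocity traces are raised cosines
$v(t) = V_{ave}(1 + P\cos(2\pi f t + \phi))$ with $f = 1$ Hz (~3 cardiac
cycles in 3 s), pulsatility decaying linearly with feeder distance
(P0 = 0.6, 5×10⁻⁴ per µm, clamped to [0, 0.95]; an exponential decay
option exists) and diastolic velocity rising with distance
(0.5 mm/s + 8×10⁻⁴ per µm), plus Gaussian noise (sd 0.05 mm/s) and a
positivity clamp. The raised cosine is the simplest periodic waveform for
which the pulsatility is analytic, which makes the noiseless construction
identities exact. OCTA slabs render each vessel's ROI with a Gaussian
axial profile (σ = 20 µm, about half the 40 µm slab thickness, matching
the bell-shaped intensity-depth curves) at amplitude 1 over background
noise sd 0.2 (SNR 5). Division images render the analytic blurred band
with optional noise. All generators consume a single explicitly seeded
RNG stream and restore the caller's RNG state, so identical
configurations give byte-identical outputs.

**Statistics scale** (`generateCohort`): correlation recovery needs
hundreds of vessels, more than one traced field contains, so the cohort
generator draws per-vessel covariates independently at realistic
marginals (feeder distances lognormal ~430 µm truncated to 150–900 µm,
depths from the mixture, branch orders 1–9 with median ~6, exponents as
above, with junction radii constructed exactly at the drawn exponents)
and embeds chosen population correlations — by default −0.6 between the
downstream exponent and $V_{ave}$, and +0.45 between feeder distance and
$V_{min}$ — through a standardized linear latent model, then synthesizes
the actual velocity traces. `cohortRecords()` re-derives every analyzed
quantity through the package's own operations (grid-search exponent fits,
trace summaries), so recovery tests exercise the full analysis path.
Mild clamps keep $0 < V_{min} \le 0.92\,V_{ave}$; they bind on a few
percent of vessels and attenuate the embedded correlations slightly,
which the recovery tolerance absorbs.

What passing these tests shows — and does not. The generators reproduce
the *statistical structure* the analysis assumes: exact junction-law
radii, bell-shaped depth profiles, cardiac-periodic traces, band-shaped
cross-sections. They do not simulate adaptive-optics image formation, eye
motion, aliasing, leukocyte/plasma gaps, pressure/resistance
hemodynamics, or segmentation/tracing errors. Recovery on synthetic data
therefore validates the estimators and the pipeline plumbing, not the
upstream measurement process on real images.

# Problem sizes and runtime choices

The test suite exercises: exponent recovery on 200 random junctions
(exact and with 5 % multiplicative radius noise); correlation recovery on
a 500-vessel cohort; depth recovery on 52 vessels at SNR 5 plus 200
single-vessel repeats; diameter recovery on 100–200-row images with
1000-resample bootstraps (200 resamples inside the 20-seed noise-scaling
comparison); and a ~770-segment network for the null-decay property.
These sizes keep each property statistically decisive while the full
suite runs in about a minute.

# Known limitations

* Branch order and feeder distance require a reachable feeder; fields
  without a wide parentless vessel raise an error rather than guessing.
* The depth estimate is quantized to the slab grid; an optional parabolic
  refinement was considered and left out to keep the estimate faithful to
  what the measurement selects.
* The diameter model assumes a straight, centered vessel with
  approximately uniform intensity along rows; strong curvature or
  centerline error biases it.
* The correlation report treats vessels as independent; subject-level
  clustering is not modeled.
* The spreadsheet importer requires an explicit column map, since
  exported workbook schemas vary; it does not guess headers.
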