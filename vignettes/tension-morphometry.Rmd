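---
title: "Mapping tension and its transcriptional readout: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tension and its transcriptional readout: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tensiomap quantifies mechanical tension in embryonic axial tissues through
three independent readouts — a genetically encoded FRET tension sensor, the
passive deformation of tracked epithelial cells, and the expression
statistics of stretch-responsive genes — and ships a seeded synthetic-embryo
generator so that each readout can be validated end to end against known
ground truth. This vignette explains the models behind each readout, the
parameters that matter, and the design decisions taken where the underlying
experimental workflow left the method open.

## 1. The FRET tensiometry model

A vinculin-based tension sensor places a FRET pair on an elastic linker:
tension across the molecule separates donor from acceptor and lowers FRET.
We summarize the photophysics in a single dimensionless **FRET index**
$f \in (0,1)$, the fraction of sensor emission routed to the acceptor
channel. The forward model per pixel is

$$
\begin{aligned}
D &= \rho\,(1-f)\,k_d + B_d + \varepsilon_d, \\
A &= \rho\,f\,k_a + B_a + \varepsilon_a,
\end{aligned}
$$

with $\rho$ the local sensor density (expression level), $k_d, k_a$
arbitrary channel brightness constants, $B$ per-channel autofluorescence
backgrounds, and $\varepsilon \sim N(0, \sigma^2)$ acquisition noise. Two
structural facts drive the whole analysis:

* the **ratio** $(A - B_a)/(D - B_d) = f k_a / ((1-f) k_d)$ is independent
  of $\rho$ — sensor expression cancels, tension does not;
* the backgrounds are estimated from uninjected embryos and subtracted as
  per-channel scalars, so the ratio is recoverable without calibration.

**Ratio convention.** Published descriptions of ratiometric FRET rarely say
which channel is the numerator. We use acceptor/donor so that a *higher*
index means *more* energy transfer, i.e. a *less* loaded sensor and *lower*
tension — matching pseudocolor conventions where red marks high FRET / low
tension. `ratio_image(invert = TRUE)` switches to the donor/acceptor
convention. When both brightness constants are equal the ratio converts
back to the index exactly, $f = r/(1+r)$ (`ratio_to_index()`), which is the
scale on which normalized FRET levels are best compared (the ratio
$r = f/(1-f)$ is convex in $f$ and exaggerates differences).

**AP profiles.** The anteroposterior axis is the image ordinate with the
anterior pole at row 0. Per image line the mean FRET over (tissue mask ∧
valid ratio) pixels gives the axis profile; lines with no contributing
pixel carry no value rather than zero — dividing an integral profile by a
zero mask count is ill-posed. The gradient is summarized by a weighted
least-squares slope (weights = per-line pixel counts) together with the
Spearman rank correlation of the profile against the coordinate; the
statistic behind "a gradient is present" was an open choice and slope +
rank correlation is this package's, because the pair separates magnitude
from monotonicity. Profiles are not smoothed by default.

**Masking and validity.** The tissue mask comes from the
background-corrected acceptor (green) channel, which shows the distributed
sensor; Otsu's threshold by default, a fixed threshold as fallback. Pixels
whose corrected donor falls below `min_signal` (default
`max(5, background_donor)` intensity units) are marked invalid rather than
zeroed, guarding against ratio blow-up at the tissue margin.

**The two validations.**

1. A load-insensitive control sensor reports a constant, high FRET index.
   Its profile must be flat (|slope| ≲ 1e-3 per pixel at 2% noise), and its
   pixel-weighted grand-mean FRET sits about twice the gradient sensor's on
   the index scale under the default conditions (control index 0.70 vs a
   0.25–0.45 sensor gradient, mean 0.35).
2. Sensor expression is never uniform. A high Pearson correlation between
   the corrected channels combined with a flat ratio profile is the
   diagnostic that intensity variation is expression-driven, not
   tension-driven; the generator's density-modulated constant-FRET embryo
   reproduces exactly this signature (r ≥ 0.9, slope ≈ 0).

## 2. What the synthetic embryo does and does not emulate

The generator renders the forward model over an elliptical tissue footprint
(margin 5% of the frame), with a smooth multiplicative density field
(low-resolution uniform grid, bilinearly interpolated, rescaled to the
requested fold-range) and additive Gaussian noise on both channels. Default
scale constants are $k_d = k_a = 1000$ intensity units — arbitrary, since
they cancel in the ratio — and the default noise is 20 units, 2% of the
typical signal; no acquisition noise magnitude or bit depth was available
to copy, so these are free parameters chosen once. Gaussian noise is the
default rather than Poisson because camera noise at these intensities is
approximately additive; a Poisson option would change nothing structural.

Not emulated: spectral bleed-through, photobleaching, optical registration
error, and any calibration from FRET to absolute force. Passing tests
therefore demonstrate that the *analysis* is correct under the stated image
formation model, not that a microscope's raw frames satisfy that model.

## 3. Cell-sheet morphometry

Frame 0 of a synthetic sheet is a bounded Voronoi tessellation of the ROI
rectangle (half-plane clipping), relaxed by two Lloyd iterations; two
sweeps give a median cell eccentricity near 0.65, which is what segmented
neural-plate epithelia look like — unrelaxed Voronoi cells are too ragged
(median ≈ 0.8) and heavily relaxed ones unrealistically round. Later
frames apply one of four kinematic modes, each the $(n-1)$-th root of its
total map so that composing the per-frame map across the series reproduces
the stated whole-series scale factors exactly:

* `translation` — rigid shift (the head-like regime), optionally with axis
  scaling about the ROI center;
* `bidirectional_stretch` — axis scaling about a fixation line, so material
  on opposite sides moves apart (the trunk-like regime);
* `apical_constriction` — each cell scales about its own centroid, areas
  change, centroids do not;
* `identity`.

Cells persist through all frames: over a 20-minute window, which is about
half the mean neighbour-exchange time in this tissue, observed deformation
is passive and rearrangement-free, and the generator encodes that regime.
The preset factors (`deformation_preset()`) encode the study conditions:
head, minor −12.04% / major −0.17% with anteriorward translation; trunk,
major +13.43% / minor −13.62% about the mid-sheet fixation line; apical
constriction, a 16.5% area reduction (the midpoint of the reported 16–17%).

**Equivalent-ellipse fitting.** Cell and ROI axes come from analytic
polygon second moments (Green's theorem contour integrals), i.e. the
ellipse with the same area-normalized second central moments — the moment
convention of the segmentation ecosystem, and exactly testable: a $w
\times h$ rectangle has variances $w^2/12, h^2/12$; an elliptical polygon
returns its true axes, so axis ratio 0.8 gives eccentricity 0.6 exactly.
The integral ROI is the union of all cell polygons; since segmentation
output (and every tessellation image under the affine maps used here) has
disjoint interiors, union moments are sums of per-polygon raw moments and
no polygon clipping is needed. Besides the principal axes the ROI report
carries the AP-aligned and lateral extents $4\sqrt{\mathrm{var}}$, which
remain stable when the ROI is nearly isotropic and the principal direction
is ill-conditioned. An oriented-bounding-box axis readout was considered
and rejected: it is discontinuous under rotation and not moment-exact.

**Order parameter.** Per cell, the displacement summed over the first two
and last two inter-frame steps, expressed as the cosine of the angle to
the anterior direction (+1 anteriorward, −1 posteriorward); "two frames"
is read as two inter-frame intervals, with a single-interval option. The
domain split scans all two-segment partitions of the ordinate-sorted
records and scores each by the *improvement over the one-domain fit* in
mean absolute cosine deviation; a split is declared when the best
improvement reaches 0.2. Scoring raw between-segment mean differences
instead would false-trigger on spatially unstructured ±1 cosines at
realistic sample sizes, which is why the improvement form is used. The
recovered split lands within about one cell diameter of the prescribed
fixation line across seeds.

**Small ROIs.** Groups of 10–11 contiguous cells, grown greedily on the
shared-edge adjacency graph from the cell at the most extreme ordinate;
every cell lands in exactly one ROI. Counts not expressible as
$10a + 11b$ (e.g. 56) leave a remainder that the last ROI absorbs with a
warning — preferable to silently dropping cells.

**Statistics.** Start-vs-end comparisons use a two-sided Mann–Whitney U
test: exact when both samples have ≤ 12 observations — via a rank-sum
counting recursion that stays exact under ties (doubled midranks) — and
the tie-corrected normal approximation otherwise, cross-checked against
`stats::wilcox.test` where that supports the case. Means are reported with
t-based 95% confidence intervals. At the study's per-region cell counts
(56 and 136) the type-I error at α = 0.05 is 0.049 over 2000 null
simulations.

## 4. Expression statistics

**Five-group percentages.** Raw read sums per group over the canonical
stage-14 group map (`default_group_map()`), as a percentage of each gene's
total; unlisted cell types fall into "other", zero-total genes are skipped
with a diagnostic. No per-cell-type depth normalization is applied — the
aggregation is defined on reads, and whether upstream counts should be
depth-normalized first is left to the caller.

**qPCR.** Amplification efficiency comes from a four-point fivefold
dilution series: replicate Cts are averaged per dilution, the dilution
exponent is regressed on mean Ct, and $E = 1/5^{-\text{slope}} =
5^{\text{slope}}$; perfect doubling shows a Ct step of $\log_2 5 \approx
2.32$ cycles per dilution, and estimates outside $(1, 5]$ are flagged.
Fold changes use ΔΔCt with dual-reference normalization: the normalizer is
the arithmetic mean of the two reference Cts (the geometric mean of
reference expression), and fold $= E^{-\Delta\Delta C_t}$ with $E = 2$
unless a measured per-gene efficiency is supplied (Pfaffl-style). Response
labels use a default 1.5-fold threshold with the confidence interval
required to exclude 1 — the underlying study reported direction only, so
the cutoff is this package's.

**Candidate filter.** Genes with $|LFC| \ge$ `lfc_min` and (adjusted)
$p \le$ `p_max`, ordered by p then |LFC|; thresholds are mandatory
arguments because the upstream study's exact cutoffs were not available,
and the filter is monotone by construction (tightening either threshold
never adds a gene). The synthetic DE table plants 84 signal genes among
10,000 nulls; at |LFC| ≥ 1 and BH-adjusted p ≤ 0.05 all 84 are recovered
with no false positives under the default noise model.

## 5. Numerical choices and degenerate inputs

* Zero-area and collinear polygons are rejected, as are images smaller
  than 4 px per side, empty masks ("no tissue"), profiles under 10 lines,
  and samples under 5 values for the start/end comparison.
* Constant profiles have Spearman ρ defined as 0; constant channels make
  the Pearson diagnostic NA ("undefined"), never a crash.
* Exact-vs-approximate Mann–Whitney switches at n = 12 per sample; the
  exact two-sided p doubles the smaller tail and caps at 1.
* Seeds: every generator takes an explicit integer seed and restores the
  caller's RNG state (`withr::with_seed`); identical seeds are
  bit-reproducible.
* 16-bit TIFF round trips quantize intensities to one unit.

## 6. Problem sizes

The shipped analyses and checks run on 256×512 images, sheets of 56–136
cells over 21 frames, 2000-replicate null calibrations, 50–100 simulated
qPCR plates, and 10,000-gene DE tables — sizes chosen so the full suite
exercises every code path in a few minutes on a laptop while keeping
Monte-Carlo error well inside the asserted tolerances.

## 7. Known limitations

* The FRET index is an emission-fraction abstraction; no spectral
  unmixing, bleed-through correction, or force calibration is attempted.
* Union moments assume non-overlapping cell polygons; overlapping
  segmentations would be double-counted (a warning-free failure mode —
  check segmentation quality upstream).
* The order-parameter split detector fits exactly two domains; more
  complex spatial patterns (three domains, gradients of cosine) return
  whichever two-segment description fits best.
* Small-ROI construction is greedy, not optimal; ROI shapes depend on the
  seeding order when the adjacency graph is sparse.
* The synthetic trunk's eccentricity shift at n = 56 cells straddles
  conventional significance across seeds — as any single-embryo comparison
  of that size will.
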