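---
title: "Quantifying mutant-huntingtin pathology in high-content images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutant-huntingtin pathology in high-content images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httquant)
```

## The measurement problem

In Huntington's disease models, mutant huntingtin (mHTT) accumulates in
neurons first as diffuse, sub-resolution species and later as discrete
inclusion bodies. Characterising that progression in tissue requires
per-cell measurements from multichannel fluorescence sections: which cells
are medium spiny neurons (DARPP-32), neurons in general (NeuN), or
transduced (GFP); how many EM48-immunoreactive inclusions each cell
carries, how large they are, and whether they sit in the nucleus or the
perinuclear cytoplasm; how "granular" the nuclear EM48 signal is before
discrete inclusions appear; and how much total huntingtin (MAB2174) a cell
retains after a knockdown treatment. httquant implements this pipeline so
each stage can be validated against synthetic scenes with exact ground
truth.

The processing chain is:

1. **Background removal** — a sliding-parabola filter.
2. **Nuclei** — global threshold on filtered DAPI, hole filling, optional
   watershed splitting, and a strict area gate at 280 px.
3. **Cells** — cytoplasm grown from each nucleus within a marker-support
   mask; marker positivity called against a local extracellular rim.
4. **Inclusions** — peak-seeded ring growth on filtered EM48 with size,
   shape and relative-intensity gates; nuclear vs extranuclear assignment
   by the geometric center and a 9-px perinuclear ring.
5. **Granularity** — a center-surround texture index over each nucleus.
6. **Intensity** — background-corrected compartment means, percent of
   control.
7. **Statistics** — per-region endpoint tables, section-to-animal
   averaging, one-way ANOVA and Sidak-adjusted pairwise comparisons.

## The sliding-parabola filter

The background is the grayscale opening of the image with the paraboloid
structuring function $s(r) = -c\,r^2$, with the curvature $c$ in intensity
units per px². A paraboloid is slid under the intensity surface; the
background is the envelope of everything it can reach, and is subtracted
with a floor at zero. Structures *narrower* than the paraboloid's local
span survive subtraction; smooth shading does not. Two consequences are
worth stating plainly:

* a *gentle* paraboloid (small $c$) bridges over narrow peaks — the
  background under an isolated 1-px spike of height $h$ is exactly
  $\min(h, c)$, so gentle curvature preserves spikes in the subtracted
  image while steep curvature follows them;
* the filter is *not* equivariant under intensity rescaling, because $c$
  has physical units. All later thresholds are relative (medians, factor
  ratios), so the pipeline is insensitive to moderate exposure changes,
  but a large change in intensity scale amounts to a different effective
  curvature. Defaults ($c{=}5$ for DAPI, $c{=}20$ for EM48) assume
  16-bit-scale intensities with nuclear amplitudes in the low thousands.

The implementation computes the opening exactly by separable
lower-envelope passes (the quadratic structuring function factorises over
rows and columns) and is tested against a brute-force double-loop oracle
over random images. Border handling truncates the structuring-function
support at the image edge; no padding values are invented. The mapping to
any vendor "curvature" setting is approximate; only the morphological
contract above is guaranteed.

## Nuclei, cells, and the local background rim

Nuclei are segmented on the filtered DAPI image with Otsu's threshold by
default (a `k * median` rule is available), holes filled, and components
labeled with 8-connectivity. The area gate is strict and in raw pixels as
printed: a 279-px region is rejected, a 280-px region kept. Touching-nuclei
watershed splitting is available but off by default; the synthetic scenes
place nuclei apart.

The "local background" of a cell is the mean intensity in a chessboard
rim 3 px wide, 2 px outside the cell border, with other cells' pixels
excluded; if exclusions empty the rim, the image median is used and the
record flagged (`rim_fallback`) so one crowded cell cannot abort a run.
A cell is positive for a marker when its mean nuclear marker intensity
strictly exceeds factor × local background, with factors 1.1 (DARPP-32),
2.0 (NeuN) and 1.5 (GFP). Equality is negative. Because both sides scale
together, calls are invariant under global rescaling, and raising a factor
can only remove positives.

Cytoplasm is grown geodesically from each nucleus, up to 15 px by default,
within a support mask of marker-positive pixels; contested pixels go to
the Euclidean-nearest nucleus with ties to the lower label. The support
threshold was a genuinely open design point. A threshold taken from a rim
just outside the nucleus is self-defeating — that rim lies on the very
cytoplasm being sought — and a global multiple of the marker median turned
out to be knife-edged once marker-bright tissue approaches half the field,
at which point the median jumps from the extracellular to the cellular
level. The default therefore removes the smooth background from the marker
channel (parabola, curvature 5) and applies Otsu's threshold to the
residual, which separates cell-body signal from the extracellular level
regardless of tissue coverage or shading; an explicit numeric threshold
can always be supplied. When several markers are present the support is
their pixelwise maximum, so a cell outlined by any marker gets a cytoplasm.

## Inclusion detection

The EM48 channel is filtered at curvature 20; the background level is the
median of the whole filtered image. Seeds are 8-neighbourhood local maxima
strictly above twice that median (equal-valued plateaus contribute one
seed, their topmost-leftmost pixel), processed in order of descending
intensity. Growth adds, ring by ring, every adjacent unclaimed pixel
strictly above the same threshold; pixels once claimed are never
reassigned, so spots are disjoint and first-seed-wins. The paper's growth
wording is internally inconsistent (pixels "above twice the background"
are added, yet growth stops at pixels "below the background"); the
stricter reading — only pixels above twice the background are ever added —
is implemented, which makes the weaker stop condition vacuous. In the
production path growth is computed as connected components of the
above-threshold mask claimed by their first seed, which is provably
identical to sequential flood fill and much faster; the per-seed
`grow_spot()` remains the reference implementation and both are tested
against an independent flood-fill oracle.

An object is an inclusion when its area strictly exceeds 5 px², its
roundness $4\pi A/P^2$ lies in $[0.5, 1.2]$, its width/length ratio (minor
over major second-moment axis) exceeds 0.4, and its mean raw intensity is
at least twice the "mean spot intensity" of the candidate pool. The
perimeter is counted as pixel-edge segments; with that convention a 3×3
square scores $36\pi/144 \approx 0.785$ and small discrete objects can
exceed 1, which is why the upper gate is 1.2 rather than 1. Note two
discrete quirks that the synthetic generator respects: digital disks of
some small areas (e.g. the 13-px diamond, roundness 0.41) fall below the
0.5 gate even though they are "round", so planted inclusions are
resampled until their rasterisation passes the gates with margin; and the
relative intensity gate presumes a candidate pool dominated by dim
diffuse texture — in a field containing only bright spots, every spot
would fall below twice the pool mean and be discarded.

The comparator's referent is configurable (`spot_mean_reference`) and the
choice matters in heavily burdened tissue. Pooling all candidate *pixels*
weights the comparator by object area, so at a realistic late-stage
burden (~1.3 inclusions per cell) the bright inclusions drag the
threshold up to roughly half their own brightness and the gate starts
rejecting dimmer true inclusions — detection would deteriorate exactly
where pathology grows. The default therefore averages the per-candidate
*mean intensities*, which is count-weighted, stays anchored to the
numerous dim texture candidates, and keeps detection stable across the
whole burden range; it is also at least as literal a reading of a "mean
spot intensity".

Compartment assignment rounds the spot's geometric center to its
containing pixel: inside a nucleus it is nuclear; inside the 9-px
chessboard ring outside a nucleus border it is extranuclear (contested
rings go to the Euclidean-nearest nucleus); otherwise unassigned.

## The granularity index

For each nucleus the EM48 image is smoothed with a Gaussian of
`scale_px` (default 1 px, sub-inclusion scale at 0.32 μm/px), a discrete
Laplacian is applied, and the bright-spot response is $R = \max(0, -L)$.
The index is

$$G = \frac{1}{n}\sum_{p \in N}\left(\frac{R(p)}{\bar m}\right)^2,$$

with $\bar m$ the mean EM48 intensity over the nucleus (index 0 if
$\bar m = 0$). It is exactly invariant under multiplying the image by any
positive constant, zero for a constant nucleus, and — the property that
makes it an early marker — it grows with the number of sub-resolution
puncta at fixed amplitude and falls when the same integrated signal
consolidates into one smooth blob much wider than `scale_px`. The
normalisation has a regime constraint worth knowing: because $\bar m$
includes the puncta themselves, the index saturates once punctate signal
dominates the nuclear mean. It is designed for, and validated in, the
dim-puncta regime (amplitudes well below discrete-inclusion brightness),
which is exactly the pre-inclusion species it is meant to detect. It is a
functional analogue of vendor spot-texture features, not a bit-level port,
and is normalised per cell so staining-batch differences cancel.

## Intensity and statistics

Compartment intensity is the raw mean minus the rim local background,
floored at zero; percent-of-control divides each cell's corrected value by
the control-group mean (the control group's own mean is exactly 100).
Per-region endpoint tables report cells, marker-positive cells, nuclear
inclusions per positive cell, mean nuclear inclusion size, the
inclusion-to-nuclear-area ratio **both** as total-area/total-area and as
count/area — the source wording for the "size" endpoint literally says
number over area, so both readings are emitted side by side rather than
silently choosing — extranuclear density per μm² of measured cell area,
and mean granularity.

`group_stats()` treats the animal as the experimental unit: section rows
are averaged per animal first (a test verifies this equals running the
ANOVA on a pre-averaged table), then each endpoint gets a one-way ANOVA
and pairwise comparisons on the pooled residual variance with the Sidak
adjustment $p_{adj} = 1-(1-p)^m$; with one comparison the adjusted value
equals the raw one. `contrasts = "consecutive"` restricts the family to
adjacent levels, the natural set for an age series. Two grouping columns
give a crossed two-way ANOVA. The pairwise machinery is cross-checked
against emmeans' Sidak adjustment in the test suite, and its family-wise
error under a simulated null is verified to stay near nominal.

## What the synthetic scenes do and do not emulate

`scene_spec()`/`render_scene()` draw a field at 0.32 μm/px on a
16-bit-like intensity scale: hard-edged elliptical nuclei (400–900 px²)
with multiplicative DAPI texture; perinuclear marker annuli for a
configurable positive fraction of cells; compact, bright, shape-passing
EM48 inclusions planted per cell at Poisson rates in nuclear and
perinuclear compartments with ≥2 px margins from compartment borders;
optional dim Gaussian micropuncta; a dense dim EM48 "speckle" texture
standing in for diffuse tissue immunoreactivity; a smooth second-order
polynomial shading; and Gaussian (optionally Poisson) noise. Every planted
object is recorded exactly, and a fixed seed reproduces a scene
byte-for-byte.

Choices that matter and why:

* **Hard-edged nuclei and inclusions** (not Gaussian blobs) make the
  planted pixel count an exact ground-truth area, so size-recovery tests
  measure detection, not rasterisation ambiguity. Micropuncta and speckle
  are Gaussians because sub-resolution structure must be continuously
  controllable.
* **Dense dim speckle** (default 60% of pixels host a small punctum of
  amplitude 180–260) shapes the filtered-intensity distribution so that
  twice its median sits just above the texture peaks. This is what makes
  the printed relative thresholds behave as intended: growth boundaries
  stay crisp, and the candidate pool is dominated by dim objects the
  intensity gate then rejects. Inclusion amplitudes (4500–6500) and
  micropunctum amplitude (800) are set relative to that texture.
* **The trajectory defaults** (`striatal_trajectory()`) encode the
  striatal nuclear-inclusion rates per DARPP-32⁺ cell at 3, 4, 6, 8 and
  12 months (0.059, 0.24, 0.55, 0.96, 1.084), their between-animal
  standard deviations, and plausible mean inclusion areas that grow with
  age.
* **Placement drops are avoided, not ignored**: when a sampled inclusion
  cannot be placed at the required margins, smaller areas are resampled so
  the realised planted count tracks the nominal Poisson rate; residual
  drops are under ~5% and all recovery comparisons use the realised truth.

What passing tests on these scenes show is that the *measurement chain* is
correct and well calibrated under controlled conditions. They do not show
robustness to real-tissue phenomena the generator omits: out-of-focus
light and true PSFs, anisotropic illumination beyond a smooth polynomial,
overlapping and touching nuclei (splitting exists but is untested against
real morphology), autofluorescent debris, or section-to-section staining
drift.

## Validation experiment sizes

The validation suite runs entirely on synthetic scenes. The problem sizes
are the package's chosen operating points: 10⁴ random 8×8 images for each
brute-force oracle; twenty 320-px fields with ~50 well-separated
inclusions each for recovery (precision/recall ≥ 0.95, sizes within 20%);
500+ spots for compartment agreement; 500+ cells across three markers for
positivity; 100 single-nucleus fields per ladder level for granularity;
and, for the age-series experiment, one five-age series at 200 cells per
688-px scene for rate recovery plus fifty replicate experiments of
5 ages × 9 synthetic animals × one 36-cell field each for the
significance check on the 6→8-month step (consecutive-age Sidak family,
m = 4). The 9 × 36 design was fixed a priori by a statistics-level Monte
Carlo: with the trajectory's between-animal SDs and Poisson counting
noise at 36 cells it gives per-replicate power ≈ 0.996 for that step, so
49–50 of 50 replicates are expected to flag it.

## Known limitations

* Curvature units are declared, not vendor-calibrated; parity with any
  particular instrument software cannot be asserted.
* Full-chain behaviour under large intensity rescaling is not invariant
  (see above); acquisition settings should be stable within a study.
* The granularity index saturates outside the dim-puncta regime.
* 2-D only; no z-stacks, no atlas registration, no mixed-effects models
  (animal means + ANOVA mirror the original analysis).
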