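# httquant

High-content quantification of mutant-huntingtin (mHTT) pathology in
multichannel fluorescence images of brain tissue sections.

In Huntington's disease models, mHTT first appears as diffuse nuclear
signal and sub-resolution puncta, then condenses into discrete inclusion
bodies. httquant measures that progression per cell: it detects nuclei
from the DAPI channel, classifies cells by marker immunoreactivity
(DARPP-32 for medium spiny neurons, NeuN for neurons, GFP for transduced
cells), detects EM48-immunoreactive inclusions and assigns them to the
nuclear or perinuclear compartment, computes a nuclear "granularity"
texture index that is sensitive to pre-inclusion aggregation species,
quantifies background-corrected pan-huntingtin (MAB2174) intensity, and
aggregates everything into per-region endpoint tables with group
statistics. A seeded synthetic-scene generator with exact ground truth
makes every stage testable without tissue.

## The method in brief

* **Background**: grayscale opening with a paraboloid structuring function
  `s(r) = -c r²` (sliding-parabola filter; `c = 5` for DAPI, `c = 20` for
  EM48), subtracted with a floor at zero.
* **Nuclei**: global threshold (Otsu) on filtered DAPI, hole filling,
  optional watershed splitting, 8-connected labeling, strict area gate —
  regions smaller than 280 px are excluded.
* **Marker positivity**: a cell is positive when its mean nuclear marker
  intensity strictly exceeds *factor* × the mean local background in an
  extracellular rim (3 px wide, 2 px gap) around the cell border; factors
  1.1 / 2.0 / 1.5 for DARPP-32 / NeuN / GFP.
* **Inclusions**: seeds are local maxima of the filtered EM48 image above
  2 × its median; objects grow ring-by-ring over pixels above the same
  threshold (first-seed-wins); inclusions are objects with area > 5 px²,
  roundness `4πA/P²` in [0.5, 1.2] (pixel-edge perimeter), width/length
  ratio > 0.4, and mean raw intensity ≥ 2 × the candidate-pool mean.
  The geometric center decides nuclear vs extranuclear (9-px perinuclear
  ring) vs unassigned.
* **Granularity**: `G = mean over nucleus of (max(0, -LoG(img)) / m̄)²`,
  with `m̄` the nuclear mean — zero for uniform nuclei, scale invariant,
  increasing in sub-resolution punctation, decreasing when signal
  consolidates into large inclusions.
* **Statistics**: sections averaged per animal, one-way ANOVA per
  endpoint, Sidak-adjusted pairwise comparisons `p_adj = 1 - (1-p)^m`.

## Worked example

Render a synthetic striatal field with a known inclusion burden, run the
full pipeline, and compare against the planted truth:

```r
library(httquant)

spec  <- scene_spec(n_nuclei = 200, shape = c(688, 688),
                    nuclear_rate = 0.96, extranuclear_rate = 0.2)
scene <- render_scene(spec, seed = 601)

nuc  <- detect_nuclei(scene$channels$dapi)
cls  <- classify_cells(scene$channels["DARPP32"], nuc,
                       factors = c(DARPP32 = 1.1))
inc  <- detect_inclusions(scene$channels$em48, nuc)
ep   <- endpoint_table(cls, inc)

ep$n_cells                        # 200   cells detected
ep$n_marker_pos                   # 189   DARPP-32 positive (189 planted)
ep$nuclear_inclusions_per_cell    # 0.952 vs 0.968 planted per positive cell
```

On this scene the pipeline recovers all 200 nuclei, calls exactly the 189
planted DARPP-32-positive cells, and measures 0.952 nuclear inclusions
per positive cell against a realized planted rate of 0.968 (1.7% low, a
handful of marginal spots at the shape gates). `autoplot()` methods show
endpoint dot plots and pairwise-comparison summaries; `plot_scene_overlay()`
overlays detections on a channel.

An age-series experiment mirrors the striatal time course: per-cell
inclusion rates 0.059 → 0.24 → 0.55 → 0.96 → 1.084 across 3–12 months
(`striatal_trajectory()`), rendered per animal and analysed with
`group_stats(..., contrasts = "consecutive")`.

A thin command-line wrapper lives at `inst/cli/httquant`
(`simulate`, `run`, `quantify`, `stats` subcommands).

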