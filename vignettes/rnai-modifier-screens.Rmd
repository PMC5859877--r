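---
title: "Scoring reproductive-fitness modifier screens with rfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring reproductive-fitness modifier screens with rfscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfscreen)
library(dplyr)
```

## The screening problem

A genetic modifier screen asks which gene knockdowns change a phenotype more
in a sensitized mutant than in an otherwise identical control strain. In the
design this package implements, *C. elegans* larvae carrying a GFP-marked
pharynx are fed dsRNA-expressing bacteria in 96-well liquid culture; after
several days each well holds a handful of adult founder worms and their
larval progeny. The phenotype is **reproductive fitness (RF)** — larval
progeny per adult parent — and the readout for each dsRNA clone is the
**RF ratio**: RF in the sensitized mutant divided by RF in the control
strain. A ratio well below 1 means the knockdown is disproportionately
deleterious in the mutant background (a genetic enhancer); a ratio above 1
suggests suppression.

Every plate reserves column 1 for controls: empty dsRNA vector (`CN1`) and
*hil-5* dsRNA (`CN2`) as negatives, *lis-1* dsRNA (`CP`) as the positive
enhancer control that anchors the hit threshold, *plk-1* dsRNA (`C`) — fully
embryonic-lethal — as an RNAi-efficiency check, and empty wells (`E`).

## The counting model

Each well is imaged once at low magnification; every animal appears as one
bright pharynx blob. Counting is two-step:

1. **Detection.** The image is binarized (global automatic Otsu threshold by
   default, or a fixed value), holes are filled, and connected components are
   labelled (8-neighbourhood by default; elongated dim pharynxes fragment
   under 4-connectivity). A component is kept when its **area** is strictly
   larger than the area bound, its **mass** (summed pixel intensity over the
   filled shape) strictly smaller than the mass bound, and its **perimeter**
   strictly smaller than the perimeter bound. Rejection records the first
   violated rule in the order area → mass → perimeter; the kept set itself is
   order-independent.
2. **Classification.** Kept objects are split by mass: at or above
   `intensity_class_threshold` they are parents (adults), below it progeny
   (larvae). Adults have larger, brighter pharynxes, so the two mass bands
   are well separated in practice.

Defaults mirror the published rules: area > 0.383 µm², mass < 300000,
perimeter < 1 mm. Two of these deserve comment. The printed area bound of
0.383 µm² is smaller than one pixel at the 2x acquisition scale
(`pixel_size = 3.25` µm, so one pixel covers ~10.6 µm²); taken literally it
rejects nothing. We keep the printed numeral as the default together with an
explicit unit field rather than silently "correcting" it; workflows that
want the area rule to bite (including our synthetic-scene tests, via
`scene_segmentation_params()`) override it — 120 µm² is far below any larva
(~320 µm²) and still catches few-pixel speckles. The mass bound mixes
intensity and pixel vocabulary in the original description; it is treated as
a pure summed-intensity bound. The adult/larva threshold is never printed at
all, so it is an explicitly calibrated parameter here:
`calibrate_class_threshold()` returns the midpoint between the largest larva
mass and the smallest parent mass of a labelled training set and refuses to
calibrate when the bands overlap.

The perimeter estimator matters for a rule expressed in millimetres: we
count boundary pixel-step edges (pixel sides shared with background or the
image border) and multiply by `pixel_size`. This estimator is exact for
axis-aligned shapes and slightly over-estimates smooth curved boundaries;
the published bound is generous enough (an adult pharynx measures ~0.3 mm)
that the estimator choice does not affect pharynx-sized objects.

## From counts to hits

For each well, RF is progeny/parents — but only when the well held 3–13
parents, the range over which progeny counts scale linearly with parents.
Outside the window the replicate carries the `OUT` sentinel. Replicate
averaging skips `OUT` values (a clone with one valid replicate keeps that
replicate's RF); a clone with no valid replicate is itself `OUT`, and its
ratio undetermined.

Selection is two-stage, exactly as the screen was run:

* **Primary** (two technical replicates per strain): clones whose control-
  strain RF is reduced by strictly more than 85 % relative to the
  negative-control baseline are excluded as lethal (their ratio is
  unreliable); remaining determinate clones are **hits** when
  RF ratio ≤ 0.5 (inclusive). The positive-control ratios also yield a
  diagnostic threshold µ + 2σ, reported alongside; selection uses the
  configured cutoff, reproducing the published behaviour (the derived
  threshold there was 0.43, the applied cutoff 0.5).
* **Secondary** (three biological replicates, two technical each, on the
  re-arrayed primary hits): each biological replicate contributes one ratio
  built from its own technical-replicate averages; a clone is a **final
  interactor** when the mean over its determinate replicate ratios is ≤ 0.5.

Boundary semantics follow the printed inequalities exactly: strict for the
detection filters, the 85 % lethality rule and the suppressor bound
(ratio > 1); inclusive for hit selection (≤ 0.5). The lethality baseline is
a design choice the original description leaves open: we use the plate-local
mean RF of the control strain's empty-vector wells, falling back to the
run-wide mean when a plate's own negative controls are invalid —
plate-local normalization absorbs batch effects, and the controls exist on
every plate. The µ + 2σ threshold uses the sample (n−1) standard deviation
by default (the positive controls are a sample of plates); both flavours
are supported because the deposited analysis does not say which was used.

```{r pipeline}
model <- screen_model(n_plates = 2, n_enhancers = 4, n_lethals = 1, seed = 11)
ts <- run_two_stage(model)
ts$primary
ts$secondary
glance(ts$primary)
```

## What the synthetic generator emulates

There is no public per-pixel or per-well raw dataset to regress against, so
the package ships a generator whose defaults *are* the study conditions,
used by every test:

* **Plates and layout**: 96-well plates, column 1 carrying
  `CN1/CN2/CP/C/E` controls (two CP wells per plate), 88 library clones.
* **Founders**: adults per well are Poisson around `founder_mean = 7`
  (capped at 3× the mean), so a few percent of wells naturally fall outside
  the 3–13 window and exercise the `OUT` machinery.
* **Progeny noise**: negative binomial with mean
  adults × baseline RF × effect multiplier and size (`dispersion`) 15.
  Overdispersion is what keeps technical-replicate correlations in the
  0.6–0.8 band reported for the real screen instead of near 1; together
  with a shared lognormal per-gene fertility spread (`effect_sdlog = 0.45`,
  applied equally to both strains so RF ratios are unaffected) the
  generator reproduces that band (r ≈ 0.69 at the defaults). These two
  values were set from this variance calibration, not fitted to any test.
* **Baselines**: 10 progeny/parent in the control strain, 9 in the mutant —
  the mutant's fertility is only mildly affected, and negative-control RF
  ratios cluster near 1.
* **Planted effects**: enhancers multiply the mutant's expected RF by 0.3
  (true ratio 0.3), suppressors by 1.6, lethal clones multiply both strains
  by 0.05 (> 85 % reduction, so they must be excluded). Control wells carry
  fixed effects: *plk-1* zero progeny in both strains; *hil-5* 0.85 in the
  mutant only (10–20 % embryonic lethality); *lis-1* 0.5 in the control and
  0.15 in the mutant (strong, mutant-biased).
* **Images**: pharynxes are anisotropic Gaussian blobs truncated at the
  foreground threshold — parents 200–300 px at peak 700–900, larvae
  30–60 px at peak 600–700 — over a background whose noise is capped below
  the threshold. Construction guarantees disjoint mass bands (parent mass
  ≥ 100000, larva mass ≤ ~45000), non-touching placement (with bounded
  retries and a placement error), and an exact per-object ground truth:
  pixel set, measured area/mass/perimeter, and the expected filter and
  classification outcome under the parameters in use. Debris comes in three
  flavours, one per filter rule: a few-pixel speckle (area), a saturated
  clump (mass), and a 170-px filament whose pixel-step perimeter exceeds
  1 mm.

What the generator does **not** emulate: touching or overlapping animals,
out-of-focus or vignetted optics, well-edge artefacts, plate-positional
(edge) effects, RNAi penetrance kinetics, or any correlation between a
gene's fertility effect and its image appearance. Tests passing on
synthetic scenes therefore certify the algorithmic contracts (exact
counting on separable scenes, correct boundary semantics, correct
selection arithmetic), not segmentation robustness on degraded real images.

## Numerical choices and degenerate inputs

* `OUT` is encoded as `NaN` in numeric RF columns (`NA` means "never
  measured", e.g. empty wells); on disk the sentinel is the literal token
  `"OUT"`, and CSV round trips are field-identical because RF numbers are
  written with full double precision.
* Correlations drop `OUT`/missing pairs listwise, require n ≥ 3 and
  non-zero variance, and report the exact two-sided t-based p-value
  (with a formatting helper for the conventional "< 0.0001" style).
* Zero-progeny clones give RF 0 (not `OUT`); a zero control-strain RF makes
  the ratio undetermined unless the lethality rule already excluded the
  clone (checked first).
* Degenerate class thresholds behave as limits: 0 classifies every kept
  object as parent, +∞ as progeny.
* Problem sizes in the tests and acceptance script (5 plates × 88 clones,
  25–100 image scenes of 384×384 px) were chosen as the smallest sizes at
  which the Monte-Carlo checks are statistically meaningful.

## Known limitations

* The published screen's headline numbers (19762 clones, 1077 primary
  selections, 38 interactors, threshold 0.43) derive from the deposited
  spreadsheets; reproducing them requires that download, which this package
  deliberately does not perform. The pipeline consumes the same CSV schema,
  so the deposited worksheets can be dropped in directly.
* Counting assumes non-touching animals; clumped worms merge into one
  component (the mass filter rejects extreme clumps rather than splitting
  them).
* No multiple-testing correction is applied — the original selection used
  none — and none is offered.
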