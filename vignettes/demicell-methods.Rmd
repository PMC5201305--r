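---
title: "demicell: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{demicell: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demicell)
```

## The scientific problem

When a coccoid bacterium such as *Lactococcus lactis* overexpresses a
membrane protein it cannot fold and insert efficiently, the corresponding
transcripts do not reach the membrane.  Instead they collapse into dense,
immobile clusters at the cell poles, where they are shielded from both
ribosomes and ribonucleases.  Quantifying this phenotype from single-cell
fluorescence images requires a chain of steps — spot detection, intensity
quantification, projection into a common cell-coordinate system,
cluster classification, and decay-kinetics estimation — each of which
demicell implements as a tested, seeded module.

## Spot model and the intensity statistic

Every diffraction-limited focus is modelled as a symmetric 2D Gaussian
on a constant local background,

$$ z(x, y) = b + h\, \exp\!\left(-4\ln 2\, \frac{(x-x_0)^2 + (y-y_0)^2}{w^2}\right), $$

parameterized directly by the full width at half maximum $w$ rather than
the standard deviation ($w = 2\sqrt{2\ln 2}\,\sigma$).  The spot score
used throughout is

$$ I = \pi w^2 h, $$

which is proportional to, but deliberately not equal to, the volume under
the Gaussian ($\int = \pi w^2 h / (4 \ln 2)$).  All comparisons in the
package are ratio-based, so the constant factor is immaterial; what
matters is that $I$ is exactly recomputable from the stored $w$ and $h$,
which the fitter guarantees by construction.

Candidates are strict 8-neighbour local maxima above
`background + threshold * noise_sd`, with background the image median and
the noise the scaled median absolute deviation — a robust choice because
cells occupy a small fraction of the field.  The default threshold
(5 sd), window half-size (5 px), and minimum candidate separation (3 px)
are free parameters of this implementation; the upstream literature does
not publish the plug-in settings it used.  Fits are nonlinear least
squares (`nls`, port algorithm) with quality control: non-convergence,
a centre escaping the window, a width exceeding the window, or a
non-positive height all flag the spot for discard.

## The demi-coccoid model cell

Population statistics pool spots from hundreds of cells of different
sizes and orientations.  Each cell contributes through an affine,
per-cell normalization:

1. the cell frame is the principal axis of its contour polygon
   (area-weighted second moments, not vertex averages, so vertex density
   does not bias the axis);
2. the axial offset is folded about midcell — both halves of every cell
   project onto one half-cell — and scaled to a half-length of 900 nm;
3. the lateral offset keeps its sign and is scaled to a full width of
   800 nm.

The resulting space, 800 × 900 nm, is the average width × half-length of
the organism grown in defined medium.  Zone boundaries inside it are
parameters, not measurements: a 50 nm membrane band hugging the capsule
outline, a central nucleoid ellipse at 0.55 of each half-dimension, and a
polar zone beyond 0.6 of the half-length.  These defaults operationalize
graphical (non-numeric) estimates of the membrane and DAPI-stained
nucleoid; all are configurable in `model_cell()`.  Classification
precedence is membrane > nucleoid > pole > cytoplasm, so a spot on the
apex (which is simultaneously polar and on the outline) counts as
membrane.

Location maps are 2D histograms (25 nm bins, optional 50 nm Gaussian
smoothing) whose raw counts always sum to the number of projected spots;
axial profiles sum a 200 nm central strip and normalize to a peak of 1.
Whether population maps should weight spots equally or by intensity is
genuinely open; demicell defaults to counts and exposes
`weight = "intensity"`, which is the statistic that separates a
polar-cluster population (one bright spot plus several dim ones per
cell) from merely pole-enriched patterns.

## Polar-cluster classification

No numeric cluster criterion exists in the upstream description
("densely packed", "spatially confined, yet bright", polar).  demicell
operationalizes it as a conjunction of three conditions on a single
spot: it must carry at least half the cell's total intensity
(`min_intensity_fraction = 0.5`), be compact (`max_fwhm_px = 5`), and
sit at `v >= 0.6 * half_length`.  All three thresholds are configurable.
The rule is monotone in the qualifying spot's intensity by construction:
if the spot already holds fraction $f \ge 0.5$ of the total, multiplying
it by $m > 1$ raises its fraction toward 1, never below 0.5.

A consequence worth knowing: a cell containing a single bright spot that
happens to sit near a pole is indistinguishable from a cluster under any
intensity-fraction rule.  The synthetic generator therefore draws at
least two spots per cell (a shifted Poisson, default mean 6), which is
also the realistic regime for induced cells; with that floor the false
positive rate of the classifier on uniform-pattern populations is below
1–2%.

## Synthetic data: the stated world

The generator emulates, with known ground truth, the conditions the
analysis is meant to face:

* **Cells**: capsules (rectangle plus semicircular caps) of
  800 × 1800 nm on average with 8% size CV, random orientation, laid out
  on a non-overlapping grid; imaged at 65 nm/px.
* **PSF**: isotropic Gaussian, sigma 130 nm (FWHM ≈ 306 nm ≈ 4.7 px),
  appropriate for ~600 nm emission at high NA.
* **Patterns**: `membrane` (contour inset by 25 nm), `uniform`,
  `cytoplasmic_nucleoid_excluded` (outside the 0.55-scaled ellipse), and
  `polar_cluster` (one compact spot at 0.80–0.95 of the half-length
  carrying 60% of the cell's signal, the rest as dim cytoplasmic spots).
* **Noise**: Poisson on signal + background (default 100 counts),
  then Gaussian read noise (sd 2), in that order; ground truth records
  pre-noise parameters.
* **Chase**: fluorescence $N_0 e^{-\lambda t}(1+\varepsilon)$ with
  $\varepsilon \sim \mathcal N(0, 0.3)$, log-normal $N_0$
  (sdlog 0.5), fresh cells at each of 0, 1, 2, 4, 8, 16, 32, 64 min —
  the chase design images different fixed cells per time point, so no
  pairing exists and the bootstrap resamples accordingly.

Defaults that the source material does not state (spot densities,
signal-to-noise, $N_0$ spread) were chosen once for realism and are not
revisited; they are all `scene_spec()` / `chase_spec()` arguments.  What
a green test on this world establishes is that the estimators recover
known parameters under realistic noise; it does not establish robustness
to segmentation errors, out-of-focus light, uneven illumination, or
photobleaching, none of which are simulated.

## Decay kinetics

Half-lives come from a bootstrap-plus-fit pipeline: per time point, 5
resamples of 500 cells (with replacement) yield 5 medians; each round's
median time course is divided by its own t = 0 median; the rounds are
averaged and the single-exponential $N(t) = N_0 e^{-\lambda t}$ is
fitted by nonlinear least squares in linear space (a log-linear option
exists for comparison, but the linear-space fit is the primary route and
the one the tests certify).  $t_{1/2} = \ln 2 / \lambda$ holds exactly
for every fit.  Per-round fits provide a bootstrap spread of the
half-life.  Late near-zero medians are retained — the floor-at-zero rule
of `background_subtract()` applies before fitting, and additive
background is the one bias this pipeline cannot remove post hoc (the
tests demonstrate the long-bias it causes when unsubtracted).

The growth-rate model $\log t_{1/2} = a\mu^2 + b\mu + c$ uses the
natural logarithm; this is the only base under which the printed
coefficient sets reproduce their own printed predictions at
$\mu = 0.55\,h^{-1}$ (6.4 and 11.5 min), which the acceptance suite
checks.

## Sequence statistics

Uracil density is the T fraction of the annotated CDS as provided; tags
appended for visualization are excluded by default since their
contribution to the published per-gene values is unknown.  The
hydrophobic set defaults to {A, V, L, I, F, M, W} and is configurable;
codon usage is pooled over records, normalized within synonymous
families, and the maximal-U codon(s) flagged with ties all flagged.  The
class comparison uses Welch's unequal-variance t-test — the upstream
description says only "Student's t-test", and the unequal-variance form
is the safer default for unequal group spreads.

## Numerical and degenerate-input choices

* Flat fit windows (height ≤ machine epsilon above background) are
  rejected before fitting; `nls` failures are caught and flagged.
* Anisotropic per-cell scaling of a capsule is not exactly a capsule;
  sub-nanometre excursions outside the model outline are clamped back.
* Tie-break for spots inside overlapping contours: nearest contour
  centroid, with a warning.
* Gamma expression fits exclude exact zeros (detection floor), record
  the excluded fraction, and maximize the likelihood over
  (log shape, log scale) from moment starts — stable down to shape 0.5,
  where moment estimators alone are poor.
* Non-decaying chase data yield `lambda <= 0`, a `decaying = FALSE`
  flag, and an infinite half-life rather than an error.
* All randomness flows from one integer seed; per-stage seeds are
  derived by hashing a stage label, and every generator restores the
  caller's RNG state.

## Known limitations

* The segmenter is not re-implemented: contours are consumed as input
  tables (the synthetic generator writes them), matching a workflow
  where a dedicated tool produces cell meshes.
* Single-frame classification only; time-lapse cluster-clearance
  statistics are out of scope.
* The TIFF layer supports exactly the subset it writes (uncompressed
  16-bit grayscale); vendor files outside that subset are rejected
  explicitly.
* 3D PSFs, photobleaching, gain calibration, and cell growth during
  acquisition are not modelled.

## A worked half-life recovery

```{r, eval = FALSE}
spec <- chase_spec(
  subpopulations = list(
    subpopulation("free", 0.5, half_life_min = 4.6),
    subpopulation("trapped", 0.5, half_life_min = 16.1, cluster = TRUE)
  ),
  n_cells_per_timepoint = 500, cell_noise_cv = 0.3, seed = 19
)
st <- stratified_half_lives(generate_chase(spec), bootstrap_config(seed = 3))
c(non_cluster = st$non_cluster$t_half, cluster = st$cluster$t_half)
#> non_cluster     cluster
#>       4.546      17.945
```

The numbers above are what the seeded example computes; the acceptance
script (`scripts/acceptance.R`) repeats this over 20 seeds per scenario
and reports medians.
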