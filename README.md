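# demicell

Single-cell quantification of mRNA localization and decay in coccoid
bacteria.

## The problem

Bacterial hosts such as *Lactococcus lactis* are workhorses for
recombinant membrane-protein production, but poorly expressed membrane
proteins leave a visible fingerprint at the single-cell level: their
transcripts pile up in dense, immobile clusters at the cell poles
instead of being translated at the membrane.  Cells carrying such polar
mRNA clusters stop dividing, and the trapped transcripts are degraded
several-fold more slowly than free ones.  Quantifying this phenotype
from fluorescence microscopy (smFISH or MS2 labelling) and
rifampicin-chase experiments requires a reproducible analysis chain,
which this package provides end to end — together with a seeded
synthetic-data generator so every stage is testable without any external
dataset.

## What it computes

* **Spot quantification** — diffraction-limited foci are detected as
  robust local maxima and fitted with a symmetric 2D Gaussian
  (background `b`, height `h`, FWHM `w`); each spot is scored with the
  intensity statistic `I = pi * w^2 * h`.
* **Model-cell projection** — spot coordinates are folded and scaled
  per cell into an 800 x 900 nm demi-coccoid model cell (width x
  half-length); location maps, axial intensity profiles, and
  membrane/nucleoid/pole/cytoplasm zone fractions summarize populations.
* **Polar-cluster classification** — a cell is cluster-positive when one
  compact spot (`w <= 5 px`) near a pole (`v >= 0.6 * half-length`)
  carries at least half of the cell's total intensity; cluster fraction
  vs expression level, Gamma fits to expression distributions, and
  spread ratios follow.
* **Decay kinetics** — per-time-point bootstrap medians (5 x 500 cells)
  are fitted with `N(t) = N0 * exp(-lambda * t)`; `t1/2 = ln(2)/lambda`.
  Half-lives can be stratified by cluster presence, and the quadratic
  growth-rate model `log(t1/2) = a*mu^2 + b*mu + c` (natural log) is
  evaluated and fitted.
* **Sequence statistics** — per-gene uracil density (T fraction of the
  CDS), hydrophobic-codon usage with maximal-U codons flagged, and a
  Welch test comparing membrane vs cytoplasmic transcript classes.

## Worked example

```r
library(demicell)

# a seeded population of 200 cells with polar mRNA clusters
sc  <- generate_scene(scene_spec(n_cells = 200, pattern = "polar_cluster",
                                 seed = 7), render = FALSE)
ns  <- normalize_spots(sc$truth$spots, sc$truth$cells)
tot <- data.frame(cell_id = sc$truth$cells$cell_id,
                  total_I = sc$truth$cells$total_I)
mean(classify_cells(ns, tot)$has_cluster)
#> [1] 1
round(zone_fractions(ns, weight = "intensity"), 3)
#>  membrane  nucleoid      pole cytoplasm
#>     0.073     0.122     0.666     0.139

# stratified half-lives from a synthetic rifampicin chase
spec <- chase_spec(
  subpopulations = list(
    subpopulation("free",    0.5, half_life_min = 4.6),
    subpopulation("trapped", 0.5, half_life_min = 16.1, cluster = TRUE)
  ),
  n_cells_per_timepoint = 500, cell_noise_cv = 0.3, seed = 19
)
st <- stratified_half_lives(generate_chase(spec), bootstrap_config(seed = 3))
round(c(free = st$non_cluster$t_half, trapped = st$cluster$t_half), 2)
#>    free trapped
#>    4.55   17.95

# growth-rate model: half-life of codY mRNA at mu = 0.55 1/h
round(evaluate_growth_model(growth_model(-2.0, 0.1, 2.4), 0.55), 1)
#> [1] 6.4
```

Every cluster-positive cell is found (the generator plants a cluster in
each), two-thirds of the signal sits in the polar zone, the two decay
strata are recovered close to their generating half-lives of 4.6 and
16.1 min and in the right order, and the quadratic growth-rate model
evaluates to 6.4 min.

A full orchestrated run (scene -> detection -> projection ->
classification -> chase -> kinetics -> sequence stats, with a checksum
manifest) is:

```r
run_pipeline(pipeline_config(seed = 1), "run1/")
```

or from the shell: `Rscript inst/scripts/pipeline.R --seed 1 --out run1/`.

## Documentation

The methods vignette (`vignettes/demicell-methods.Rmd`) describes the
models, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and the package's design
decisions.
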