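# smlmplex

Post-processing and analysis for **multiplexed multi-round single-molecule
localization microscopy (SMLM)**.

In serial re-staining experiments, one sample is labeled, imaged by dSTORM,
stripped, and re-labeled — ten or more times — so that many protein targets
end up imaged in the same physical specimen.  Each round produces a
localization table in its own coordinate frame.  `smlmplex` is for
microscopists and image analysts who need to turn those per-round tables
into one registered, quality-controlled, multi-target dataset and then
quantify the spatial organization it reveals — here, the presynaptic
nano-architecture of the calyx of Held, a giant terminal that appears as
an ~1 µm-thick annulus in cross-section.

## What it computes

**Registration** (translation, fiducial-based).  For bead *i* in rounds
*A* and *B*, Δx<sub>i</sub> = x<sub>A,i</sub> − x<sub>B,i</sub>; rounds are
aligned by the mean displacement (Δx̄, Δȳ), and the per-axis registration
error is the mean absolute deviation

&nbsp;&nbsp;&nbsp;&nbsp;RE<sub>x</sub> = (1/n) Σ<sub>i</sub> |Δx̄ − Δx<sub>i</sub>|,

reported for all round pairs as a matrix (upper triangle RE<sub>x</sub>,
lower RE<sub>y</sub>).

**Quality control.**  Localization precision from adjacent-frame
nearest-neighbour distances (Rayleigh + linear-background histogram fit);
feature-based intra-round drift correction (binned-image cross-correlation
with sub-pixel peak interpolation); re-staining efficiency as the OLS
slope of the normalized per-round signal ("% loss per round"); and
round-to-round Pearson cross-correlation of rendered images.

**Calyx nano-architecture.**  Membrane-perpendicular thick line profiles
along a traced synaptic membrane (1 µm segments, 700 nm profile width);
calyx borders from a two-Gaussian fit of the WGA profile; a ≥ 70 %
membrane-contiguity inclusion filter; normalization of all profiles onto
an average-calyx axis (0 = inner synaptic border, mean thickness = outer
border); hierarchical cohort averaging; Gaussian peak localization with
one-way ANOVA + Bonferroni post hoc statistics; active-zone
stratification (AZ-positive vs AZ-free segments, 300 nm profiles); and
all-pairs Pearson colocalization matrices with unpaired two-tailed t
tests between AZ classes.

**Synthetic ground truth.**  A seeded generator builds annular calyx
scenes (radial Gaussian-mixture density profiles, AZ patches with
enrichment/depletion, membrane labels), simulates multi-round
acquisitions (blinking emitters over 20,000 frames, per-round rigid
offsets, drift, signal loss, ≥ 5 immobile fiducials) and retains the
ground truth, so every stage of the pipeline is validated by recovery
tests.

## Worked example

```r
library(smlmplex)

preset <- calyx16_preset(seed = 7, density_scale = 0.5)
ds <- generate_experiment(preset$scene, preset$exp)
ds
#> <smlm_dataset> 10 rounds, 16 targets, 17453 ground-truth molecules

sets <- lapply(ds$rounds, function(r) extract_bead_positions(r$fiducials))
report <- registration_matrix(sets)
report
#> <registration_report> 10 rounds; RE range 0.1-1.3 nm
round(report$matrix[1:4, 1:4], 2)   # upper: RE_x, lower: RE_y (nm)
#>      1    2    3    4
#> 1 0.00 0.47 0.92 0.94
#> 2 0.77 0.00 0.73 0.95
#> 3 0.39 0.58 0.00 0.66
#> 4 0.33 0.74 0.40 0.00
report$shifts$SR2                   # maps round 2 into round 1's frame
#> <shift2d> dx = -84.09 nm, dy = -100.76 nm (5 beads)

nn_precision(ds$rounds$SR1$tables$WGA)
#> <precision_estimate> sigma = 7.36 nm (6494 NN pairs, bg 0.01)
```

The registration error of a fraction of a nanometre reflects beads
averaged over ~200 re-localizations each; the precision estimate recovers
the generator's 7.5 nm localization noise from the blinking structure
alone.

The full pipeline — simulate (or load), register, QC, line profiles,
AZ/colocalization, report — runs from one configuration:

```r
res <- run_pipeline(run_config(seed = 1), "out/")
```

and writes `registration_matrix.csv` + heatmap, `qc_precision.csv`,
`profile_curves.csv` + figure, `coloc_matrix.csv` + heatmap, t-test
tables, a Markdown `report.md` and a `provenance.json` (config, version,
output hashes).  The same stages are available from a shell via the
installed `exec/smlmplex` script
(`smlmplex run --config run.yaml --out dir`).

## Documentation

The methods vignette (`vignettes/smlmplex-methods.Rmd`) describes the
models, estimators, numerical choices, generator assumptions, and known
limitations in detail.
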