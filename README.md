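# minfluxr

Single-molecule MINFLUX analysis for trimeric membrane channels: from raw 3D
localization streams to per-molecule **interblade distance** distributions
(fixed-cell, DNA-PAINT) and single-molecule **diffusion coefficients**
(live-cell tracking), with the statistical comparisons used on both, a
two-channel STED colocalization branch, and a synthetic-data generator so the
entire pipeline is testable without microscope data.

## Who this is for

Labs measuring the conformation and mobility of trimeric mechanosensitive
channels (or any trimeric membrane protein labelled at equivalent subunit
positions) with an Abberior-style 3D MINFLUX instrument. Input is the
localization table exported per acquisition — trace id, timestamp, x/y/z,
EFO (effective photon frequency at offset), validity flag — as CSV/TSV or an
Imspector `.mat` export.

## The method in brief

**Structure.** After a 0.7 refractive-index z correction, per-localization
EFO filtering (cutoff 130 kHz; single-dye mode ≈ 75 kHz, two active dyes
≈ 2×) and trace-quality filters (≥ 10 localizations, per-dimension s.d.
< 10 nm, membrane-plane z window), localizations are clustered by two-step
3D DBSCAN (eps 10 nm / minPts 5 to remove noise, then eps 7 nm / minPts 5)
and refined with a spherical Gaussian-mixture EM fit (init σ = 5 nm, one
component per cluster). Fluorophore positions with member s.d. > 10 nm are
discarded. Trimers are isolated clusters of exactly three positions
(DBSCAN eps 60 nm / minPts 3) whose pairwise 3D distances all lie in
(6, 60) nm; the per-molecule statistic is

    d_mean = (d12 + d13 + d23) / 3        (3D Euclidean, rotation-invariant)

**Tracking.** Trajectories are grouped by trace id, truncated at the first
gap > 18 ms, and kept when they have > 200 localizations and mean
EFO ≤ 130 kHz. The time-averaged 3D MSD over all displacement pairs is
binned into 7 ms lags and fitted by weighted least squares through the
origin with

    MSD(tau) = 6 D tau

over 5–50 ms (microscopic D) and 50–350 ms (macroscopic D); the ensemble
curve pools trajectories into 50 bins to 350 ms with pair-count weights.

**Statistics.** Two-sided two-sample Kolmogorov–Smirnov (exact or
asymptotic), variance F test (larger variance in the numerator), seeded
percentile-bootstrap median CIs, Kruskal–Wallis with Dunn's post hoc.

**STED colocalization.** ROI mask from the reference channel (Gaussian blur
radius 10 px + fixed threshold + connected components), per-ROI Pearson r
and Spearman rho, and puncta FWHM = 2√(2 ln 2)·σ from 1D Gaussian profile
fits.

## Worked example

```r
library(minfluxr)

# --- structural branch on a synthetic scene -------------------------------
scene <- simulate_scene(scene_config(n_trimers = 60, rng_seed = 7))
res <- analyze_structure(scene$localizations, pipeline_config(rng_seed = 7))
res$summary
#> molecules: 25
#> median interblade distance: 20.84 nm (95% CI 20.39-21.33)

# --- tracking branch ------------------------------------------------------
tracks <- simulate_tracks(track_config(n_tracks = 80, d_true = 0.01,
                                       loc_sigma = 5, rng_seed = 8))
tres <- analyze_tracks(tracks$localizations, pipeline_config(rng_seed = 8))
#> trajectories: 80; ensemble D micro = 0.0108, macro = 0.0102 um^2/s
#> median per-trajectory D micro = 0.0107 um^2/s

# --- comparing two distance distributions ---------------------------------
ks_test(rnorm(50, 20, 2), rnorm(60, 22, 3))
#> KS_D = 0.51, two-sided p = 5.48e-07 (n = 50, 60)
```

The recovered median exceeds the generating 20 nm side slightly: vertex
position noise inflates measured pairwise distances (a Jensen-type effect),
and cluster-merging losses at high localization density preferentially
remove small trimers — both quantified in the methods vignette
(`vignettes/minflux-pipeline.Rmd`). The tracking example recovers the
generating D = 0.01 µm²/s within sampling error; the small micro/macro gap
reflects static localization noise (5 nm) inflating short lags.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "minfluxr", package = "minfluxr"))')
Rscript $CLI simulate-scene --seed 7 --out out/scene
Rscript $CLI analyze-structure --input out/scene/localizations.csv \
        --seed 7 --out out/structure
Rscript $CLI analyze-tracks --input tracks.csv --seed 1 --out out/tracks
Rscript $CLI coloc --input twochannel.tif --threshold 0.5 --out out/coloc
```

Each run writes a `manifest.json` (full configuration, seed, per-stage
filter counts, package version): reported n's are filter outputs, so the
filters are part of the result.

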