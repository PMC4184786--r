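# rbtrack

Quantitative analysis of the growth and mobility of protein aggregates in
the early secretory compartment — Russell bodies (RBs), the dilated ER
cisternae that accumulate condensed, detergent-insoluble immunoglobulin
mutants — from fluorescence microscopy. The package is written for cell
biologists and microscopists who need reproducible, scriptable versions of
two measurements that are usually done with ad-hoc interactive tools:

1. **How fast do aggregates grow?** In a two-colour pulse-chase, pre-existing
   ("old") protein is labelled red and newly synthesised ("young") protein
   green; growing aggregates appear as a red core wrapped in a green shell.
   The cluster diameter in each channel is measured as the **full width at
   half maximum (FWHM)** of an intensity profile through the cluster centre,
   and growth is the relative size increase

   ```
   rel_increase = (d_g − d_r) / d_r
   ```

   summarised as mean ± SEM over clusters (or over cells).

2. **How mobile are aggregates?** Individual clusters are detected
   (Laplacian-of-Gaussian blob detection), linked across frames (optimal
   bipartite assignment with a displacement gate), and each track's
   time-averaged **mean-square displacement** is fitted over its first 20
   lags with the anomalous-diffusion power law

   ```
   MSD(t) = 4 D t^α
   ```

   where `D` (µm²/s) is the short-term diffusion coefficient and `α` the
   anomalous exponent (`α < 1` subdiffusive/constrained, `α = 1` Brownian,
   `α ≈ 2` ballistic/directed). Populations are compared between conditions
   (e.g. untreated vs. microtubule depolymerisation by Nocodazole) with
   two-sided Mann–Whitney tests, and mobility is related to cluster size by
   Spearman rank correlation.

Because raw microscopy movies for this system are typically not available,
the package ships a first-class synthetic-data generator: 2D fractional
Brownian motion trajectories (per-axis fractional Gaussian noise with Hurst
exponent `H = α/2`, simulated by Davies–Harte circulant embedding with an
exact Cholesky fallback), and confocal-like images and movies (PSF-blurred
disks, Poisson shot noise) with complete ground truth. Every analysis stage
is validated against this ground truth.

## Worked example

Simulate a population at the scale of a typical live-cell experiment
(115 tracks of 300 frames at 2 frames/s) with ground-truth `D = 0.0045`
µm²/s and `α = 0.74`, then fit every track:

```r
library(rbtrack)

cfg    <- track_sim_config(D = 0.0045, alpha = 0.74,
                           n_frames = 300, frame_interval = 0.5)
tracks <- simulate_population(cfg, 115, seed = 1)
fits   <- fit_population(tracks, n_points = 20)
summarize_population(fits, condition = "untreated")
#> Population mobility (115 tracks, untreated):
#>   D     = 0.004481 +/- 2.7e-05 um^2/s (mean +/- SEM)
#>   alpha = 0.736 +/- 0.007
```

The population estimates recover the generating values: the fitted mean
`D` is within 1% of 0.0045 µm²/s and the mean `α` within 0.005 of 0.74
(individual tracks scatter more — that is the point of fitting per track
and averaging). A single fit is a first-class model object:

```r
fits[[1]]
#> Anomalous-diffusion fit (MSD = 4 D t^alpha), track 'track_1'
#>   D     = 0.004497 um^2/s
#>   alpha = 0.828
#>   R^2   = 0.9992  (20 lags, loglog)
```

with `coef()`, `summary()`, `predict()`, `plot()`, `residuals()` and
`simulate()` methods.

Growth measurement on a rendered red-core / green-shell cluster with a 16%
shell (the scenario mirroring a measured day-scale growth):

```r
pair <- render_cluster_pair(image_sim_config(shell_growth_fraction = 0.16,
                                             seed = 1))
measure_cluster(pair$image, c(pair$truth$x_um, pair$truth$y_um),
                half_length = 2)
#>   cluster_id cell_id    d_r_um   d_g_um rel_increase
#> 1  cluster_1  cell_1 0.9782509 1.138325    0.1636332
```

The measured `rel_increase` of 0.164 recovers the rendered 0.16 to within
the PSF-induced measurement error (the blur broadens both channels and
largely cancels in the ratio).

A command-line interface covering simulation, growth measurement, tracking,
MSD fitting and condition comparison is available via `rb_cli()` or the
installed shim:

```sh
Rscript inst/scripts/rbtrack simulate-tracks --n 115 --frames 300 \
    --dt 0.5 --alpha 0.74 --D 0.0045 --seed 1 --out tracks.csv
Rscript inst/scripts/rbtrack fit-msd --tracks tracks.csv --out fits.csv
```

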