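# fluctr — Number & Brightness and scanning FCS for photon-count data

`fluctr` is an R toolkit for fluorescence fluctuation spectroscopy (FFS) of
confocal photon-counting data. It addresses a concrete experimental
question: *how bright is one molecule, and what fraction of fluorescent
protein subunits actually fluoresce?* Those two numbers — the molecular
brightness and the apparent fluorescence probability *pf* — are what let
brightness-based oligomerization measurements (dimer vs monomer, receptor
clustering, and the like) be read quantitatively instead of relatively.

The package implements four connected analyses plus the simulator that
validates them:

* **Number & Brightness (N&B).** Pixel-wise moment analysis of an image
  time-stack. For photon-counting detection the estimators are

      epsilon = (sigma^2 - k) / k        (brightness, counts/dwell/molecule)
      n       = k^2 / (sigma^2 - k)      (particle number)

  with `k` and `sigma^2` the temporal mean and unbiased variance of each
  pixel's counts. Detector saturation is excluded by a 1 MHz counting-rate
  mask; photobleaching and slow movement are partially corrected by
  computing brightness in consecutive 8-frame boxcar windows and
  extrapolating the window values back to the start of the acquisition.
  The bleached fraction (signal lost between the first and last frames) is
  reported per cell.

* **Scanning FCS (sFCS).** A line scan perpendicular to a membrane gives a
  kymograph; the membrane is localized per 1000-line block (Gaussian +
  constant fit), lateral drift is removed by integer-pixel shifts, the
  membrane trace is summed in a ±2.5 sigma window, background-subtracted
  and autocorrelated with a multi-tau estimator. The curve is fitted with
  the 2D Brownian diffusion model

      G(tau) = (1/N) (1 + tau/tau_d)^(-1/2) (1 + tau/(tau_d S^2))^(-1/2)

  (S fixed from calibration), and the molecular brightness follows as
  B = ⟨I⟩ / N.

* **Point-FCS calibration.** Dye acquisitions are correlated, averaged per
  measurement, and fitted with a 3D diffusion + triplet model; the pooled
  diffusion time and structure parameter S characterize the detection
  volume (w0 = sqrt(4 D tau_d), V_eff = pi^(3/2) w0^3 S) and S is fixed in
  subsequent sFCS fits.

* **Fluorescence probability (pf).** For each day, the monomer cells set a
  reference brightness; each tandem-dimer cell then gives
  `pf = B_dimer / B_monomer - 1`, and the per-cell values are pooled
  (mean ± SEM). For independently fluorescent subunits this recovers the
  per-subunit fluorescence probability exactly
  (B_dimer = (1 + p) B_monomer).

* **Simulator.** Brownian-dynamics photon-count generators for all three
  modalities (compound-Poisson raster stacks, membrane traces and
  kymographs, 3D point-detection traces) with closed-form ground truth
  (`expected_stats()`), so every stage of the pipeline is tested against
  known answers.

## Worked example

Simulate four monomer and four tandem-dimer "cells" (per-subunit
fluorescence probability 0.7), run the N&B pipeline on each, and estimate
pf:

```r
library(fluctr)

mono <- sapply(1:4, function(i) {
  cfg <- sim_config(seed = i)                      # monomer, lambda = 0.5
  nb_cell_brightness(simulate_nb_stack(cfg))$epsilon_cps
})
dimr <- sapply(1:4, function(i) {
  cfg <- sim_config(seed = 100 + i, subunits = 2,
                    fluorescence_probability = 0.7)
  nb_cell_brightness(simulate_nb_stack(cfg))$epsilon_cps
})
ref <- mean(mono)
pf  <- pool_pf(pf_per_cell(dimr, ref))
```

Output:

```
monomer cells (counts/s/molecule): 10024 9929 10047 10133
dimer cells   (counts/s/molecule): 16829 17143 16947 16987
monomer reference: 10033
pf = 0.692 +/- 0.006 (SEM), n = 4
```

The monomer brightness recovers the generator's 10,000 counts/s/molecule,
the dimers sit near (1 + 0.7) times that, and the pooled pf lands on the
simulated per-subunit probability 0.7.

## Analysis workflow

The `analysis/` directory holds the narrative pipeline, each script a thin
driver over the package:

| script | what it does |
|---|---|
| `01_simulate_data.R` | writes the example dataset (N&B TIFF stacks, an sFCS kymograph, calibration trace CSVs) under `results/example_data/` |
| `02_nandb_brightness.R` | per-cell N&B brightness + bleached fraction → `results/nandb_cells.csv` |
| `03_point_calibration.R` | detection-volume calibration → `results/calibration.json` |
| `04_sfcs_membrane.R` | full sFCS analysis of the kymograph → `results/sfcs_summary.csv` |
| `05_fluorescence_probability.R` | per-day referencing and pf pooling → `results/pf_estimates.csv` |

Run them in order from the repository root: `Rscript analysis/01_simulate_data.R`, etc.

## Documentation

The methods vignette (`vignettes/ffs-methods.Rmd`) describes the models,
the estimator choices, the simulator's assumptions and its known
limitations, and every tunable constant with its default and rationale.
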