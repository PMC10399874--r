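---
title: "Models and methods: Number & Brightness, scanning FCS, and the fluorescence probability"
author: "fluctr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fluctr)
```

# Scope

`fluctr` analyses photon-count fluctuation data from confocal microscopes:
image time-stacks (Number & Brightness), membrane line-scan kymographs
(scanning FCS), and point-detection traces (point FCS for detection-volume
calibration), and combines monomer and tandem-dimer brightness into the
apparent fluorescence probability *pf* of a fluorescent protein. Because
live-cell measurements cannot be regenerated, the package ships a
Brownian-dynamics photon-count simulator whose closed-form ground truth
(`expected_stats()`) anchors every test: each analysis stage is validated
by recovering known inputs, not by comparison with archived outputs.

# Number & Brightness

## Estimators

For photon-counting detection, each pixel's temporal mean $\bar k$ and
unbiased variance $\sigma^2$ over the stack give the molecular brightness
and particle number:

$$\varepsilon = \frac{\sigma^2 - \bar k}{\bar k}, \qquad
  n = \frac{\bar k^2}{\sigma^2 - \bar k}.$$

Subtracting $\bar k$ from the variance removes the shot-noise (Poisson)
contribution, so an immobile or background-only pixel has
$\varepsilon = 0$. Pixels with $\sigma^2 \le \bar k$ carry no number
fluctuation above shot noise: they receive the boundary value
$\varepsilon = 0$, are flagged invalid (`valid_mask`), and are excluded
from ROI averages; `n` is never reported there, and no `NaN`/`Inf` is ever
emitted. The unbiased $(n-1)$ variance matters because the boxcar windows
are only 8 frames long.

Brightness is reported in counts/s/molecule ($\varepsilon$ divided by the
pixel dwell time) so values are comparable across dwell settings; the
per-dwell value is retained alongside.

## Saturation masking

Photon-counting detectors go nonlinear near 1 MHz. A pixel is excluded if
*any* frame exceeds `max_rate` (default $10^6$ counts/s, i.e. 50 counts in
a 50 µs dwell). The per-frame maximum is used rather than the mean because
even a single saturated frame corrupts the variance; the mask is monotone
in the threshold.

## Boxcar correction and extrapolation

Photobleaching and slow cell movement inflate the temporal variance and
bias $\varepsilon$ upward. The stack is split into consecutive
non-overlapping windows of 8 frames (remainder dropped); the brightness is
computed per window; and an ordinary least-squares line through the window
values versus their mid-times is extrapolated to the temporal midpoint of
the first frame. A stationary stack gives a flat line, so the correction
is a no-op there.

Within a window the default pooling is *moment pooling* over the ROI:
$\varepsilon_w = (\langle \sigma^2 \rangle_{px} - \langle \bar k
\rangle_{px}) / \langle \bar k \rangle_{px}$. Averaging per-pixel ratios
instead would be dominated by the heavy noise of 8-frame variances (and by
the truncation of the invalid-pixel tail); moment pooling is unbiased for
a homogeneous ROI at any window length. A per-pixel mode
(`pool = "pixel"`) exists for spatial maps.

With occupancy bleaching producing a ~30% signal loss over 100 frames, the
uncorrected whole-stack estimate is biased upward by the intensity trend
(a few percent at these settings), while the extrapolated value recovers
the true brightness within noise; both numbers are reported per cell so
the correction is auditable.

## Bleached fraction

$1 - \text{mean(last 5\% of frame totals)} / \text{mean(first 5\%)}$.
Endpoint averages (rather than single frames) make the readout robust to
shot noise; both segment means are returned. Slightly negative values are
possible under noise and are flagged, not clipped.

# The correlation models

Scanning FCS perpendicular to a membrane sees a two-dimensional diffusion
process through an elliptical Gaussian detection area (waist $w_0$
laterally, $S w_0$ along the optical axis):

$$G(\tau) = \frac{1}{N}\left(1+\frac{\tau}{\tau_d}\right)^{-1/2}
  \left(1+\frac{\tau}{\tau_d S^2}\right)^{-1/2} + G_\infty,$$

with $\tau_d = w_0^2 / 4D$. Point FCS uses the 3D model with the standard
multiplicative triplet term:

$$G(\tau) = \left(1 + \frac{T}{1-T}e^{-\tau/\tau_T}\right)\frac{1}{N}
  \left(1+\frac{\tau}{\tau_d}\right)^{-1}
  \left(1+\frac{\tau}{\tau_d S^2}\right)^{-1/2} + G_\infty.$$

$T = 0$ reduces exactly to the pure 3D model; $S \to \infty$ drops the
axial factor.

## Fitting

`fit_acf()` is Levenberg–Marquardt least squares (`minpack.lm::nls.lm`)
with box bounds, optional per-lag SD weights, and fixed parameters.
Defaults:

| parameter | bounds | rationale |
|---|---|---|
| $N$ | $(10^{-3}, 10^6)$ | numerical stability |
| $\tau_d$ | $(1\,\mu s, 10\,s)$ | sampling-limited range |
| $S$ | $(0.5, 100)$ | weakly identified; keep finite |
| $T$ | $[0, 0.5]$ | dark fractions above 0.5 indicate model misuse |
| $\tau_T$ | $(0.1\,\mu s, 20\,\mu s)$ | photophysically plausible triplet range |

The $\tau_T$ ceiling deserves emphasis: without it the triplet factor can
exchange with the diffusion terms and act as a spurious second diffusing
component — on synthetic curves this corrupted $\tau_d$ by up to a factor
of two. Slow dark-state kinetics can still be fitted by widening the bound
explicitly (`upper = c(tau_T = ...)`).

Starting values come from `initial_guess()`: $N_0$ is the reciprocal of
the early-lag plateau, and $\tau_{d,0}$ the half-decay lag divided by 3
(2D) or 1 (3D), reflecting where each model family reaches half amplitude.
Weighting is unweighted by default and switches to per-lag SD weights when
the curve carries them (as segment-averaged sFCS curves and
multi-acquisition calibration curves do). Fits report standard errors from
the scaled Jacobian, the reduced $\chi^2$, the fixed set, and a
convergence flag; non-convergence is flagged, never silently defaulted.

# Scanning FCS pipeline

1. **Localization** (`detect_membrane`): lines are averaged in blocks of
   1000; each block profile is fitted with Gaussian + constant. A block is
   accepted only if the fitted amplitude exceeds 5 residual SDs *and* the
   peak explains at least 20% of the profile variance — a flat
   (background-only) kymograph therefore fails cleanly rather than
   latching onto a noise spike.
2. **Alignment** (`align_lines`): per-line centres are interpolated
   linearly between blocks; each line is shifted by the negated integer
   offset (circular shift, so line totals are conserved exactly); the
   fractional remainder is recorded, not resampled — resampling would
   break the Poisson statistics the estimators assume.
3. **Trace extraction** (`membrane_trace`): counts are summed within
   $\pm 2.5\sigma$ of the centre; the background level, estimated from
   pixels beyond twice the window half-width, is subtracted; negative bins
   are clamped to zero and counted.
4. **Correlation** (`compute_acf`): a multi-tau estimator — the first $2m$
   lags ($m = 16$) at the native line time, then $m$ lags per octave on a
   trace pairwise-binned by 2 — of the plain normalized estimator
   $G(\tau) = \langle F(t)F(t+\tau)\rangle / \langle F\rangle^2 - 1$. The
   reported $G$ is always the full-trace estimator (it matches a direct
   $O(n^2)$ oracle to $10^{-12}$ at unbinned lags); segmenting the trace
   (default 8) supplies per-lag SEs and flags segments whose mean
   intensity is a >3 SD outlier.
5. **Fit and brightness**: the 2D model with $S$ fixed to the daily
   calibration (free on request), lags restricted to a tenth of the trace
   duration; then $B = \langle I \rangle / N$ in counts/s/molecule, and
   the trace's bleached fraction.

Every stage's diagnostics are retained in the returned record, and errors
propagate with the failing stage named.

## What single curves can and cannot pin down

On simulated 2×10^5-line kymographs at the default conditions, a single
measurement determines $N$ and $B$ to a few percent, but $\tau_d$ from one
curve scatters by 10–25% — ACF noise is strongly correlated across lags,
and the amplitude–decay trade-off amplifies it. This matches general FCS
experience and is why the recovery contract is formulated on ensemble
medians (20 kymographs: median errors measured at roughly 3%, 9% and 3%
for $N$, $\tau_d$, $B$), while single-measurement tests assert
correspondingly wider bounds.

# Point-FCS calibration

Dye acquisitions are correlated individually; within each measurement the
curves are averaged (per-lag SE from the spread across acquisitions) and
the average is fitted with the 3D + triplet model, $S$ free. Pooled
estimates are means ± SD across measurements. Supplying the dye's
diffusion coefficient derives $w_0 = \sqrt{4 D \tau_d}$ and
$V_{\text{eff}} = \pi^{3/2} w_0^3 S$; the coefficient is a required user
input, never a hard-coded constant, because it is temperature- and
dye-specific. `fixed_s_for_day()` hands the pooled $S$ to the sFCS fits,
flagging values outside a configurable plausibility band (default 3–15).

When the first lag of the curve is longer than the admissible triplet
range (e.g. 40 µs bins against microsecond dark states), $T$ is
structurally unidentifiable; `calibrate()` then fixes $T = 0$, says so,
and records `triplet_resolved = FALSE`. Free-$T$ behaviour is exercised on
finely sampled traces where the term is actually constrained.

# Fluorescence probability

Per day, condition and method, the monomer cells give a reference
brightness (arithmetic mean; a warning is raised below 3 cells, and mixing
days in one reference is an error — day referencing is structural, not a
convention). Each tandem-dimer cell then yields

$$pf = \frac{B_{\text{dimer}}}{B_{\text{monomer}}} - 1,$$

and the per-cell values are pooled across sessions (mean, SEM =
SD/$\sqrt n$). Values outside $[0, 1]$ — possible under noise — are kept,
flagged and included in the mean; excluding them would bias the estimator.
For subunits that fluoresce independently with probability $p$, the
brightness-weighted average gives
$B_{\text{dimer}} = (1+p) B_{\text{monomer}}$, so pf estimates $p$
directly; the simulator's binomial labelling makes this an exact oracle
for the full pipeline.

`summarize_group()` reports the descriptive set used beneath group plots:
mean, median, SEM, and IQR with linear-interpolation (type 7) quantiles.
Hypothesis testing (ANOVA and post-hoc comparisons) is out of scope —
standard tools do it off the shelf.

# The simulator

## Raster path (N&B stacks)

At the default geometry (128×128 px, 50 µs dwell) a frame takes ~0.82 s,
far longer than cytosolic diffusion times, so successive frames are
statistically independent. The generator exploits this with an exact
compound-Poisson fast path: per pixel and frame, occupancy
$m \sim \text{Poisson}(N \cdot e^{-k_b t})$; the occupants jointly carry
$Q \sim \text{Binomial}(m \cdot s, p)$ fluorescent subunits; counts are
$\text{Poisson}(Q \lambda + b)$ with $\lambda$ the per-fluorophore counts
per dwell and $b$ the background. Bleaching reduces occupancy (irreversible
loss of emitters), not per-emitter brightness. The apparent brightness of
this process is $\lambda \, \mathbb E[q^2] / \mathbb E[q] =
\lambda (1 + (s-1)p)$ — the closed form the N&B tests check against, and
the reason pf recovers $p$.

## Trajectory paths (sFCS and point FCS)

Membrane and point traces come from Brownian dynamics in periodic boxes
(Rcpp integrators driven by R's RNG stream, so every trace is
bit-reproducible under `set.seed`): per step of length `dt`, Gaussian
increments of SD $\sqrt{2D\,dt}$; emission weights
$\exp(-2x^2/w_0^2 - 2y^2/(Sw_0)^2)$ (membrane) or the 3D analogue; Poisson
counts around the summed weights. The membrane detection area is
anisotropic with the config's structure parameter — that makes the
generator's autocorrelation *exactly* the two-factor 2D model the pipeline
fits ($S = 1$ recovers the isotropic special case). Optional per-step
bleaching converts fluorophores dark with probability proportional to the
local excitation; optional telegraph blinking (bright↔dark rates)
emulates triplet-like kinetics.

Kymographs distribute each line's membrane counts multinomially across
pixels with a Gaussian profile (centre + drift), conserving line totals
exactly, plus independent Poisson background. This preserves both the
temporal statistics and the spatial profile the sFCS pipeline needs at
desk-scale cost; the full 3D scan geometry is deliberately not simulated.

## Numerical limits of the box

The default box side is 20 detection lengths per axis ($20 w_0$ laterally;
$20 S w_0$ axially). Periodic boundaries truncate the diffusion spectrum
at the box's slowest lateral mode, $L^2/(4\pi^2 D)$; for the 3D model's
axial tail (around $S^2 \tau_d$) to be represented faithfully this mode
must be slower than the tail, which requires the lateral box to exceed
$\sim 2\pi S w_0$. `simulate_point_trace()` warns when it does not. The
synthetic calibrations therefore use $S = 3$ with the default box — at the
instrument-typical $S \approx 5$–9 the box factor would have to grow
beyond 30, which is not worth the cubic particle-count cost at desk scale.

## What the simulator does not emulate

No vectorial PSF or pinhole diffraction, no detector afterpulsing or dead
time, no chromophore maturation kinetics or pH-dependent protonation, no
microsecond-resolved hardware correlation (traces are binned at the line
or sampling time). Passing tests therefore demonstrate the estimators'
correctness on data satisfying their statistical assumptions — not
robustness to every instrument artefact of real hardware.

# Problem sizes and study conditions

Chosen once, as the package's own desk-scale study design:

* N&B: 100 frames of 128×128 px, 50 µs dwell, 400 nm pixels; occupancy 5;
  10 kHz per-molecule peak brightness ($\lambda = 0.5$ counts/dwell);
  bleaching scenarios target ~30% total loss.
* pf recovery: 20 monomer + 20 dimer cells per probability
  ($p \in \{0.5, 0.7, 0.9\}$), split over two sessions.
* sFCS: 256-px lines at 472.73 µs, 2×10^5 lines per kymograph (scaled
  down from a ~3-minute, 4×10^5-line acquisition), $D = 1\,\mu m^2/s$,
  $w_0 = 0.2\,\mu m$ ($\tau_d = 10$ ms), 20 kymographs for ensemble
  statistics.
* Calibration: a dye-like species with $D = 50\,\mu m^2/s$,
  $w_0 = 0.25\,\mu m$ ($\tau_d = 312.5\,\mu s$, slower than a real
  small-molecule dye so that 40 µs software binning resolves the decay),
  $S = 3$, acquisitions of 4 s grouped into measurements.

# Known limitations

* The boxcar correction assumes the brightness trend is linear in time
  over the acquisition; strong non-exponential bleaching would need
  shorter windows or nonlinear extrapolation.
* Alignment uses integer-pixel shifts; sub-pixel drift within a block is
  recorded but not corrected.
* $S$ from a single calibration measurement is weakly identified (the
  axial factor is nearly flat where the data are precise); pooling across
  measurements and acquisitions is essential, and the band check in
  `fixed_s_for_day()` is the guard against silent outliers.
* The multi-tau estimator uses plain normalization with the global trace
  mean; traces with strong slow trends should be detrended upstream (the
  sFCS path deliberately does not detrend by default, matching low-power
  acquisition practice).
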