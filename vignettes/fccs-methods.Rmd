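---
title: "Dual-color FCCS: models, estimators and design choices"
author: "fccs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-color FCCS: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and the statistic

Dual-color fluorescence cross-correlation spectroscopy (FCCS) asks whether
two differently labelled proteins — say a GFP-tagged transcription factor
and an mCherry-tagged binding partner — diffuse through a femtoliter-scale
confocal detection volume *together*. Each channel's intensity trace
$I_i(t)$ fluctuates as labelled molecules enter and leave the volume. The
normalized correlation functions

$$G_x(\tau) = 1 + \frac{\langle \delta I_i(t)\,\delta I_j(t+\tau)\rangle}
                       {\langle I_i\rangle \langle I_j\rangle}$$

summarise those fluctuations: the two auto-correlations $G_g, G_r$
($i = j$) and the cross-correlation $G_c$ ($i = r$, $j = g$). Only
molecules carrying **both** labels contribute correlated fluctuations to
both channels, so a positive cross-amplitude $G_c(0) - 1$ is direct
evidence of complex formation in the living cell.

Each curve is fitted with the free-diffusion model for a 3D-Gaussian
detection volume (radial waist $w_0$, axial half-length $z_0$, structure
parameter $s = z_0/w_0$),

$$G(\tau) = 1 + \frac{1}{N}\sum_i F_i
  \left(1+\frac{\tau}{\tau_i}\right)^{-1}
  \left(1+\frac{\tau}{s^2\tau_i}\right)^{-1/2}
  \left(1 + \frac{T}{1-T}e^{-\tau/\tau_T}\right),$$

with mean particle number $N$ in the effective volume
$V_\mathrm{eff} = \pi^{3/2} w_0^2 z_0$, up to three diffusing components
(fractions $F_i$, diffusion times $\tau_i = w_0^2/4D_i$), and an optional
multiplicative triplet-blinking factor. The amplitude law
$G(0) - 1 = (1/N)(1 + T/(1-T))$ makes $1/N$ the triplet-stripped
diffusion amplitude.

The interaction statistic is the **relative cross-correlation amplitude**

$$\mathrm{RCA} = \frac{G_c(0) - 1}{G_r(0) - 1},$$

which under the ideal identities $G_c(0)-1 = N_c/(N_g N_r)$ and
$G_x(0)-1 = 1/N_x$ equals the bound fraction $N_c/N_g$: the fraction of
green-labelled molecules travelling in complexes. Normalizing by the
green amplitude instead yields $N_c/N_r$; both are reported.
Per-condition RCA values are compared with a two-sample Student's
t-test (equal variances; a Welch option exists) with the conventional
star annotation (\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.005, 0.001).

## What the simulator emulates

Raw FCCS recordings from a commercial instrument are rarely deposited, so
the package carries a first-class generator that replaces the microscope:
point emitters performing Brownian dynamics in a periodic box, observed
through two co-aligned 3D-Gaussian detection volumes with Poisson photon
statistics. Per time step $\Delta t$ every coordinate receives an
independent $\mathcal N(0, 2D\Delta t)$ increment; the expected detection
rate of a particle at $(x, y, z)$ relative to the volume centre is
$B \exp(-2(x^2+y^2)/w_0^2 - 2z^2/z_0^2)$ with molecular brightness $B$
(counts/s). Rates are accumulated over each bin, mixed by the spectral
crosstalk fractions (conserving total rate), augmented by uncorrelated
background, and Poisson-sampled into integer counts. Species can be
green-only, red-only, or dual-labelled; dual species are what produce a
genuine cross-correlation. Triplet blinking is a symmetric two-state
telegraph process parameterised by the stationary dark fraction and the
dark residence time.

Features of real data the generator deliberately does **not** model:
photobleaching, FRET between the labels, detector afterpulsing and
dead-time, incomplete fluorophore maturation, channel-dependent volume
mismatch (available as an option only through differing optics), and cell
heterogeneity. Passing recovery tests therefore demonstrates the
correctness of the estimators and fits under the stated photophysics —
not robustness to every artifact of live-cell data; the crosstalk test
shows one such artifact (spectral bleed-through inflating RCA) is
reproduced rather than corrected.

Numerical choices in the generator:

* **Boundaries** are periodic; with box edges at least twice (and in all
  shipped configurations four or more times) the axial half-length,
  periodic images of the detection profile are below $e^{-8}$.
* **Rates are evaluated at the post-step positions**, one evaluation per
  step. Evaluating at step midpoints would double the random-number cost
  for a sub-bin-resolution effect; stationary statistics are identical.
* **Particle numbers are Poisson-drawn per realization** (open-volume
  statistics), which makes the amplitude law $G(0)-1 = 1/N$ exact in
  expectation; a fixed-count mode exists for variance-reduction in tests.
* The default acquisition is 10 s of 10 µs bins — a typical live-cell
  FCCS setting; both are configurable, and several shipped experiments
  use coarser bins matched to the species' diffusion time
  (about 12 bins per $\tau_D$), which resolves the decay while keeping
  desk-scale run times.

### Finite-box physics

A periodic box only supports concentration modes with wavevectors
$k \ge 2\pi/L$. The missing long-wavelength modes make the simulated
correlation tail decay slightly faster than the infinite-medium model
once the diffusion length $\sqrt{4D\tau}$ approaches $\sim L/5$; with
$L = 5\,\mu m$ and $w_0 = 0.25\,\mu m$ this appears beyond roughly
12 diffusion times, while $L = 10\,\mu m$ is clean past 15. The shipped
experiment designs respect this: amplitude and RCA studies use
$L = 5\,\mu m$ (the RCA is a ratio of amplitudes, and the small common
tail bias cancels), whereas diffusion-time recovery and
structure-parameter calibration restrict the fitted lag window to about
10 diffusion times (multi-tau `n_stages = 4`) and use geometries for
which that window is unbiased.

## Estimators

`correlate_direct()` evaluates the definition at every integer lag, with
**symmetric normalization**: channel means are computed over the
overlapping window of each lag, which removes the dominant finite-trace
bias. `correlate_multitau()` evaluates the *same* estimator on the
standard multi-tau grid (16 linear lags per stage, lag spacing doubling
each stage). Because each grid point is computed exactly rather than on a
coarsened trace, multi-tau values agree with the direct estimator at
shared lags to machine precision; the grid, not an approximation, is what
makes it fast. Lag zero is reported but flagged: auto-correlations carry
shot noise there, so fits exclude the first auto-correlation point by
default.

Per-lag uncertainties come from **segment resampling**
(`segment_errors()`, default 10 contiguous segments): the reported curve
is the segment mean and the errors are standard errors of that mean.
These feed the weighted fit.

Averaging per-segment curves carries a normalization bias that scales
as one over the segment length (each segment subtracts its own mean,
depressing the curve by roughly $2\int (G-1)\,dt / T_\mathrm{seg}$ —
a constant offset that distorts the tail most in relative terms).
Where tail fidelity matters, `segment_errors(values = "full")` reports
the full-trace estimate (bias $\propto 1/T_\mathrm{total}$ instead)
and uses the segments only for the error bars; and `pool_curves()`
averages repeated measurements of the same system into one
better-conditioned curve, the way repeated dye runs are pooled before
a calibration fit.

## Fitting

`fit_curve()` minimises $\sum_\tau ((G_\mathrm{obs} -
G_\mathrm{model})/\sigma_\tau)^2$ with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`; `ftol = ptol = gtol = 10^{-10}`, numerical
Jacobian). Defaults and bounds: $N \in (10^{-3}, 10^6)$; $\tau_i$ between
a tenth of the bin width and ten times the largest lag; fractions in
$[0,1]$ with the last fraction implied; $T \in [0, 0.5)$. Components are
reported sorted by increasing $\tau_i$. Starting values invert the
amplitude law ($N_0 = 1/(G-1)$ at the first fitted lag) and use the
half-decay lag for $\tau_0$; a near-flat curve (no correlated signal —
the normal situation for the cross-correlation of a non-interacting
pair) falls back to a weak-signal start instead of failing, so negative
controls remain analysable. Model order is **not** selected
automatically; the caller states the component count.

The structure parameter is degenerate with the diffusion times in noisy
single-curve fits, so it is fixed during cell-curve fits and floated only
in `calibrate_structure_parameter()`, which emulates the classical
reference-dye calibration: a one-component fit with $s$ free to a dye
curve of known $D$, then $w_0 = \sqrt{4 D \tau_D}$. The fitted $s$
responds to the *shape* of the correlation tail with a roughly
threefold amplification of any relative tail error, which drives three
calibration-specific choices: dye curves are pooled over many repeated
runs (`pool_curves()`), curve values come from the full-trace
estimator (`values = "full"`), and the simulation box for dye studies
is elongated axially so the slow axial decay — the part of the curve
that carries the $s$ information — is not distorted by missing
long-wavelength axial modes. A nuisance baseline $G_\infty$
(`offset_free`) is available to absorb residual constant depression of
short single-run measurements, but it is weakly degenerate with the
axial decay and therefore off by default; the pooled workflow keeps
the baseline fixed at 1, preserving the model's $G \to 1$ limit.

Amplitudes entering the RCA are the fitted models extrapolated to
$\tau = 0$ with the triplet factor stripped ($1/N$), not raw first-lag
values — raw lag-0 points contain shot noise, and extrapolation through
the fitted shape is what analysis software attached to commercial
instruments effectively does.

## Design choices where the ground was open

* **RCA normalization** defaults to the red auto-correlation amplitude
  (yielding $N_c/N_g$); green and min-amplitude options are provided and
  the choice is recorded in every result object.
* **Student's equal-variance t-test** is the default comparison (a Welch
  flag exists); p-values are per-comparison, with no multiple-testing
  correction — a deliberate mirror of common practice in the field, and
  a documented limitation.
* **Per-curve fits with group summaries.** Curves are fitted one cell at
  a time with a shared model form; no parameters are shared across cells.
* **Triplet factor** uses the standard multiplicative form
  $1 + (T/(1-T))e^{-\tau/\tau_T}$.
* **Degenerate over-parameterisation is reported, not hidden**: a
  two-component fit of one-component data flags "components poorly
  separated" in `summary()` when one fraction exceeds 0.95 or the two
  diffusion times sit within a factor of two.

## Problem sizes of the shipped experiments

The package's validation experiments (tests and `scripts/acceptance.R`)
use: 10^4–2×10^5-bin traces; an N-recovery study at
$N_\mathrm{eff} \approx 2$ (1000 particles in a 6 µm box, 2 s, 25 µs
bins, 10 seeds); a 3×3 grid of $N_\mathrm{eff} \in \{1, 5, 20\}$ ×
$\tau_D \in \{10^{-4}, 10^{-3}, 10^{-2}\}$ s (durations 1.5–15 s with
~12 bins per $\tau_D$); RCA cohorts of 10 cells per dual-labelled share
in $\{0, 0.25, 0.5, 0.75, 1\}$ plus a 30 % bound-fraction cohort
(6 s traces, 100 green- and red-labelled molecules each); a
reference-dye calibration at $D = 400\ \mu m^2/s$ pooling 18 runs of
3 s in a $7.5 \times 7.5 \times 13$ µm box; and 1000 null replicates
for the t-test level check. These sizes were chosen so each study
resolves its target quantity well inside the stated tolerance while
remaining runnable on a laptop CPU in minutes. The structure parameter is the
most delicate of these quantities — its statistical error shrinks
only with the square root of the pooled dye data — but at the shipped
problem size the pooled estimate is reproducible to a few percent,
comfortably inside the ±10 % recovery band, and the beam waist to
1–2 % throughout.

## Known limitations

* No correction for spectral crosstalk, background, partial labelling or
  differential brightness: RCA values are relative, as in the live-cell
  practice the package mirrors, and crosstalk demonstrably inflates them.
* No anomalous-diffusion or flow terms in the model; no photon-arrival
  (time-tag) correlation — binned traces only.
* No absolute binding-constant estimation; the statistic is a bound
  fraction, not a $K_d$.
* The simulator's finite box and finite time step are approximations
  whose visible consequences (correlation-tail deficit) are measured and
  designed around, as described above.
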