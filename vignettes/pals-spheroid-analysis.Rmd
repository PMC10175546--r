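---
title: "Decomposing positronium lifetime spectra from melanoma spheroids"
author: "palspheroid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing positronium lifetime spectra from melanoma spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palspheroid)
```

## The measurement and the model

In positron annihilation lifetime spectroscopy (PALS) of biological samples,
a ²²Na source emits a positron together with a prompt 1274 keV photon; the
positron thermalizes in the tissue and annihilates, emitting 511 keV photons.
The time between the prompt photon and an annihilation photon is histogrammed
over about a million coincidences. In soft matter the positron either
annihilates directly ("free" annihilation) or forms positronium: the singlet
state (para-positronium, p-Ps, 125 ps) in a quarter of formation events and
the triplet state (ortho-positronium, o-Ps) in three quarters. The o-Ps
lifetime is cut down from its 142 ns vacuum value to the nanosecond scale by
pick-off annihilation on surrounding molecular electrons — about 1.8 ns in
water — so it reports on the size and abundance of intermolecular voids. In
three-dimensional melanoma spheroids this lifetime discriminates cell lines
of different malignancy: the more proliferative, more densely packed line
shows a shorter o-Ps lifetime.

Each decay channel contributes a one-sided exponential with mean lifetime
$\tau_i$ and intensity $I_i$, convolved with the Gaussian timing response of
the spectrometer (standard deviation $\sigma$, parameterized by its FWHM).
The per-channel density is the exponentially modified Gaussian

$$f(t \mid \tau, t_0, \sigma) = \frac{1}{2\tau}
  \exp\!\Big(\frac{\sigma^2}{2\tau^2} - \frac{t - t_0}{\tau}\Big)\,
  \mathrm{erfc}\!\Big(\frac{\sigma/\tau - (t - t_0)/\sigma}{\sqrt2}\Big),$$

and the spectrum model is the intensity-weighted sum of four such channels
(p-Ps, annihilation in the Kapton-wrapped source, free annihilation, o-Ps)
plus a flat background of accidental coincidences over the acquisition
window. Expected bin contents are computed from CDF differences, not
midpoint densities, so fits are independent of the bin width. The erfc
factor is evaluated in log space through the Gaussian tail log-probability;
the two large exponents cancel analytically, which keeps the density finite
for $\sigma/\tau$ well beyond the p-Ps regime ($\sigma \approx \tau$).

## Defaults and what they mean

* **Component lifetimes** 0.125 ns (p-Ps), 0.374 ns (source), 0.395 ns
  (free), with the o-Ps lifetime and intensity taken per condition from the
  published spheroid decomposition (`spheroid_conditions`).
* **Resolution** — the spectrometer's timing FWHM is not published; the
  package defaults to a single Gaussian of FWHM 0.25 ns, typical of
  fast BaF₂ scintillator spectrometers, and accepts any single- or
  multi-Gaussian response.
* **Window and binning** — $(-2, 25)$ ns in 0.025 ns bins: the window covers
  more than five o-Ps lifetimes past the prompt peak at the water-like
  1.8 ns scale, and the pre-peak region pins the background level.
* **Unpublished intensities** — only the o-Ps intensity is published per
  condition. The simulator fixes $I_{pPs} = I_{oPs}/3$ (the 1:3
  singlet:triplet formation ratio), a 10% source contribution typical of
  foil-wrapped sources, a 0.5% accidental background, and gives the
  remainder to free annihilation. These are generator conventions, all
  configurable; only the o-Ps truth is anchored to measurement.

## Fitting and the constraint policy

The fit minimizes the Poisson deviance (Cash statistic)
$C = 2\sum_b [\mu_b - k_b + k_b \ln(k_b/\mu_b)]$ — appropriate for the
low-count tail bins at long times, where Gaussian weighting is biased — with
the simplex constraint $\sum_i I_i + b = 1$ enforced by a stick-breaking
parameterization. Pearson's $\chi^2$ is reported alongside for familiarity.
Uncertainties come from the inverse Hessian at the optimum, propagated to
the natural parameters by the delta method; `profile_uncertainty()` offers
the deviance-rise-by-one profile interval as a robust cross-check, and the
two agree to a few percent in the quadratic (large-count) regime.

By default the three short-lived lifetimes are *fixed* at their calibration
values and the source intensity is fixed from a source-only calibration run
(mirrored by `make_calibration_model()`); the free parameters are the o-Ps
lifetime, the p-Ps/free/o-Ps/background intensity split, and time zero. The
0.374 ns source and 0.395 ns free lifetimes are near-degenerate: freeing
either couples the short-component complex to the o-Ps channel (correlation
about 0.6) and roughly doubles the o-Ps lifetime uncertainty, from about
0.009 ns to 0.011 ns per million-event spectrum against a published
statistical precision of 0.005–0.006 ns. Fixing short components from
calibration is the standard practice in PALS decomposition, and it is what
makes the two-condition separation reproducible at the measured event
budget; users who wish to propagate short-component uncertainty can free any
lifetime through `fit_constraints()`. Whether the original analysis fixed
lifetimes, fitted time zero, or source-corrected its intensities is not
published; this policy is the package's own explicit choice, not an
inference about the original software. Reported intensities are fractions
of all events in the fit window, not source-corrected.

Initialization: time zero starts at the peak bin, the background at the mean
rate of the bins more than $4\sigma$ before the peak, the o-Ps lifetime at
the 1.8 ns water anchor. The optimizer is a bounded quasi-Newton run with a
$10^{-10}$ relative tolerance; on a reported non-convergence the fit is
restarted from three deterministically jittered starts and the lowest
deviance wins, with the convergence flag returned rather than an error.

## What the simulator does and does not emulate

`sample_events()` draws each event's channel from the categorical law over
intensities, adds exponential decay and Gaussian resolution jitter (or a
uniform draw over the window for background events), and keeps events that
fall outside the window until binning clips them, so that configured
intensities remain true formation fractions. This reproduces the statistical
structure of a coincidence spectrum — Poisson bin counts, resolution
broadening, flat accidentals — but not detector physics: no energy spectra,
Compton scatter, pile-up, source-geometry effects, or drift of the time
axis. Passing recovery tests on these simulations validates the estimator
under the stated model, not the spectrometer calibration of a real
instrument.

A typical check (two seconds per million-event fit on one core): simulate a
published condition, fit, compare.

```{r, eval = FALSE}
truth <- make_condition_truth("WM266-4", 4)
h <- simulate_spectrum(truth, seed = 1)
fit <- fit_spectrum(h)
fit
summarize_fit(fit)
```

Across 20 replicate million-event spectra of that condition the fitted o-Ps
lifetime scatters with a standard deviation in the 0.007–0.010 ns range (the
published statistical precision is 0.005 ns; the real instrument's
resolution and background are unknown, so order-of-magnitude agreement is
the meaningful statement), the ±1σ intervals cover the truth at close to the
nominal 68%, and the day-4 WM115 vs WM266-4 contrast separates by a median
of about 2.5 combined standard deviations — the package's operational
reading of the published two-standard-deviation discrimination claim. Under
equal truths the same pipeline's z statistic follows the half-normal law,
which is the end-to-end test that the fitted uncertainties are calibrated.
These are the problem sizes used throughout the test-suite and in
`scripts/acceptance.R` (20 replicates, $10^6$ events).

## Growth and radial image analysis

Spheroid growth is summarized by the doubling time
$DT = t \ln 2 / \ln(V_2/V_1)$ between two volumes (or cell counts) separated
by $t$ days, with `sphere_volume()` converting microscopy diameters. A
shrinking spheroid returns a negative DT with a warning rather than an
error, since the formula is well defined and regression phases are real.
No growth-curve model (Gompertz, logistic) is fitted.

The radial module emulates confocal images of dye-loaded spheroids: a
Gaussian ridge of intensity at the proliferation rim plus a Gaussian core
term inside the spheroid disk, with clipped Gaussian noise.
`radial_profile()` averages pixel intensities in half-open annuli around the
intensity-weighted centroid of the Otsu-thresholded image (the published
analysis used ImageJ without stating a center definition; a manual center
override is provided). Region statistics default to the necrotic core at
[50, 100) µm and the proliferation rim at [100, 200) µm from the center —
half-open so every pixel belongs to exactly one region, and configurable
because real layer extents scale with spheroid size. Group contrasts use a
Welch two-sample t-test on per-spheroid region means; the original report
gives p-values without naming a test, so Welch is this package's documented
choice. The synthetic images carry no optical blur, depth attenuation, or
cell-scale texture: tests against them validate the profiling arithmetic,
not segmentation of real confocal data, and the published per-figure
p-values are not reproducible because the underlying pixel data are not
available.

## Known limitations

* The o-Ps lifetime/intensity anticorrelation (about −0.8) is intrinsic to
  tail fitting; quoted intensities and lifetimes should not be interpreted
  independently at the percent level.
* Short-component intensities besides o-Ps are conventions, so absolute
  recovered values of $I_{pPs}$ and $I_{free}$ test self-consistency only.
* The resolution FWHM default (0.25 ns) is an assumption; all uncertainty
  comparisons against published precisions are order-of-magnitude
  statements.
* Lifetime *distribution* analysis (inverse-Laplace / MELT-style) is out of
  scope; the model is a finite mixture of discrete components.
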