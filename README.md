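# palspheroid

Positron annihilation lifetime spectroscopy (PALS) analysis for
three-dimensional tumor spheroids.

When a ²²Na source irradiates a biological sample, each emitted positron is
tagged by a prompt 1274 keV photon, and the delay to its annihilation
(511 keV) photon is histogrammed over ~10⁶ coincidences. Part of the
positrons form positronium; the triplet state, ortho-positronium (o-Ps), is
quenched by pick-off annihilation on surrounding molecular electrons, so its
mean lifetime (about 1.8 ns in water) reports on the size of intermolecular
voids. In melanoma spheroids this lifetime separates cell lines of different
malignancy — more proliferative, denser spheroids show shorter o-Ps
lifetimes — making positronium a candidate tissue-pathology biomarker for
PET. This package is for physicists and biologists who want to simulate,
decompose and compare such spheroid lifetime spectra, with a known ground
truth standing in for measurements.

## The model

A spectrum is a four-channel mixture. Channel *i* (p-Ps, Kapton source,
free annihilation, o-Ps) contributes a one-sided exponential with mean
lifetime τᵢ and intensity Iᵢ convolved with the Gaussian timing resolution
(FWHM-parameterized), i.e. an exponentially modified Gaussian

f(t | τ, t₀, σ) = (1/2τ) exp(σ²/2τ² − (t−t₀)/τ) erfc((σ/τ − (t−t₀)/σ)/√2),

plus a flat accidental background over the acquisition window, with
Σᵢ Iᵢ + b = 1. Decomposition is by constrained Poisson maximum likelihood:
the Cash deviance C = 2 Σ_b [μ_b − k_b + k_b ln(k_b/μ_b)] is minimized with
the intensity simplex enforced by stick-breaking; per-bin expectations are
exact CDF differences, so fits do not depend on the bin width. One-sigma
uncertainties come from the inverse Hessian (delta method), with
profile-likelihood intervals (`profile_uncertainty()`) as a cross-check.
Conditions are compared in combined standard deviations,
z = |τ_a − τ_b| / √(σ_a² + σ_b²). Growth arithmetic (doubling time
DT = t·ln2 / ln(V₂/V₁)) and radial fluorescence profiling of synthetic
spheroid images (necrotic core [50, 100) µm, proliferation rim
[100, 200) µm) round out the pipeline.

## Worked example

Simulate one million coincidence events from the published WM266-4 day-4
decomposition (o-Ps: 1.876 ns, 16.5%), fit it back, and compare against the
published WM115 day-4 values:

```r
library(palspheroid)
truth <- make_condition_truth("WM266-4", 4)
h <- simulate_spectrum(truth, seed = 1)
fit <- fit_spectrum(h)
fit
#> <pals_fit> converged, Cash = 1057.5, Pearson chi2/ndf = 0.949 (ndf = 1075)
#>   p-Ps     tau = 0.1250 (0.0000) ns   I = 0.0533 (0.0021)
#>   source   tau = 0.3740 (0.0000) ns   I = 0.1000 (0.0000)
#>   free     tau = 0.3950 (0.0000) ns   I = 0.6766 (0.0026)
#>   o-Ps     tau = 1.8771 (0.0087) ns   I = 0.1652 (0.0009)
#>   background = 0.0048 (0.0001), t0 = -0.0002 (0.0004) ns

s <- summarize_fit(fit)
wm115 <- condition_summary("WM115:day4", 1.909, 0.006, 0.180, 0.008)
lifetime_z(s, wm115)
#> [1] 3.026515
```

The fitted o-Ps lifetime (1.8771 ± 0.0087 ns) recovers the generating truth
(1.876 ns) well within one sigma; lifetimes with a (0.0000) uncertainty are
held at their calibration values (see `fit_constraints()`). The reduced
Pearson χ² near 1 says the four-component model describes the simulated
spectrum. The z of 3.0 means the fitted condition sits three combined
standard deviations from the published WM115 day-4 lifetime — the same scale
on which the original study separates the two cell lines.

Growth arithmetic, e.g. a 1.7-fold cell-number increase over 8 days:

```r
doubling_time(1, 1.7, 8)
#> [1] 10.45021
```

A thin command-line wrapper over the same functions ships in
`inst/cli/pals.R` (verbs: `simulate`, `fit`, `recover`, `compare`,
`discriminate`, `growth`, `profile`); histograms travel as two-column ASCII
(`# key = value` header, then `bin_center_ns<TAB>count`), results as JSON,
run configs as YAML.

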