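---
title: "Methods: spectral induced polarization analysis of root systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral induced polarization analysis of root systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootsip)
```

## The measurement and its containers

A spectral electrical impedance survey drives current through an electrode
pair (A, B) and measures the complex voltage across another pair (M, N),
giving a transfer impedance Z(ω) = U(ω)/I(ω) per four-point configuration
and frequency. After tomographic inversion (out of scope here — we start
from its output), every cell of a 2D profile carries a complex resistivity
spectrum ρ̂(ω) = |ρ̂| e^{iφ}. The package's central container is the
`tomogram_stack`: a cell grid (x along the profile, z positive down, volume
V_j = in-plane cell area × 1 m out-of-plane thickness, as profile
inversions are per unit length) with one spectrum per cell on a shared
frequency grid.

Phase is stored in radians and written to file in mrad, the unit in which
such data are displayed and filtered; a capacitive (normal polarization)
response has negative resistivity phase and hence positive imaginary
conductivity σ″ = Im(1/ρ̂). The acquisition grid emulated throughout is 23
log-evenly spaced frequencies from 0.1 Hz to 10 kHz, with analysis capped
at 1 kHz where phase accuracy of field instruments degrades.

Two frequencies used by the root index, 3.125 Hz and 1 kHz, are not exact
members of that 23-point grid; `value_at()` therefore supports log-log
interpolation (linear in log f for log-magnitude and phase), the natural
choice for log-evenly sampled spectra, and refuses to extrapolate beyond
the grid span.

## Scheme generation and data quality

`enumerate_scheme()` builds, for an ordered injection list, all unordered
potential dipoles {M, N} disjoint from {A, B}, then applies two filters:
a cap on the absolute geometric factor (default 5 m; small |K| means high
signal-to-noise) and removal of configurations whose potential electrodes
carried current in the immediately preceding injection (electrode
polarization decays slowly). "Previous" means i−1 only, matching the decay
argument rather than a blanket exclusion. Dipoles are stored with M < N;
the sign of K carries orientation, so the |K| filter uses the absolute
value.

Measurement errors follow linear models: Δ|Z| = a|Z| + b and
Δφ = c|φ| + d. The relative phase term uses |φ| because an error is a
magnitude — the signed form would predict negative errors for the
(normal) negative phases. Defaults are a = 2 %, b = 0.01, c = 2 %,
d = 1 mrad; `phase_error_from_data()` alternatively sets d to half the
sample standard deviation of the phases at each frequency (sample, n−1,
because per-frequency ensembles are small). The raw-data filters run in a
fixed order: positive phases above +5 mrad are removed first, then a
single-pass 3σ rule per frequency (mean and sample SD over currently valid
entries; no iteration — re-running the rule on its own survivors is
deliberately not a fixed point we promise). Filters only ever shrink the
valid set.

## Debye decomposition

Each spectrum is decomposed into a superposition of Debye relaxations,

ρ̂(ω) = ρ₀ [ 1 − Σₖ mₖ (1 − 1/(1 + iωτₖ)) ],

with chargeabilities mₖ ≥ 0 on a fixed log-spaced relaxation-time grid
(20 nodes per decade, spanning one decade beyond
[1/(2π f_max), 1/(2π f_min)]). Because the model is linear in
(ρ₀, bₖ = ρ₀ mₖ), the fit is a single non-negative least-squares problem
on the stacked real and imaginary parts, weighted by the propagated
magnitude/phase errors when an error model is supplied. The NNLS solver is
an active-set method operating on the normal equations, which makes the
regularization path cheap: the Gram matrix is assembled once and each
smoothing weight only adds λ L'L (L = second differences on m, which
stabilizes the notoriously ill-posed m(τ) recovery). Smoothing acts on
m = b/ρ₀, so an outer loop (two passes) rescales the penalty block by the
current ρ₀ estimate; without smoothing the problem needs no outer loop at
all.

The smoothing weight is chosen by the discrepancy principle — the largest
λ whose error-weighted rms misfit stays ≤ 1, found by bisection on
log₁₀ λ — *only when an error model supplies weights*; an rms target of 1
is meaningless without error estimates, so error-model-free fits use the
fixed λ argument (default 0) and reproduce noise-free synthetic spectra to
machine precision. ρ₀ is initialized at the lowest-frequency magnitude
(the DC limit) and refined jointly; data are normalized by that magnitude
for conditioning.

Integral parameters: m_tot = Σ mₖ sums all grid nodes. The reported
τ_mean = exp(Σ mₖ ln τₖ / Σ mₖ) (natural logarithm; the result is
base-invariant) is computed over in-band nodes only, τ ∈
[1/(2π f_max), 1/(2π f_min)]. The out-of-band grid extension exists to
absorb processes the truncated band cannot resolve — in the ≤ 55 Hz
restricted fit, the in-band tail of the ≥ 100 Hz dispersion lands on the
shortest-τ absorber nodes — and including those nodes in the
chargeability-weighted geometric mean would bias the slow relaxation time
by factors of 2–5. `mean_relaxation_time(fit)` with no window remains the
plain all-node definition. The restricted variant `fit_debye_restricted()`
truncates the spectrum (default 55 Hz) before fitting and records the band
used.

## The electrical root index

Fine roots polarize strongly at high frequencies, but in loamy field soils
the soil's own polarization masks the absolute chargeability near maize
plants. The ERI normalizes the high-frequency (root + soil) response by
the low-frequency (soil-dominated) response as a log-log slope:

ERI = log(σ″_HF / σ″_LF) / log(f_HF / f_LF),  f_LF = 3.125 Hz, f_HF = 1 kHz.

As a ratio of ratios it is invariant to the logarithm base and to any
frequency-independent multiplicative field on σ″ — which is also why ERI
images retain contrast at depth, where four-point sensitivity (a roughly
frequency-independent gain) fades. Cells with σ″ ≤ 0 at either bound
(imaginary parts near zero at 3.125 Hz are the known failure mode) are
flagged invalid and dropped from zone means, with the zone volume
renormalized. A small-phase variant, ERI ≈ log(φ_HF/φ_LF)/log(f_HF/f_LF),
holds when |σ̂| is nearly equal at both bounds; the definition on σ″ is
the default and the phase form a flagged alternative.

## Zones, traits, length scales

`select_zone()` collects cells whose centers fall in a closed window
20 cm wide × 25 cm deep around each stem — the excavated soil-root volume
used for biomass validation — and `soil_reference_zone()` takes the
50–100 cm depth band as mostly root-free. Zone aggregation is volume
weighted: x̄ = Σ V_j x_j / Σ V_j. Root biomass density is
RBD = M_root / V_rz. Correlations use the sample Pearson coefficient with
the two-sided t-test (n − 2 df) via `stats::cor.test`.

Relaxation times map to polarizing-structure sizes through the Schwarz
relation τ = r²/(2D): d = 2√(2Dτ), with D = 10⁻⁹ m²/s as a typical ion
diffusion coefficient (a config scalar; no temperature correction).
Reported cell diameters truncate to integer micrometres — the only
rounding convention consistent with all three quoted seasonal values
(11.66 → 11, 20.0 → 20, 25.3 → 25 μm for τ = 17/50/80 ms).

## What the synthetic generator does and does not emulate

`build_scene()` composes per-cell Debye parameters — a soil background
plus species anomalies inside each plant's root zone — evaluates the
forward model, and adds independent Gaussian noise in (magnitude, phase)
with standard deviations from the error models. The soil preset produces a
monotone phase decrease to ≈ −10 mrad at 1 kHz with a few mrad at 1 Hz;
maize anomalies add a ≥ 100 Hz dispersion (added chargeability graded
0.010–0.035 across the eight preset plants, matching the observed maize
chargeability range) taking zone phases to −15…−30 mrad; sugar-beet
anomalies add a strong high-frequency term plus a low-frequency storage
term whose relaxation time grows 17 → 50 → 80 ms across the t1/t2/t3
presets, shifting the low-frequency phase peak from ≈ 9 to ≈ 2 Hz. Scene
"timesteps" are independent presets, not a growth model. The soil Debye
parameters themselves are synthetic: no quantitative soil decomposition
was available to copy, so they are tuned only to the qualitative phase
levels above.

Validation biomass is drawn as
mass = gain × m̄_HF,root × V_rz × exp(N(0, σ)) + intercept, where
m̄_HF,root is the zone-mean *root-attributable* high-frequency
chargeability (the anomaly term; the spatially constant soil background
carries no information about roots) and σ = 0.25 lognormal noise
represents excavation losses. With gain = 50 the preset biomasses span
25–90 g per plant (RBD 0.5–1.8 kg/m³), plausible for excavated maize
crowns.

What passing tests on these scenes show: that the chain — noisy spectra →
(restricted) decomposition → ERI → zone means → correlations — recovers
known ground truth at realistic noise levels. What they do not show:
robustness to inversion artifacts (spatially correlated errors, resolution
loss with depth), soil heterogeneity, electrode effects, or any claim
about real fields; those require the inversion stage and field data, both
out of scope.

## Numerical choices and edge cases

* NNLS tolerance scales with the Gram matrix norm; non-convergence raises
  an error rather than returning a silent partial fit.
* Discrepancy bisection runs 24 steps on log₁₀ λ ∈ [−8, 6]; if even λ = 0
  misfits above 1 the data are under-described by the error model and the
  unsmoothed fit is returned; if the maximally smoothed fit still meets
  the target, that end of the bracket is used.
* Spectra that are inductive (positive phase) throughout fit with m ≈ 0
  and a warning, not an error.
* Zone windows are closed intervals; a cell center exactly on the boundary
  is included.
* Magnitude noise in the generator is floored at 5 % of the true magnitude
  to keep spectra physical (|ρ̂| > 0); at the default 2 % noise level the
  floor is effectively never active.
* Problem sizes in the shipped tests: 3 900-cell scenes (0.05 m cells over
  9.75 m × 1 m), 23 frequencies, 200-seed noise ensembles for bias checks
  and 20-seed ensembles for the end-to-end correlation — small enough to
  run the whole suite in well under a minute, large enough that zone means
  average ~20 cells as in the emulated surveys.

## Known limitations

* The Debye fit's λ selection assumes the error model describes the data;
  for zone-averaged spectra the single-cell model overstates the noise and
  the discrepancy principle smooths heavily — the band-restricted τ_mean
  is robust to this, but per-node m(τ) shapes from averaged spectra should
  not be over-interpreted.
* No Cole-Cole or constant-phase-angle alternatives, no uncertainty
  quantification of m(τ), no 3D grids, no reciprocal-error models.
* The beet-diameter → storage-cell-diameter literature regression used for
  field validation is not reproduced (coefficients unpublished); the
  generator's biomass coupling is a configurable linear map instead.
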