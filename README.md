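# rootsip

Spectral induced polarization (SIP) analysis for in-situ root phenotyping.

Root systems are hard to characterize in the field because they are buried.
Multi-frequency electrical impedance imaging (spectral electrical impedance
tomography, sEIT) recovers the complex resistivity
ρ̂(ω) = |ρ̂| e^{iφ} of the subsurface per tomogram cell and per frequency;
roots polarize — they store charge — and leave a frequency-dependent
signature in the phase φ and in the imaginary conductivity
σ″ = Im(1/ρ̂). `rootsip` implements the trait-extraction chain that turns
such per-cell spectra into root traits, for agrogeophysicists and root
phenotypers who have (or simulate) inverted multi-frequency resistivity
profiles over crop rows.

The package covers:

* **Measurement schemes** — enumeration of four-point (A,B,M,N)
  configurations from an electrode line with half-space geometric factors
  K = 2π / (1/r_AM − 1/r_AN − 1/r_BM + 1/r_BN), a maximum-|K| cap and a
  previous-injection exclusion rule, plus three-point superposition
  Z = (U_M − U_N)/I.
* **Raw-data quality** — linear error models Δ|Z| = a|Z| + b and
  Δφ = c|φ| + d, a data-driven phase error (half the per-frequency phase
  standard deviation), a positive-phase cutoff (default +5 mrad) and a
  single-pass 3σ phase-outlier filter.
* **Debye decomposition** — non-negative fit of
  ρ̂(ω) = ρ₀ [1 − Σₖ mₖ (1 − 1/(1 + iωτₖ))] on a log-spaced relaxation-time
  grid, yielding the total chargeability m_tot = Σ mₖ and the mean
  relaxation time τ_mean = exp(Σ mₖ ln τₖ / Σ mₖ), with a
  low-frequency-restricted variant (≤ 55 Hz) that isolates slow polarization
  processes such as sugar-beet storage tissue.
* **Electrical root index (ERI)** — the log-log slope of σ″ between
  3.125 Hz and 1 kHz, ERI = log(σ″_HF/σ″_LF) / log(f_HF/f_LF), a dispersion
  measure that normalizes the root-plus-soil high-frequency polarization by
  the soil-dominated low-frequency polarization and is invariant to
  frequency-independent sensitivity fields.
* **Root-zone traits** — volume-weighted means over a 20 cm × 25 cm window
  around each stem, root biomass density RBD = M_root/V_rz, Pearson
  trait correlations, and the Schwarz relation τ = r²/(2D) translating
  relaxation times into polarizing-structure diameters d = 2√(2Dτ).
* **A synthetic field generator** — ground-truth scenes with soil, maize
  and sugar-beet polarization signatures, error-model noise and linked
  root-biomass validation tables, so the whole chain is testable without
  field data.

## Worked example

Simulate a mid-season profile (8 maize plants with graded root anomalies,
2 sugar beets with a 50 ms storage-tissue relaxation), write it to CSV, and
run the pipeline:

```r
library(rootsip)
scene <- build_scene(scene_preset("t2", seed = 42))
dir <- tempfile(); write_scene(scene, dir)
cfg <- run_config(spectra = file.path(dir, "spectra.csv"),
                  plants  = file.path(dir, "plants.csv"))
report <- run_pipeline(cfg)
report
#> <pipeline_report> 10 plants, 3900 cells (0 ERI-invalid), config 2a528639
#>   maize_eri_rbd: PC = 0.891 (p = 0.00294)
report$traits[, c("plant_id", "species", "mean_tau_s", "mean_eri", "rbd",
                  "cell_diameter_um")][c(1, 8, 9), ]
#>   plant_id    species mean_tau_s mean_eri   rbd cell_diameter_um
#> 1     m_01      maize         NA   0.2986 0.626               NA
#> 8     m_08      maize         NA   0.4332 2.580               NA
#> 9     s_09 sugar_beet     0.0499   0.0963 1.526               19
```

Reading the output: the zone-mean ERI of the maize plants (0.30–0.43, vs a
soil-reference mean of 0.24) tracks the root biomass density in kg/m³ with
a Pearson correlation of 0.89 — the ERI works as a root-presence proxy
where the soil polarization masks the absolute chargeability. For the sugar
beet, the restricted (≤ 55 Hz) Debye decomposition recovers the slow
relaxation (τ_mean ≈ 50 ms, the generator's ground truth), which the
Schwarz relation converts to a storage-cell diameter of 19 μm (truncated
integer micrometres).

Single quantities work the same way standalone:

```r
schwarz_diameter_um(c(0.017, 0.050, 0.080))   # 11 20 25 (μm)
eri(sigma_lf = 1e-4, sigma_hf = 1e-3)          # 0.3992
```

## Scope

The tomographic complex-resistivity inversion itself (e.g. CRTomo),
inductive cable-coupling and leakage-current corrections, and instrument
control are out of scope: the pipeline starts from inverted per-cell
spectra (or their synthetic stand-ins).
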