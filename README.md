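# spectraquant

Chemometrics for label-free immunosensor quantification from near-infrared
reflectance spectra (surface-enhanced reflectance FTIR, ~4000–7000 cm⁻¹).

Analyte binding on a plasmonic sensor surface deepens absorption dips in the
reflectance spectrum; the dip depth at a characteristic overtone band falls
linearly with analyte concentration over the assay's validated 10–100
(ng/mL or U/mL) range. `spectraquant` implements the full workflow a study of
such a sensor needs:

* **Spectrum I/O and alignment** — two-column delimited text (as exported by
  compact NIR spectrometers), delimiter and header auto-detection, linear
  resampling onto a common grid.
* **Preprocessing** — zero-phase Butterworth smoothing (forward–backward, so
  band positions never shift) and improved asymmetric least squares (IASLS)
  baseline correction on a Whittaker penalty:
  `(W + λ D₂ᵀD₂ + λ₁ D₁ᵀD₁) z = (W + λ₁ D₁ᵀD₁) y`, with asymmetric weights
  `p` / `1 − p` so the fit hugs the baseline side of the signal.
* **Quantification** — prominence-based peak detection, consensus peaks across
  scans, overlapping-peak-region finding, an exhaustive calibration-window
  search (widths 20–370 cm⁻¹) scored by the R² of the
  intensity-vs-concentration line with an inverse-slope constraint, classical
  inverse prediction `c = (I − b)/m` with a 10–100 validity flag, and the
  plasmonic enhancement factor `EF = (I_SE/I_ref) · (C_ref/C_SE)`.
* **Chemometrics** — FFT cross-correlation whose lag-0 amplitude equals the
  Pearson correlation, PLS (NIPALS) + ridge-stabilized LDA under repeated
  stratified cross-validation, PCA scores, and z-scored heatmap matrices.
* **Synthetic data** — a seeded band-superposition simulator
  (`R(ν) = baseline(ν) − Σ (dⱼ + sⱼ·c)·exp(−(ν−μⱼ)²/2σⱼ²) + noise`) with known
  ground truth, so every stage is testable without instrument data.

## Worked example

Simulate a calibration series (10 concentrations × 3 replicates), preprocess,
search for the optimal quantification window, and predict an unknown:

```r
library(spectraquant)

cfg <- synth_config(noise_sd = 0.003, seed = 42)      # responsive band at 6750
cal <- simulate_calibration_series(cfg)               # 10, 20, ..., 100 ng/mL
corrected <- lapply(seq_len(nrow(cal$intensities)), function(i)
  correct_spectrum(set_spectrum(cal, i)))
res <- search_optimal_window(assemble_set(corrected), step = 20)
res$best
#> <calibration_model> window 6740-6760 cm^-1: I = -0.002941 * c -0.05045, R2 = 1.000 (n = 10, ng/mL)

unknown <- simulate_spectrum(cfg, 42, seed = 777)
predict_concentration(correct_spectrum(unknown), res$best)
#> predicted 42.0 (in_range)
```

The search landed on a 20 cm⁻¹ window containing the responsive band centre
(6750 cm⁻¹), the fitted slope is negative (reflectance falls with
concentration), R² is 1.000 at this noise level, and the unknown simulated at
42 ng/mL is recovered as 42.0, inside the validated range.

Enhancement-factor arithmetic works directly on substrate intensities; with
the enhanced substrate probed at a 10⁴-fold lower dye concentration:

```r
enhancement_factor(0.72, 1.35, 1e-2, 1e-6)
#> <ef_record> EF = 1.875e+04 (I ratio 1.875, C ratio 1e+04)
```

A thin command-line front end (`inst/cli/spectraquant.R`) exposes the same
pipeline as `simulate` / `calibrate` / `predict` / `report` / `ef`
subcommands with exit codes 0/1/2 (ok / data error / usage error).

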