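# qmribrain

Digital-phantom simulation and analysis of quantitative brain MRI for
paired two-condition studies of cerebral compartment shifts.

Anesthesia, sleep state and other physiological manipulations redistribute
volume between the brain's compartments — cerebrospinal fluid (CSF), grey
matter (GM) and white matter (WM) — and change hemodynamically sensitive MR
parameters such as T2\* and the apparent diffusion coefficient (ADC).
Detecting those shifts requires a chain of estimators: tissue segmentation
and volumetry from proton-density-weighted (PDW) images, multi-echo T2\*
relaxometry, multi-b-value diffusion fitting, and voxel-wise paired
statistics with false-discovery-rate control. qmribrain implements the full
chain **and** a three-compartment digital brain phantom with known ground
truth, so every estimator can be validated end to end — parameter recovery,
volume recovery, detection of planted effects — without scanner data. It is
aimed at quantitative-MRI methodologists and at analysts who want a tested,
reproducible reference pipeline for paired compartment studies.

## Models

* **T2\* relaxometry** — mono-exponential decay
  `S(TE) = S0 · e^(−TE/T2*)`, fitted per voxel by ordinary least squares on
  `ln S` vs TE; compartment means are percentile-trimmed (0.1–99%).
* **Diffusion** — the three orthogonal-direction signals are combined by
  geometric mean; range ADCs come from the Stejskal–Tanner model
  `S(b) = S0 · e^(−b·ADC)` fitted by log-linear least squares inside three
  b-windows (low 20–205, mid 235–1016, high 1117–2518 s/mm²); the wide-range
  signal follows the IVIM–kurtosis form
  `S(b)/S0 = f_IVIM·e^(−b·D*) + (1−f_IVIM)·e^(−b·ADC0 + (b·ADC0)²·K/6)`,
  and for b ≥ 235 s/mm² the simplified three-parameter model
  `S(b) = S0·e^(−b·ADC0 + (b·ADC0)²·K/6)` is fitted per voxel by bounded
  Levenberg–Marquardt (init K = 0.623; boxes `0.5·S0_mid < S0 < 2·S0_mid`,
  `0.5·ADC_mid < ADC0 < 2·ADC_mid`, `0 < K < 2`).
* **Morphometry** — polynomial bias-field correction, a prior-weighted
  Gaussian-mixture EM with explicit partial-volume (mixed-tissue) classes,
  and probabilistic (soft) volume counting.
* **Statistics** — voxel-wise paired t-tests with Benjamini–Hochberg FDR,
  paired tests on compartment totals, and ROI tables.

The methods vignette (`vignettes/qmribrain-methods.Rmd`) documents every
model, default and numerical choice.

## Worked example

```r
library(qmribrain)

## a DMSO-like phantom is mono-exponential: every b-window returns its ADC
prot <- diffusion_protocol()        # 57 b-values, 20-2518 s/mm^2
dmso <- simulate_dmso(prot, adc = 6.8e-4, s0 = 1000)
sapply(c("low", "mid", "high"), function(w)
  1e6 * fit_adc_range(matrix(dmso$signal, 1), prot, w)$adc_map)
#>  low  mid high
#>  680  680  680        # um^2/s, identical across windows

## reducing kurtosis inflates the high-b ADC: calibrated so that -20% K
## gives +9%, a -40% K reduction then gives ~+18%
base <- calibrate_kurtosis_anchor(target_pct = 9, reduction = 0.2)
simulate_kurtosis_effect(base, c(0.2, 0.4))[, c("reduction", "pct_change")]
#>   reduction pct_change
#> 1       0.2    9.00000
#> 2       0.4   17.96067

## a paired phantom brain: CSF 180 -> 190 mm^3, intracranial volume conserved
grid  <- voxel_grid(c(96, 96, 64), 0.23)
truth <- compartment_truth()
maps  <- build_anatomy(grid, truth, seed = 1)
compartment_volumes(maps)
#> compartment volumes (mm^3): CSF 180.0 | GM 1200.0 | WM 641.0 | parenchyma 1841.0 | TIV 2021.0
shifted <- apply_condition_effect(maps,
          effect_spec(csf_scale = 190/180, t2star_shift = -1.8))
compartment_volumes(shifted)
#> compartment volumes (mm^3): CSF 190.0 | GM 1190.5 | WM 640.5 | parenchyma 1831.0 | TIV 2021.0

## simulate PDW with a 10% bias field and 2% noise, then recover the volumes
tmpl   <- build_anatomy(grid, truth, seed = 99)       # template anatomy
priors <- tissue_prob_maps(grid,
            p_gm  = smooth_map(tmpl$p_gm,  grid, 0.9),
            p_wm  = smooth_map(tmpl$p_wm,  grid, 0.9),
            p_csf = smooth_map(tmpl$p_csf, grid, 0.9))
pdw <- simulate_pdw(maps, truth, bias_amplitude = 0.1, noise_sd = 0.02, seed = 2)
bc  <- correct_bias(pdw, grid, priors = priors)
seg <- segment_tissue(bc$corrected, priors)
compartment_volumes(seg)
#> compartment volumes (mm^3): CSF 178.4 | GM 1203.4 | WM 641.2 | parenchyma 1844.5 | TIV 2022.9
```

The segmentation recovers CSF within 1% (178.4 vs 180 mm³) and parenchyma
within 0.2% (1844.5 vs 1841 mm³) despite the bias field and noise. A
multi-echo series fitted with `fit_t2star()` and summarised with
`compartment_t2star_mean()` similarly returns the parenchymal T2\* to
within ~1% of its probability-weighted truth.

`run_pipeline(default_run_config(), "out/")` chains the whole analysis for
a 12-pair cohort — volumes, T2\* tables, ADC/kurtosis ROI tables, and
FDR-corrected paired stat maps — deterministically for a fixed seed. A thin
command-line wrapper lives at `inst/cli/qmri.R`.

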