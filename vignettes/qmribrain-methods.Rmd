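---
title: "Models and methods behind qmribrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qmribrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

qmribrain simulates and analyses quantitative brain MRI for paired
two-condition studies of cerebral compartment shifts: how much cerebrospinal
fluid (CSF), grey matter (GM) and white matter (WM) a brain holds, how the
effective transverse relaxation time T2\* and the apparent diffusion
coefficient (ADC) behave across b-value regimes, and whether paired
voxel-wise statistics recover planted between-condition differences. Every
stage is driven by a digital phantom with known ground truth, so each
estimator in the package can be validated end to end without scanner data.

This vignette records the models, the defaults and the design decisions; the
package tests compute every empirical number referenced here.

## The digital phantom

### Anatomy

`build_anatomy()` lays out a schematic three-compartment brain as nested
ellipsoids: a WM core, a GM rind, and CSF distributed over (i) a thin outer
shell (subarachnoid film), (ii) two ventricle-like cavities in the core, and
(iii) four cistern-like pockets on the ventral and lateral brain surface.
The pockets matter: real rodent CSF is not a uniform sub-voxel film — basal
and ambient cisterns are several voxels thick and hold much of the
subarachnoid volume. An anatomy whose CSF is almost entirely
partial-volume would make CSF volumetry ill-posed for *any* estimator, which
is a property of that artificial geometry, not of the measurement problem.

Compartment boundaries carry a one-voxel linear partial-volume ramp. The
overall brain scale and the two tissue boundaries are solved by monotone 1-D
root finding so that each compartment's probabilistic volume (sum of
per-voxel probability times voxel volume) matches its target to well below
one voxel volume. A seed drives a small (~3%) jitter of ellipsoid axis
ratios and cavity placement — per-subject anatomy — while the volume solves
keep the targets exact.

Defaults encode the study conditions the package emulates: a 96 × 96 × 64
grid at 0.23 mm isotropic, base-condition volumes CSF = 180 mm³,
GM = 1200 mm³, WM = 641 mm³ (parenchyma 1841 mm³, total intracranial volume
2021 mm³).

### The paired condition effect

`apply_condition_effect()` derives condition A from condition B on the same
subject anatomy:

* **CSF rescaling.** A CSF–parenchyma exchange at partial-volume interface
  voxels, solved (capped water-filling) so the final CSF volume equals
  `csf_scale` times the pre-effect CSF volume essentially exactly. The
  exchange is volume-neutral, so total intracranial volume is conserved — a
  Monro–Kellie emulation. The default `csf_scale = 190/180` plants the
  ~6% CSF difference the analysis should detect.
* **Focal GM swelling.** Quadratic bumps at chosen sites add GM probability,
  drawing mass from CSF, then WM, then background inside the site only.
* **Global T2\* shift.** `t2star_shift` (default −1.8 ms for the altered
  condition) is applied to every compartment's T2\*, giving parenchymal
  truths of 28.8 versus 30.6 ms in the default cohort.

`generate_cohort()` adds between-subject variability in the volume targets
(SD 19 mm³ for CSF, 90 mm³ for parenchyma — the population spread the
cohorts should exhibit) and hands out deterministic per-subject,
per-condition, per-modality seeds.

### Forward models

All three simulators are exact closed forms plus optional noise:

* PDW: `sum_c p_c PD_c`, multiplied by a smooth second-order polynomial bias
  field with mean 1 (B1-inhomogeneity emulation; amplitude is defined over
  the central head region, not the empty grid corners), plus Gaussian noise.
* MGE: `sum_c p_c PD_c exp(-TE / T2*_c)` per echo.
* DWI: per b-value, the probability-weighted sum of each compartment's
  IVIM-kurtosis signal
  `S0 (f e^{-b D*} + (1 - f) e^{-b ADC0 + (b ADC0)^2 K / 6})`, identical in
  the three orthogonal directions (isotropy) with independent noise.

Noise is Gaussian on magnitude by default — appropriate for the log-linear
estimators at the SNR regime simulated — with a Rician option for bias
studies. The defaults (sigma/S0 = 2% for PDW, MGE and DWI; bias amplitude
10%) were set once as representative of high-field small-animal imaging
with the protocol's signal averaging, and are stated here because they are
conditions of every downstream recovery figure, not tuning knobs.

The default diffusion protocol spans 57 b-values, 20–2518 s/mm², placed
evenly inside the three analysis windows (15 in 20–205, 21 in 235–1016,
21 in 1117–2518 s/mm²) with the window gaps left empty, so each b-value
belongs to at most one window. The echo protocol is 16 evenly spaced echoes
from 2 to 32 ms.

What the phantom does **not** emulate: realistic rodent neuroanatomy,
perfusion physiology, motion, susceptibility-induced T2\* structure,
multi-shot EPI artefacts, or scanner drift. Passing recovery tests therefore
demonstrates estimator correctness under the stated noise and geometry, not
robustness to every in-vivo confound.

## Relaxometry

`fit_t2star()` fits `ln S = ln S0 - TE / T2*` per voxel by unweighted
ordinary least squares. The log-linear route was chosen over nonlinear
fitting because it is deterministic and closed-form, and at 16 echoes over
2–32 ms with 2% noise its bias on a 30 ms T2\* is below 2% (verified by
Monte Carlo in the tests). Voxels with any non-positive signal or a
non-negative slope are flagged invalid and reported as NA — never silently
zeroed.

`compartment_t2star_mean()` averages valid T2\* over voxels whose summed
membership probability for the requested compartment set exceeds 0.5, after
discarding values outside the 0.1–99 percentile interval. The 0.5 threshold
is our choice of compartment-voxel selection; the asymmetric percentile trim
is the outlier guard. Partial-volume voxels bordering CSF (long T2\*) bias
the parenchymal mean upward by roughly +1.5% at the default geometry — a
genuine property of compartment averaging, visible in the recovery tests.

## Diffusion analysis

`combine_directions()` takes the voxel-wise geometric mean of the read,
phase and slice signals per b-value (trace weighting); negative noise
excursions are clamped to zero first.

`fit_adc_range()` is the Stejskal–Tanner estimator per window: unweighted
OLS of log-signal against b restricted to one named window. On pure
mono-exponential input all three windows agree to 1e-6 relative; on
IVIM-plus-kurtosis input the fitted ADCs order as low > mid > high, the
perfusion term inflating the low window and the kurtosis upturn deflating
the high window.

`fit_ivim_kurtosis()` fits the simplified high-b model
`S = S0 exp(-b ADC0 + (b ADC0)^2 K / 6)` per voxel over all b at or above
the mid-window floor (235 s/mm², where the pseudo-diffusion term is
negligible), by Levenberg–Marquardt on **signal amplitudes** with box
constraints (`minpack.lm::nls.lm`): initialisation `S0 <- S0_mid`,
`ADC0 <- ADC_mid`, `K <- 0.623`; per-voxel boxes
`0.5 S0_mid < S0 < 2 S0_mid`, `0.5 ADC_mid < ADC0 < 2 ADC_mid`,
`0 < K < 2`. Amplitude-domain residuals match the stated
Levenberg–Marquardt usage; a log-domain option (`on_log = TRUE`) exists.
Voxels whose mid-window fit failed are masked (initialisation impossible);
non-converged voxels keep their parameters but are flagged, and a parameter
landing on its box (e.g. a true K above 2) is reported pinned. Convergence
controls: 200 iterations, relative tolerances 1e-10.

### The kurtosis-reduction simulation

`simulate_kurtosis_effect()` quantifies how a kurtosis decrease inflates the
mono-exponentially fitted high-b ADC: noiseless signals from the simplified
model over 1200–2500 s/mm² (21 b-values), a mono-exponential NLS fit on
amplitudes at the reference K and at each reduced K, and the percent ADC
change. The reference parameters for the headline figure are not free:
`calibrate_kurtosis_anchor()` finds, by monotone 1-D search over the tissue
diffusivity (K_ref = 1.0, S0 = 1000), the parameter set at which a 20%
kurtosis reduction produces exactly a 9% ADC increase; the 40% reduction is
then evaluated at that calibrated set and lands near 18%. The fit domain and
amplitude weighting are recorded in the output metadata, since the percent
changes shift by about a point between amplitude- and log-weighted fits.

### Smoothing width

Parameter maps are smoothed with a 0.6 mm Gaussian kernel before voxel-wise
testing, consistent with the morphometry stream. Published ADC pipelines
sometimes quote far larger kernels (6 mm would exceed this brain's
dimensions at desk scale); both widths are supported via configuration, and
0.6 mm is the default.

## Morphometry

### Bias-field correction

`correct_bias()` models log-intensity as tissue offsets plus a second-order
polynomial field. Two paths:

* **Prior-guided** (used by the pipeline): class memberships from spatial
  priors; each iteration hard-assigns voxels with prior-weighted Gaussian
  responsibilities, keeps only confident single-tissue voxels (residual
  within 2.5 standard deviations of the class mean and unambiguous
  posterior), re-estimates class means and the noise scale from them, and
  refits the polynomial. Spatial priors are essential: a compartment that
  lives only at the brain rim (CSF) and a radial quadratic field are
  otherwise confoundable, and an unsupervised fit will trade one for the
  other.
* **Prior-free**: the same alternation with 1-D k-means intensity classes;
  classes closer than 2.5 standard deviations are merged so a near-uniform
  object does not shred the field into class offsets.

Eight alternations; the field is normalised to mean 1 inside the head mask
and divided out everywhere. On the default phantom the prior-guided
estimate correlates with the true field at r > 0.99 with residual
inhomogeneity near 1.5%.

### Segmentation

`segment_tissue()` is a prior-weighted Gaussian-mixture EM over four pure
classes (GM, WM, CSF, background) **plus explicit partial-volume classes**:
each anatomically adjacent tissue pair (GM/WM, GM/CSF, WM/CSF,
CSF/background) gets a mixed class whose likelihood integrates a uniform
mixing fraction between the parent means. Without these, boundary voxels of
a thin compartment are systematically misassigned — a CSF/background ramp
sweeps through the parenchymal intensity range and lands in GM or WM.

Implementation choices:

* A single pooled variance across classes (magnitude-MRI noise is
  class-independent) prevents a thin-compartment class from degenerating
  into a large-variance catch-all.
* The latent mixing fraction enters through its truncated-normal
  conditional moments E[f | y] and E[f² | y], both in the
  weighted-least-squares update of the class means (mixed voxels anchor the
  mean of a compartment that has few pure voxels) and in the final fold-back
  of mixed-class posterior mass onto the parent compartments.
* The M-step is approximate (the fraction moments are held fixed within an
  update), so a monotonicity safeguard reverts and stops if an iteration
  ever decreases the observed-data log-likelihood; in practice the trace is
  non-decreasing.
* The mixed-class prior weight (`mix_weight = 3`, relative to the product of
  the parents' smoothed template priors) was calibrated once on phantoms
  with known compartment volumes — smoothed priors understate how likely an
  interface voxel is to be truly mixed. This is the usual way segmentation
  tools fix such constants (digital-phantom validation), and it is the one
  tuned constant in the module.
* Uninformative (flat) priors trigger a deterministic farthest-point-seeded
  1-D k-means initialisation with centres assigned in the conventional
  proton-density brightness order background < WM < GM < CSF.
* The EM runs inside a head mask (tissue prior above 1e-3 or intensity above
  15% of the 98th percentile); off-mask voxels are unambiguous background.

`compartment_volumes()` counts softly: volume equals the sum of per-voxel
posterior times voxel volume, with no thresholding — unbiased under partial
volume. On 12-subject cohorts at the default grid, geometry and noise, the
mean signed error is below 1% for CSF and below 0.5% for GM and WM, and the
planted 190-versus-180 mm³ CSF difference is detected by the paired test
with the correct sign.

There is no Jacobian modulation: all subjects live in one common space by
construction (spatial registration is out of scope), so volume effects are
carried entirely by the probability maps.

### Smoothing

`smooth_map()` is separable Gaussian convolution with
sigma = FWHM / 2.3548 per axis, reflective boundaries (recorded in the
output attribute), FWHM 0 being the identity. Interior mass is preserved to
0.1%.

## Voxel-wise statistics

`paired_ttest_map()` computes the paired t statistic on within-subject
differences with n − 1 degrees of freedom and two-tailed p-values,
vectorised across voxels. Zero-variance voxels get t = 0, p = 1 and a flag
— map geometry stays intact. `fdr_correct()` applies Benjamini–Hochberg
(via `stats::p.adjust`); a voxel is significant when its adjusted value is
at most the q-level, which is exactly the step-up rejection rule. The
conservative Benjamini–Yekutieli variant is an option.
`paired_total_test()` covers compartment totals (volumes, compartment-mean
T2\*) and `roi_extract()` builds tidy ROI tables, excluding and counting
invalid voxels. The mixed-model and post-hoc analyses some studies apply to
such tables are deliberately out of scope; this module supplies paired
tests and descriptive tables of the same quantities.

## Pipeline, units and determinism

`run_pipeline()` chains simulate → bias-correct → segment → volumes →
T2\* fit → direction combining → three range-ADC fits → kurtosis fit →
smoothing → paired voxel tests with FDR → ROI tables, writing CSVs (units
in the column names: mm³, ms, µm²/s), NIfTI-1 stat maps and a JSON summary
stamped with a configuration hash. ADC is stored in mm²/s internally (so
b·ADC is dimensionless with b in s/mm²) and converted to µm²/s only at
table boundaries. All randomness derives from the single configured seed
through fixed per-subject/condition/modality offsets; reruns are
bit-identical. The kurtosis map is fitted inside the ROI mask by default —
the per-voxel nonlinear fit is the one expensive stage, and the ROI tables
are its consumer.

## Problem sizes and numerical tolerances

The validation suite exercises: anatomy and volumetry at the full
96 × 96 × 64 default grid (12-subject paired cohorts); T2\* cohorts at
64 × 64 × 48 / 0.345 mm (the estimator is resolution-independent, and this
keeps the multi-echo series compact); unit fixtures at 32 × 32 × 24 and
smaller. Root solves use tolerance 1e-10; EM stops at a relative
log-likelihood change of 1e-6; Levenberg–Marquardt at 1e-10. NIfTI
round-trips are bit-exact in the voxel data; header geometry is preserved
to float32 precision.

## Known limitations

* The anatomy is schematic. Estimator performance on real rodent data will
  additionally depend on registration quality, susceptibility artefacts and
  anatomical priors — none of which are modelled.
* The partial-volume mixture model is pairwise; three-tissue corner voxels
  (e.g. GM/CSF/background) violate it and are resolved only approximately.
* f_IVIM and D\* are simulation inputs, never estimated from data; the
  perfusion regime is represented in the forward model and in the low-b ADC
  inflation only.
* The T2\* compartment mean inherits a small positive partial-volume bias
  near CSF; at the default geometry it stays within the 2% recovery bound
  but it is not zero.
* Rician noise is available in the simulator but the estimators assume
  Gaussian noise; at sigma/S0 = 2% the magnitude bias is negligible, at much
  lower SNR it would not be.
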