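# hp13c — dynamic hyperpolarized [2-¹³C]pyruvate brain MRI analysis

Hyperpolarized [2-¹³C]pyruvate MRI watches an injected, transiently
polarized substrate convert in the living brain: the C2 label passes to
lactate via LDH (rate constant kPL) and — unlike the common C1 label —
into the TCA cycle, making [5-¹³C]glutamate observable (rate constant
kPG). `hp13c` is an R implementation of the full post-acquisition chain
for such data, written for researchers processing dynamic, multicoil,
multi-resolution ¹³C EPI acquisitions (high-resolution pyruvate at
7.5 mm / 20°, coarse glutamate and lactate-doublet channels at
22.5 mm / 60°, five slices, 20 frames at 3 s):

1. **Preprocessing** — coil noise covariance from signalless frames,
   prewhitening by the inverse Cholesky factor, per-voxel SVD coil
   combination, zeroth-order phasing.
2. **Denoising** — patch-based higher-order SVD (HOSVD): similar
   spatiotemporal patches are stacked into a patch × time × group tensor
   whose HOSVD core is hard-thresholded at
   τ = k·σ·√(2 ln N) (k_global = 0.4, k_local = 0.8, step 2; patch 3 /
   search 4 for low-resolution channels, patch 5 / search 6 for
   high-resolution).
3. **Quantification** — lactate-doublet QC (Pearson r, SSIM) and
   combination, AUC maps, global-peak-pyruvate-normalized signal maps,
   AUC ratios, SNR_AUC maps, GM+WM > 40% brain masking.
4. **Kinetics** — voxelwise fits of the irreversible three-site exchange
   model
   dP/dt = −(kPL+kPG+R1P)P, dL/dt = kPL·P − R1L·L, dG/dt = kPG·P − R1G·G,
   sampled with effective flips (B1-scaled; M·sinθ measured, M·cosθ
   retained), measured pyruvate as the source ("inputless" fit), yielding
   kPL/kPG maps filtered at SNR_AUC > 3 and fit error < 30%.

Because volunteer data of this kind are not publicly deposited, the
package includes a first-class digital brain phantom (tissue fractions
with partial volume, gamma-variate bolus, three-site kinetics, coil
sensitivities, complex Gaussian noise, lactate-doublet split) so every
stage is testable against known ground truth.

## Worked example

```r
library(hp13c)
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
```

```
Pipeline result
  kPL 0.01003 +/- 5.4e-05 1/s (coverage 100.0%)
  kPG 0.001541 +/- 9.5e-06 1/s (coverage 99.7%)
  AUC ratios lac/pyr 0.14, glu/pyr 0.0215, glu/lac 0.152
  doublet r 0.999, SSIM 0.988
```

This simulates the default two-rate phantom (GM kPL 0.012 / WM 0.0071
s⁻¹, GM kPG 0.0019 / WM 0.0010 s⁻¹, 24 coils, noise at the raw-SNR regime
of the in vivo data), runs the whole chain and reports whole-brain
masked means: the recovered kPL ≈ 0.0100 s⁻¹ and kPG ≈ 0.00154 s⁻¹ match
the phantom's delivery-weighted ground-truth means (0.0102 and
0.00157 s⁻¹) to within ~2% under noise, coverage is the fraction of brain
voxels surviving the SNR and fit-error filters, and the doublet row shows
the agreement of the independently processed lactate doublet channels.

The step-by-step version of the same analysis lives in `analysis/`
(`01_simulate_phantom.R` … `06_report.R`); each script prints what it
found and writes tables/maps under `results/`:

```sh
Rscript analysis/01_simulate_phantom.R 1   # phantom + raw multicoil data
Rscript analysis/02_preprocess.R           # covariance, whitening, combination
Rscript analysis/03_denoise.R              # HOSVD, per-channel SNR gains
Rscript analysis/04_quantify.R             # doublet QC, AUC ratios
Rscript analysis/05_fit_kinetics.R         # kPL / kPG maps
Rscript analysis/06_report.R 1             # end-to-end summary experiments
```

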