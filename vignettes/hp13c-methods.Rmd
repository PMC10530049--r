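---
title: "Methods: dynamic hyperpolarized [2-13C]pyruvate brain MRI analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic hyperpolarized [2-13C]pyruvate brain MRI analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`hp13c` implements the post-acquisition analysis of dynamic, multicoil,
multi-resolution hyperpolarized [2-13C]pyruvate brain MRI: noise
prewhitening, SVD coil combination, zeroth-order phasing, patch-based
higher-order SVD (HOSVD) denoising, lactate-doublet handling, AUC and
metabolite-ratio mapping, and voxelwise fitting of the irreversible
three-site exchange model yielding kPL and kPG rate maps. Because no
volunteer data are distributed with the package, a digital phantom
generator produces multicoil datasets with known ground truth so that
every stage is verifiable end to end. This vignette records the modelling
choices, defaults, and their rationale.

## The kinetic model

The state is the longitudinal magnetization of three pools,
$(P, L, G)$ for pyruvate, lactate and glutamate, evolving as

$$\frac{dP}{dt} = -(k_{PL} + k_{PG} + R_{1P})\,P,\qquad
  \frac{dL}{dt} = k_{PL} P - R_{1L} L,\qquad
  \frac{dG}{dt} = k_{PG} P - R_{1G} G,$$

with $R_1 = 1/T_1$. Conversion is irreversible (no $k_{LP}$ back-flux and
no compartmental astrocyte--neuron exchange; both are deliberate
non-goals). Sampling a metabolite with effective flip angle $\theta$
measures $M_z \sin\theta$ and leaves $M_z \cos\theta$; the effective flip
is the nominal flip (20 degrees for pyruvate, 60 degrees for glutamate and
each lactate doublet line) scaled by the B1 calibration factor, 0.8 by
default. Between the 3-s frames the system is evolved with the exact
closed-form matrix exponential of the lower-triangular rate matrix
(`three_site_propagator()`), which the tests cross-check against a
general-purpose matrix exponential and a fine-step ODE integration.

**Bolus input.** Delivery is a gamma-variate (default delay 8 s, shape 3,
scale 4 s, peak-normalized amplitude), values chosen once to give a signal
rise-and-decay over roughly a minute, as typical of intravenous pyruvate
injection; they are free parameters of the generator, not literature
claims. The input is applied as discrete additions to the pyruvate pool at
frame times. This convention makes the inter-frame evolution exactly
homogeneous, so the simulation is closed-form and -- more importantly --
the fitting model below is *exact* at the optimum, which turns noiseless
round-trip recovery into a sharp correctness test (tolerance 0.1%) rather
than a discretization-limited one.

**Fitting.** `fit_voxel()` is an "inputless" fit: the measured pyruvate
signal is converted to magnetization by $\div \sin\theta_P$ and used as
the metabolite's source, with the pyruvate state reset to the measured
value at every frame. A single rate is estimated per metabolite by bounded
nonlinear least squares (bounds $[0, 0.1]\ \mathrm{s^{-1}}$, analytic
Jacobian, multistart from $\{0.001, 0.01, 0.05\}\ \mathrm{s^{-1}}$).
$T_1$s are fixed: $T_{1P} = 47$ s and $T_{1L} = T_{1G} = 25$ s by default
-- representative literature-scale values, configurable; the synthetic
experiments use the simulation's own $T_1$s so results are
$T_1$-consistent. The non-fitted conversion rate enters only the pyruvate
inter-frame decay; `fit_volume()` refines both maps by alternating passes
so each fit uses the other rate's current voxel estimate. The model
decouples given measured pyruvate, and a joint two-rate fit agrees with
the two single-rate fits to solver tolerance (tested).

**Fitting error** is not uniquely defined in the field; we use the
relative standard error $100 \cdot \mathrm{SE}(\hat k)/\hat k$ from the
Jacobian-based covariance, and exclude voxels at or above 30% from
whole-volume averages, alongside the $\mathrm{SNR_{AUC}} > 3$ inclusion
filter and the GM+WM $> 0.40$ brain mask.

## The digital phantom

Each slice is an ellipse composite: a gray-matter rim around a
white-matter core, two CSF ventricles, and two vessel spots, with
partial-volume tissue fractions from 3x3 subvoxel sampling. Default
per-tissue rates come from representative gray/white-matter voxel
dynamics: GM $k_{PL} = 0.012$, WM $k_{PL} = 0.0071$, GM $k_{PG} = 0.0019$,
WM $k_{PG} = 0.0010\ \mathrm{s^{-1}}$ (CSF and vessels convert nothing).
Two conventions matter and are easy to get wrong:

* **Rates are intensive.** A voxel's rate map value is the
  delivery-weighted mixture of its tissues' rates normalized by the total
  tissue fraction: partial volume dilutes the *signal* (via the delivery
  map), not the per-magnetization conversion rate.
* **The coarse grid is consistent.** Glutamate and lactate are simulated
  on a 3x coarser grid (22.5 mm = 3 x 7.5 mm) and nearest-neighbour
  replicated onto the common 32x32 matrix. Coarse-block rates are
  delivery-weighted block means and coarse delivery is the plain block
  mean, so a coarse voxel's metabolite signal is exactly what its own
  block-averaged pyruvate would produce. The pipeline fits kinetics after
  block-averaging the measured pyruvate the same way; on a uniform-rate
  phantom the whole chain then recovers rates to numerical precision.

The lactate doublet is split $(1, a)/2$ across the downfield/upfield
channels with asymmetry $a \in (0, 1]$ (default 0.9), emulating the
unequal excitation of the two J-coupled lines; each channel receives
independent noise.

The receive array has 24 coils on a ring with smooth Gaussian magnitude
profiles and spatially varying phases, normalized to unit
root-sum-of-squares gain everywhere -- i.e. an intensity-corrected array.
Relative coil profiles and phases still vary, so prewhitening and
combination are fully exercised, but the net gain field is flat;
uncorrected receive shading (a known open issue for this kind of data) is
out of scope. Noise is i.i.d. circular complex Gaussian per coil (default
per-component sigma 0.005, set once so the combined raw glutamate peak
SNR lands near 17, the raw regime of the lowest-SNR channel in vivo; the
resulting lactate-channel peak SNR is about 55), optionally mixed by a
user-supplied inter-coil covariance. Two frame-volumes of pure noise are
appended, standing for the signalless end-of-scan pyruvate frames used
for covariance estimation.

**What the phantom does not emulate:** k-space/EPI trajectories, B0
inhomogeneity, motion, receive-gain shading, and -- importantly -- the
in vivo heterogeneity of SNR across the brain. Because the phantom's
GM/WM signal levels are homogeneous, raw data already pass the
$\mathrm{SNR_{AUC}}$ filter almost everywhere, so denoising cannot
demonstrate the large in vivo coverage gains; the corresponding test
asserts only that denoised coverage is never below raw coverage. Passing
tests therefore validate the machinery, not those in vivo effect sizes.

## Preprocessing

The coil noise covariance is the sample covariance of the signalless
block; data are multiplied by the inverse of its Cholesky factor after
relative diagonal loading of $10^{-6}\,\mathrm{tr}(C)/n$ (numerical
robustness). The published combination method is not fully specified, so
we fix a documented stand-in: per voxel, the weight vector is the dominant
left singular vector of the whitened pyruvate coil-by-frame matrix
(phase-referenced to the strongest coil), shared across channels, because
the metabolite channels are too low-SNR to self-derive sensitivities.
Phasing is zeroth-order per voxel (rotate by the phase of the temporal
peak frame and keep the real part); single-metabolite images have no
spectral dimension, so no frequency or first-order term exists.

## HOSVD denoising

The published parameterization is adopted exactly ($k_{global} = 0.4$,
$k_{local} = 0.8$, step 2; patch 3 / search radius 4 at low resolution,
patch 5 / search radius 6 at high resolution), and the algorithm around it
is fixed as follows. Slices are processed independently in 2D+time (the
3-cm slices are spatially decoupled). For each reference patch position on
a stride-2 grid, spatial patches (all frames) in the search window are
ranked by Euclidean distance, the 32 most similar (a configurable cap that
bounds tensor size) are stacked into a patch-pixels x frames x group
tensor, its HOSVD core is hard-thresholded at
$\tau_l = k_{local}\,\sigma\sqrt{2 \ln N_{tensor}}$, and overlapping
reconstructions are aggregated with weights inversely proportional to each
group's retained-coefficient count. A preliminary global pass thresholds
the singular values of the full space-by-time unfolding at
$\tau_g = k_{global}\,\sigma\sqrt{2 \ln N_{total}}$; whether the global
pass precedes or follows the local pass is not documented for the original
method, so the order is configurable (global-first by default). At
realistic problem sizes the global threshold sits far below the noise
singular values, so the local patch pass does essentially all the work.
$\sigma$ is the scaled median absolute deviation of designated signal-free
samples (the pre-bolus frames in the pipeline); $\sigma = 0$ makes
denoising the identity, as does $k_{local} = 0$ with the global pass
disabled. Exact translation invariance holds for shifts by the stride away
from image borders, where search-window clipping breaks the symmetry.

## Quantification

AUC maps are plain frame sums. Signal maps are normalized to the *global*
peak pyruvate signal (maximum over all voxels, slices and frames). The
doublet channels are processed independently, QC'd against each other
(Pearson r pooled over masked voxels; SSIM with K1 = 0.01, K2 = 0.03, an
11x11 Gaussian window of sd 1.5 truncated and renormalized at borders,
joint-maximum dynamic range, computed per slice on AUC images and
averaged -- the windowing is the common default and the AUC-image choice
is documented, with dynamic frames as the stated alternative), and
combined. The pipeline estimates the doublet asymmetry as the
origin-constrained regression slope of upfield on downfield AUC and
rescales the upfield channel in the summation, so the total lactate
observable recovers the full amplitude; the plain voxelwise sum remains
the default of `sum_lactate_doublet()`.
$\mathrm{SNR_{AUC}} = \mathrm{AUC}/(\sigma\sqrt{n_{frames}})$. AUC ratios
(lactate/pyruvate, glutamate/pyruvate, glutamate/lactate) are reported as
masked means with standard errors. A two-fold Fourier zero-filling helper
exists for display only and is never used in quantification.

## Numerical choices and degenerate inputs

* Propagator entries use a series limit when a relaxation rate approaches
  the total pyruvate decay rate (difference below $10^{-10}$).
* All-zero voxels combine to 0 (no NaN); all-zero metabolite signal
  returns $k = 0$ with an infinite fit error and `converged = FALSE`.
* Covariance estimation warns (but proceeds) with fewer samples than
  coils; prewhitening rejects singular covariances not rescued by
  loading.
* Identical voxel time-series pairs (replicated coarse blocks) are fitted
  once and shared.
* Determinism: phantom structure, coil phases and noise derive from the
  config seed; two runs with one seed are bit-identical.

## Problem sizes

The synthetic experiments run at the native acquisition size (32x32, 5
slices, 20 frames, 24 coils). Unit tests use reduced grids (e.g. 16x16,
1-2 slices, 4-6 coils) where the property under test does not depend on
size; the Monte-Carlo bias check uses 200 replicates at
$\mathrm{SNR_{AUC}} \approx 10$, and the denoising SNR-gain experiment
uses 10 noise seeds at raw peak SNR 15 on the full-size glutamate
channel.

## Known limitations

* The exact algorithms behind the published coil combination and HOSVD
  variant are not restated in full anywhere public; ours are documented
  stand-ins reproducing the stated parameterizations.
* The inputless convention ignores pyruvate's own fit; bolus arrival
  before the first frame would bias the first-frame initial condition.
* No reversible or compartmental models; no Bayesian uncertainty.
* In vivo effect sizes that depend on the unavailable volunteer data
  (maximum SNRs, in vivo AUC ratio values, denoising-driven coverage
  gains) are plausibility references only and are not reproduced by the
  phantom.
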