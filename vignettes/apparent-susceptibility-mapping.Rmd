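---
title: "Apparent susceptibility mapping from clinical SWI phase: model, phantom and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apparent susceptibility mapping from clinical SWI phase: model, phantom and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swiqsm)
```

## The problem

Parkinson's disease (PD), progressive supranuclear palsy (PSP) and multiple
system atrophy (MSA) are hard to distinguish clinically, particularly early.
Iron accumulates differently in the deep gray nuclei across these disorders,
and magnetic susceptibility is a usable proxy for tissue iron. Clinical
susceptibility-weighted imaging (SWI) protocols, however, archive only
magnitude and *high-pass filtered* phase; a susceptibility map reconstructed
from such phase is an *apparent* susceptibility — systematically attenuated
relative to the true tissue value, but still carrying diagnostically useful
contrast.

This package implements the complete computational chain for that setting:

1. a forward-physics simulator producing synthetic SWI acquisitions from a
   digital phantom with known susceptibility;
2. the reconstruction chain — brain-mask erosion, Laplacian phase
   unwrapping, V-SHARP background field removal, and iLSQR dipole inversion;
3. ROI extraction with left/right averaging and CSF referencing;
4. a cohort simulator with the group structure of a four-group
   parkinsonism study (PD/PSP/MSA/control, n = 134/11/10/44);
5. the statistical layer: ANCOVA with LSD pairwise comparisons,
   Mann-Whitney U, ROC with DeLong confidence intervals, equal-prior LDA
   with leave-one-out cross-validation, partial correlations, and
   Bonferroni correction at 0.05/30.

No patient data ship with the package: the phantom and cohort simulators
define the study conditions under which every claim here is tested.

## Forward model

A susceptibility distribution $\chi(\mathbf r)$ (ppm) induces a resonance
offset field (in ppm of $B_0$) given in k-space by the dipole kernel

$$\Delta B(\mathbf k) = D(\mathbf k)\,X(\mathbf k), \qquad
D(\mathbf k) = \frac13 - \frac{k_z^2}{|\mathbf k|^2},$$

with $B_0$ along the slice axis ($z$) of an axial acquisition and
$D(\mathbf 0) \equiv 0$: the spatial mean of $\chi$ is unobservable, so all
susceptibilities in this package are *relative*, which is also why regional
values are referenced to CSF downstream. The field maps to phase at echo
time as $\phi = \gamma B_0 \,\Delta B \cdot 10^{-6}\, T_E$ (defaults:
3 T, $T_E$ = 20 ms, $\gamma = 2.675153\times10^8$ rad/s/T, so 0.1 ppm
$\mapsto$ 1.605 rad). The scanner's product filter is emulated as homodyne
filtering: the complex image is divided, slice by slice, by its own
low-pass reconstruction from a Hanning-windowed central k-space block
(64 × 64 samples by default). The clinical filter's true size and window
are not public; the width is therefore a configurable convention, and the
tests quantify its effect (strong attenuation of smooth phase, ~50%+
preservation of point-like structure) rather than assume a particular
scanner. Noise, when enabled, is additive complex Gaussian with
$\sigma = \bar m_{\text{brain}}/\mathrm{SNR}$ — appropriate in the
high-SNR regime; Rician magnitude statistics are deliberately not modeled
since all downstream use is phase-driven.

The default phantom is a 96 × 96 × 48 grid at 0.86 × 0.86 × 1.5 mm³ —
the voxel geometry of the emulated protocol, with the grid size chosen for
desk-scale runtimes (a full simulation + reconstruction takes ~15 s on one
CPU). It contains the five paired nuclei (globus pallidus, putamen,
substantia nigra, red nucleus, dentate nucleus) as ellipsoids at
susceptibilities typical of iron-rich deep gray matter (0.10–0.18 ppm), a
frontal-horn CSF pair at 0.02 ppm, one strong external susceptibility
sphere and a linear field ramp as background sources. Nuclei are placed
near the brain center, as the deep nuclei are anatomically, which also
keeps them inside the V-SHARP-valid region.

## Reconstruction chain

**Erosion.** The brain mask is eroded 3 mm (default) with an ellipsoidal
structuring element respecting voxel anisotropy, implemented by FFT
convolution. The source only says masks were "three-dimensionally eroded";
3 mm is our choice, exposed as a parameter.

**Laplacian unwrapping.** The unwrapped phase solves
$\nabla^2\phi_u = \cos\phi\,\nabla^2\sin\phi - \sin\phi\,\nabla^2\cos\phi$
spectrally, with the DC term of the inverse Laplacian set to zero. Any
global constant is irrelevant after CSF referencing. On a smooth phase with
many wraps the recovery is exact to ~1e-6 relative RMS; at sharp source
edges spectral ringing bounds the round-trip fidelity to a few percent,
which the tests state explicitly.

**V-SHARP.** For each kernel radius (12 mm down to one voxel, in one-voxel
steps), the spherical-mean-value filter $(\delta - \rho_r)$ annihilates any
field that is harmonic inside the mask, i.e. generated by outside sources.
Each voxel uses the largest radius whose sphere fits inside the mask; the
composite is deconvolved by the largest-radius kernel with a truncated
inverse (threshold 0.05), and the valid output region is the mask eroded by
the largest radius. The radii and threshold are standard literature
defaults — the original study names the method but not its settings, so
acceptance targets properties (≤ 5% residual RMS on a purely background
field) rather than bit-equality with any particular toolbox.

**iLSQR.** Dipole inversion solves
$\min_\chi \lVert M(F^{-1} D F \chi - f)\rVert_2$ by LSQR (matrix-free,
tolerance 0.01, ≤ 50 iterations), restricted to the valid mask, followed by
one streaking-suppression pass: the spectrum inside the ill-conditioned
dipole-cone region ($|D| < 0.1$) is replaced by the spectrum of a
truncated-k-division fast solution ($|D|$ floored at 0.15). Non-convergence
returns the best iterate with a warning rather than failing. The chain
contains no randomness anywhere: identical inputs give identical maps.

On the default noiseless phantom without the scanner filter, referenced
ROI means are recovered within 15% of truth; with the 64-sample filter the
maps show the expected behavior of apparent susceptibility — ROI values
attenuated to roughly 20–30% of truth, with within-experiment contrast
ratios of similar-size structures preserved within 25% and group-level
rank order preserved for well-separated values. Passing these tests shows
the chain is a faithful implementation of the stated operators on
piecewise-constant ellipsoidal sources; it does not certify performance on
real anatomy, where segmentation error, flow, calcification and
microstructure all perturb phase in ways the phantom does not emulate.

## ROI extraction

Per-label means are taken over the intersection with the V-SHARP valid
mask (a region entirely outside it is an error, not a silent NaN), paired
structures are averaged unweighted, and every region is referenced by
*subtracting* the CSF frontal-horn mean. Subtraction, not division:
because $D(\mathbf 0) = 0$, reconstructed susceptibility is defined only up
to an additive constant, so an additive reference is the physically
meaningful normalization, and it makes the referenced values exactly
invariant to global map offsets. Both frontal horns share one label, so
the reference is the both-horn mean.

## Cohort simulator

The simulator draws, per group: age (group-specific normal; 66.9 ± 9.6,
72.2 ± 5.5, 63.4 ± 11.4, 66.0 ± 7.8 years for PD/PSP/MSA/control), gender
(group-specific female fraction), and disease duration for patients.
Regional susceptibility is
`group mean + age slope × (age − 65) + duration slope × duration (PD) + noise`
with a common residual SD of 0.02 ppm. Absolute group-by-region levels are
*not* published (the source figures are graphical only), so the defaults
are synthetic free parameters chosen once to satisfy the published
ordering: PSP highest of all groups in the red nucleus and above PD and
controls everywhere; MSA above PD and controls in the putamen and above PD
in substantia nigra and dentate; PD identical to controls everywhere.
Age slopes are nonzero for putamen, red nucleus and dentate; duration
slopes (PD) for globus pallidus and substantia nigra — the regions where
such effects were reported.

UPDRS-III is built from group anchors, covariate effects, and a loading
$\lambda$ on the putamen residual chosen so the age/gender/duration-adjusted
partial correlation with putaminal susceptibility in PD equals the target
$\rho = 0.213$ in expectation:
$\lambda = \rho\,\sigma_u /(\sigma_\chi\sqrt{1-\rho^2})$. Scores are
floored to integers ≥ 0 and Hoehn & Yahr is derived by binning UPDRS-III —
a modeling convenience, not a claim about the scales' true joint
distribution. Everything is deterministic under the configured seed and
round-trips byte-identically through CSV.

## Statistical layer

- **Normality:** Lilliefors-corrected one-sample KS test against a normal
  with estimated parameters (via `nortest`); the analytic p-value
  approximation is used — deterministic, no Monte-Carlo seed to manage.
- **ANCOVA:** `lm` with group indicators plus age and gender (0/1); the
  group F is the nested-model comparison, which for this additive design
  equals the Type III F of the usual software convention, yielding the
  F(3, 193) layout at the study's sizes. LSD pairwise comparisons are
  unadjusted t-tests on covariate-adjusted means from the model
  covariance; cross-checked against `emmeans`.
- **Mann-Whitney U:** exact two-sided p for min(n) ≤ 8 without ties,
  normal approximation with tie correction otherwise; used by default for
  the dentate MSA-vs-PD contrast, where normality fails.
- **ROC/AUC:** rank-based Mann-Whitney AUC with half credit for ties,
  direction auto-flipped (and flagged) so AUC ≥ 0.5; operating points by
  Youden's J with ties broken toward higher specificity — the published
  figures report sens/spec without stating a cutoff rule, so Youden is our
  documented choice. Confidence intervals by DeLong structural components
  (Wald, clipped to [0, 1]; degenerate separation flagged), cross-checked
  against `pROC` and a bootstrap oracle.
- **Discriminant analysis:** Gaussian LDA with pooled covariance and
  *equal priors*, so the boundary is invariant to the heavy class
  imbalance (134 vs 11); near-singular pooled covariance falls back to a
  small relative ridge. Pairwise diagnostics refit one-vs-one per group
  pair (matching the published pairwise table layout) rather than slicing
  the four-class model; LOOCV refits with each subject left out.
  Cross-checked against `MASS::lda`.
- **Predictive-value reconstruction:** `confusion_from_rates()` rebuilds
  integer confusion matrices from printed sensitivity/specificity and
  group sizes using round-half-away-from-zero, then recomputes PPV, NPV
  and accuracy; this round-trips every published discriminant and ROC row
  to the printed precision.
- **Partial correlation:** residualization on the covariates, p from the
  t transform with df = n − 2 − k; matches the recursive closed form to
  1e-10.
- **Multiplicity:** Bonferroni 0.05/30 = 0.0017 for the 6 group pairs × 5
  regions.

## Numerical choices and degenerate inputs

All spectral operations use periodic FFTs on the native grid without zero
padding — a documented approximation; masks should not touch the grid
edges (the phantom's brain ellipsoid never does). Erosion to an empty mask,
V-SHARP radii exceeding the mask, all-zero masks, constant samples in the
KS test, zero-margin contingency tables, collinear covariates and zero
residual variance are all hard errors naming the cause. An AUC of exactly
0/1 collapses the DeLong interval and is flagged rather than patched.

## Problem sizes used by the tests

The component tests run on 48³–64³ grids; the end-to-end file and the
acceptance checks use the native 96 × 96 × 48 default phantom, a 96³
isotropic sphere phantom for the V-SHARP/iLSQR oracles, 2000-replicate
null calibrations for the ANCOVA type-I rate, a 2000-replicate bootstrap
for the DeLong comparison, and an n = 5000 PD cohort for the
partial-correlation recovery — sizes chosen so the whole suite runs in
about two minutes on one CPU.

## Known limitations

- Apparent susceptibility from filtered phase is attenuated
  size-dependently; between-structure ratios are only approximately
  preserved, exactly as the tests quantify.
- The phantom's piecewise-constant ellipsoids contain no microstructure,
  flow, calcification, or segmentation error; diagnostic accuracies on the
  synthetic cohort characterize the *statistical machinery* under the
  published group structure, not clinical performance.
- The cohort's absolute susceptibility levels are synthetic; only their
  ordering and correlation structure are anchored to published results.
- No DICOM ingestion, no multi-echo, no alternative dipole inversions
  (MEDI, COSMOS), no real-anatomy segmentation.
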