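# swiqsm

Apparent susceptibility mapping from clinical SWI phase, with the
diagnostic statistics used to separate parkinsonian disorders.

## What this is for

Clinical susceptibility-weighted imaging (SWI) stores magnitude and
**high-pass filtered** phase. Quantitative susceptibility mapping (QSM)
applied to such phase yields *apparent* susceptibility — attenuated
relative to true tissue susceptibility but still reflecting iron content
in the deep gray nuclei, which differs characteristically between
Parkinson's disease (PD), progressive supranuclear palsy (PSP), multiple
system atrophy (MSA) and healthy controls. This package is for
neuroimaging methodologists who want a fully tested, self-contained
implementation of that pipeline — from forward physics to group
diagnostics — with synthetic data generators standing in for patient data.

The core is the dipole inversion problem. A susceptibility map
$\chi(\mathbf r)$ (ppm) induces a field (ppm of $B_0$) via the k-space
dipole kernel

$$\Delta B(\mathbf k) = \Big(\tfrac13 - \tfrac{k_z^2}{|\mathbf k|^2}\Big) X(\mathbf k),$$

observed as phase $\phi = \gamma B_0 \Delta B \cdot 10^{-6} T_E$. The
reconstruction chain inverts this: 3-D mask erosion → Laplacian phase
unwrapping → V-SHARP background field removal → iLSQR dipole inversion
(LSQR plus a streaking-suppression pass near the dipole cone). Regional
values are extracted as left/right-averaged ROI means referenced to
frontal-horn CSF, and analyzed with ANCOVA + LSD pairwise comparisons,
Mann-Whitney U, ROC with DeLong confidence intervals, equal-prior linear
discriminant analysis with leave-one-out cross-validation (LOOCV), partial
correlations and Bonferroni correction (0.05/30).

## Worked example

Simulate an SWI acquisition of the built-in digital phantom, reconstruct
the apparent susceptibility map, and extract referenced ROI values:

```r
library(swiqsm)

spec <- default_phantom_spec()                       # 96 x 96 x 48 phantom
acq  <- acquisition_params(snr = 40)                 # 3 T, TE 20 ms, HPF 64
sim  <- simulate_acquisition(spec, acq)
sim
#> Synthetic SWI acquisition
#>   grid: 96 x 96 x 48, voxel 0.86 x 0.86 x 1.50 mm
#>   B0 = 3.0 T, TE = 20.0 ms, HPF kernel = 64, SNR = 40

chi <- qsm_reconstruct(sim, recon_params(acq = acq))
rec <- build_subject_record(chi, sim$truth$roi_atlas,
                            list(subject_id = "phantom01", group = "Phantom"))
round(rec[, c("gp", "put", "sn", "rn", "dn")], 4)
#>       gp    put     sn     rn     dn
#> 1 0.0317 0.0154 0.0339 0.0334 0.0155
```

The phantom's true referenced values are 0.16/0.08/0.14/0.11/0.08 ppm: the
reconstruction from *filtered* phase recovers roughly a fifth to a third
of each — this is what "apparent susceptibility" means. Without the
scanner filter (`hpf_kernel = NULL`), the same chain recovers every region
within 15% of truth.

Simulate a structured four-group cohort and run the full statistics:

```r
cohort <- simulate_cohort(default_separation_scenario(seed = 17))
res <- run_full_analysis(cohort)
res
#> Cohort susceptibility analysis
#>   groups: PD n=134, PSP n=11, MSA n=10, Control n=44
#>   significance: alpha = 0.05, Bonferroni-corrected = 0.0017
#>   region ANCOVA F (p):
#>     gp   F(3,193) =  13.012  p = 8.91e-08
#>     put  F(3,193) =  44.302  p = 7.9e-22
#>     sn   F(3,193) =  21.349  p = 5.51e-12
#>     rn   F(3,193) =  76.442  p = 1.25e-32
#>     dn   F(3,193) =  35.607  p = 2.32e-18
#>   pairwise LDA (LOOCV accuracy):
#>     PSP vs PD      100.0% (sens 100.0%, spec 100.0%)
#>     PSP vs MSA     100.0% (sens 100.0%, spec 100.0%)
#>     MSA vs PD      94.4% (sens 90.0%, spec 94.8%)
#>     PSP vs Control 100.0% (sens 100.0%, spec 100.0%)
#>     MSA vs Control 88.9% (sens 90.0%, spec 88.6%)
#>     PD vs Control  53.9% (sens 55.2%, spec 50.0%)
#>   four-group LOOCV accuracy: 54.3%
```

Every region separates the groups at the corrected threshold, PSP is
cleanly separable from PD (the red nucleus is the strongest single
region), and PD is indistinguishable from controls — the qualitative
pattern the scenario is built to encode.

Reconstruct predictive values from published sensitivity/specificity
pairs and group sizes:

```r
confusion_from_rates(1.00, 0.970, n_pos = 11, n_neg = 134)
#> sens 100.0%  spec 97.0%  accuracy 97.2%  PPV 73.3%  NPV 100.0%  (TP 11 FP 4 TN 130 FN 0)
```

An end-to-end pipeline (`run_pipeline()`, or
`inst/scripts/qsm-pipeline.R` from a shell) writes NIfTI volumes, cohort
CSVs, report tables and JSON provenance sidecars keyed to a single root
seed.

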