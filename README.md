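# rilkinetics

Modelling radiation-induced lymphopenia (RIL) from longitudinal blood
counts and treatment-plan dosimetry.

Radiotherapy depletes circulating lymphocytes: the blood pool passing
through the irradiated volume receives a dose at every fraction, and
severe lymphopenia (CTCAE grade ≥ 3, ALC < 0.5 × 10³/µL) is associated
with worse oncological outcomes. Commonly used endpoints — ALC at a fixed
week, or the nadir — depend heavily on when blood happens to be drawn.
`rilkinetics` implements a kinetics-based alternative for analysts of
retrospective radiotherapy cohorts: every ALC measurement in the first
weeks of treatment contributes to a per-patient decay curve, and the
endpoint is the relative ALC deficit integrated over the observation
window.

## The model

For each patient, ALC from RT start (day 0) to a 45-day window is fitted
with a bounded exponential decay

```
ALC(t) = a · exp(−b · t) + c ,   a ≥ 0, c ≥ 0
```

by Levenberg–Marquardt least squares (initial values: depletion rate
b₀ = 0.10/day, plateau c₀ = 0.34 × 10³/µL). Fits are quality-controlled:
non-convergence, b outside [0, 1], or R² < 0.5 are fit failures and the
patient is excluded from modelling. The endpoint is the percentage ALC
loss

```
%loss = 100 · ( 1 − AUC(0, T) / (ALC₀ · T) ) ,
AUC(0, T) = a/b · (1 − e^(−bT)) + c·T ,
```

with ALC₀ the baseline (measurement closest to RT start, no later than
day 2) and T the curve-fitting time (last measurement in the window).

On the dosimetry side the package validates cumulative DVH summaries
(Dmin/Dmean/Dmax and V_x for x ∈ {0.5, 1, 2, 5, …, 55} Gy) for the lungs,
heart and whole body, converts them to EQD2 (α/β = 10 Gy), and computes
EDRIC, the effective dose to circulating immune cells:

```
EDRIC = 0.12·MLD + 0.08·MHD + (0.45 + 0.35 · 0.85 · n/45) · MBD .
```

The association stage reproduces a full analysis pipeline: univariable
R² screening of each dose metric (adjusted for concurrent chemotherapy),
ANCOVA comparison of VMAT vs IMRT plans adjusted for PTV volume,
Spearman comparison of the %loss and nadir endpoints, PCA summarising the
strongly collinear dose metrics into PC1, and multivariable linear models
(CRT + baseline ALC + EDRIC or PC1) with 95% CIs, MSE, AIC and
optimism-corrected R² (Harrell bootstrap, 300 resamples).

Because clinical cohorts of this kind are rarely shareable, the package
includes a seeded synthetic cohort generator (`generate_cohort()`) with
stored ground truth — true decay parameters, a latent plan-intensity
factor driving all DVH metrics, and configured covariate effects — so the
whole pipeline can be validated end-to-end against known truth.

## Worked example

```r
library(rilkinetics)

cfg    <- cohort_config(n_patients = 306, seed = 2718)
cohort <- generate_cohort(cfg)
ep     <- compute_endpoints(cohort$blood, window = 45)
table(ep$status)
#>             fail_b_range fail_insufficient_points                  fail_r2
#>                        2                        8                       14
#>                  success
#>                      282

ed   <- edric_table(cohort$dvh, cohort$clinical)
dvh2 <- eqd2_transform_dvh(cohort$dvh, cohort$clinical[, c("patient_id", "n_fractions")])
tab  <- build_analysis_table(ep, cohort$clinical, dvh2, ed)

pca <- pca_dose(tab)
round(100 * pca$explained_fraction[1], 1)
#> [1] 49

tab$pc1 <- pca$pc1_scores
fit_multivariable(tab, "pc1", B = 300, seed = 7)
#> Linear model for percent ALC loss (dose summary: pc1, n = 282)
#>          term             estimate p_value
#>   (Intercept) 47.24 (44.33, 50.15)  <0.001
#>           crt    7.13 (5.23, 9.04)  <0.001
#>  baseline_alc    1.28 (0.07, 2.48)  0.0385
#>           pc1    0.62 (0.44, 0.81)  <0.001
#> R2 0.269 | bias-corrected R2 0.254 (B = 300) | MSE 60.5 | AIC 1967.4
```

282 of 306 patients yield a quality-controlled decay fit; their median
percentage ALC loss is 53%. The first principal component captures about
half of the variance of the 51 dose metrics, and both concurrent
chemotherapy (+7 percentage points of loss) and a more dose-intense plan
(higher PC1) independently predict lymphocyte loss. `run_pipeline()`
chains all of these stages and writes every table, a JSON model report
and a manifest to an output directory, byte-reproducibly for a fixed
seed.

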