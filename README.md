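# ratconn

Multimodal MRI network analysis for two-group rodent studies, built around
the 5-HTT (serotonin transporter) knockout rat design: does a lifelong loss
of serotonin reuptake rewire the brain's functional and structural
networks? The package provides the full analysis chain such a study needs —
resting-state functional connectivity, pharmacological MRI of a cocaine
challenge, and diffusion-tensor tractography connectomes — together with a
synthetic multimodal study generator with known ground truth, so every
stage is testable without animal data. It is aimed at researchers who
analyze small-animal MRI cohorts and at methodologists who want a
reference implementation whose estimators are pinned by oracle tests.

## What it computes

**Resting-state functional connectivity.** After Gaussian smoothing
(FWHM 1.0 mm), linear detrending, nuisance regression (global signal, six
motion parameters, trend) and 0.01–0.1 Hz band-pass, connectivity between
ROI signals is the Fisher-transformed correlation, z′ = atanh(r).
Homologous left/right seeds are averaged into intra- and inter-hemispheric
values per ROI pair; one- and two-sample t-tests with Benjamini–Hochberg
FDR and Monte-Carlo cluster-extent thresholds provide inference.

**Weighted brain graphs.** From an FC or structural matrix, G = (V, W)
keeps positive weights only. Reported metrics are the mean Onnela
clustering coefficient
C_i = Σ_{jk} (ŵ_ij ŵ_jk ŵ_ik)^{1/3} / (k_i(k_i−1)), the characteristic
path length with distance 1/w, and small-worldness
σ = (C/C_surr)/(L/L_surr), normalized against 1000 edge-weight-permutation
surrogate networks.

**Pharmacological MRI.** The drug-induced %BOLD response is a scaled gamma
density f(t) = λ β^α t^(α−1) e^(−βt) / Γ(α), so total activation (AUC) is
exactly λ and the peak is at (α−1)/β. Seed-wise group tests use
generalized least squares with continuous-time AR(1) errors
(Corr = φ^|Δt|) and physiological covariates (PaCO₂, blood pressure);
subject × ROI gamma parameters are estimated in a hierarchical Bayesian
model (log-parameters normal around group-level means, stationary AR(1)
noise, bespoke vectorized MCMC with split-R-hat < 1.1 convergence gate);
overall group differences use linear mixed models with ROIs-per-subject
random effects.

**DTI connectomes.** Voxel-wise tensors by log-linear least squares, FA/MD
maps, deterministic interpolated-streamline tractography (FA > 0.2, 35°
angle threshold, 10 random seeds per voxel, minimum length 1.0 mm) and
ROI-pair connectomes weighted by the mean FA along connecting tracts, plus
white-matter ROI FA group statistics.

## Worked example

Simulate a small two-group cocaine-challenge study (the knockout-style
group has its response scale λ inflated: 18 vs 13 %BOLD·min) and fit the
hierarchical gamma-variate model:

```r
library(ratconn)
sim  <- sim_phmri(n_subjects = c(6, 6), n_rois = 5, seed = 11)
post <- fit_hierarchical(sim$sessions, chains = 3, iter = 2500, seed = 4)
print(post)
#> phmri_posterior: 3 chains x 1250 kept draws; converged ; phi = 0.307
#> group-level means (natural scale):
#>     alpha   beta     lam
#> WT 3.3267 0.2930 11.8423
#> KO 2.9552 0.2438 18.0421
#> group differences ( WT - KO ):
#>   parameter     mean  lower95 upper95
#> 1     alpha  0.37154 -0.36132  1.2046
#> 2      beta  0.04926 -0.03539  0.1429
#> 3       lam -6.19981 -9.55280 -2.9071
```

The fit recovers the generating group means (α = 3, β = 0.25 min⁻¹;
λ = 13 vs 18), estimates the noise autocorrelation (φ ≈ 0.31, truth 0.3),
and the 95 % credible intervals tell the right story: the shape and rate
differences contain zero (the groups truly share them) while the scale
difference excludes zero — the injected 40 % knockout effect. Effect-size
arithmetic for literature-style tables is one call:
`d_from_t(2.56, 12, 15)` returns `0.99`.

The numbered scripts under `analysis/` run the full workflow on a complete
synthetic study — `01_simulate_study.R` (generate and serialize),
`02_resting_connectivity.R` (seed-based FC and group tests),
`03_network_graphs.R` (surrogate-normalized graph metrics),
`04_phmri_response.R` (GLS, hierarchical fit, mixed models),
`05_dti_connectome.R` (tensors, tractography, connectome) — writing their
tables under `results/`.

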