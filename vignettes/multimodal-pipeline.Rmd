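---
title: "Models and methods behind the ratconn pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ratconn pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratconn)
```

ratconn re-implements, as a tested pipeline over synthetic data with known
ground truth, a multimodal MRI characterization of brain networks in
two-group rodent studies of the 5-HTT (serotonin transporter) knockout
model: resting-state functional connectivity and weighted graph analysis,
pharmacological MRI of a cocaine challenge, and diffusion-tensor
tractography connectomes. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic generators do and
do not emulate.

## The synthetic study

Real studies of this design cannot be redistributed, so every stage is
exercised against generators whose ground truth is recorded.

**Atlas** (`make_atlas`). 23 bilateral gray-matter ROI pairs (46 labels)
named after the limbic and cortical structures typical of rodent seed
analyses (prefrontal subdivisions, insula, accumbens, caudate-putamen,
amygdala, thalamus, hippocampus, raphe, VTA, sensory cortices, ...), plus 4
midline white-matter ROIs (genu and body of the corpus callosum, anterior
commissure, internal capsule). Four structures (VTA, DRN, ventral OFC,
frontal cortex) are rendered as single voxels by default: at typical rodent
fMRI resolution they span less than two voxels and are excluded from
resting-state analyses by the two-voxel rule in `roi_timeseries`. Placement
is a deterministic mirrored lattice; white-matter ROIs sit on the midline
and carry no hemisphere/homolog assignment.

**Resting BOLD** (`sim_rest_bold`). ROI signals are white Gaussian noise
band-pass filtered to 0.01–0.1 Hz — the same ideal zero-phase spectral mask
the analysis uses — then mixed through the matrix square root of the target
correlation matrix, so the *population* correlation equals `fc_target`
exactly and FC recovery is unbiased by construction. Defaults: 1200 frames
at TR = 0.5 s. The voxel mode broadcasts ROI signals into the label volume
and adds iid voxel noise, a global signal, six motion traces (normalized
random walks with per-voxel loadings) and per-voxel linear drift; all
injected nuisance traces are stored on the series as the known regressor
set. A degenerate (non-positive-semi-definite) target is rejected with a
pointer to the eigenvalue-clipping projection used by `example_fc_target`.

**phMRI** (`sim_phmri`). Each subject × ROI series is
`offset + lam * g(t - t_inj; alpha, beta) + noise`, with `g` the gamma
density — 20 baseline frames (10 min) and 80 post-injection frames (40 min)
at 30 s spacing. Subject × ROI parameters are log-normal with the
configured *natural-scale* group means (the log-mean is shifted by
−sd²/2), so sample means converge to the configuration. Defaults emulate a
wild-type group (α = 3, β = 0.25 min⁻¹, λ = 13 %BOLD·min) versus a
knockout-style group with λ inflated ≈ 40 % (λ = 18), between-subject log-SDs
(0.15, 0.15, 0.35), and stationary AR(1) noise with lag-1 correlation 0.3
at SD 0.5 %BOLD. Physiological covariates (PaCO₂ before the scan, mean
arterial blood pressure before and at 5–15 min post-injection) are drawn
from group-typical distributions and act as small *multiplicative* gains on
the response amplitude. An earlier design added covariate effects as an
additive step on the post-injection frames; that injects signal outside the
gamma family, and the sampled group-mean covariate level then biases λ
recovery — the multiplicative form keeps the generator's identifiable
structure aligned with the models that analyze it, which is why it is the
one we ship.

**Diffusion** (`make_scheme`, `sim_tensor_phantom`, `sim_dwi`). Gradient
schemes place 50 unit directions (plus 2 leading b0 volumes, b = 1250
s/mm²) by electrostatic repulsion of antipodal pairs. Phantoms fill an
atlas grid with near-isotropic tensors (FA 0.05) and prolate tensors
(FA 0.8, closed-form eigenvalues at fixed MD = 0.7 × 10⁻³ mm²/s) aligned to
bundle centerline tangents; crossing voxels carry the first-listed bundle's
tensor only, because the analysis model is single-tensor. The DWI forward
model is `S = S0 exp(-b gᵀ D g)` with optional Rician noise
(SNR = S0/σ of the underlying Gaussian).

What the generators do **not** emulate: registration misalignment, motion
artifacts beyond additive traces, physiological (cardiac/respiratory)
signal, susceptibility distortion, multi-fiber voxels, and — importantly —
the modular small-world organization of real cortical networks. The default
`example_fc_target` (homotopic 0.6, three modules at 0.35 over a 0.1
baseline) produces strong homotopic coupling but only mild clustering
excess, so surrogate-normalized clustering sits near 1 and small-worldness
can fall below 1; passing tests therefore validate the *estimators*, not
the claim that the synthetic brain is small-world.

## Resting-state functional connectivity

Preprocessing follows the order: spatial smoothing (Gaussian FWHM 1.0 mm,
σ = FWHM/2.3548, separable with edge renormalization) and per-voxel linear
detrend (`preprocess`); nuisance regression of global signal, six motion
parameters and a linear trend plus intercept (`regress_nuisance`), with
collinear columns dropped by QR rank detection; then band-pass 0.01–0.1 Hz
(`bandpass`). Nuisance regression is deliberately run *before* the
band-pass, so filtered spectra are not re-contaminated by the projection.
The filter is an ideal zero-phase spectral mask rather than a
forward–backward IIR filter: both satisfy the contract (passband gain
1 ± 0.05, ≥ 90 % attenuation an octave outside), and the mask meets it
exactly with no edge transient tuning. Global-signal regression is kept (as
in most resting-state protocols) but is togglable via the `include` argument,
since removing the global mean can manufacture negative correlations; the
package takes no stance on its validity.

FC is Pearson correlation Fisher-z transformed, with |r| clipped at
1 − 10⁻⁷ so degenerate synthetic inputs yield a large finite z′ instead of
aborting batch runs. Homologous averaging reduces the 2n × 2n matrix to
intra-hemispheric (mean of left–left and right–right) and inter-hemispheric
(mean of left–right and right–left) values per ROI pair, with the
inter-hemispheric diagonal holding homotopic connectivity.

## Weighted brain graphs

Graphs keep all positive weights (self-loops removed, negative edges
dropped — thresholding sweeps are deliberately out of scope). Clustering is
Onnela's weighted form with weights normalized by the graph maximum; path
length maps weight to distance as 1/w — the standard choice for
correlation-like weights, where stronger coupling means a shorter
functional path; the mapping is stated prominently because other choices
(1 − w, −log w) change numbers. L averages over ordered node pairs, which
equals the unordered average on these symmetric graphs. Unreachable pairs
on disconnected graphs are excluded from the mean and their fraction
reported, a case the weighted-graph literature rarely spells out.

Normalization uses surrogate networks obtained by permuting edge weights
across the *retained* edge slots (topology and density preserved), 1000 per
graph by default; `surrogate = "rewire"` instead re-draws edge positions
with the same weights, for users who read "random edge weight permutations"
as full rewiring. Equal-weight graphs are permutation-invariant, so all
normalized metrics are exactly 1 there — a useful identity test.

## Pharmacological MRI response

The response model is a scaled gamma density
\(f(t) = \lambda\,\beta^\alpha t^{\alpha-1} e^{-\beta t}/\Gamma(\alpha)\)
(t in minutes post-injection). This exact form makes the two derived
summaries closed-form: total activation (AUC) is λ and peak amplitude is
\(\lambda\beta(\alpha-1)^{\alpha-1}e^{-(\alpha-1)}/\Gamma(\alpha)\) at
peak time (α−1)/β.

**Subject-level fits** (`fit_subject_gamma`) are Levenberg–Marquardt
nonlinear least squares with method-of-moments starts; α is bounded in
[1.01, 50] and β in [0.02, 20] min⁻¹ because responses slower than a
≈ 50-minute time constant are indistinguishable from drift within the
40-minute window, and letting β collapse lets λ blow up on flat series. A
fit whose implied peak lies beyond twice the observation window is treated
as non-converged and replaced by its start values. On flat data λ itself
remains loosely determined (it is an area under a curve mostly outside the
window); the identifiable magnitude is the fitted peak amplitude, and the
tests assert on that.

**Hierarchical Bayesian fit** (`fit_hierarchical`). Log-parameters
(log α, log β, log λ) of each subject × ROI series are normal around
group-level means (positivity enforced by the log link, which the source
protocol leaves open). Noise is stationary AR(1) on the frame grid with a
single lag-1 correlation φ estimated jointly — matching the generator and
the GLS analysis; with iid errors the posterior is overconfident and
credible intervals under-cover. Priors: group-level means normal, centred
on the median of the initial subject-level fits with SD 10 × their IQR
(wide, data-located); group-level SDs half-normal(1); noise variances
near-Jeffreys inverse-gamma per ROI; φ uniform on [0, 0.95]. The sampler is
Metropolis-within-Gibbs vectorized over all series, with four ingredients
that matter for mixing: (i) componentwise random walks with burn-in
adaptation; (ii) a joint (log α, log β) ridge move, because shape and rate
are strongly correlated through the peak time; (iii) collective group-shift
moves that translate a group's mean and all of its subject-level parameters
together (a hierarchical-centering move — within-group deviations, and
hence the τ likelihood, are untouched); (iv) an independence
Metropolis–Hastings update for each τ from its likelihood-implied
inverse-gamma, so the acceptance ratio reduces to the half-normal prior
ratio. Three chains, 50 % burn-in and a split-R-hat < 1.1 gate on all
group-level parameters are the convergence contract; an engine such as JAGS
would satisfy the same contract, but the bespoke vectorized sampler keeps a
20-subject × 21-ROI study within minutes on one CPU. Group-level means are
reported on the natural scale as exp(μ + τ²/2) — the mean of the implied
log-normal, which is what the generator's configured group means are — and
group differences summarize the per-draw difference of these quantities
with central 95 % credible intervals.

**GLS with continuous-time AR(1)** (`gls_ar1`) implements
Corr(εᵢ, εⱼ) = φ^|tᵢ−tⱼ| by exact Markov whitening and profiles φ out by
maximum likelihood on [0, 0.999]; φ may also be fixed (φ = 0 reproduces
OLS to machine precision). `nlme::gls(corCAR1)` serves as the independent
cross-check in the tests, never as the implementation. Coefficients can be
reported on z-scored response/predictors, matching the normalized-variable
convention of the seed-wise group tables. The voxel-level design matrix is
a three-block construction: representative gamma-variate curve
(fitted to the grand-mean time course), six motion parameters, and the
first three left singular vectors of the per-subject deviation matrix;
per-subject voxelwise GLS coefficients on the response column feed a
second-level linear model with group and physiological covariates (missing
values imputed by group means). The overall group test is a linear mixed
model with a random intercept per subject over the per-ROI AUC or peak
summaries; with zero random-effect variance and a balanced design it
coincides with ordinary regression, which the tests exploit as an oracle.

## DTI and structural connectomes

Tensors are fitted by log-linear least squares on ln(S/S0); non-positive
signals are clamped to a small ε and flagged. Eigenvalues come from the
closed-form trigonometric solution for symmetric 3 × 3 matrices (vectorized
over voxels); negative eigenvalues are clamped to zero with a per-voxel
flag before FA/MD. FA uses \(\sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert /
\lVert\lambda\rVert\); the prolate eigenvalues (1.7, 0.2, 0.2) × 10⁻³ mm²/s
give FA = 0.8704, a fixed point the tests pin.

Tractography seeds 10 uniformly random points in every voxel with FA > 0.2
(the same criterion gates propagation) and integrates bidirectionally along
the principal eigenvector of the trilinearly interpolated tensor
(interpolate components, then decompose), step 0.1 mm — about 0.4 voxel on
the 0.25 mm grid, small enough that the 35° turn threshold approximates a
curvature limit; the step size is a package choice since the reference
protocol does not state one. Termination: FA ≤ threshold, turn > 35°, or
leaving the volume. Streamlines contribute to an ROI pair when their
endpoint voxels (containing-voxel label, no dilation) carry the two labels
and the arc length is ≥ 1.0 mm; the edge weight is the mean FA sampled
along all contributing tracts, pooling all samples by default
(`per_streamline = TRUE` averages per-streamline means — the protocol does
not say which; both are provided). The resulting connectome feeds
`build_graph` unchanged, so structural and functional networks share one
graph implementation.

## Shared inference

Two-sample tests default to pooled variance (Student), consistent with
d = t√(1/n₁ + 1/n₂) reproducing printed effect sizes at n = 12 vs 15;
Welch is a flag, and d then still uses the pooled SD. Both effect-size
conversions found in this literature are provided —
`d_from_t(t, n1, n2) = t√(1/n1 + 1/n2)` and `d_from_t_df(t, df) = 2t/√df` —
without declaring either "the" convention, because reported tables in this literature mix
them. BH-FDR delegates to `p.adjust`; the tests keep a direct step-up
enumeration as the oracle. Cluster-extent thresholds are Monte-Carlo:
smooth white noise to the stated FWHM, re-standardize, threshold one-sided
at the voxel p, record the maximum suprathreshold cluster
(face-connectivity), and take the (1 − α) quantile; the contract is this
quantile definition, not any particular reference implementation's
internals. Group-mean imputation preserves observed values and group means
exactly and refuses a group with no observed value.

## Problem sizes and runtime choices

The test-suite and acceptance-script study sizes are chosen so a full run
completes in minutes on one CPU while keeping each check informative: FC
recovery uses a 4-pair atlas on a 16 × 12 × 6 grid at the full 1200 frames;
hierarchical recovery uses the full 10 + 10 subjects × 21 ROIs at 3 chains
× 3000 iterations; the identical-groups credible-interval calibration uses
6 + 6 subjects × 4 ROIs at 700 iterations per replicate; tractography
phantoms use 24 × 10 × 8 grids at 0.25 mm. Larger studies only tighten the
same comparisons.

## Known limitations

Single-tensor diffusion cannot represent crossing fibers (by design);
streamline endpoints are assigned by containing voxel only; the band-pass
mask assumes uniformly sampled frames; the hierarchical model shares one φ
and per-ROI noise variances across subjects; and all simulators assume an
axis-aligned world (world coordinate = voxel index × voxel size, 0-based),
so no rotation or shear information is carried through the NIfTI round
trip.
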