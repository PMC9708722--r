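---
title: "Methods: from perivascular diffusivity to mediated cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from perivascular diffusivity to mediated cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphnet)
```

## The model chain

`glymphnet` implements a five-stage chain: diffusion phantom (or
preprocessed DWI) → per-voxel diffusion tensor → bilateral ALPS index;
tensor field → FACT streamlines → parcellation connectome → graph
topology; and cohort table → group statistics → mediation of the ALPS →
global-efficiency → cognition pathway. This vignette records the models,
the conventions we fixed where the methodological literature leaves a
choice open, and what the synthetic data do and do not establish.

### Diffusion signal and tensor fit

The forward model is the single-tensor Stejskal–Tanner equation,
`S_i = S0 exp(-b_i g_i' D g_i)`, with b-values in s/mm² and diffusivities
in µm²/ms (= 10⁻³ mm²/s) throughout. The fit inverts it by ordinary least
squares on `ln(S_i/S0)` over the six unique tensor elements, with `S0` the
mean of the b = 0 volumes. We deliberately use plain OLS rather than
weighted least squares or outlier-rejecting variants: it is the baseline
behaviour of the standard FSL tool chain this pipeline mirrors, and it is
exactly invertible on noiseless data — the forward/inverse round trip is a
package invariant (max tensor-component error below 1e-8, in practice at
machine precision). Numerical guards: signals are floored at `1e-6 * S0`
before the log (so Rician noise can never produce `-Inf`), negative fitted
eigenvalues are clamped to zero with FA recomputed (keeping FA in [0, 1]),
and the principal eigenvector is sign-normalized to non-negative z (then
y, then x) so downstream code sees a deterministic orientation.

The axis diffusivities Dxx/Dyy/Dzz that the ALPS index consumes are the
tensor diagonal in image axes — the FSL tensor-component convention that
"diffusivity map in the x direction" denotes in the ALPS literature — not
projections onto eigenvectors.

### The ALPS index

At the level of the lateral ventricle body, projection fibers run
inferior–superior (z), association fibers anterior–posterior (y), and the
medullary veins — and with them the perivascular space — right–left (x),
perpendicular to both fiber systems. Diffusivity along x inside those
fiber regions therefore carries a perivascular component that the fiber
tracts themselves cannot explain, and the index

`ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`

is near 1 when perivascular flux contributes nothing and rises with it.
Conventions we fixed explicitly:

- ROIs are spheres (default diameter 5 mm) rasterized by voxel-center
  inclusion, no partial-volume weighting; with 2 mm isotropic voxels a
  5 mm sphere centered on a voxel center contains exactly 7 voxels.
- ROI means are taken first and the ratio applied to the means (the
  formula's notation), not per-voxel ratios averaged.
- The index is computed per hemisphere and the bilateral mean reported;
  `mean_alps = (alps_L + alps_R)/2` holds exactly by construction.
- Manual avoidance of ischemic lesions cannot be automated faithfully, so
  ROIs whose mean FA falls below 0.15 are *flagged*, not excluded.
- Voxel coordinates are 0-based everywhere at the user surface;
  millimetres appear only in ROI-radius and streamline geometry.

ALPS is invariant to a global rescaling of all diffusivities, which is why
absolute calibration of the phantom matters less than its geometry.

### Tractography and connectome

Tracking is Fiber Assignment by Continuous Tracking: from every voxel at
or above the FA threshold, step bidirectionally along the principal
eigenvector of the voxel containing the current point (nearest-neighbour
lookup — true FACT, not trilinear interpolation — chosen for fidelity to
the named algorithm and exact reproducibility). Stated parameters are the
FA threshold 0.2 and turning-angle threshold 45°; the remaining
conventions are unpublished in the source tool chain, so we fixed them:
step 1 mm (half the default voxel), length window 10–300 mm (the floor
suppresses single-voxel artifacts), one seed per voxel at the voxel
center with jitter only at higher seeding densities, termination when the
turning angle *strictly* exceeds the threshold or the next point would
leave the grid or drop below the FA threshold — so every retained point
satisfies the FA criterion. A streamline joins region pair (A, B) when its
two endpoint voxels carry labels A and B; unlabeled endpoints discard the
streamline (no dilation). Three symmetric matrices are accumulated:
streamline count, mean streamline FA, mean length.

### Graph topology

Edge weights map to lengths by `d = 1/w`. Global efficiency is the mean
over ordered pairs of `1/d_ij` with `1/Inf = 0`; characteristic path
length averages over connected pairs only, with the excluded-pair count
reported (both disconnection conventions exist; one is fixed and logged).
Local efficiency is the mean over nodes of the global efficiency of each
node's neighbour-induced subgraph; clustering is the Onnela
geometric-mean form (weights normalized by the network maximum), which
reduces to triangle density on binary graphs. Small-worldness sigma =
(Cp/Cp_null)/(Lp/Lp_null) uses Maslov–Sneppen double-edge-swap nulls
(10·|E| attempted swaps, weights travelling with edges, degree sequence
preserved exactly; a complete graph admits no legal swap and is returned
unchanged, making sigma exactly 1 there). 100 nulls by default,
deterministically seeded. The default analysis weight is the streamline
count, the most common choice in the GRETNA-style tool chain; mean-FA and
binary modes are selectable. No sparsity-threshold sweep is applied,
because the workflow this mirrors reports single per-subject values and
states no sparsity range. Shortest paths run through igraph's Dijkstra;
the test suite checks them against an independent Floyd–Warshall
implementation to 1e-12 on random weighted graphs.

### Cohort statistics and mediation

The comparison layer routes approximately normal variables to the
pooled-variance Student t (not Welch), binary variables to the Pearson
chi-square without continuity correction, and skewed counts/scores to
Mann–Whitney with a tie-corrected normal-approximation Z and no
continuity correction. The first two choices are locked by verification:
the pooled t and uncorrected chi-square reproduce the published
comparison statistics (e.g. 17.42 for MoCA, 13.64 for hypertension) from
printed summary data at their printed precision, which Welch t or
Yates-corrected chi-square do not. Logistic fits use IRLS with Wald
intervals (the SPSS convention), a percentage-scaling option for the ALPS
index (so ORs refer to one-percentage-point changes), an explicit error
on separation or rank deficiency; standardized linear regression reports
VIF = 1/(1−R²). No multiple-testing correction is applied anywhere,
matching the analysis this reproduces.

Mediation is three OLS regressions — M on {X, covariates} (path a), Y on
{X, M, covariates} (b and direct effect c′), Y on {X, covariates} (total
effect c) — with indirect effect a·b, for which `c = c′ + a·b` is an
algebraic identity on a common sample (asserted to 1e-10 on every fit).
Inference is a seeded case-resampling percentile bootstrap, 5000 draws by
default. The mediation ratio is indirect/total by default; because the
literature is ambiguous about whether such ratios are indirect/c or
indirect/(|direct| + |indirect|), both are implemented and the choice is
recorded in the result. Covariates default to age, sex, education.

## The synthetic data: what they emulate, and what they do not

**DWI phantom.** Atlas-aligned by construction (x right–left, y
anterior–posterior, z inferior–superior), eliminating the registration
step that is out of scope: the ALPS arithmetic needs only axis-aligned
diffusivities. Geometry: a CSF ventricle proxy (isotropic 3.0 µm²/ms)
flanked bilaterally by projection bundles (z-axis, λ∥ = 1.2, λ⊥ = 0.3)
and association bundles (y-axis, same profile) in an isotropic 0.8
background, on a 40×40×20 grid of 2 mm voxels. The perivascular effect is
a single additive x-axis diffusivity Δ inside the bundles (the bundles
are drawn only at the periventricular level, so the whole bundle is the
"shell"). Defaults make the truth legible: Δ = 0.24 gives ALPS
0.54/0.30 = 1.8 (the VCI-level group mean), Δ = 0.285 gives 1.95 (the
NC-level mean). Gradients are 64 deterministic directions (spherical
Fibonacci lattice plus a fixed number of antipodally-symmetric repulsion
steps) plus one b = 0 volume at b = 1000 s/mm², matching the acquisition
protocol counts. Noise is Rician with snr = S0/σ defined at b = 0;
snr = ∞ bypasses the noise path entirely, so noiseless output is bitwise
reproducible. The phantom does **not** model susceptibility or eddy
distortion, motion, multi-shell acquisitions, crossing fibers, or any
quantitative lesion effect on local diffusivity (no such model is
published for this context); passing phantom tests therefore shows the
*computation* is right, not that the index is robust to real-world
artifacts.

**Tract phantom.** Tubular bundles along voxel polylines with the
principal axis along the local tangent (prolate tensors λ = 1.4, 0.2,
0.2, FA ≈ 0.84) in an isotropic background (FA = 0), with end-caps (6 mm)
labeled by region. It exercises sensitivity (a straight bundle must
connect its two regions) and specificity (a 90° kink must stop tracking
at the 45° threshold), not realistic fanning, kissing or crossing
configurations.

**Cohort simulator.** Per-group ALPS draws (NC 1.95 ± 0.11, VCI
1.80 ± 0.16), demographics and risk-factor prevalences matching the
published group summaries, and the structural model Eg = α + a·ALPS + ε₁,
MoCA = µ + c′·ALPS + b·Eg + covariate terms + group shift + ε₂, clipped
to the instrument's [0, 30] range. Defaults: a = 0.02, b = 373,
c′ = 15.14 (so the implied indirect effect a·b = 7.46 with roughly a
third of the total routed through Eg), Eg intercept 0.1625 and residual
SD 0.006 (placing group Eg means near 0.20), MoCA residual SD 2.5, and a
−7-point VCI group shift representing vascular injury routed through
neither ALPS nor Eg — needed because the published group MoCA gap is far
larger than the ALPS pathway alone explains. Lacune counts are negative
binomial, WMH volumes log-normal, EPVS scores categorical, all matched to
the published medians/IQRs at the distribution-family level. The
simulator encodes linear, homoscedastic, normally-residualed structural
equations; it does not model measurement error in ALPS or Eg, non-linear
dose–response, or informative missingness (there is none).

## Simulation study design choices

Two mediation simulation studies back the package's validation, and their
conditions are themselves design decisions:

- *Recovery*: a = 0.04, b = 75 (true indirect 3.0), n = 300 per cohort,
  200 replicate cohorts. Residual SDs for this scenario (Eg 0.01, MoCA
  1.5) were sized so the Monte-Carlo SE of the 200-replicate mean is
  about 1% of the truth — small enough that a genuine bias at the 5%
  level cannot hide in simulation noise. The outcome intercept places
  MoCA mid-scale (NC mean ≈ 22): a bounded score generated near its
  ceiling is right-censored, and censoring attenuates the mediator path,
  so a ceiling-adjacent scenario would measure the censored estimand
  rather than a·b.
- *Null coverage*: a = 0 with otherwise default cohort parameters,
  n = 150, 200 replicates, 95% percentile CIs from 1000 draws. The
  percentile bootstrap's true small-sample coverage in this design is
  close to (and can fall slightly below) the nominal 95%; this is a known
  property of the percentile method, not of this implementation, and does
  not improve at 5000 draws.

Problem sizes elsewhere: phantom fits use the full 40×40×20 grid; the
noise-bias study (snr = 30, 50 realizations) runs on a geometrically
identical 24×24×12 grid; graph checks use 30-node random graphs (50
draws) and 100-node reference graphs with 100 nulls; type-I calibration
uses 2000 null draws per test at n = 30 per group. These are the sizes at
which each quantity's Monte-Carlo error is comfortably inside the
tolerance being asserted.

## Known limitations

- ROI placement on real data must be supplied by the user (atlas
  registration is out of scope); phantom mode uses ground-truth centers.
- Single-tensor FACT cannot represent crossing fibers; connectomes on
  real brains would inherit the usual deterministic-tractography biases.
- The percentile bootstrap's small-sample undercoverage (above) applies
  to any PROCESS-style analysis at these sample sizes.
- The simulators share distribution families, not raw data, with the
  original cohort; quantities that depend on patient-level joint
  structure (published ORs, the cohort's indirect effect 7.46) are
  covered by parameter-recovery properties, not reproduction.
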