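---
title: "Methods: cortical microstructure and psychosexual development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortical microstructure and psychosexual development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexmicro)
```

## What this package computes

`cortexmicro` implements an adolescent neuroimaging analysis relating two
quantitative MRI measures of cortical gray matter — T1 relaxation time
(ms), which falls with macromolecule density, and mean diffusivity
(MD, mm²/s), which rises as water moves more freely — to age, sexual
attractions and gender identity in three groups: cisgender boys, cisgender
girls, and adolescents assigned female at birth with gender dysphoria
(GD AFAB). Four analysis stages are exposed as package functions and
chained by `run_pipeline()`; every stage is exercised end to end on
seeded synthetic data, so the statistical machinery is testable without
any participant data.

## Psychosexual scoring

Two 8-item EROS subscales measure attractions to males (androphilia) and
females (gynephilia) on a 1–5 scale; the 27-item GIDYQ-AA measures gender
identity/dysphoria (lower = more dysphoria). A scale mean is computed when
at least 75% of items are answered (`score_scale()`); otherwise the score
is missing and propagates — nothing is imputed. Participants with missing
behavior values are excluded from the PLS stage with a warning.

The two EROS means $(a, g)$ are treated as a vector in the score plane:

* strength of attractions $= \sqrt{a^2 + g^2}$, the vector magnitude,
  attainable range $[\sqrt{2}, \sqrt{50}] \approx [1.41, 7.07]$;
* degree of androphilia–gynephilia
  $= \arccos(a / \sqrt{a^2+g^2}) \cdot 180/\pi$, the vector phase in
  degrees: $\approx 11°$ is exclusive androphilia, $\approx 79°$ exclusive
  gynephilia, and $45°$ exactly equal scores (the attainable range is
  symmetric, $45° \pm 33.69°$). Larger values are more gynephilic.

Equal inputs return exactly 45°: the landmark is a definitional identity,
so floating-point rounding in `acos()` is not allowed to blur it. Display
rounding is half-up to two decimals (`round_half_up()`); all internal
computation keeps full precision. A GIDYQ-AA mean strictly below 3.00
flags likely gender dysphoria; 3.00 itself does not.

Reverse-keying of GIDYQ-AA items is not modeled: items are averaged as
given, which matches scoring conventions in which the instrument's items
are already aligned before data entry.

## ROI extraction from volumetric maps

`extract_all()` reduces co-registered volumes (metric map, gray-matter
probability map, integer atlas labels for 76 cortical ROIs — 38 bilateral
regions of the AAL parcellation, bundled as a lookup table) to one scalar
per ROI:

* Voxels enter only when they carry the ROI label **and** their
  gray-matter probability is strictly greater than 0.40. Equality is
  excluded; tests verify that corrupting every sub-threshold voxel leaves
  all summaries bit-identical.
* **T1**: values strictly inside (500, 5000) ms are binned at 30 ms; a
  cubic interpolating spline (`stats::splinefun`, FMM end conditions) is
  fitted through the (bin center, count) pairs over the occupied support,
  and the mode is the abscissa of the spline maximum on a 1 ms grid. The
  mode rather than the mean is used because partial-volume mixing with CSF
  skews T1 distributions to the right, which would otherwise overestimate
  the ROI's T1. An interpolating spline is used, not a smoothing spline:
  a smoothing parameter would be one more unreported degree of freedom,
  whereas interpolation plus a fixed evaluation grid is exactly
  reproducible. With fewer than four occupied bins the spline is
  unreliable and the max-count bin center is returned with a warning.
* **MD**: the arithmetic mean of values inside (0.0005, 0.004) mm²/s. The
  histogram range doubles as an outlier gate before averaging
  (`gate = FALSE` disables it). The MD bin width is 5×10⁻⁵ mm²/s — a
  width of "50" in the map's native 10⁻⁶ mm²/s unit, 70 bins over the
  range — mirroring the T1 convention of stating the width in map units.
* ROIs with fewer than 10 qualifying voxels are flagged and excluded from
  downstream matrices; absent labels are reported by name.

## Group comparisons

For age, GIDYQ-AA, strength and degree: classical one-way ANOVA
(`stats::aov`) with unadjusted LSD post hocs on the pooled error term;
Levene's test on absolute deviations from the **group mean** (the default
of the commercial package this analysis family is usually run in); and,
for variables with unequal variances, the Welch test
(`stats::oneway.test`), the Brown–Forsythe variance-weighted F with
Satterthwaite degrees of freedom, and Games–Howell post hocs (Welch-type
SE, Welch–Satterthwaite df, studentized-range reference). Games–Howell and
Brown–Forsythe are implemented in the package because no installed
dependency provides them; tests pin them to the two-group Welch t-test
reduction and to their textbook formulas. Two-tailed α = 0.05 throughout;
p-values render as "<0.001" below three decimals.

## The T1→MD multilevel model

The association between the two metrics across cortex is tested with a
two-level model: MD observations (76 per participant) regressed on T1 with
a fixed slope and a random participant intercept, fitted by full maximum
likelihood with `lme4::lmer` (ML, not REML, matching the default of the
SEM software this model family is typically fitted in; `reml = TRUE` is
available and the difference is examined in tests). Both variables are
grand-standardized — z-scored across all observations, not within
participant — because the question is the overall T1–MD association across
regions and participants; the slope is therefore the standardized
estimate, with a Wald normal-reference p. Sample SDs (not model-implied
SDs) define the standardization. `mlm_loglik()` evaluates the marginal
Gaussian likelihood directly (Sherman–Morrison within clusters, GLS for
the fixed effects) and is used in tests as an independent check that the
fitted variance components sit at the profile-likelihood optimum on a
21×21 grid. Random slopes, crossed ROI effects and sandwich SEs are out of
scope by design.

## Behavior PLS

The brain block is the participants × 152 matrix (76 T1 columns then 76 MD
columns), z-scored per column across all participants so metric-specific
ranges cannot dominate. The behavior block is (strength, degree, age in
months); behaviors are not rescaled because within-group Pearson
correlation is scale-invariant. For each group the three behaviors are
correlated with every brain column; stacking the three 3 × 152 blocks
group-major gives the 9 × 152 cross-block matrix $R$, decomposed as
$R = V S U^\top$. Each latent variable (LV) carries behavior/group
saliences (a column of $V$), brain saliences (a column of $U$), and a
singular value whose squared share, $100 s_i^2 / \sum_j s_j^2$, is the
percentage of cross-block covariance explained. Signs are fixed by making
the largest-magnitude element of each $V$ column positive (ties: lowest
row index). Brain scores are $X u$.

**Permutation test** (default 1000 samples): rows of the brain block are
permuted across the whole sample while behavior and group assignment stay
fixed — the standard exchangeability null between brain and behavior; a
within-group-only scheme is available behind a flag
(`within_group_perm`). The whole pipeline (cross-block + SVD) is re-run
per permutation and $p_i = (\#\{s_i^{perm} \ge s_i\} + 1)/(n_{perm}+1)$,
so a never-exceeded LV reports the resolution floor (rendered as e.g.
"<0.001"), never 0.000.

**Bootstrap** (default 1000 samples): participants are resampled with
replacement within groups (sizes preserved; resamples with a constant
behavior are redrawn and counted). Each resample's $(U, V)$ is aligned to
the original by the orthogonal Procrustes rotation of its $V$ block —
without alignment, axis reflections between resamples inflate the SEs.
The bootstrap ratio (original salience / bootstrap SE) approximates a
z-score; $|ratio| \ge 3$ marks a stable contribution. 95% percentile
intervals are reported for the nine within-group brain-score–behavior
correlations per LV. All nine LVs are retained and tested independently.

## The synthetic-data generators

`generate_cohort()` draws, per participant, a degree (phase) from a
truncated normal on the attainable range whose location is solved
(`uniroot`) so the post-truncation mean equals the group target; then a
strength (magnitude) from a truncated normal over the phase-conditional
attainable interval, with a single location solved so the marginal mean
over the realized phases hits the group target. Item responses are emitted
by a mean-preserving discretization: a symmetric perturbation clipped to
the distance to the nearer scale bound, then randomized rounding, so
$E[\text{item} \mid \text{latent}] = \text{latent}$ with no boundary
bias. Defaults are the study's group sizes (14/15/17), per-group month
ranges, and the reported group means/SDs for strength (3.25/2.98/2.83),
degree (64.60/46.99/30.94) and GIDYQ-AA (≈4.9 cis, ≈2.2 GD).

Two features of the real data are knowingly not emulated. First, the
strength and degree targets are *marginal* moments, but the score plane
couples them (a 75° phase forces a magnitude above $1/\cos 75°$); group
means are matched in expectation, while SDs compress where a target sits
near the attainable boundary. Second, item-level covariance beyond the
participant latent is not modeled — only scale-level statistics are
reported for the instruments, so anything richer would be invented.

`generate_brain()` plants, in the cisgender-boy and GD AFAB groups only, a
rank-1 effect on a behavior composite (z-scored strength, degree, age with
equal weights): negative loadings on 29 T1 columns and positive on 9 MD
columns, matching the published stable-ROI spatial pattern, so that
shorter T1 and faster MD accompany older age and stronger gynephilia. The
default loading (0.5 SD per unit composite) was fixed a priori as a
moderate single-column effect; its aggregate over 38 columns makes the
latent variable reliably detectable at 50 participants per group, while at
the study's 46 participants detection is borderline — sampling variability
at that size is real and the package does not pretend otherwise. MD
columns are generated as `MD = 0.089 · T1 + intercept + residual` with an
intercept ICC of 0.5, so the multilevel stage has a known standardized
slope to recover. T1 columns carry their own participant intercept (share
0.3). Physical scales use *flat* per-metric baselines (1700 ms, 9.5e-4
mm²/s): correlated between-ROI baseline profiles would enter the
grand-standardized T1→MD model as covariance unrelated to the planted
within-ROI coupling. Real cortices do have correlated regional profiles;
consequently, passing recovery tests here validates the estimator, not the
claim that regional profiles are flat.

`generate_phantom()` lays one cube per ROI on a lattice: a gray-matter
core (probability 0.95) inside a same-labeled rind at probability 0.30
whose metric values are deliberately extreme, so any leak through the
>0.40 gate is caught. Core T1 values come from shifted gamma distributions
with analytically known modes, sampled at stratified quantiles so the
empirical histogram tracks the density closely and mode recovery is sharp
(the extraction tests require every ROI within the 30 ms bin width, and
the workflow's phantom stage prints the realized maximum error); core MD is
constant per ROI.

All generators are pure functions of (spec, seed); `derive_seeds()` gives
each pipeline stage its own sub-stream so toggling one stage never
perturbs another.

## Numerical choices and degenerate inputs

* Permutation p-values use the add-one estimator; they can never be 0.
* Zero-variance brain columns, behaviors constant within a group, and
  singular designs raise errors naming the offender; empty voxel
  selections and sparse histograms return flagged results, not errors.
* The truncated-normal location solver brackets adaptively and treats
  far-outside locations as mass collapsed on the nearer bound
  (post-truncation means are monotone in the location, so the root is
  unique).
* SVD sign indeterminacy is resolved once, deterministically; bootstrap
  rotation uses the Procrustes solution $Q = AB^\top$ from the SVD of
  $V_{boot}^\top V_{orig} = A \Sigma B^\top$.

## Problem sizes used by the test suite

The suite checks size and recovery claims at scales chosen to keep the
checks sharp but routine to run: the permutation-test size uses 500 null
cohorts of 45 participants with 200 permutations each; multilevel recovery
uses 200 replicates of 46 clusters × 76 observations; planted-effect
recovery uses 50 participants per group with 1000 permutations and 1000
bootstrap samples; phantom fidelity uses the full 76-ROI grid. The
deterministic reproduction of the published Welch statistic, standardized
slope and covariance share (`reproduce_study()`) runs only where a local
copy of the public data deposit exists, since the package ships no
participant data.

## Known limitations

* The cohort generator matches group means (and approximately SDs) of the
  psychosexual variables but not their higher moments or the reported
  age–strength correlations (injectable via a shared latent factor is out
  of scope; correlation defaults to none).
* The phantom is an already-fitted metric map on axis-aligned cubes; no
  acquisition physics, registration error or segmentation noise is
  simulated.
* Bootstrap stability counts are sensitive to resampling noise at small
  n; qualitative patterns (which groups carry the effect; planted vs null
  columns) are the tested claims, not exact stable-ROI counts.
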