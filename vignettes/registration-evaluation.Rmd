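---
title: "Evaluating ASL-to-T1w registration on phantoms with known ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ASL-to-T1w registration on phantoms with known ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and design

`aslregsim` evaluates how the choice of ASL-to-T1w registration strategy
propagates into regional perfusion analyses. Everything runs on synthetic
phantom participants whose ground truth — anatomy, boundary surface, true
CBF map, true rigid transform, injected group effects, severity coupling —
is known by construction, so every stage of the pipeline can be tested
against an analytic or brute-force oracle rather than against another
implementation.

The pipeline is: simulate a pCASL acquisition per participant; quantify a
mean CBF map; gate it with a quality index; align it to the structural
volume with three strategies (emulated-manual, rigid intensity-based,
boundary-based refinement of either); project CBF to the gray/white
boundary surface; parcellate; and run the two families of statistics that
depend on alignment quality — the pairwise inter-subject correlation (CC)
consistency framework and ROI-wise group comparisons with Bonferroni
control.

## The phantom

The anatomy is a set of nested shells around a common centre: a
white-matter core bounded by the analytic radius function

$$R(\theta,\phi) = r_{ell}(\theta,\phi)\,\bigl(1 + A\,g(\theta,\phi)\bigr),$$

where $r_{ell}$ is the radius of an ellipsoid with semi-axes 56/66/44 mm
and $g$ a fixed low-order angular harmonic (terms in $\sin^k\theta
\cos(m\phi)$, vanishing at the poles); around it lie a gray-matter ribbon
of constant 9 mm radial thickness and a 5 mm CSF shell. Two deliberate
departures from a plain ellipsoid matter:

* **Boundary ripple** (`boundary_ripple`, default 0.08, i.e. bumps of a few
  mm). A smooth ellipsoid is almost rotationally degenerate for a
  boundary-driven cost: sliding samples along a surface of constant
  intensity changes nothing, so rotations would be unidentifiable. The
  ripple is the phantom's stand-in for cortical folding and is what lets
  BBR (and, to a lesser degree, the intensity cost) see rotations. It is
  analytic, so boundary vertices and outward normals are exact.
* **Perfusion texture** (`cbf_texture`, default 0.15). True GM CBF is
  $60\,(1 + 0.15\,t(\theta,\phi))$ mL/100g/min with a second fixed
  harmonic $t$. This shared angular topography is what makes two
  well-registered participants correlate: without it, surface CBF maps are
  nearly constant and pairwise CC would measure only noise.

Baselines are GM 60 and WM 20 mL/100g/min (physiological convention),
T1w-like tissue intensities WM > GM > CSF (1000/600/200). Grids: the ASL
grid defaults to the acquisition being emulated — 64×64 in-plane, 34
slices, 3.75 mm isotropic — while the structural grid is configurable
(the bundled analyses use 48³ at 4 mm to keep runtimes in minutes; the
same code runs at any resolution).

## Forward simulation and quantification

Each acquisition is 14 label/control pairs (28 volumes) plus a separate
noise-free M0. The label-control difference is the exact closed-form
inverse of the quantification model, evaluated on the true CBF map carried
into the participant's ASL space through the inverse of the true rigid
transform (drawn uniformly within ±5 mm / ±5° per axis). Each volume's
static tissue signal is modulated by a multiplicative radial sinusoid with
per-pair random phase and wavelength — the "ringing" artifact of
stack-of-spirals readouts. Because the artifact is an acquisition-state
effect, it is identical within a pair and cancels exactly in the
control − label subtraction; additive Gaussian noise (`noise_sd`, default 1
signal unit ≈ 4 mL/100g/min per-voxel in the 14-pair mean CBF) does not.

Quantification applies the single-compartment pCASL closed form

$$\mathrm{CBF} = \frac{6000\,\lambda\,\Delta M\,e^{PLD/T_{1b}}}
{2\,\alpha\,T_{1b}\,M_0\,(1 - e^{-\tau/T_{1b}})}$$

with τ = 1.8 s, PLD = 1.8 s, α = 0.72 (constants of the emulated
acquisition) and T1b = 1.65 s, λ = 0.9 mL/g (consensus physiological
defaults — documented parameters of `acquisition_params()`, chosen by
convention rather than measured).
Voxels with non-positive M0 are masked. At zero noise the
simulate→quantify round trip is exact to floating-point (the test suite
asserts ≤ 10⁻⁶ relative; measured ~10⁻¹⁴). Motion correction registers
each volume to a reference with the same rigid engine; the simulated
series has no inter-volume motion, so the experiment driver leaves it off
by default and it is exercised separately (identity recovery, injected
2 mm shift).

## Quality gate

The QEI combines three interpretable components multiplicatively:
`max(0, r)` for the Pearson correlation of the map with a
segmentation-derived pseudo-CBF (GM:WM = 2.5:1), `1/(1 + CV)` for the
spatial coefficient of variation of GM CBF, and `1 − negfrac` for the
fraction of negative GM voxels. The form is increasing in structural
plausibility, decreasing in spatial noise and in non-physiological
negativity, invariant to global positive rescaling, and maps to [0, 1].
The exclusion rule is strict: a participant is kept only when QEI > 0.4.
An ideal map by construction scores ≈ 1, the study-noise maps ≈ 0.7, and
structureless or sign-flipped maps ≈ 0 — the gate separates them by a wide
margin (asserted in the tests rather than tuned).

## Registration

**Emulated manual.** Ground truth perturbed by seeded Gaussian operator
error, default 1 mm and 1° SD per axis (a placeholder for interactive
alignment accuracy, configurable). This is the benchmark method, and its
error budget is deliberately larger than the automated residuals.

**Rigid intensity engine.** 6-DOF transforms parameterised as rotations
(degrees, Rz·Ry·Rx) about the fixed-image mask centroid plus translation.
Cost: the correlation ratio of moving-image samples conditioned on 32
fixed-intensity bins, evaluated at up to 8000 head-mask points over a
three-level stride pyramid. Optimizer: deterministic compass (pattern)
search with step halving — every accepted step strictly decreases the
cost, initial steps 4 → 1 → 0.25 (mm / degrees) per level, convergence at
0.02. Samples falling outside the moving image are dropped; if fewer than
25% remain the cost is pegged high, and a result whose cost did not
decrease is flagged failed (the operational analogue of a
failed-registration count, with no visual QC step).

**Boundary-based refinement.** For each boundary vertex $v$ with outward
unit normal $n$, the moving image is sampled at
$T^{-1}(v \pm d\,n)$ and scored as $1 - \tanh(s\,\sigma\,Q_v)$ with the
percent contrast $Q_v$ defined above ($\sigma = +1$ because GM CBF exceeds
WM CBF); the total cost is the mean over vertices with both samples in
volume, and an initialization with under 50% valid vertices is rejected.
Defaults that required a choice:

* `offset_distance` d = 3 mm. At 3.75 mm voxels a 2 mm offset samples
  inside the partial-volume zone of the boundary voxel, which displaces
  the cost minimum; 3 mm clears most of the blur while staying inside the
  9 mm ribbon.
* `slope` s = 0.01 per percent. The phantom's GM/WM contrast gives
  $Q \approx 100$; at the FreeSurfer-style 0.5 the tanh saturates to
  machine precision and the cost has no usable gradient. 0.01 puts typical
  contrasts at tanh(1), in the responsive range.
* 6-DOF by default, with a 12-parameter affine option (rotation,
  translation, log-scales, shears about the vertex centroid) for the
  more-degrees-of-freedom variant.

The same pattern-search optimizer refines from the emulated-manual or the
rigid result, yielding `manual+BBR` and `FLIRT+BBR`.

**A documented accuracy floor.** With symmetric-offset sampling across a
*curved* boundary, the per-vertex contrast is not maximised exactly on the
surface: curvature and the asymmetric GM profile (CSF beyond the outer
edge) displace the cost optimum by ~0.3° in rotation on this geometry.
The effect is intrinsic — it does not shrink with finer grids, analytic
voxel-averaged forward models, smoothing (which enlarges it), or
symmetrised ripple patterns — so refinement started at truth stays within
0.2 mm but only within ~0.5° of truth. Consequently BBR cannot out-rotate
the rigid engine on this phantom: with the *mean CBF* image as the moving
image (rather than a single ringing-contaminated volume), the
correlation-ratio engine is already at a sub-voxel floor (~0.1 mm / 0.1°
median, even at study noise). What the simulation does reproduce — and
what the consistency framework measures — is that both automated routes
sit far below the manual error budget, that BBR rescues the
manual initialization (residuals drop from ~1.6 mm / 1.7° to
~0.08 mm / 0.5°), and that the two BBR variants agree to well under
0.01 in mean participant CC.

## Surfaces, parcels, consistency

CBF is sampled at each vertex displaced +1 mm along its outward normal
(mid-ribbon side of the interface; the projection fraction is a
configurable choice, not a datum), through the inverse of each method's
transform, trilinearly; out-of-volume vertices are flagged invalid and
excluded pairwise. The parcellation is a seeded farthest-point partition
of the boundary into exactly 219 contiguous, nonempty parcels — a
cardinality-faithful stand-in for a cortical atlas. Because all phantoms
share the mesh, parcel ids correspond across participants by construction,
which plays the role of template-space normalization in the consistency
framework.

Pairwise CC enumerates each unordered within-group pair once (n(n−1)/2:
1225/210/91 for groups of 50/21/14, 301 for the combined patients) over
vertices valid in both maps; a participant's consistency score is the mean
of its n−1 pair CCs, and the mean of those means equals the mean of all
pair CCs exactly. Method comparisons run paired t-tests on per-pair
differences by default; a pooled two-sample mode (df = 2·n_pairs − 2) is
provided because both df conventions appear in practice, and Cohen's d is
always the pooled standardised mean difference. Group comparisons of mean
participant CC use the pooled two-sample t (df = n₁ + n₂ − 2, e.g. t(62)
for 50 vs 14). No correction is attempted for the dependence among pairs
sharing a participant.

## Group statistics

ROI-wise two-tailed two-sample t-tests (pooled variance by default, so
df = n₁ + n₂ − 2 as in t(33) for 21 vs 14; Welch by flag) serve both the
CBF (hypoperfusion) and ROI-volume (atrophy) contrasts, Bonferroni-corrected
over 219 tests at pFWE < 0.05. Severity regressions are per-ROI OLS with
CBF as response, reported uncorrected at p < 0.05, participants lacking a
score excluded; an inverse association is a negative slope. Demographic
comparisons use pooled t-tests for ordinal covariates and chi-squared
(no continuity correction by default) for sex. Degenerate inputs are
handled explicitly: zero-variance parcels yield t = 0 / p = 1 when means
agree, groups below 2 observations are skipped with a log entry, and
single-pair paired comparisons return NA rather than a fabricated
statistic.

Calibration of this engine runs on a light generative path
(`generate_roi_cohort()`) that draws parcel means from the same effect
model as the voxel pipeline without rendering images; this is what makes
100-replicate FWER and 1000-replicate slope-recovery studies affordable.
The voxel pipeline and the light path share the effect parameterisation,
so effect conservation (realised ROI ratio = 1 − reduction) is asserted on
the voxel path directly.

## Group effects and the synthetic cohort

Each non-control group carries: a multiplicative CBF reduction in a set of
affected parcels; an atrophic thinning of the GM ribbon in those parcels
(per-participant multiplier 0.7–1.3 around the group mean, so ROI volumes
vary within groups); and a linear severity coupling
(CBF shift = slope × severity + noise) with severity drawn uniformly on
1–12 for patients and fixed at 0 for controls. The bundled experiment uses
a compact frontal-type pattern (5 parcels, 20% reduction, slope −1) and a
broader temporal-type pattern (8 parcels, 30% reduction, slope −1.5).
These effect sizes are study-design choices for power on desk-scale
cohorts — real regional effect magnitudes are unknown here — and
are not estimates of any real population.

Seeding is hierarchical: master seed → per-participant stream → per-stage
stream, so adding a participant never perturbs the draws of the others,
and identical seeds give bit-identical cohorts and output tables.

## What passing tests do and do not show

The phantom demonstrates that the pipeline's machinery is correct (exact
kinetic inversion, oracle-equal statistics, FWER control, unbiased slope
recovery) and that the consistency framework ranks registration methods as
designed when operator error dominates automated residuals. It does not
demonstrate performance on real cortices: there is no realistic folding
geometry, no EPI distortion, no partial-volume or background-suppression
physics beyond grid resampling, no scanner or site effects, and
inter-subject anatomical variability is limited to regional thinning. CC
magnitudes on phantoms (~0.3–0.7 here) are therefore not comparable to
values on real cohorts, where population variance caps attainable CC;
only their ordering across methods is meaningful.

## Problem sizes used in the bundled runs

The analyses and the acceptance script run at a 48³ × 4 mm structural grid
with the full 64×64×34 × 3.75 mm ASL grid, a 3122-vertex boundary mesh,
cohorts of 8–18 participants for the imaging stages, and 100–1000
replicates for the table-level statistical calibrations. All sizes are
arguments; the same code runs unchanged at finer grids and larger cohorts.
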