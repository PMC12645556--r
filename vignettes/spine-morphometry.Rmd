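---
title: "Quantifying spinal deformity, differential proteomes and calcium transients with spinemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spinal deformity, differential proteomes and calcium transients with spinemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

# What the package models

Recessive mutations in *RYR1*, the skeletal-muscle calcium-release channel,
impair muscle spindles — the stretch receptors whose proprioceptive input
helps maintain spinal alignment — and mouse models carrying such mutations
develop scoliosis and kyphosis. Quantifying that phenotype from micro-CT
requires a chain of small, well-defined computations, and this package
implements each link as a tested, reusable unit:

1. **Centerline geometry.** A mouse spine annotated as per-vertebra landmark
   rings is collapsed to vertebral centroids and fitted with a parametric
   cubic spline $\gamma(t) = (\gamma_x(t), \gamma_y(t), \gamma_z(t))$,
   $t \in [0,1]$, from which curvature
   $\kappa(t) = \lVert\gamma'(t)\times\gamma''(t)\rVert / \lVert\gamma'(t)\rVert^3$
   and radius $r(t) = 1/\kappa(t)$ follow analytically.
2. **Cobb angles.** The standard scalar severity measure of scoliosis
   (coronal plane) and kyphosis (sagittal plane), computed automatically as
   the maximum angle between centerline tangents in the projection plane.
3. **Population comparison.** A two-sample permutation test on per-spine
   curvature summaries.
4. **Differential proteome filtering.** The retention rule used for
   spindle (intrafusal-fibre) proteomics: at least 2 peptides, $q \le 0.05$
   and a fold change of at least 20% in either direction.
5. **Calcium-transient kinetics.** $\Delta F/F_0$, time to peak, half time
   to peak and half relaxation time of electrically evoked transients
   sampled at 300 frames/s.

Raw micro-CT, proteomics and imaging data are replaced by seeded synthetic
generators with known ground truth, so every stage is testable end to end.

# The flat-ended spline centerline

## Construction

Vertebral centroids $p_1,\dots,p_n$ (rostral to caudal, $n \ge 4$) are
assigned knot parameters by normalized cumulative chord length, and each
coordinate is interpolated by a **natural cubic spline**: the unique $C^2$
piecewise cubic with $\gamma''(0)=\gamma''(1)=0$. Since
$\gamma''=0 \Rightarrow \gamma'\times\gamma''=0 \Rightarrow \kappa=0$, the
ends of every fitted centerline are exactly flat. This realizes the
biological modelling choice that the first and last annotated vertebrae
border the head and tail, where the annotation stops and any apparent
curvature would be an artifact of truncation. The natural spline is also the
minimizer of the bending energy $\int \lVert\gamma''\rVert^2\,dt$ among all
$C^2$ interpolants, so no other interpolating construction satisfies the
flat-end constraint with less curvature.

Coordinates follow a right-handed convention — x medio-lateral, y
dorso-ventral, z rostro-caudal — which fixes "coronal" (x–z, normal y) and
"sagittal" (y–z, normal x) unambiguously. Uniform parametrization is
available as a sensitivity option; chord length is the default because it
keeps $\lVert\gamma'\rVert$ nearly constant, which stabilizes the curvature
denominator.

## The boundary layer, and what "interior" means

Flattening the ends is not free. For data sampled from a curve whose true
second derivative does not vanish at the ends (a circular arc, say), forcing
$\gamma''=0$ there introduces an error that propagates inward, attenuating
by a factor $2-\sqrt{3}\approx 0.268$ per knot — the classical decay rate of
natural-spline boundary effects. Three knots in, a boundary error of 100%
has decayed below 2%. The package therefore treats the first and last
**three knot spacings** as the *flat-end boundary layer* and reports
curvature accuracy on the interior beyond it. For the reference case used
throughout the tests — a 60° arc of radius 20 mm annotated at 24 vertebrae —
the interior fitted $\kappa$ is within 2% of $1/R = 0.05\,\mathrm{mm^{-1}}$
(measured maximum 1.9%), while inside the layer the error grows to ~4% at
2.3 knots and reaches 100% at the ends by construction.

The same mechanism costs the fitted curve a little tangent rotation at each
end: roughly $\tfrac{2}{3}$ of one inter-vertebral rotation step per end.
For a circular arc of subtended angle $\phi$ sampled at $n$ stations the
automated Cobb angle therefore underestimates $\phi$ by about
$\tfrac{4}{3}\,\phi/(n-1)$ — e.g. ~1° for a 35° arc at 24 stations. This
bias is a property of the flat-end model, not of the implementation; it
vanishes as sampling densifies (0.1° at 200 stations) and is absent for
deformities whose curvature genuinely tapers at the ends (the S-curve
family below recovers its Cobb angle to <0.01° at 24 stations).

## Smoothing for noisy landmarks

With `smoothing = 0` the spline interpolates the centroids — appropriate for
noise-free geometry checks. Real landmark placement is noisy, and the Cobb
angle, being a maximum over tangent pairs, is an extreme-value statistic
that *inflates* under interpolated noise (about +3° at 0.2 mm landmark
noise on a 15° arc). `fit_spine_curve(..., smoothing = "gcv")` first
smooths each coordinate with a cubic smoothing spline whose penalty is
chosen by generalized cross-validation, then re-interpolates naturally so
the flat-end constraint still holds exactly. GCV smoothing reduces the
noisy-Cobb bias to below 2° in the regimes the tests exercise (it slightly
over-smooths, trading the positive inflation for a small negative bias). A
fixed numeric penalty is accepted for users who want explicit control.

## Curvature profile numerics

Profiles are evaluated on a uniform 512-point $t$-grid. Derivatives come
from the stored polynomial coefficients, never finite differences. Arc
length and $\int\kappa\,ds$ use the trapezoidal rule on that grid; the
summaries are `max` (peak $\kappa$, first grid point on ties), `mean`
($\int\kappa\,ds / \int ds$, arc-length weighted) and `total`
($\int\kappa\,ds$, in radians — for a planar arc this is its subtended
angle). $\kappa$ below $10^{-12}\,\mathrm{mm^{-1}}$ is treated as exactly
flat and the radius reported as `Inf`, avoiding overflow; a tangent norm
below $10^{-12}$ anywhere aborts with a degenerate-tangent error rather
than returning garbage curvature.

# The analytic Cobb angle

Clinically, the Cobb angle is read between the endplates of the two most
tilted vertebrae. The automated surrogate implemented here projects the
fitted centerline into the chosen anatomical plane, orients all tangents
rostral→caudal, and reports the maximum pairwise angle between them, in
$[0, 180)$ degrees:

```{r}
arc <- generate_spine(spine_template("arc", deformity_amplitude = 35))
spine_cobb(arc, plane = "coronal")
```

For a planar circular arc the oriented tangent rotates by exactly the
subtended angle from end to end, so the analytic Cobb equals the clinical
quantity the endplate construction approximates (34.1° here rather than
35.0° — the flat-end tangent loss discussed above). Ties in the maximizing
pair are broken toward the smallest $(t_{lower}, t_{upper})$. Grid points
whose projected tangent nearly vanishes are dropped; if more than half
vanish, the curve is essentially orthogonal to the plane and the projection
aborts.

# The synthetic spine generator

`spine_template()` describes an analytic centerline — `straight`, circular
`arc` (amplitude = subtended angle, degrees), `sinusoid` (lateral amplitude,
mm) or `s_curve` — sampled at `n_vertebrae` equal arc-length stations, each
carrying a ring of 8 landmarks of radius 0.8 mm in the plane normal to the
local tangent, perturbed by isotropic Gaussian noise. Defaults (24
vertebrae, 80 mm length) approximate an annotated mouse cervical-to-lumbar
column. Ground truth (station positions, tangents, true $\kappa(t)$, true
Cobb angle) travels with every generated cloud as an attribute, so accuracy
tests never re-derive it.

The `s_curve` shape deserves a definition, because "two opposed arcs of
$a$° each" is ambiguous: two circular arcs that each rotate the tangent by
$a$ in opposite senses produce a tangent-angle *range* of only $a$, hence an
analytic Cobb of $a$, not $2a$. The generator instead uses the tangent-angle
profile $\theta(u) = a\,\sin(2\pi u)$ along normalized arc length: two
opposed bends that each deflect the tangent up to $\pm a$ about the long
axis. Its analytic Cobb is exactly $2a$, its curvature
$\kappa = |\theta'|/L$ tapers smoothly to zero at both ends (so the
flat-end fit is unbiased for this family), and it is the family used for
the "double-curve" oracle (per-bend deflection 20° ⇒ Cobb 40°).

`generate_population()` emulates a case-control cohort: per-mouse deformity
amplitudes drawn from Normal(group mean, between-mouse SD), truncated at
zero, with per-mouse landmark-noise streams derived deterministically from
a single top-level seed (`sub = (seed·1000003 + index·7919) mod (2³¹−1)`),
so cohorts are reproducible spine by spine. `study_population()` fixes the
group parameters at the motivating phenotype — arc amplitudes 2.4° (SD 0.9)
for wild-type versus 19.3° (SD 9.4) for the affected compound-heterozygous
genotype, n = 5 per group, 0.1 mm landmark noise — which are the published
group mean ± SD Cobb statistics of that design.

What the generator does **not** emulate: vertebra shape and segmentation
error (landmarks are ideal rings), kyphoscoliotic coupling between planes
(deformity lives in one plane per template), growth-related length
variation, and annotation dropout. Passing tests therefore demonstrate
correctness of the geometry pipeline under idealized annotation, not
robustness to every failure mode of real micro-CT landmarking.

# The permutation test

Groups are compared through a per-spine scalar summary (default: mean
curvature). The observed statistic is the difference of group means (or
medians); the null distribution re-assigns the pooled summaries to groups of
the original sizes. With $\binom{n_A+n_B}{n_A} \le 20{,}000$ assignments the
null is enumerated exhaustively and the p-value is exact — the 5-vs-5 study
design ($\binom{10}{5} = 252$) always enumerates, giving a smallest
achievable two-sided p of $2/252 \approx 0.0079$. Larger designs fall back
to seeded Monte-Carlo sampling with the add-one estimate
$p = (1 + \#\{|T^*| \ge |T_{obs}|\})/(B+1)$, which can never return 0.
"As or more extreme" is inclusive, with a $10^{-8}$ relative slack so
permuted statistics equal to the observed one up to float round-off count
as ties. Exhaustive mode needs no correction and reports the exact
proportion. Under the null the exact p-value is discrete-uniform, so the
type-I error at $\alpha = 0.05$ is $12/252 \approx 0.0476$ — slightly
conservative, as an exact test must be.

# The differential-protein retention rule

A protein is retained iff it was quantified on ≥ 2 peptides, has
$q \le 0.05$, and $\log_2\mathrm{FC}$ outside $[-0.321, 0.263]$. The band is
deliberately asymmetric on the log scale because it encodes "at least a 20%
change" on the *linear* scale in each direction
($\log_2 0.8 = -0.321$, $\log_2 1.2 = 0.263$); the package keeps it exactly
as published rather than symmetrizing. All comparisons are inclusive — the
published table has no boundary rows, so inclusivity is declared for
determinism, not to change any call. Excluded rows record the first failing
criterion in the fixed order peptides → q → band. Input tables may carry
either a linear `fold_change` or a `log2_fc` column, never both; the
packaged published table (38 proteins, linear FC and q as printed) partitions
into 14 up- and 24 down-regulated proteins with nothing excluded:

```{r}
filter_differential(read_protein_table(intrafusal_diff_table()))
```

Peptide counts were not published per row in that table; the fixture sets
`n_peptides = 2`, the minimum consistent with the rows having passed the
published filter. Upstream steps that *produce* the q-values (spectral
quantification, moderated tests, Benjamini–Hochberg adjustment) are out of
scope — the rule consumes their output.

# Calcium-transient kinetics

The kinetic contract, fixed here because conventions vary between
laboratories: resting fluorescence $F_{rest}$ is the mean of *all*
pre-stimulus samples; $F_{max}$ the maximum post-stimulus sample;
$\Delta F/F_0 = (F_{max} - F_{rest})/F_{rest}$; TTP the time from stimulus
to the $F_{max}$ sample; HTTP the time from stimulus to the first
rising-phase crossing of the half-amplitude level
$F_{rest} + 0.5\,(F_{max}-F_{rest})$, linearly interpolated between samples;
HRT the time from the peak to the first falling-phase crossing of the same
level, also interpolated. A trace that never decays to half amplitude gets
`hrt_ms = NA` with `hrt_defined = FALSE` rather than a fabricated value. No
smoothing precedes peak detection by default; a 3-point median filter is
available for noisy traces and is off everywhere in the test suite.

The synthetic generator produces the canonical double-exponential
$F(t) = F_{rest} + A\,(e^{-\Delta t/\tau_d} - e^{-\Delta t/\tau_r})/s$,
normalized so the analytic peak equals exactly $A$ above rest; its peak time
$t^\* = \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)$ (≈ 7.23 ms for
$\tau_r = 3$, $\tau_d = 25$ ms) and half-crossings have closed or
root-findable forms that serve as independent oracles. At 300 frames/s the
sample grid is 3.33 ms, so sampled TTP/HTTP/HRT can each be off by up to one
frame — the tests assert exactly that bound — and $\Delta F/F_0$ is exact
only when the analytic peak falls on a frame; the recovery checks place the
stimulus so that it does, isolating the estimator from grid phase.

```{r}
t_star <- log(25 / 3) * 3 * 25 / (25 - 3)          # analytic peak, ms
tr <- generate_transient(f_rest = 1000, amplitude = 1310,
                         stimulus_time = 60 / 300 - t_star / 1000)
compute_kinetics(tr)
```

# Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data at
the sizes the analyses themselves use: cohorts of 5 + 5 spines of 24
vertebrae, 512-point curvature grids, exhaustive 252-assignment permutation
nulls, 2,000 null simulations for type-I calibration, 500 for power, and
10 replicate cohorts when group means are compared to their generating
values (pooling 50 spines per group damps the $\mathrm{SD}/\sqrt{5}$
sampling noise a single 5-mouse cohort would carry). Every stochastic
component takes an explicit integer seed; generators restore the caller's
RNG state, and identical seeds give byte-identical outputs, which
`run_pipeline()` records in a JSON manifest alongside the configuration and
input digests.

# Known limitations

- The flat-end constraint biases arc-like deformities: curvature is
  unreliable within three knot spacings of the ends and Cobb angles of
  uniformly curved spines are underestimated by ~$\tfrac{4}{3}\phi/(n-1)$.
  Report curvature on the interior, or densify annotation if end behaviour
  matters.
- The analytic Cobb angle is a tangent-based surrogate; agreement with
  manual endplate-based readings is approximate by construction, and no
  claim is made of equivalence with any specific manual protocol.
- GCV smoothing is tuned for function recovery, not tangent extremes; for
  very noisy data it mildly attenuates true deformity (negative Cobb bias
  up to ~1.5° in the tested regimes).
- The permutation test compares exactly two groups on one scalar summary;
  pointwise $\kappa(t)$ comparisons with multiplicity control are out of
  scope.
- Kinetic estimates are single-transient; stimulus artifacts, multi-pulse
  trains and ratiometric calibration to absolute calcium are not handled.
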