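---
title: "Methods: centreline morphometrics of tubular organs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centreline morphometrics of tubular organs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutmorph)
```

gutmorph quantifies the 3D shape of tubular organs — motivated by the
looping adult fly gut — from traced centrelines, segmented surface meshes
and arclength intensity traces. This vignette documents the models and the
numerical choices behind each stage, what the synthetic-data generator does
and does not emulate, and the limitations a user should keep in mind.

## Centreline representation

A centreline is an ordered, unbranched polyline in micrometres, anterior
end first. Arclength parameterization assigns each point the cumulative
sum of segment lengths, giving the coordinate $s \in [0, L]$. Anatomical
landmarks (`loop_start`, `loop_end`, `R3`) are independent 3D picks made on
the image stack, so they rarely lie exactly on the trace; they are snapped
to the nearest centreline point and rejected beyond a configurable snap
radius (default 30 µm, about ten image voxels). The anterior end is defined
as the SWC root or the first CSV row — traces are assumed to start at the
proventriculus, and nothing in the data itself enforces this, so it is a
documented input convention.

Pseudolandmark resampling places $k$ points at arclengths $jL/(k-1)$ by
linear interpolation (defaults: 1000 for whole guts, 500 for the loop
region). A single interpolation pass leaves the chord spacings slightly
unequal wherever the polyline bends, so the resampler re-measures its own
chordal arclength and repeats (at most 12 passes) until consecutive
spacings agree to within $10^{-9}$ relative. The points move by far less
than the tracing noise; the payoff is that spacing-sensitive downstream
code (GPA, profile grids) sees genuinely uniform landmarks.

## Curvature, torsion, radius, tilt

Around every evaluation point the curve is fitted, per coordinate, by an
unweighted least-squares cubic in $(s - s^*)$ over the neighbourhood
$|s - s^*| < \delta$ with $\delta = 0.05\,L$ by default; derivatives are
read from the coefficients, and

$$\kappa(s^*) = |x''(s^*)|, \qquad
  \tau(s^*) = \frac{(x' \times x'') \cdot x'''}{\kappa^2(s^*)}.$$

Choices worth knowing:

* **Evaluation grid.** Profiles are evaluated at 1000 equally spaced
  points by default (`n_eval`); pass `NULL` to use the trace's own points.
* **Endpoints.** Neighbourhoods are truncated, not dropped, at the curve
  ends, so profiles span the full length; the first and last few percent
  are the least reliable samples.
* **Window bias.** The cubic cannot represent the quartic term of a curve,
  which biases $|x''|$ low by roughly $(\omega\delta)^2/14$, where
  $\omega = \kappa$ for a circle. On a one-turn helix sampled at 600
  points this is under 1%; on a tightly coiled loop stack whose total
  turning is large, $\delta = 0.05\,L$ can attenuate curvature by ~10%.
  The attenuation is monotone, so group *orderings* survive; where
  absolute recovery matters (generator round-trip tests) a smaller window
  (`delta_frac = 0.01`–`0.02`) is used.
* **Smoothing.** The profiles are low-pass filtered with a zero-phase
  (forward–backward) 4th-order Butterworth filter, cutoff 0.3 as a
  fraction of Nyquist. Low-pass routines differ in kernel detail between
  numerical systems, so only the qualitative response (DC preserved,
  high-frequency jitter strongly attenuated) should be relied on, and all
  curvature oracles use tolerant bounds. The filter is applied with
  odd-reflection padding and steady-state initial conditions, so constant
  profiles pass through bit-for-bit.
* **Torsion guard.** Where $\kappa < 10^{-6}\,\mu m^{-1}$ the torsion is
  recorded as undefined (NA), not zero, because the formula divides by
  $\kappa^2$. Downstream consumers interpolate over up to 5% undefined
  samples and refuse beyond that.
* **Normalization.** $\tilde\kappa = L\kappa$ and $L\tau$ are
  scale-invariant; a circle of any radius has $\tilde\kappa = 2\pi$.
* **Radius.** The tube radius at a centreline point is the minimum
  distance to the mesh *vertices* (not point-to-triangle), matching the
  proximity module's convention; this biases the radius low by about half
  the mesh edge length, which is immaterial on decimated microCT meshes
  and accounted for in test tolerances.
* **Tilt.** The main axis of a point set is the leading eigendirection of
  its $3\times3$ covariance matrix. Tilt is reported as
  $\arccos |V_g \cdot V_m|$ in degrees, folded into $[0°, 90°]$; the
  absolute value resolves the arbitrary sign of eigenvectors. Isotropic
  clouds (degenerate leading eigenvalue, relative gap below $10^{-8}$) are
  rejected rather than silently returning an unstable axis.

## Procrustes shape statistics

Configurations are centred, scaled to unit centroid size and iteratively
rotated to the consensus with the optimal rotation constrained to
determinant +1 — reflections are disallowed because anatomy has a fixed
chirality. Convergence is declared when the consensus moves less than
$10^{-8}$; the alignment objective is non-increasing by construction and is
exposed for inspection. Scaling is unit-size only (no per-specimen scale
refitting); this matches the convention of the standard geometric-
morphometrics toolchains (geomorph and kin).

The Procrustes ANOVA treats the flattened aligned coordinates as a
multivariate response. For each term the marginal (type III) sum of squares
is the difference in residual SS between the full model and the model with
that term dropped; continuous covariates are mean-centred before
interactions are formed. Significance uses residual randomization (RRPP):
permuted responses are reduced-model fits plus row-permuted reduced-model
residuals, the F ratio is recomputed, and

$$p = \frac{\#\{F_{perm} \ge F_{obs}\} + 1}{\text{iterations}},$$

with the observed statistic included in the reference set — hence the
familiar floor of $p = 0.001$ at 1000 iterations. Ties count toward the
rank (conservative). Because projections onto nested model subspaces
commute, the permuted statistics reduce to quadratic forms in the residual
Gram matrix, which makes 500-run calibration studies cheap. Effect size Z
is the standardized position of $\log F_{obs}$ in the permuted
$\log F$ distribution. Pairwise group comparisons measure Euclidean
distances between least-squares mean shapes and randomize residuals of a
stated null model (`~ 1` or `~ batch`), which is configurable because the
appropriate null varies by contrast.

## Elastic curvature comparison and MDS

Profiles are re-expressed on relative arclength $s/L \in [0,1]$ (normalized
curvature is already dimensionless), converted to square-root-slope
functions $q = \mathrm{sign}(f')\sqrt{|f'|}$, and registered by dynamic
programming over monotone boundary-anchored warps with local slopes from a
fixed coprime step set. The diagonal step is tried first and ties must
strictly improve, so flat (constant) profiles register to the identity.
The distance is the discretized root-mean-square difference on 200 equally
spaced $s_1$ points. Two asymmetries are resolved deliberately:

* The one-directional formula is computed in both directions and averaged,
  because MDS requires a symmetric dissimilarity.
* If the registered difference exceeds the unregistered one (possible,
  since the warp optimizes the Fisher–Rao criterion, not the plain RMS),
  the identity warp is used for that direction — registration never makes
  a pair look *more* different.

Relative distances divide by the maximum over all pairs in the analysis.
The MDS is metric least-squares: classical scaling initializes, SMACOF
majorization refines (stress is non-increasing every iteration), and
seeded random restarts guard against local minima; because classical
scaling is the starting point, exactly embeddable inputs are reproduced to
machine precision with stress ≈ 0. Group regions are summarized by
Gaussian ellipsoids with radii $\sqrt{\lambda_i \chi^2_{3}(0.95)}$.

The location test battery is applicability-driven, *not*
smallest-p-driven: univariate data use a Welch t test when both groups pass
a Shapiro–Wilk screen (paired variants when paired) and the Mann–Whitney U
(or signed-rank) test otherwise; multivariate embeddings use Hotelling's
T² under per-coordinate normality (Bonferroni-combined so the screen keeps
its nominal level) and a permutation test on the centroid distance
otherwise. Selecting the minimum p across tests would inflate the type I
error, so the selection rule is fixed, logged in the output, and
calibrated: over 500 null simulations the empirical rejection rate at
$\alpha = 0.05$ stays within $0.05 \pm 0.02$.

## Proximity

Interorgan distances are deliberately vertex-to-vertex rather than
point-to-surface: per vertex of organ X, the distance to the nearest
vertex of organ Y, computed exactly (blockwise expansion; verified
identical to a brute-force double loop). The centreline-referenced profile
resamples the gut centreline to 100 points, links each to its 20 nearest
gut-mesh vertices, and takes the minimum of their distances to the target
organ. The nearest-20 rule presumes decimated meshes — with very fine
rings the 20 links cover only part of the cross-section — so a warning
fires above $10^5$ vertices and decimation is the caller's responsibility.
Contact calling needs a distance threshold, which is inevitably a
reporting choice: the default is 5 µm (biologically meaningful organ
adjacencies in the fly abdomen sit below 10 µm), it is configurable, and
it is echoed with every result so no contact frequency is reported without
its threshold.

## Intensity profiles and the AR null

Traces are anchored at R3 (piecewise-linear rescale mapping the anchor to
50% of gut length), binned into 40 equal-width bins (left-closed,
right-open, final bin closed); each specimen contributes its per-bin mean
and the output reports across-specimen means and standard deviations. Unit
normalization maps the range to $[0, 1]$ via $(I - \min I)/(\max I - \min
I)$; the affine choice of range does not affect Pearson correlations. The
all-pairs correlation registers the intensity curve onto the curvature
curve (one direction — the curvature grid is the reference frame of the
question being asked) and computes Pearson r on the $s_1$ grid, giving
$n_{curv} \times n_{int}$ coefficients per group. The null model fits an
AR(p) process to each observed trace (least squares, Yule–Walker fallback;
order 1 by default — the lowest order that captures the dominant
short-range autocorrelation), simulates surrogate
traces, and recomputes the same correlations; stationarity is enforced via
the roots of the characteristic polynomial.

## The synthetic cohort generator

The generator exists so that every estimator has recoverable ground truth;
its defaults *are* the study conditions of the test suite. A centreline is
three joined unit-speed segments totalling `total_length`: an anterior
meander (25%), a midgut loop stack (55%) and a terminal coil (20%). The
loop stack is a helix, because a helix has spatially constant, closed-form
curvature — `loop_curvature_amp` exactly — and its axis is tilted
`loop_tilt_deg` from the body axis. A smooth random displacement field
(spline through 15 control points per coordinate, amplitude `noise_sd`)
models tracing and biological noise. Landmarks are recorded on the final
curve; R3 is the arclength midpoint of the loop region.

Default group parameters (chosen once as plausible for adult flies at
microCT scale, since no quantitative effect sizes are available to import):
females 6500 µm long, loop curvature 0.006 µm⁻¹ over 4 turns, tilt 15°,
radius 90 µm; males 5500 µm, 0.004 µm⁻¹ over 2 turns, tilt 30°, radius
70 µm; noise 30 µm. The male stack uses fewer, tighter turns so that the
coil stays compact: an open helix would dominate the whole-gut covariance
and collapse the measured tilt toward zero for *any* tilt parameter.
Specimen-level jitter is mean-preserving (±5% multiplicative on length,
curvature and radius; ±2° on tilt), so group parameter means equal the
specified values; jittered curvature is clipped to what the loop geometry
can realize. Covariates (gonad, crop volume) are log-normal with
sex-specific means, correlated with length through one shared factor.

What the generator does **not** emulate: self-contact and packing against
other organs, non-helical loop asymmetries, left–right chirality
differences, tracheal branching, realistic intensity point-spread — so
green tests certify the estimators and the statistical machinery, not the
biology of any particular dataset. Two readouts are attenuated by
construction and should be read as orderings, not absolutes: the measured
tilt (the whole-gut axis itself rotates with the loop stack) and the
curvature under the default 5% window (see above).

Tube meshes sweep a vertex ring along parallel-transport frames (no frame
twist) and close both ends, so vertex-to-centreline distance equals the
local radius up to ring discretization; a warning fires when the radius
exceeds 80% of the local radius of curvature (median-filtered so a single
tangent kink at a segment joint does not trip it). Organ pairs are built
with their poles on the separation axis, making the minimal vertex
distance equal the requested gap exactly.

## Pipeline, problem sizes, determinism

`run_pipeline()` chains the stages on one configuration (R list or YAML),
writes per-stage CSV/JSON artifacts and a manifest with MD5 checksums,
seed and effective parameters, and is idempotent: identical configuration
and seed give byte-identical data artifacts. All randomness flows from a
single seed via fixed per-stage derivations. There is no shell entry
point; the exported functions, `run_pipeline()` and `scripts/acceptance.R`
are the interface.

The test suite and the acceptance script run at desk scale by choice:
cohorts of 8–10 per sex with 400–600 centreline points, 150–300
pseudolandmarks, 200–1000 RRPP iterations, 500-run calibration studies,
and 60–200-point registration grids. These sizes keep every quantity's
sampling error well inside its assertion tolerance; the same code runs
unchanged at full scale (1000 pseudolandmarks, arbitrary cohort sizes).

## Known limitations

* Curvature/torsion estimates inherit the Taylor-window bias described
  above; choose `delta_frac` consciously for tightly coiled specimens.
* Vertex-based distances (radius, proximity) are biased by mesh
  resolution; tolerances of twice the mean edge length are appropriate.
* The elastic registration is grid-based; warps are piecewise linear with
  slopes from the fixed step set, so extremely sharp reparameterizations
  are approximated.
* The RRPP implementation targets moderate cohort sizes (tens of
  specimens, up to a few thousand coordinates); it holds the residual Gram
  matrix in memory.
* SWC support covers unbranched paths only — branching trees are a
  different data type and are rejected with the offending node named.
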