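# gutmorph

Quantitative 3D morphometrics for tubular organs traced from volumetric
images — built around the looping adult *Drosophila* gut, where organ shape
is sexually dimorphic: female guts are longer and wider, and their midgut
loops curve more tightly and tilt less against the body axis than male
ones. The package quantifies such differences from three kinds of raw
input: traced centrelines (SWC or CSV polylines, µm), triangular surface
meshes of segmented organs (Wavefront OBJ), and fluorescence-intensity
traces along the gut.

## What it computes

**Centreline differential geometry.** A centreline is arclength-
parameterized (s from 0 to L). Around every point, the curve is fitted by a
third-degree Taylor expansion over the neighbourhood |s − s*| < δ (default
δ = 0.05 L), and the Frenet–Serret relations give local curvature and
torsion:

    κ(s*) = |x″(s*)|,    τ(s*) = ((x′ × x″) · x‴) / κ²(s*)

both smoothed by a zero-phase low-pass filter (cutoff 0.3 × Nyquist).
Multiplying by L yields the scale-invariant normalized curvature κ̃ = L κ
(a circle of any size has κ̃ = 2π). Tube radius is read off as the minimum
centreline-to-mesh-vertex distance; tilt is the angle between the leading
covariance eigendirections of the loop region and the whole organ.

**Procrustes shape statistics.** Centrelines are resampled to k equally
spaced pseudolandmarks (1000 whole gut / 500 loop region), aligned by
generalized Procrustes analysis (translation, unit centroid size, optimal
rotation without reflection), and analysed by shape PCA and Procrustes
type III ANOVA whose p values come from randomizing reduced-model
residuals (RRPP; with 1000 iterations p is floored at 0.001), plus pairwise
least-squares-mean comparisons.

**Elastic curvature comparison.** Normalized-curvature functions of two
specimens are registered by minimizing the Fisher–Rao (square-root-slope)
misalignment with dynamic programming, and compared by the discretized
distance

    dist(κ̃₁, κ̃₂) = sqrt( (1/200) Σₙ [κ̃₁(sₙ) − κ̃₂(γ(sₙ))]² )

Relative pairwise distances feed a metric MDS embedding (µ₁, µ₂, µ₃) with
95% Gaussian confidence ellipsoids per group and a location test between
groups.

**Interorgan proximity.** Per-vertex nearest-neighbour distances between
organ meshes; centreline-referenced proximity profiles (100 points, each
linked to its 20 nearest gut-mesh vertices); cohort contact frequencies at
a stated threshold.

**Intensity profiles.** Traces are anchored at the R3 landmark (mapped to
50% gut length), binned into 40 bins, unit-normalized, and correlated with
curvature — all pairs within a sex, after elastic registration — against a
null of surrogate traces simulated from per-trace autoregressive fits.

**Synthetic cohorts.** A seed-deterministic generator produces dimorphic
centreline cohorts (anterior run, helical loop stack with closed-form
curvature, terminal coil), watertight tube meshes, neighbour organs at
controlled separations, and intensity traces with AR noise — so every
estimator can be validated against analytic ground truth.

## Worked example

```r
library(gutmorph)
coh  <- generate_cohort(cohort_spec(n_per_group = 8, seed = 1), n_points = 600)
meta <- cohort_metadata(coh)

# geometry of one specimen
p    <- parameterize(coh[[1]]$centreline)
loop <- subset_by_landmarks(p, "loop_start", "loop_end")
kt   <- curvature_torsion(loop, delta_frac = 0.05)
signif(c(L_um = p$L, loop_kappa = median(kt$curvature$values),
         tilt_deg = tilt_angle(p, loop)), 3)
#>       L_um loop_kappa   tilt_deg
#>   6.82e+03   4.89e-03   8.70e+00

# Procrustes ANOVA with RRPP
al <- gpa_align(lapply(coh, function(sp)
  resample_equal(parameterize(sp$centreline), 500)))
procrustes_anova_rrpp(al, ~ sex + gut_length + batch, meta,
                      iterations = 1000, seed = 2)
#> Procrustes type III ANOVA with RRPP (1000 iterations)
#>        term Df     SS     R2      F      Z     p
#>         sex  1 0.0313 0.1103 8.3742 3.6720 0.001
#>  gut_length  1 0.0041 0.0145 1.1043 0.3963 0.318
#>       batch  1 0.0037 0.0132 1.0026 0.1691 0.417
#>   Residuals 12 0.0448 0.1580     NA     NA    NA
#>       Total 15 0.2835 1.0000     NA     NA    NA
```

This specimen is a 6.8 mm female gut whose midgut loops bend with ~4.9/mm
curvature and tilt 8.7° off the body axis; across the cohort, sex explains
11% of shape variance and is significant at the RRPP floor (p = 0.001),
while gut length and imaging batch are not. Embedding the pairwise elastic
curvature distances by MDS and testing group location:

```r
profs <- lapply(seq_along(coh), function(i) {
  lp <- subset_by_landmarks(parameterize(coh[[i]]$centreline),
                            "loop_start", "loop_end")
  k  <- normalize_by_length(curvature_torsion(lp, n_eval = 400)$curvature)
  k$specimen_id <- meta$specimen_id[i]; k
})
emb <- mds_embed(distance_matrix(profs, relative = TRUE), dim = 3, seed = 3)
fem <- meta$sex == "female"
location_test(emb$points[fem, ], emb$points[!fem, ])[c("p", "test")]
#> $p        5.64e-09
#> $test     "Hotelling T2"
```

The sexes separate cleanly in curvature space (stress 0.053, Hotelling
p ≈ 6e-9). `run_pipeline(list(seed = 1))` chains all stages (simulate →
geometry → morphometrics → compare → proximity → profiles) and writes CSV/
JSON artifacts with a checksummed manifest.

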