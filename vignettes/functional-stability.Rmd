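---
title: "Surface-based dynamic functional stability: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based dynamic functional stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfstab)
```

## The statistic

Resting-state functional connectivity (FC) is not constant over a scan.
A vertex whose connectivity profile keeps the same *shape* over time is
functionally stable; one whose profile reorders is dynamic. `surfstab`
quantifies this per cortical vertex as the Kendall coefficient of
concordance (W) of the vertex's sliding-window FC maps:

1. Slide a rectangular window (default 64 s, advanced in 4 s steps)
   along the vertex's band-passed BOLD series.
2. Within each window, correlate (Pearson) the vertex with every
   connectivity target — all other vertices inside the cortex mask
   (`vertex_by_vertex`), or per-window parcel-mean series
   (`vertex_by_atlas`, the default, with the seed's own parcel mean
   recomputed without the seed).
3. Treat windows as judges ranking the targets and compute the
   tie-corrected W:
   \[ W = \frac{12 \sum_i R_i^2 - 3 k^2 n (n+1)^2}
             {k^2 n (n^2-1) - k \sum_j T_j} \]
   with \(k\) windows, \(n\) targets, \(R_i\) the rank sum of target
   \(i\), and \(T_j\) the usual per-judge tie correction. W lies in
   \([0, 1]\); 1 means every window induces the same ranking.

Because W depends on the windowed correlations only through their
within-window ranks, any strictly increasing per-window transform —
Fisher's z in particular — leaves it unchanged. The test suite asserts
this exactly, which settles the question of whether correlations should
be z-transformed first: it cannot matter.

Subject-level maps are standardised to Z-scores (masked mean 0, sample
SD 1, pooled across hemispheres when two are supplied) and smoothed on
the surface. Group differences are assessed by a vertex-wise GLM
(patient − control, mean framewise displacement as the default nuisance
covariate), thresholded two-sided at vertex p < 0.001, clustered on the
mesh adjacency with an areal-extent threshold (strictly greater than
20 mm²), assigned permutation p-values, and corrected with
Benjamini–Hochberg FDR at q < 0.05 (optionally halved per hemisphere as
a Bonferroni split).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `discard` | 10 | volumes | signal equilibration |
| `low_hz`, `high_hz` | 0.01, 0.1 | Hz | band-pass edges |
| `window_s` | 64 | s | sliding-window length |
| `step_s` | 4 | s | window step |
| `fwhm_mm` | 6 | mm | surface smoothing FWHM |
| `vertex_p` | 0.001 | — | two-sided vertex threshold |
| `min_area_mm2` | 20 | mm² | cluster extent (strict >) |
| `q` | 0.05 | — | cluster-level FDR |
| `n_perm` | 499 | — | permutations for cluster p |
| `max_trans_mm`, `max_rot_deg` | 2.5, 2.5 | mm, ° | motion exclusion (strict >) |

The robustness protocol (`parameter_grid()` / `run_grid()`) re-runs the
full chain over windows {50, 64, 100} s × steps {2, 4} s × FWHM
{6, 8, 10} mm and quantifies agreement between settings as the Pearson
correlation of group t-maps plus the Dice overlap of surviving-cluster
vertex sets. The source protocol demonstrates such agreement only
visually; the Dice/correlation pairing is this package's
quantification, and the 0.5 Dice reference used in the tests is a
package convention, not an external claim.

## Null behaviour of W with overlapping windows

For independent judges the null expectation of W is \(1/k\); the test
suite confirms this for non-overlapping windows (iid noise, 8 disjoint
windows, mean W ≈ 0.125). Sliding windows that overlap are *dependent*
judges: with a 64 s window advanced by 4 s, adjacent windows share
~94% of their samples and the null W is inflated well above \(1/k\)
(empirically ≈ 0.2 under iid noise at the default geometry). Raw W
values are therefore comparable only within a fixed window
specification — which is why maps are Z-standardised before any
between-subject analysis and why the reproducibility grid re-derives
group maps per setting instead of comparing raw W across settings.

## The synthetic cohort

No public data accompany the source study, so the package ships a
generative model rich enough to exercise every downstream stage with
known truth.

**Latent structure.** Parcels (default 12, a Voronoi partition of an
icosphere around the icosahedral directions) carry unit-variance latent
signals with a circulant baseline correlation profile
\(\rho_{ij} = 0.9\, e^{-d_{ij}/3}\) over circular label distance
(0.64 for neighbours on the label circle down to 0.12 opposite; minimum
eigenvalue ≈ 0.23). The circulant choice makes parcels exchangeable, so
"stationary vs modulated at equal coupling baseline" is exactly
well-posed. Vertices observe their parcel latent plus independent
Gaussian noise (SD 0.5), both with AR(1) temporal structure
(coefficient 0.3).

**Temporal modulation.** A parcel with modulation amplitude
\(a \in [0,1]\) *reconfigures* its connectivity between regimes: its
latent blends from its own factor toward a state-switch partner's
factor, \(x_p = \sqrt{1 - a s(t)}\, z_p + \sqrt{a s(t)}\,
z_{\mathrm{partner}(p)}\), as the regime state \(s(t)\) alternates
(piecewise-constant dwell of 96 s by default; a sinusoidal form is
available). Two design points matter here and were settled during
generator design:

* *Reconfiguration, not attenuation.* Scaling a parcel's couplings
  multiplicatively would leave their ranking — and hence a rank-based
  concordance — nearly untouched; only the collapse of signal below the
  sampling noise of a 32-volume window would register. Blending toward
  a different profile genuinely reorders the windowed FC map between
  regimes, which is the dynamic-FC notion of a state change and the
  contrast the statistic is built to detect. The construction is
  positive semi-definite for free, because every instantaneous
  correlation matrix is the correlation of explicit mixtures of the
  jointly Gaussian baseline factors.
* *Asynchronous regimes.* Each modulated parcel runs its own
  independently phased regime sequence. With a single global state
  clock, one strongly modulated parcel degrades the concordance of
  *every* seed whose target set contains it, and a second parcel's own
  amplitude then adds almost nothing — the dose–response between a
  parcel's amplitude and its own stability saturates. Independent
  phases keep that mapping monotone, which the parameter-recovery tests
  require and which is also the more plausible physiology.

The dwell time must be at or above the window length for windowed FC to
vary across windows at all; 96 s against the 64 s default window gives
roughly 3.5 regime episodes per 340 s scan.

**Cohort design.** Two groups (default 15 + 15 after the source
design's 70/45 is scaled to desk size) share the mesh, atlas and
baseline configuration; patients additionally receive amplitude
+0.6 in the designated effect parcel (stationary at baseline, so the
patient value is 0.6), optional reductions in compensatory parcels, and
a per-patient covariate-parcel amplitude drawn uniformly on [0, 0.8]
whose rank correlation with the visual-field mean deviation (`md_vf`,
dB, clamped to the clinically observed [−32, 1.7] range) is set by a
Gaussian copula to −0.5: worse fields go with more modulation, hence
lower stability, reproducing the positive stability–MD correlation
reported for patients. Controls carry `NA` for `md_vf`, and
correlations are computed in patients only. Motion is a random-walk
six-parameter trace; framewise displacement is the Power convention
(sum of absolute backward differences, rotations converted on a 50 mm
sphere). Subject seeds derive deterministically from the master seed,
so cohorts are bit-reproducible.

**What the generator does not emulate.** Hemodynamic convolution,
scanner drift and physiological artefact spectra, spatial
autocorrelation of noise within parcels, geometry of real cortical
folding, and registration error. Passing tests therefore demonstrate
the *statistical machinery* — estimator correctness, error control,
power under a known effect, parameter robustness — not performance on
real surface BOLD.

## Surface numerics

**Vertex areas** use the barycentric one-third rule, which partitions
the total mesh area exactly; the 20 mm² cluster threshold is evaluated
against these areas. The default study mesh (icosphere level 2, radius
12 mm) is chosen so per-vertex area ≈ 11 mm² matches fsaverage5 areal
density, keeping the areal threshold meaningful at desk scale.

**Smoothing** is mask-restricted graph diffusion,
\(f \leftarrow (I - cL)f\) with the combinatorial Laplacian of the
masked submesh and step \(c = 0.5/\mathrm{max\ degree}\). Column sums
of \(I - cL\) are 1, so the masked mean is preserved *exactly*; each
update is a convex combination, so values never leave the masked range;
and the operator is linear. Because the width added per iteration is a
mesh property, the iteration count (and, on coarse meshes, the step
size) is calibrated per mesh/mask/FWHM from the measured geodesic
full-width-at-half-maximum of a point-impulse response
(`smoothing_calibration()`), with a 15% acceptance band. A mesh whose
edge length exceeds the requested FWHM cannot represent it; calibration
then fails loudly rather than silently under-smoothing. Vertices
outside the mask are passed through untouched and excluded from
averaging weights, so nothing bleeds across the mask boundary.

**Band-pass filtering** is a frequency-domain mask (components inside
[0.01, 0.1] Hz retained, DC removed whenever the low edge is positive),
which preserves in-band sinusoid amplitudes to within interpolation
error and gives exact out-of-band rejection.

**Order of operations.** Confound regression (Friston-24 + linear
trend, intercept always included) precedes band-pass filtering, and the
two are not re-orthogonalised jointly — frequency content reintroduced
by regression is not removed again. Z-scoring precedes smoothing, the
order implied by the source protocol's description; since both
operations are affine the alternative order changes only the final
scale, and the pipeline exposes the switch (`zscore_before_smooth`).
Z-scoring uses the sample (n−1) standard deviation.

**Degenerate inputs.** Windows with zero-variance series yield
undefined correlations; the affected target is dropped from *all*
windows' rankings for that seed (keeping the judge/item grid
rectangular) and the count is reported. A stack in which every target
ties in every window has no defined W and returns `NA` with a warning.
Constant maps cannot be Z-scored (error). Ties in rankings receive
average ranks with the standard tie correction.

## Cluster-level inference

The source protocol reports cluster-level FDR-adjusted q-values without
stating how cluster p-values arise. This package derives them by group-
label permutation: labels are permuted (covariates stay with their
subjects and the GLM is re-fit), the maximal same-sign suprathreshold
cluster area is recorded per permutation, and
\(p = (1 + \#\{\text{perm maxima} \ge \text{observed area}\}) /
(1 + n_{\mathrm{perm}})\), followed by BH-FDR across clusters. This is
assumption-light and exactly testable; it is *not* claimed to be
numerically equivalent to the original toolbox's correction. Null
calibration (≤10% of null cohorts with any surviving cluster over 40
seeds) and power (≥80% recovery of the designed effect over 20 seeds)
are asserted in the acceptance tests at the problem sizes below.

Positive and negative excursions are clustered separately after
thresholding |t| at the two-sided critical value, so signed peaks are
reported. When hemispheres are analysed separately the cluster-level
q threshold may be halved (`hemi_bonferroni`), mirroring the 0.05/2
validation analysis.

One demographic reference value deserves a note: the published
male/female table (41/29 vs 26/19) is accompanied by a chi-square
statistic of 0.674 *and* a p of 0.933. These are mutually inconsistent —
the Pearson statistic implied by the counts is ≈ 0.007, whose p ≈ 0.933
matches the printed p (and 0.674 appears once more as a p-value in the
table itself). The package reproduces the p from the counts with the
uncorrected Pearson test and does not target the stray 0.674.

## Problem sizes and determinism

Tests and the acceptance script run the full chain on a 162-vertex
icosphere, 12 parcels, 180 acquired volumes (170 after discard,
TR 2 s), 15 + 15 subjects and 499 permutations; recovery and error-
control properties are evaluated over 10–40 master seeds. These sizes
were chosen so the complete validation suite runs on a laptop-class
single core in minutes while leaving every statistical property
measurable. All randomness flows from explicit seeds; re-running any
stage with the same seed reproduces its outputs byte-for-byte, and the
vertex loops are order-independent, so parallel execution cannot change
results.

## Known limitations

* The vertex-by-atlas target definition (parcel means, seed's parcel
  included as a leave-one-out mean) is one of several defensible
  readings of the source method; `include_self` and `drop` variants are
  switchable, and vertex-by-vertex mode is exact against a naive
  reference.
* Permutation cluster p-values assume group exchangeability under the
  null after covariate adjustment.
* The generator's noise is spatially white within parcels; real
  surface noise is spatially correlated, so real-data cluster sizes
  will differ from synthetic ones.
* GIFTI I/O is not provided (no GIFTI codec exists in the supported
  dependency set); the neutral plain-text + JSON sidecar formats carry
  the same information and are what the tests exercise.
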