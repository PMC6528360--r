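---
title: "Ontogenetic shape analysis with ontomorph: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontogenetic shape analysis with ontomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ontomorph` analyses how body shape changes across development in several
species sampled at successive ontogenetic stages, the design typical of
studies on demersal fishes with a bipartite (pelagic juvenile / benthic
adult) life cycle. This vignette explains the statistical machinery, the
choices made where the methodology leaves room, and what the package's
synthetic validation data do and do not demonstrate about real specimens.

## Superimposition

Raw 2D landmark configurations carry position, orientation and size, none
of which are shape. `gpa_align()` removes them by Generalized Procrustes
Analysis: every configuration is centered, scaled to unit centroid size
(CS, the square root of the summed squared landmark distances from the
centroid), and rotated by the least-squares optimal rotation onto an
iteratively updated consensus. Rotations come from the SVD of the
cross-product matrix with the determinant constrained to +1: reflections
are never applied, so all specimens must be digitized on the same side.
Iteration stops when the root-mean-square change of the consensus falls
below `tol` (default 1e-8, `max_iter` 100). The final solution is rotated
so the consensus lies along its principal axes, which makes the output
exactly invariant under similarity transforms of any input — a property
the test suite checks at 1e-8.

Statistics downstream treat the aligned coordinates as Euclidean data,
i.e. an orthogonal tangent-space approximation at the consensus. At the
shape variation typical of intraspecific and ontogenetic series
(Procrustes distances well below 0.3) the approximation error is orders
of magnitude below the effects of interest.

### Sliding semilandmarks

Curve points without point-to-point homology are declared as slider
triples (`before`, `slider`, `after`). During each GPA iteration every
semilandmark may move along its tangent direction — the unit chord
between its neighbours — by the amount that minimizes the thin-plate
spline (TPS) bending energy of the specimen relative to the current
consensus. Because the objective is an exact quadratic in the
displacements, each sliding step is a single linear solve and can only
decrease bending energy; `gpa_align()` records the before/after energies
of every step in `slide_bending_energy` so the monotonicity is
verifiable per run.

Two practical guards keep the interleaved iteration well behaved:

* A common drift of all specimens' semilandmarks along their curves moves
  the shapes and the consensus together without changing any relative
  bending energy — a gauge freedom under which the consensus would wander
  indefinitely. The mean slide displacement across specimens is therefore
  removed each iteration.
* Sliding is frozen after `slide_iter` (default 20) iterations, or
  earlier once its RMS displacement falls below `sqrt(tol)`; subsequent
  plain-GPA iterations then converge to machine-level tolerance. The
  displacement tail beyond 20 rounds is far below landmark digitizing
  precision.

The bending-energy criterion is the one implemented; minimum-Procrustes
sliding was considered and not included, since relative comparisons of
integration indices depend on the bending-energy geometry anyway.

## Thin-plate spline basis

`bending_energy_matrix()` uses the standard 2D kernel `U(r) = r^2 log r`.
The alternative `r^2 log r^2` convention differs by a global factor of 2
that cancels in the GI slope and in all relative comparisons; the choice
is stated so results are reproducible bit for bit. The bending energy
matrix of the consensus is symmetric positive semidefinite with exactly
three null directions (the 2D affine maps). `partial_warp_scores()`
orders its eigenvalues ascending, discards the three null eigenvectors as
principal warps, and keeps the scores on the full null-space basis as the
affine (uniform) component — slightly wider than the classical
two-parameter uniform term, but it makes the warp + uniform
reconstruction of every aligned shape exact, which the tests assert at
1e-8, and it is excluded from GI either way (zero bending energy has no
defined log).

## Permutation inference (RRPP)

All tests share one machinery: a statistic is computed on the observed
data, then on many datasets rebuilt as `fitted(reduced model) + permuted
residuals(reduced model)`, and the p-value is `(1 + #null >= observed) /
(1 + n_perm)` — never exactly zero. Permutation index streams are drawn
once per seed, so every statistic of a given analysis sees the same
permutations and results are bit-reproducible. Effect sizes `Z` are
standard deviates of the observed statistic against its null, computed on
the log scale for sums of squares (their permutation distributions are
right-skewed); angles and distances are left on their natural scale.

* `procrustes_anova()` uses sequential (type I) decomposition via a
  single QR of the cumulative design, the reduced model for each term
  being all terms before it. The default 10,000 permutations match
  common practice for this design size.
* `compare_allometric_slopes()` fits each species' multivariate
  regression of shape on log CS (log is the standard allometry scale and
  the generator's convention; raw CS is a flag away) and permutes
  residuals of the common-slope model `shape ~ group + size`. The
  statistic permuted is the pairwise angle in degrees.
* `compare_trajectories()` permutes residuals of the additive
  `shape ~ group + stage` model (the no-interaction null) and rebuilds
  the stage means each round. One permutation stream serves the angle,
  shape and magnitude attributes so their p-values are mutually
  consistent.
* `disparity_test()` permutes group-mean-centered residual vectors among
  groups and recomputes Procrustes variances (trace of the group
  covariance with divisor `n`, per its definition).
* `covariance_ratio()` permutes whole landmarks (x and y together)
  across modules of fixed sizes; modules are anatomical landmark sets,
  so landmark-level permutation is the relevant null.

Known behaviour worth stating: residual permutation discards the
`rank(X)/n` share of residual variance absorbed by the reduced model, so
scale-free statistics such as trajectory angles become mildly liberal in
very small designs (noticeable at 2 groups x 2 stages x 5 specimens). At
the package's reference design — four stages with around ten specimens
per cell — the empirical size of the angle test is nominal, which the
acceptance suite verifies over 200 null simulations.

## Trajectory attributes

A group's phenotypic trajectory is its ordered sequence of stage mean
shapes. Magnitude is the summed Euclidean path length; direction is the
leading principal axis of the stage means, oriented from the first toward
the last stage; trajectory shape is the stage-mean configuration itself,
centered and scaled to unit size. Angles between directions use the
absolute-correlation convention (range 0–90°) because a principal axis
has no intrinsic sign. Trajectory-shape distance superimposes the two
4-point configurations with an orthogonal rotation computed in their
joint span; reflections are permitted there because the axes of shape
space have no handedness. Degenerate (zero-length) trajectories are
flagged and reported as undefined in angle and shape comparisons rather
than silently zeroed.

## Integration and modularity

The covariance ratio compares the summed squared between-module
covariances with the geometric mean of the within-module ones, excluding
diagonals and each landmark's own x–y covariance (an orientation
artifact, not anatomy; a flagged alternative could include it). Values
near 0 indicate modularity, the random-landmark-partition null is
centered on 1, and significance is the lower-tail proportion of the null.

The global integration coefficient regresses the log variance of each
partial warp (x- and y-score variances summed — the isotropic treatment)
on the log of its bending energy. A slope of −1 is self-similarity across
spatial scales; steeper (more negative) slopes mean variance concentrated
in large-scale deformation (integration), shallower slopes mean localized
variation (disintegration). The self-similar band is ±0.05 around −1 by
default — an implementation choice, not an inference about any published
threshold — and the slope is provably invariant to the TPS kernel-scale
convention, which the tests check at 1e-10.

## Staging by centroid size

Juveniles are binned per species into three stages by their CS percentile
among that species' juveniles: 1–33, 34–66, above 66; adults are stage 4.
Percentiles are `floor(100 * rank / n)` with average ranks for ties, so
the bins match the printed integer boundaries, equal sizes always share a
stage, and staging depends only on the within-species size ordering (it
is invariant under any monotone rescaling of CS). Species with fewer than
three juveniles are staged by the same rule under a warning — degenerate
but defined.

## The synthetic generator

`generate_dataset()` builds specimens in the tangent space at a fish-like
35-landmark template (15 fixed points, 20 semilandmarks on four outline
curves) and applies size, rotation and translation nuisance last, so a
correct GPA must remove exactly what was added — this closes the loop for
the invariance tests. A specimen's deviation is the sum of:

* a species offset, shrunk toward the species centroid by the per-stage
  convergence factor (default 0, 0.3, 0.8, 0.8) — juvenile convergence;
* the stage's trajectory point: a shared ontogeny direction with
  coefficients 0, 0.04, 0.08, 0.22, plus a species-specific divergence
  direction of norm 0.10 at the adult stage — the abrupt post-settlement
  divergence;
* a species allometric vector times `log(CS / CS_ref)`, with pairwise
  vector angles controlled by an admixture parameter;
* modular noise with per-stage standard deviations 0.012, 0.009, 0.006,
  0.016 — disparity contraction during settlement, release in adults.

Noise follows a factor model rather than raw equicorrelation: coherent
displacement of a whole module is a rigid translation that Procrustes
centering necessarily converts into spurious between-module covariance,
so within-module covariation is carried by module-confined zero-sum
deformation contrasts (orthogonal to the similarity subspace),
between-module covariation by global deformation factors, and the rest is
isotropic. `within_module_corr` and `between_module_corr` set the
variance fractions of the tiers; with `between = 0` the population
between-module covariance is exactly zero and remains so after
superimposition, which is what makes the covariance-ratio recovery tests
meaningful end to end.

Default centroid-size ranges are 15–30, 30–45, 45–60 and 90–150 mm across
the four stages — representative of settlement-to-adult series in small
sparid fishes — with `CS_ref` 20 mm. `paper_like_scenario()` freezes a
390-specimen design (291 juveniles, 99 adults; cell sizes 34/35/37/21,
16/15/17/18, 26/27/29/38, 18/18/19/22 for the four species).

What passing on this generator shows: the estimators recover the
quantities they are defined on, the permutation tests hold their size and
have power at the configured effects, and the qualitative ontogenetic
pattern (convergence at late settlement, adult divergence, U-shaped
disparity) is reproduced end to end. What it does not show: robustness to
digitizing error structure, landmark drop-out, asymmetric or curved
trajectories, non-Gaussian shape variation, or tangent-space distortion
at large shape distances — real data can violate all of these.

## Problem sizes and numerical conventions

The test suite runs the full pipeline once at the 390-specimen design
with 999 permutations and the calibration studies at 2 groups x 4 stages
x 10 specimens with 199 permutations over 200 simulations; these sizes
give stable empirical rates while keeping the default suite around a
minute. Convergence tolerances are 1e-8 (GPA consensus RMS), with
sliding frozen after 20 rounds; permutation p-values use the
`(1 + count)/(1 + n_perm)` convention; coincident landmarks in a TPS
reference and zero-length slider tangents are hard errors naming the
offending landmarks; user-facing slider and partition files are 1-indexed
(converted at the I/O boundary). `SCALE=` factors in TPS files are
applied on read; whether source coordinates were digitized in physical
units is recorded nowhere else in the file, so applying the stated scale
is the only defensible reading.

## Known limitations

* 2D landmarks only; no 3D TPS.
* Reflections are disallowed throughout: specimens digitized on opposite
  sides must be flipped before import.
* Trajectory comparison assumes equal stage counts across groups.
* The trajectory-angle permutation test is mildly liberal in very small
  designs (see above).
* Procrustes ANOVA uses sequential SS; term order matters and is the
  user's modelling decision.
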