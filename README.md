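# ontomorph

Geometric-morphometric analysis of ontogenetic shape change in 2D
landmark data. The package targets the standard design of evo-devo
studies on species with bipartite life cycles — several species sampled
across successive developmental stages (e.g. pelagic juveniles settling
into benthic adults) — and asks how developmental trajectories diverge,
where disparity contracts and expands, and how integration and
modularity shift along ontogeny.

Everything after data import is built in:

* **Generalized Procrustes Analysis** with sliding semilandmarks.
  Configurations are centered, scaled to unit centroid size
  (`CS = sqrt(Σ_i |x_i − x̄|²)`) and rotated (SVD, no reflections) onto an
  iterated consensus; semilandmarks slide along neighbour-chord tangents
  to minimize thin-plate-spline bending energy relative to the consensus.
* **Thin-plate spline machinery**: bending energy matrix (kernel
  `U(r) = r² log r`), principal warps, partial-warp scores, uniform
  component.
* **Procrustes ANOVA with RRPP**: sequential (type I) Procrustes sums of
  squares on the `n × 2k` shape matrix; null distributions from residual
  randomization of the reduced model; `p = (1 + #null ≥ obs)/(1 + n_perm)`
  and effect sizes `Z` on the log-SS scale.
* **Allometry**: per-species multivariate regression vectors of shape on
  `log(CS)` and pairwise angle tests under the common-slope null.
* **Phenotypic trajectory analysis**: per-species stage-mean paths with
  magnitude (path length), direction (leading axis, angles folded to
  0–90°) and shape (Procrustes distance between superimposed stage-mean
  configurations), each tested by RRPP against the no-interaction null.
* **Disparity**: Procrustes variance (`Σ‖x_i − x̄‖²/n`) per group with
  permutation tests, plus stage-wise intra/inter-group profiles.
* **Modularity and integration**: the covariance ratio CR (between- vs
  within-module squared covariances, landmark-permutation null centered
  on 1) and the global integration slope GI (log partial-warp variance on
  log bending energy; −1 = self-similar, below −1 integrated, above −1
  disintegrated).
* **A synthetic ontogeny generator** with known ground truth — species
  offsets, juvenile convergence, adult trajectory divergence,
  species-specific allometry, stage-wise noise levels and modular factor
  noise — so every stage of the pipeline is validated against
  constructions whose answers are known.

## Worked example

Simulate a 4-species × 4-stage design (12 specimens per cell), align,
and run the core analyses:

```r
library(ontomorph)

cfg <- ontogeny_sim_config(n_per_cell = 12, seed = 42)
sim <- generate_dataset(cfg)
aligned <- gpa_align(sim$configs, metadata = sim$metadata)
aligned
#> GPA-aligned dataset: 192 specimens, 35 landmarks (20 semilandmarks), 21 iterations

shape_pca(aligned)
#> Shape PCA: 66 components
#>   PC1-PC3: 39.53%, 8.10%, 6.51%

procrustes_anova(aligned, ~ species * life_stage, n_perm = 999, seed = 42)
#> Procrustes ANOVA (RRPP, 999 permutations, seed 42)
#>                term  df     SS       MS       F      Z     p
#>             species   3 0.1918 0.063920   6.582  4.303 0.001
#>          life_stage   1 1.1470 1.147000 118.100  8.162 0.001
#>  species:life_stage   3 0.2902 0.096740   9.961 11.230 0.001
#>           Residuals 184 1.7870 0.009712      NA     NA    NA
#>               Total 191 3.4160       NA      NA     NA    NA

cmp <- compare_trajectories(build_trajectories(aligned), n_perm = 999, seed = 42)
round(cmp$theta["species_1", "species_2"], 1)   # degrees between trajectories
#> [1] 40
cmp$p_theta["species_1", "species_2"]
#> [1] 0.001

global_integration(aligned)
#> Global integration: slope = -0.4795 (disintegrated, 32 partial warps)
```

Reading the output: the life-stage term dwarfs the species term
(F 118 vs 6.6) — shape change across ontogeny exceeds interspecific
differences, the signature of a bipartite life cycle. Trajectory angles
around 40° with `p = 0.001` show the species follow significantly
different developmental directions, and a GI slope above −1 means shape
variation is dominated by localized (high-bending-energy) deformation.

`run_pipeline()` wraps the whole graph (GPA → PCA → ANOVA → allometry →
trajectories → disparity → CR/GI) with per-step seeds, CSV outputs and a
run manifest; `inst/scripts/ontomorph-pipeline.R` is a thin shell wrapper
around it.

## Data formats

TPS landmark files (`LM=`, `ID=`, `IMAGE=`, `SCALE=`, `CURVES=`/`POINTS=`
blocks whose interior points become sliding semilandmarks), classifier
CSV/TSV (`specimen_id`, `species`, `life_stage`, optional stage and
centroid size), 1-indexed slider tables and module-partition tables. See
`vignettes/ontogenetic-shape-analysis.Rmd` for the statistical model,
the design decisions and the known limitations.
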