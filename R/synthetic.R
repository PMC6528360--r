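# Synthetic ontogenetic landmark data with known ground truth: a template
# fish-like outline, species offsets, stagewise trajectory paths with
# convergence/divergence, species-specific allometry, and block-structured
# (modular) landmark noise.

#' Template landmark configuration for simulations
#'
#' A fish-like 2D configuration of 35 landmarks: 15 fixed anatomical points
#' (snout, jaw, eye, opercle, fin insertions, caudal peduncle) and 20
#' semilandmarks equally spaced along four outline curves anchored at fixed
#' landmarks (dorsal head profile, dorsal body outline, ventral body
#' outline, caudal margin). Scaled to unit centroid size. The partition
#' assigns the head landmarks (and head-curve semilandmarks) to module
#' `head` and the rest to `trunk_tail`.
#'
#' @return List with `coords` (`35 x 2`), `sliders` (`20 x 3`), `partition`
#'   (length-35 character), `n_fixed`.
#' @export
ontogeny_template <- function() {
  fixed <- rbind(
    c(0.00,  0.02),   # 1 snout tip
    c(0.02, -0.05),   # 2 lower jaw
    c(0.10,  0.05),   # 3 eye
    c(0.18,  0.12),   # 4 nape
    c(0.22,  0.05),   # 5 opercle top
    c(0.20, -0.08),   # 6 opercle bottom
    c(0.28, -0.02),   # 7 pectoral fin insertion
    c(0.35,  0.16),   # 8 dorsal fin, anterior
    c(0.62,  0.13),   # 9 dorsal fin, posterior
    c(0.33, -0.15),   # 10 pelvic fin insertion
    c(0.55, -0.13),   # 11 anal fin, anterior
    c(0.68, -0.10),   # 12 anal fin, posterior
    c(0.82,  0.07),   # 13 dorsal peduncle
    c(0.82, -0.06),   # 14 ventral peduncle
    c(0.95,  0.00))   # 15 caudal midpoint
  # quadratic Bezier interior points between two anchors with a
  # perpendicular bulge at the midpoint
  bezier_interior <- function(p0, p1, bulge, m) {
    chord <- p1 - p0
    nrm <- c(-chord[2L], chord[1L])
    nrm <- nrm / sqrt(sum(nrm^2))
    ctrl <- (p0 + p1) / 2 + bulge * nrm
    t <- seq_len(m) / (m + 1L)
    cbind((1 - t)^2 %o% p0[1L] + 2 * t * (1 - t) * ctrl[1L] + t^2 * p1[1L],
          (1 - t)^2 %o% p0[2L] + 2 * t * (1 - t) * ctrl[2L] + t^2 * p1[2L])
  }
  curves <- list(list(a = 1L, b = 4L, bulge = 0.03, m = 3L),   # head profile
                 list(a = 8L, b = 13L, bulge = 0.05, m = 6L),  # dorsal outline
                 list(a = 10L, b = 14L, bulge = -0.05, m = 6L),# ventral outline
                 list(a = 13L, b = 14L, bulge = 0.04, m = 5L)) # caudal margin
  coords <- fixed
  sliders <- matrix(integer(0), ncol = 3L)
  for (cv in curves) {
    pts <- bezier_interior(fixed[cv$a, ], fixed[cv$b, ], cv$bulge, cv$m)
    idx <- nrow(coords) + seq_len(cv$m)
    chain <- c(cv$a, idx, cv$b)
    coords <- rbind(coords, pts)
    sliders <- rbind(sliders,
                     cbind(chain[seq_len(cv$m)], idx, chain[3:length(chain)]))
  }
  colnames(sliders) <- c("before", "slider", "after")
  coords <- center_config(coords) / centroid_size(coords)
  partition <- rep("trunk_tail", nrow(coords))
  partition[c(1:7, 16:18)] <- "head"   # head points + head-curve semis
  list(coords = coords, sliders = sliders, partition = partition,
       n_fixed = nrow(fixed))
}

# Orthonormal basis of the similarity subspace at a reference shape
# (x/y translation, rotation, scale), as flattened 2k-vectors.
similarity_basis <- function(reference) {
  x <- reference[, 1L]; y <- reference[, 2L]
  k <- nrow(reference)
  S <- cbind(as.vector(t(cbind(rep(1, k), 0))),
             as.vector(t(cbind(0, rep(1, k)))),
             as.vector(t(cbind(-y, x))),
             as.vector(t(cbind(x, y))))
  qr.Q(qr(S))
}

# Orthonormal non-affine deformation fields in the tangent space at the
# template: smooth harmonic displacement fields, projected orthogonal to
# the similarity directions (translations, rotation, scale) and
# Gram-Schmidt orthonormalized.
tangent_basis_fields <- function(template, n_fields) {
  x <- template[, 1L]; y <- template[, 2L]
  xs <- (x - min(x)) / (max(x) - min(x))
  raw <- list()
  for (m in 1:5) {
    raw[[length(raw) + 1L]] <- cbind(sin(m * pi * xs), 0)
    raw[[length(raw) + 1L]] <- cbind(0, sin(m * pi * xs))
    raw[[length(raw) + 1L]] <- cbind(0, y * cos(m * pi * xs))
    raw[[length(raw) + 1L]] <- cbind(y * sin(m * pi * xs), 0)
  }
  k <- nrow(template)
  flat <- vapply(raw, function(f) as.vector(t(f)), numeric(2L * k))
  sim <- similarity_basis(template)
  flat <- flat - sim %*% crossprod(sim, flat)
  Q <- qr.Q(qr(flat))
  if (ncol(Q) < n_fields) stop("not enough independent deformation fields")
  Q[, seq_len(n_fields), drop = FALSE]
}

# Factor model for modular landmark noise. Procrustes superimposition
# removes similarity transforms, so module-wide rigid displacement (the
# common mode of an equicorrelated block) cannot survive alignment:
# centering converts it into spurious between-module covariance. Real
# modular covariation is coherent deformation *within* a module, so the
# generator draws it from module-confined contrast factors (loadings sum
# to zero within the module and are orthogonal to the similarity
# directions), with between-module covariance carried by global factors
# and the remainder isotropic. With between_module_corr = 0 the population
# covariance between modules is exactly zero, and stays so after GPA.
#
# Variance bookkeeping per coordinate (on average): between_module_corr
# from global factors, (within - between) from module factors, the rest
# isotropic, totalling 1 before the noise_sd scaling.
make_noise_model <- function(template, partition, within, between, seed) {
  k <- nrow(template)
  p <- 2L * k
  S <- similarity_basis(template)
  coords_of <- function(lms) sort(c(2L * lms - 1L, 2L * lms))
  # Orthonormal loading columns exactly supported on `support_coords` and
  # exactly orthogonal to the given constraint vectors (only their
  # restriction to the support matters for supported loadings).
  orthonormal_factors <- function(support_coords, q, constraints) {
    raw <- matrix(stats::rnorm(length(support_coords) * q),
                  length(support_coords), q)
    Cres <- constraints[support_coords, , drop = FALSE]
    Cres <- qr.Q(qr(Cres))[, seq_len(qr(Cres)$rank), drop = FALSE]
    raw <- raw - Cres %*% crossprod(Cres, raw)
    Lres <- qr.Q(qr(raw))[, seq_len(q), drop = FALSE]
    L <- matrix(0, p, q)
    L[support_coords, ] <- Lres
    L
  }
  set.seed(seed)
  modules <- unique(partition)
  module_loadings <- list()
  for (m in modules) {
    lms <- which(partition == m)
    idx <- coords_of(lms)
    # zero-sum (contrast) constraint per axis within the module
    cx <- cy <- numeric(p)
    cx[2L * lms - 1L] <- 1; cy[2L * lms] <- 1
    q <- max(2L, length(lms) %/% 3L)
    L <- orthonormal_factors(idx, q, cbind(S, cx, cy))
    module_loadings[[m]] <- L * sqrt(length(idx) / q)
  }
  qg <- 3L
  Lg <- orthonormal_factors(seq_len(p), qg, S) * sqrt(p / qg)
  list(global = Lg, modules = module_loadings,
       within = within, between = between, similarity = S)
}

# One draw of flattened (2k) noise from the factor model, unit scale.
draw_noise <- function(nm) {
  p <- nrow(nm$global)
  z <- sqrt(nm$between) * (nm$global %*% stats::rnorm(ncol(nm$global)))
  for (L in nm$modules)
    z <- z + sqrt(nm$within - nm$between) * (L %*% stats::rnorm(ncol(L)))
  eps <- stats::rnorm(p, sd = sqrt(1 - nm$within))
  eps <- eps - nm$similarity %*% crossprod(nm$similarity, eps)
  drop(z + eps)
}

# Population covariance (unit noise scale) implied by a noise model.
implied_noise_covariance <- function(nm) {
  p <- nrow(nm$global)
  Sg <- nm$between * tcrossprod(nm$global)
  for (L in nm$modules) Sg <- Sg + (nm$within - nm$between) * tcrossprod(L)
  P <- diag(p) - tcrossprod(nm$similarity)
  Sg + (1 - nm$within) * P       # P is an orthogonal projector
}

#' Configuration for the ontogeny simulator
#'
#' Defines the generating model of [generate_dataset()]: a specimen's
#' tangent-space deviation from the template is
#' `species_offset * (1 - convergence[stage]) + trajectory_path[stage] +
#' allometric_vector * log(CS / cs_ref) + correlated noise`, after which
#' the configuration is emitted at centroid size `CS` with random rotation
#' and translation. Species offsets are centered across species, so
#' convergence shrinks them toward their common centroid. By default the
#' trajectory is a shared ontogeny direction whose stage-4 step adds a
#' species-specific divergence direction — the convergence-then-divergence
#' regime of a settlement/recruitment life cycle. Noise follows a modular
#' factor model on the template's head vs trunk+tail partition:
#' within-module covariation is carried by module-confined deformation
#' contrasts (zero-sum loadings orthogonal to the similarity directions,
#' so superimposition cannot alias it), between-module covariation by
#' global deformation factors, and the remainder is isotropic; the
#' `within_module_corr` / `between_module_corr` parameters set the
#' fractions of per-coordinate noise variance carried by each tier.
#'
#' @param n_species,stages,n_per_cell Design: `n_per_cell` is a scalar or
#'   an `n_species x stages` matrix of cell sizes.
#' @param species Optional species labels.
#' @param template Template list as from [ontogeny_template()].
#' @param offset_scale Norm of each species offset in shape units
#'   (tangent space of the unit-size template).
#' @param convergence Per-stage shrinkage of species offsets, in `[0, 1]`.
#' @param trajectory_scale Per-stage coefficient of the shared ontogeny
#'   direction.
#' @param divergence_scale Norm of the species-specific stage-4 divergence.
#' @param trajectory_paths Optional explicit per-species paths (list of
#'   `stages x 2k` matrices in tangent space) overriding the default
#'   construction.
#' @param species_offsets Optional explicit `n_species x 2k` offset matrix.
#' @param allometry_scale Norm of the allometric vectors (shape change per
#'   unit log centroid size); 0 disables allometry.
#' @param allometry_divergence Per-species admixture of a species-specific
#'   direction into the common allometric vector (controls pairwise slope
#'   angles).
#' @param allometric_vectors Optional explicit `n_species x 2k` matrix.
#' @param cs_ranges `stages x 2` matrix of (min, max) centroid size per
#'   stage (same length units as the landmark coordinates, e.g. mm).
#' @param cs_ref Reference centroid size for the allometric term.
#' @param noise_sd Per-stage landmark noise standard deviation (shape
#'   units); scalar recycled.
#' @param within_module_corr,between_module_corr Fractions in `[0, 1)` of
#'   the per-coordinate noise variance carried by within-module and global
#'   (between-module) factors; between must not exceed within, and the
#'   implied covariance must be positive semidefinite.
#' @param seed Integer seed.
#' @return Object of class `ontogeny_sim_config`.
#' @export
ontogeny_sim_config <- function(n_species = 4L, stages = 4L, n_per_cell = 30L,
                                species = NULL,
                                template = ontogeny_template(),
                                offset_scale = 0.04,
                                convergence = c(0, 0.3, 0.8, 0.8),
                                trajectory_scale = c(0, 0.04, 0.08, 0.22),
                                divergence_scale = 0.10,
                                trajectory_paths = NULL,
                                species_offsets = NULL,
                                allometry_scale = 0.04,
                                allometry_divergence = c(0.15, 0.7, 0.25, 0.35),
                                allometric_vectors = NULL,
                                cs_ranges = cbind(c(15, 30, 45, 90),
                                                  c(30, 45, 60, 150)),
                                cs_ref = 20,
                                noise_sd = c(0.012, 0.009, 0.006, 0.016),
                                within_module_corr = 0.5,
                                between_module_corr = 0.2,
                                seed = 1L) {
  if (is.null(species)) species <- paste0("species_", seq_len(n_species))
  stopifnot(length(species) == n_species)
  if (length(n_per_cell) == 1L)
    n_per_cell <- matrix(n_per_cell, n_species, stages)
  n_per_cell <- as.matrix(n_per_cell)
  stopifnot(nrow(n_per_cell) == n_species, ncol(n_per_cell) == stages)
  k <- nrow(template$coords)
  p <- 2L * k
  convergence <- rep_len(convergence, stages)
  trajectory_scale <- rep_len(trajectory_scale, stages)
  noise_sd <- rep_len(noise_sd, stages)
  allometry_divergence <- rep_len(allometry_divergence, n_species)
  if (between_module_corr > within_module_corr)
    stop("between_module_corr must not exceed within_module_corr")

  n_fields <- 10L + n_species
  fields <- tangent_basis_fields(template$coords, n_fields)
  if (is.null(species_offsets)) {
    species_offsets <- t(fields[, seq_len(min(n_species, 4L)), drop = FALSE]) *
      offset_scale
    if (n_species > 4L)
      stop("default species offsets support at most 4 species; ",
           "supply species_offsets")
  }
  species_offsets <- sweep(species_offsets, 2L, colMeans(species_offsets), "-")
  if (is.null(trajectory_paths)) {
    u0 <- fields[, 5L]
    trajectory_paths <- lapply(seq_len(n_species), function(s) {
      w <- fields[, 5L + s]
      path <- outer(trajectory_scale, u0)
      path[stages, ] <- path[stages, ] + divergence_scale * w
      path
    })
  }
  stopifnot(length(trajectory_paths) == n_species,
            all(vapply(trajectory_paths, function(m)
              all(dim(m) == c(stages, p)), logical(1))))
  if (is.null(allometric_vectors)) {
    a0 <- fields[, 10L]
    allometric_vectors <- t(vapply(seq_len(n_species), function(s) {
      v <- a0 + allometry_divergence[s] * fields[, 10L + s]
      allometry_scale * v / sqrt(sum(v^2))
    }, numeric(p)))
  }
  stopifnot(all(dim(allometric_vectors) == c(n_species, p)))

  # modular noise: factor model on the template's module partition
  if (within_module_corr < 0 || within_module_corr >= 1 ||
      between_module_corr < 0)
    stop("module correlations must lie in [0, 1)")
  noise_model <- make_noise_model(template$coords, template$partition,
                                  within_module_corr, between_module_corr,
                                  seed = derive_seed(seed, "noise_model"))
  ev <- eigen(implied_noise_covariance(noise_model), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied noise covariance is not positive semidefinite")

  structure(list(n_species = n_species, stages = stages,
                 n_per_cell = n_per_cell, species = species,
                 template = template,
                 species_offsets = species_offsets,
                 convergence = convergence,
                 trajectory_paths = trajectory_paths,
                 allometric_vectors = allometric_vectors,
                 cs_ranges = cs_ranges, cs_ref = cs_ref,
                 noise_sd = noise_sd, noise_model = noise_model,
                 within_module_corr = within_module_corr,
                 between_module_corr = between_module_corr,
                 seed = as.integer(seed)),
            class = "ontogeny_sim_config")
}

#' @export
print.ontogeny_sim_config <- function(x, ...) {
  cat("Ontogeny simulation config: ", x$n_species, " species x ", x$stages,
      " stages, ", sum(x$n_per_cell), " specimens, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic ontogenetic landmark dataset
#'
#' Draws specimens under the model described in [ontogeny_sim_config()]:
#' tangent-space shape construction at the template, followed by scaling
#' to the drawn centroid size and random rotation/translation nuisance
#' transforms (which a correct GPA must remove exactly). A fixed seed
#' yields byte-identical output.
#'
#' @param config An `ontogeny_sim_config`.
#' @return Object of class `ontogeny_sim`: `configs` (list of
#'   [landmark_config()]), `metadata` (data frame with specimen_id,
#'   species, life_stage, ontogenetic_stage, centroid_size), `truth`
#'   (the config, the per-specimen noiseless tangent deviations, and the
#'   realized unit-scale noise draws), and the `partition`/`sliders` of
#'   the template.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "ontogeny_sim_config"))
  set.seed(config$seed)
  tpl <- config$template
  k <- nrow(tpl$coords)
  configs <- list(); md <- list(); true_dev <- list(); noise_rec <- list()
  counter <- 0L
  for (s in seq_len(config$n_species)) for (t in seq_len(config$stages)) {
    for (i in seq_len(config$n_per_cell[s, t])) {
      counter <- counter + 1L
      id <- sprintf("%s_st%d_%03d", config$species[s], t, i)
      cs <- stats::runif(1, config$cs_ranges[t, 1L], config$cs_ranges[t, 2L])
      det_dev <- config$species_offsets[s, ] * (1 - config$convergence[t]) +
        config$trajectory_paths[[s]][t, ] +
        config$allometric_vectors[s, ] * log(cs / config$cs_ref)
      noise_unit <- draw_noise(config$noise_model)
      noise <- config$noise_sd[t] * matrix(noise_unit, ncol = 2L, byrow = TRUE)
      dev_mat <- matrix(det_dev, ncol = 2L, byrow = TRUE) + noise
      raw <- tpl$coords + dev_mat
      raw <- raw * (cs / centroid_size(raw))
      th <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      shift <- stats::runif(2, -50, 50)
      coords <- sweep(raw %*% R, 2L, shift, "+")
      configs[[counter]] <- landmark_config(id, coords, sliders = tpl$sliders)
      md[[counter]] <- data.frame(specimen_id = id,
                                  species = config$species[s],
                                  life_stage = if (t == config$stages)
                                    "adult" else "juvenile",
                                  ontogenetic_stage = t,
                                  centroid_size = cs,
                                  stringsAsFactors = FALSE)
      true_dev[[counter]] <- det_dev
      noise_rec[[counter]] <- noise_unit
    }
  }
  metadata <- do.call(rbind, md)
  rownames(metadata) <- NULL
  structure(list(configs = configs, metadata = metadata,
                 partition = tpl$partition, sliders = tpl$sliders,
                 truth = list(config = config,
                              deterministic_deviation =
                                do.call(rbind, true_dev),
                              unit_noise = do.call(rbind, noise_rec))),
            class = "ontogeny_sim")
}

#' @export
print.ontogeny_sim <- function(x, ...) {
  cat("Synthetic ontogenetic dataset: ", length(x$configs), " specimens, ",
      length(unique(x$metadata$species)), " species\n", sep = "")
  invisible(x)
}

#' Frozen study-design scenario
#'
#' A seeded simulation configuration mirroring a four-species ontogenetic
#' sampling design of 390 specimens (291 juveniles across three settlement
#' stages plus 99 adults), with convergence of species differences at late
#' settlement, divergence of trajectories at the adult stage, and adult
#' within-species disparity exceeding the juvenile one.
#'
#' @param seed Integer seed (default frozen).
#' @return An `ontogeny_sim_config`.
#' @export
paper_like_scenario <- function(seed = 20190521L) {
  counts <- rbind(c(34L, 35L, 37L, 21L),
                  c(16L, 15L, 17L, 18L),
                  c(26L, 27L, 29L, 38L),
                  c(18L, 18L, 19L, 22L))
  ontogeny_sim_config(
    n_species = 4L, stages = 4L, n_per_cell = counts,
    species = c("D_annularis", "D_puntazzo", "D_sargus", "D_vulgaris"),
    seed = as.integer(seed))
}

#' Write a synthetic dataset to disk
#'
#' Emits the TPS file, classifier CSV, slider table, module-partition table
#' and a truth JSON, the file set consumed by [run_pipeline()].
#'
#' @param sim An `ontogeny_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ontogeny_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(tps = file.path(dir, "landmarks.tps"),
                classifiers = file.path(dir, "classifiers.csv"),
                sliders = file.path(dir, "sliders.csv"),
                partition = file.path(dir, "partition.csv"),
                truth = file.path(dir, "truth.json"))
  write_tps(sim$configs, paths$tps)
  utils::write.csv(sim$metadata, paths$classifiers, row.names = FALSE)
  write_sliders(sim$sliders, paths$sliders)
  write_partition(sim$partition, paths$partition)
  cfg <- sim$truth$config
  truth <- list(seed = cfg$seed, n_species = cfg$n_species,
                stages = cfg$stages, species = cfg$species,
                n_per_cell = cfg$n_per_cell,
                convergence = cfg$convergence,
                noise_sd = cfg$noise_sd,
                within_module_corr = cfg$within_module_corr,
                between_module_corr = cfg$between_module_corr,
                cs_ranges = cfg$cs_ranges, cs_ref = cfg$cs_ref)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
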