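test_that("centroid size matches its definition and scales linearly", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(1)
  m <- random_config_matrix(35)
  # brute-force per-coordinate sum of squares
  expect_equal(centroid_size(m),
               sqrt(sum((m[, 1] - mean(m[, 1]))^2 +
                        (m[, 2] - mean(m[, 2]))^2)))
  expect_equal(centroid_size(3.7 * m), 3.7 * centroid_size(m))
})

test_that("GPA of trivial inputs behaves as superimposition demands", {
  set.seed(2)
  m <- random_config_matrix(8)
  one <- gpa_align(list(landmark_config("a", m)), slide = FALSE)
  ctr <- sweep(m, 2, colMeans(m), "-")
  expect_lt(max(abs(colMeans(one$shapes[, , 1]))), 1e-8)
  expect_equal(sqrt(sum(one$shapes[, , 1]^2)), 1, tolerance = 1e-8)
  expect_lt(procrustes_distance(one$shapes[, , 1], ctr / sqrt(sum(ctr^2))),
            1e-10)

  # an exactly superimposable pair aligns exactly
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  two <- gpa_align(list(landmark_config("a", m),
                        landmark_config("b", sweep(m %*% R, 2, c(3, -1), "+"))),
                   slide = FALSE)
  expect_lt(procrustes_distance(two$shapes[, , 1], two$shapes[, , 2]), 1e-10)
})

test_that("GPA matches a brute-force alternating-optimization oracle", {
  set.seed(3)
  # perturbations of one base triangle: consistent chirality, as for
  # specimens digitized on the same side
  base <- rbind(c(0, 0), c(1, 0), c(0.4, 0.8))
  mats <- lapply(1:10, function(i)
    (base + matrix(rnorm(6, sd = 0.1), 3)) * runif(1, 0.5, 2))
  al <- gpa_align(lapply(seq_along(mats), function(i)
    landmark_config(paste0("t", i), mats[[i]])), slide = FALSE,
    tol = 1e-12, max_iter = 2000)
  or <- oracle_gpa(mats)
  # orientation is a convention: rotate the oracle solution onto the package
  # consensus before comparing coordinates
  R <- svd(crossprod(or$consensus, al$consensus))
  R <- R$u %*% t(R$v)
  expect_lt(max(abs(or$consensus %*% R - al$consensus)), 1e-8)
  for (i in seq_along(mats))
    expect_lt(max(abs(or$shapes[[i]] %*% R - al$shapes[, , i])), 1e-8)
})

test_that("aligned shapes and consensus satisfy the dataset invariants", {
  sim <- generate_dataset(ontogeny_sim_config(n_per_cell = 4, seed = 11))
  al <- gpa_align(sim$configs, metadata = sim$metadata)
  cs <- apply(al$shapes, 3, function(m) sqrt(sum(sweep(m, 2, colMeans(m))^2)))
  expect_lt(max(abs(cs - 1)), 1e-8)
  expect_lt(max(abs(apply(al$shapes, 3, colMeans))), 1e-8)
  expect_lt(max(abs(al$consensus - apply(al$shapes, c(1, 2), mean))), 1e-10)
  expect_equal(unname(al$centroid_sizes),
               vapply(sim$configs, centroid_size, numeric(1)))
})

test_that("GPA output is invariant under similarity transforms of inputs", {
  sim <- generate_dataset(ontogeny_sim_config(n_per_cell = 3, seed = 5))
  al <- gpa_align(sim$configs, metadata = sim$metadata)
  set.seed(9)
  mangled <- lapply(sim$configs, function(cfg) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    s <- runif(1, 0.2, 5)
    landmark_config(cfg$specimen_id,
                    sweep(s * cfg$coords %*% R, 2, runif(2, -20, 20), "+"),
                    sliders = cfg$sliders)
  })
  al2 <- gpa_align(mangled, metadata = sim$metadata)
  expect_lt(max(abs(al$shapes - al2$shapes)), 1e-8)
  expect_lt(max(abs(al$consensus - al2$consensus)), 1e-8)
})

test_that("summed squared distance to the consensus is non-increasing", {
  sim <- generate_dataset(ontogeny_sim_config(n_per_cell = 3, seed = 13))
  ssd <- vapply(1:6, function(m) {
    al <- suppressWarnings(gpa_align(sim$configs, slide = FALSE, max_iter = m))
    sum(apply(al$shapes, 3, function(sh) sum((sh - al$consensus)^2)))
  }, numeric(1))
  expect_true(all(diff(ssd) <= 1e-10))
})

test_that("bending energy matrix is PSD, annihilates affine maps, and agrees
          with the TPS interpolation route", {
  set.seed(4)
  for (ref in list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                   random_config_matrix(6))) {
    B <- bending_energy_matrix(ref)
    expect_equal(B, t(B))
    affine <- cbind(1, ref)
    expect_lt(max(abs(B %*% affine)), 1e-8)
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    expect_equal(sum(abs(ev) < 1e-10), 3L)
    for (r in 1:3) {
      z <- rnorm(nrow(ref))
      expect_equal(sum(z * (B %*% z)), tps_energy_oracle(ref, z),
                   tolerance = 1e-8)
    }
  }
  expect_error(bending_energy_matrix(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "coincident landmarks 1 and 2")
})

test_that("semilandmark sliding minimizes bending energy along tangents", {
  set.seed(6)
  tpl <- ontogeny_template()
  ref <- tpl$coords
  sliders <- tpl$sliders
  # a shape identical to the reference does not move
  slid <- slide_semilandmarks(ref, ref, sliders)
  expect_lt(max(abs(slid - ref)), 1e-8)

  # perturb one semilandmark along its own tangent: sliding must strictly
  # decrease bending energy and recover the reference position
  j <- sliders[7, 2]
  tang <- ref[sliders[7, 3], ] - ref[sliders[7, 1], ]
  tang <- tang / sqrt(sum(tang^2))
  pert <- ref
  pert[j, ] <- pert[j, ] + 0.02 * tang
  be <- function(sh) {
    B <- bending_energy_matrix(ref)
    sum(sh[, 1] * (B %*% sh[, 1])) + sum(sh[, 2] * (B %*% sh[, 2]))
  }
  slid <- slide_semilandmarks(pert, ref, sliders)
  expect_lt(be(slid), be(pert))
  # 1D quadratic oracle for the single perturbed slider, all others fixed
  obj <- function(l) {
    sh <- pert
    sh[j, ] <- sh[j, ] + l * tang
    be(sh)
  }
  lam_star <- stats::optimize(obj, c(-0.1, 0.1))$minimum
  expect_lt(obj(lam_star) - be(slid), 1e-10)

  expect_error(slide_semilandmarks(ref, ref, rbind(c(1L, 16L, 1L))),
               "distinct|tangent")
})

test_that("bending energy is non-increasing at every sliding step of GPA", {
  sim <- generate_dataset(ontogeny_sim_config(n_per_cell = 4, seed = 21))
  al <- gpa_align(sim$configs, slide = TRUE)
  sb <- al$slide_bending_energy
  expect_gt(nrow(sb), 0L)
  expect_true(all(sb[, "after"] <= sb[, "before"] + 1e-9))
})

test_that("partial warps reconstruct shapes and have zero-BE uniform part", {
  sim <- generate_dataset(ontogeny_sim_config(n_per_cell = 3, seed = 8))
  al <- gpa_align(sim$configs)
  basis <- partial_warp_scores(al)
  expect_length(basis$bending_energies, nrow(al$consensus) - 3L)
  expect_true(all(diff(basis$bending_energies) >= -1e-12))
  n <- dim(al$shapes)[3]
  B <- bending_energy_matrix(al$consensus)
  for (i in c(1L, n)) {
    rec <- al$consensus +
      basis$principal_warps %*% basis$scores[i, , ] +
      basis$uniform_basis %*% basis$uniform_scores[i, , ]
    expect_lt(max(abs(rec - al$shapes[, , i])), 1e-8)
    upart <- basis$uniform_basis %*% basis$uniform_scores[i, , ]
    expect_lt(abs(sum(upart[, 1] * (B %*% upart[, 1])) +
                  sum(upart[, 2] * (B %*% upart[, 2]))), 1e-10)
  }
  # projecting the consensus itself gives all-zero scores
  cons_scores <- crossprod(basis$principal_warps,
                           al$consensus - basis$reference)
  expect_lt(max(abs(cons_scores)), 1e-12)
})

test_that("per-warp score variance matches a direct projection oracle", {
  set.seed(10)
  ref <- random_config_matrix(6)
  al <- shapes_from_warps(ref, sd_per_warp = rep(0.02, 3), n = 12)
  basis <- partial_warp_scores(al)
  for (j in seq_len(ncol(basis$principal_warps))) {
    proj <- vapply(seq_len(12), function(i)
      sum(basis$principal_warps[, j] * (al$shapes[, 1, i] - ref[, 1])),
      numeric(1))
    expect_equal(stats::var(proj), stats::var(basis$scores[, j, 1]),
                 tolerance = 1e-10)
  }
})
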