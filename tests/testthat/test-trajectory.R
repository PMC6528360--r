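traj_metadata <- function(groups, stages, m) {
  data.frame(specimen_id = paste0("s", seq_len(length(groups) * length(stages) * m)),
             species = rep(groups, each = length(stages) * m),
             life_stage = "juvenile",
             ontogenetic_stage = rep(rep(stages, each = m), length(groups)))
}

test_that("trajectory attributes match their definitions on built cases", {
  # collinear stage means with equal step s: path length 3s, direction along
  # the line
  p <- 8; m <- 6; s_len <- 0.5
  dirvec <- c(1, rep(0, p - 1))
  md <- traj_metadata("A", 1:4, m)
  Y <- t(vapply(seq_len(nrow(md)), function(i)
    (md$ontogenetic_stage[i] - 1) * s_len * dirvec, numeric(p)))
  tr <- build_trajectories(make_aligned(Y, md))
  expect_equal(tr$summaries$A$path_length, 3 * s_len, tolerance = 1e-10)
  expect_equal(abs(sum(tr$summaries$A$direction * dirvec)), 1,
               tolerance = 1e-10)
  expect_false(tr$summaries$A$degenerate)
  # oriented from stage 1 toward stage 4
  expect_gt(sum(tr$summaries$A$direction * dirvec), 0)

  # all stages identical: degenerate, zero length
  Y0 <- matrix(rep(c(1, 2, 0, 0, 0, 0, 0, 0), nrow(md)), nrow(md),
               byrow = TRUE)
  tr0 <- build_trajectories(make_aligned(Y0, md))
  expect_true(tr0$summaries$A$degenerate)
  expect_equal(tr0$summaries$A$path_length, 0)
})

test_that("stage means equal brute-force cell averages", {
  set.seed(41)
  md <- traj_metadata(c("A", "B"), 1:4, 5)
  Y <- matrix(rnorm(nrow(md) * 10), nrow(md), 10)
  tr <- build_trajectories(make_aligned(Y, md))
  for (g in c("A", "B")) for (st in 1:4) {
    idx <- md$species == g & md$ontogenetic_stage == st
    expect_equal(unname(tr$summaries[[g]]$stage_means[as.character(st), ]),
                 unname(colMeans(Y[idx, ])), tolerance = 1e-12)
  }
  md2 <- md[md$species != "B" | md$ontogenetic_stage != 3, ]
  expect_error(build_trajectories(make_aligned(Y[seq_len(nrow(md2)), ], md2)),
               "empty cell")
})

test_that("constructed orthogonal trajectories are recovered at 90 degrees", {
  set.seed(42)
  p <- 12; m <- 8
  md <- traj_metadata(c("A", "B"), 1:4, m)
  d1 <- c(1, rep(0, p - 1)); d2 <- c(0, 1, rep(0, p - 2))
  Y <- 0.02 * matrix(rnorm(nrow(md) * p), nrow(md), p)
  for (i in seq_len(nrow(md))) {
    d <- if (md$species[i] == "A") d1 else d2
    Y[i, ] <- Y[i, ] + (md$ontogenetic_stage[i] - 1) * d
  }
  tr <- build_trajectories(make_aligned(Y, md))
  cmp <- compare_trajectories(tr, n_perm = 199, seed = 2)
  expect_equal(cmp$theta["A", "B"], 90, tolerance = 2)
  expect_lte(cmp$p_theta["A", "B"], 0.05)
  expect_equal(cmp$theta, t(cmp$theta))
  expect_equal(diag(cmp$theta), c(A = 0, B = 0))
  expect_equal(diag(cmp$D), c(A = 0, B = 0))
})

test_that("identical trajectories give near-zero angle and shape distance", {
  set.seed(43)
  p <- 10; m <- 6
  md <- traj_metadata(c("A", "B"), 1:4, m)
  path <- rbind(rep(0, p),
                c(0.5, 0.1, rep(0, p - 2)),
                c(1.0, 0.4, rep(0, p - 2)),
                c(1.5, 1.0, rep(0, p - 2)))
  Y <- t(vapply(seq_len(nrow(md)), function(i)
    path[md$ontogenetic_stage[i], ], numeric(p))) +
    1e-4 * matrix(rnorm(nrow(md) * p), nrow(md), p)
  cmp <- compare_trajectories(build_trajectories(make_aligned(Y, md)),
                              n_perm = 199, seed = 3)
  expect_lt(cmp$theta["A", "B"], 2)
  expect_lt(cmp$D["A", "B"], 0.01)
  expect_lt(cmp$magnitude["A", "B"], 0.01)
})

test_that("trajectory shape distance is invariant to rigid rotation of the
          trajectory in the plane of its leading axes", {
  set.seed(44)
  p <- 14
  Z1 <- matrix(rnorm(4 * p), 4, p)
  Z1 <- scale(Z1, scale = FALSE)
  Z1 <- Z1 / sqrt(sum(Z1^2))
  # rotate within the plane of the two leading axes of Z1
  sv <- svd(Z1)
  a1 <- sv$v[, 1]; a2 <- sv$v[, 2]
  th <- 0.83
  R <- diag(p) +
    (cos(th) - 1) * (a1 %o% a1 + a2 %o% a2) +
    sin(th) * (a2 %o% a1 - a1 %o% a2)
  Z2 <- Z1 %*% t(R)
  expect_lt(ontomorph:::trajectory_shape_distance(Z1, Z2), 1e-6)
  # and a uniformly scaled copy has distance zero after size standardization
  Z3 <- scale(5 * Z1, scale = FALSE); Z3 <- Z3 / sqrt(sum(Z3^2))
  expect_lt(ontomorph:::trajectory_shape_distance(Z1, Z3), 1e-10)
})

test_that("degenerate trajectories are reported as undefined in comparisons", {
  set.seed(45)
  p <- 8
  md <- traj_metadata(c("A", "B"), 1:4, 4)
  Y <- matrix(0, nrow(md), p)
  sel <- md$species == "B"
  Y[sel, 1] <- (md$ontogenetic_stage[sel] - 1) * 0.5
  cmp <- compare_trajectories(build_trajectories(make_aligned(Y, md)),
                              n_perm = 49, seed = 1)
  expect_true(is.na(cmp$theta["A", "B"]))
  expect_true(is.na(cmp$p_theta["A", "B"]))
  expect_false(is.na(cmp$magnitude["A", "B"]))
})
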