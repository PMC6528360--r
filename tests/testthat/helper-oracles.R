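# Test fixtures and independent oracles. Everything is generated in code;
# oracles deliberately use different computational routes than the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap an n x 2k matrix as an aligned_dataset so linear-model machinery can
# be exercised on exactly known inputs, bypassing GPA.
make_aligned <- function(Y, metadata = NULL, csize = NULL) {
  Y <- as.matrix(Y)
  ids <- metadata$specimen_id %||% paste0("s", seq_len(nrow(Y)))
  rownames(Y) <- ids
  if (!is.null(metadata)) metadata$centroid_size <- csize %||% rep(1, nrow(Y))
  structure(list(shapes = matrix_to_arr(Y),
                 consensus = matrix(colMeans(Y), ncol = 2L, byrow = TRUE),
                 centroid_sizes = stats::setNames(csize %||% rep(1, nrow(Y)), ids),
                 sliders = matrix(integer(0), ncol = 3L),
                 metadata = metadata,
                 iterations = 1L, converged = TRUE),
            class = "aligned_dataset")
}

# Random non-degenerate k-landmark configurations.
random_config_matrix <- function(k, spread = 1) {
  cbind(stats::rnorm(k, sd = spread), stats::rnorm(k, sd = spread))
}

# Brute-force GPA by alternating optimization, with rotations found through
# the closed-form 2D angle (independent of the SVD route in the package).
oracle_gpa <- function(mats, max_iter = 5000, tol = 1e-14) {
  shapes <- lapply(mats, function(m) {
    m <- sweep(m, 2, colMeans(m), "-")
    m / sqrt(sum(m^2))
  })
  cons <- shapes[[1]]
  for (it in seq_len(max_iter)) {
    shapes <- lapply(shapes, function(X) oracle_rotate(X, cons))
    nc <- Reduce(`+`, shapes) / length(shapes)
    nc <- sweep(nc, 2, colMeans(nc), "-")
    nc <- nc / sqrt(sum(nc^2))
    ch <- sqrt(mean((nc - cons)^2))
    cons <- nc
    if (ch < tol) break
  }
  list(shapes = shapes, consensus = Reduce(`+`, shapes) / length(shapes))
}

# Rotate X onto C by the closed-form optimal 2D rotation angle. With the
# column-major rotation matrix below, (X R) = (x cos + y sin, -x sin + y cos),
# so the angle maximizing the match is atan2(sum(y Cx - x Cy), sum(x Cx + y Cy)).
oracle_rotate <- function(X, C) {
  th <- atan2(sum(X[, 2] * C[, 1] - X[, 1] * C[, 2]),
              sum(X[, 1] * C[, 1] + X[, 2] * C[, 2]))
  X %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
}

# TPS bending energy of a scalar deformation z over a reference, via the
# interpolation route: solve the full TPS system for the warp coefficients
# and evaluate w' K w (independent of the L-inverse block extraction).
tps_energy_oracle <- function(ref, z) {
  k <- nrow(ref)
  d <- as.matrix(stats::dist(ref))
  K <- ifelse(d > 0, d^2 * log(d), 0)
  Q <- cbind(1, ref)
  A <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  w <- qr.solve(A, c(z, 0, 0, 0))[seq_len(k)]
  sum(w * (K %*% w))
}

# Sequential one-term ANOVA via explicit hat matrices.
anova_oracle_one_term <- function(Y, groups) {
  n <- nrow(Y)
  H <- function(X) X %*% solve(crossprod(X), t(X))
  H0 <- H(matrix(1, n, 1))
  H1 <- H(stats::model.matrix(~groups))
  ss <- sum(((H1 - H0) %*% Y)^2)
  rss <- sum(((diag(n) - H1) %*% Y)^2)
  df1 <- nlevels(groups) - 1L
  dfr <- n - nlevels(groups)
  list(SS = ss, RSS = rss, F = (ss / df1) / (rss / dfr))
}

# Shapes built on the principal-warp basis of a reference, with prescribed
# per-warp score standard deviations (per axis). Returns an aligned_dataset
# whose consensus is the reference.
shapes_from_warps <- function(ref, sd_per_warp, n) {
  B <- bending_energy_matrix(ref)
  ev <- eigen(B, symmetric = TRUE)
  ord <- order(ev$values)
  warps <- ev$vectors[, ord[-(1:3)], drop = FALSE]
  k <- nrow(ref)
  shapes <- array(NA_real_, c(k, 2, n))
  for (i in seq_len(n)) {
    zx <- stats::rnorm(ncol(warps), sd = sd_per_warp)
    zy <- stats::rnorm(ncol(warps), sd = sd_per_warp)
    shapes[, , i] <- ref + cbind(warps %*% zx, warps %*% zy)
  }
  ids <- paste0("s", seq_len(n))
  dimnames(shapes) <- list(NULL, c("x", "y"), ids)
  structure(list(shapes = shapes, consensus = ref,
                 centroid_sizes = stats::setNames(rep(1, n), ids),
                 sliders = matrix(integer(0), ncol = 3L),
                 metadata = NULL, iterations = 1L, converged = TRUE),
            class = "aligned_dataset")
}

# n x 2k coordinate data (x1,y1,x2,y2,...) with a given per-axis landmark
# correlation matrix (x and y independent).
correlated_coord_data <- function(n, Rcor, sd = 1) {
  k <- nrow(Rcor)
  U <- chol(Rcor)
  Y <- matrix(NA_real_, n, 2 * k)
  for (i in seq_len(n)) {
    x <- sd * drop(crossprod(U, stats::rnorm(k)))
    y <- sd * drop(crossprod(U, stats::rnorm(k)))
    Y[i, ] <- as.vector(rbind(x, y))
  }
  Y
}

module_correlation <- function(partition, within, between) {
  same <- outer(partition, partition, "==")
  R <- ifelse(same, within, between)
  diag(R) <- 1
  R
}

# Small simulation config with all deterministic structure switched off
# (pure noise around the template) — used for covariance-level tests.
noise_only_config <- function(n, noise_sd, within = 0.5, between = 0.2,
                              seed = 1L, stages = 1L) {
  ontogeny_sim_config(n_species = 1L, stages = stages, n_per_cell = n,
                      offset_scale = 0, trajectory_scale = 0,
                      divergence_scale = 0, allometry_scale = 0,
                      noise_sd = noise_sd, within_module_corr = within,
                      between_module_corr = between, seed = seed)
}
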