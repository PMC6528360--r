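# Generalized Procrustes alignment, thin-plate-spline bending energy,
# semilandmark sliding and partial warps.

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances between each landmark
#' and the configuration centroid — the standard geometric size measure.
#' Scales linearly with the configuration (`CS(c * X) = c * CS(X)`).
#'
#' @param coords A `k x 2` coordinate matrix or a [landmark_config()].
#' @return Non-negative scalar; 0 only when all landmarks coincide.
#' @export
centroid_size <- function(coords) {
  if (inherits(coords, "landmark_config")) coords <- coords$coords
  coords <- as.matrix(coords)
  sqrt(sum(center_config(coords)^2))
}

# Optimal rotation (det +1) carrying X onto target C, both centered.
optimal_rotation <- function(X, C) {
  s <- svd(crossprod(X, C))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 2L] <- -u[, 2L]
    R <- u %*% t(s$v)
  }
  R
}

#' Full Procrustes distance between two configurations
#'
#' Centers, scales to unit centroid size and optimally rotates (no
#' reflection) before taking the root summed squared difference.
#'
#' @param a,b `k x 2` coordinate matrices with the same `k`.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- center_config(as.matrix(a)); a <- a / sqrt(sum(a^2))
  b <- center_config(as.matrix(b)); b <- b / sqrt(sum(b^2))
  R <- optimal_rotation(a, b)
  sqrt(sum((b - a %*% R)^2))
}

# Canonical orientation: rotate all shapes so the consensus lies along its
# principal axes, det +1, with the 180-degree ambiguity fixed by the sign of
# the x coordinate of the landmark farthest from the centroid along x.
canonical_rotation <- function(consensus) {
  ev <- eigen(stats::cov(consensus), symmetric = TRUE)
  R <- ev$vectors
  if (det(R) < 0) R[, 2L] <- -R[, 2L]
  rotated <- consensus %*% R
  j <- which.max(abs(rotated[, 1L]))
  if (rotated[j, 1L] < 0) R <- -R  # 180-degree rotation, det unchanged
  R
}

#' Generalized Procrustes alignment
#'
#' Iteratively removes translation (centering), size (unit centroid size)
#' and rotation (least-squares fit to an updating consensus via SVD, with
#' reflections disallowed) from a set of landmark configurations. When
#' `slide = TRUE` and slider triples are present, each iteration interleaves
#' a bending-energy-minimizing semilandmark sliding step (see
#' [slide_semilandmarks()]) before re-superimposition; the mean slide
#' displacement across specimens is removed each iteration (a common drift
#' of semilandmarks along their curves moves shapes and consensus together
#' without changing relative bending energy, so it is a gauge freedom that
#' would otherwise keep the consensus wandering), and sliding is frozen
#' once its root-mean-square displacement falls below `sqrt(tol)`. The
#' total bending energy before and after each sliding step is recorded in
#' the result's `slide_bending_energy` matrix. The converged
#' solution is rotated to a canonical orientation (principal axes of the
#' consensus), so the output is invariant under similarity transforms of
#' the input configurations.
#'
#' @param configs List of [landmark_config()] objects sharing `k` and
#'   slider definitions, or a `k x 2 x n` array.
#' @param slide Logical; slide semilandmarks during alignment.
#' @param slide_iter Maximum number of iterations that include a sliding
#'   step (default 20); sliding also stops earlier once its displacements
#'   settle. Subsequent iterations are plain GPA, which converges to
#'   machine-level tolerance.
#' @param max_iter Maximum number of alignment iterations.
#' @param tol Convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param metadata Optional data frame of specimen metadata (matched by
#'   `specimen_id` or row order); carried into the result.
#' @return An object of class `aligned_dataset` with elements `shapes`
#'   (`k x 2 x n` aligned coordinates), `consensus` (`k x 2`),
#'   `centroid_sizes` (original units), `sliders`, `metadata`,
#'   `iterations` and `converged`.
#' @export
gpa_align <- function(configs, slide = TRUE, slide_iter = 20L,
                      max_iter = 100L, tol = 1e-8, metadata = NULL) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    ids <- dimnames(configs)[[3]]
    if (is.null(ids)) ids <- paste0("specimen_", seq_len(dim(configs)[3]))
    configs <- lapply(seq_len(dim(configs)[3]), function(i)
      landmark_config(ids[i], configs[, , i]))
  }
  n <- length(configs)
  if (n == 0L) stop("empty dataset")
  k <- nrow(configs[[1L]]$coords)
  sliders <- configs[[1L]]$sliders
  for (cfg in configs) {
    if (nrow(cfg$coords) != k)
      stop("all configurations must share the same number of landmarks ",
           "(specimen '", cfg$specimen_id, "' has ", nrow(cfg$coords),
           ", expected ", k, ")")
    if (!identical(unname(cfg$sliders), unname(sliders)))
      stop("all configurations must share slider definitions")
  }
  ids <- vapply(configs, function(cfg) cfg$specimen_id, character(1))
  cs <- vapply(configs, function(cfg) centroid_size(cfg$coords), numeric(1))
  if (any(cs <= 0)) stop("degenerate configuration (centroid size 0): ",
                         paste(ids[cs <= 0], collapse = ", "))

  shapes <- array(NA_real_, c(k, 2L, n), dimnames = list(NULL, c("x", "y"), ids))
  for (i in seq_len(n))
    shapes[, , i] <- center_config(configs[[i]]$coords) / cs[i]

  do_slide <- slide && nrow(sliders) > 0L && n > 1L
  consensus <- shapes[, , 1L]
  iter <- 0L; change <- Inf
  slide_be <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      shapes[, , i] <- shapes[, , i] %*% optimal_rotation(shapes[, , i], consensus)
    if (do_slide) {
      B <- bending_energy_matrix(consensus)
      be_pre <- sum(bending_energy(shapes, consensus, B))
      slid <- slide_semilandmarks(shapes, consensus, sliders)
      be_post <- sum(bending_energy(slid, consensus, B))
      slide_be <- rbind(slide_be, c(before = be_pre, after = be_post))
      # remove the mean slide displacement (common drift of semilandmarks
      # along the curves is a gauge freedom: it moves shapes and consensus
      # together without changing relative bending energy)
      drift <- apply(slid - shapes, c(1L, 2L), mean)
      rms_slide <- sqrt(mean((slid - shapes)^2))
      shapes <- sweep(slid, c(1L, 2L), drift, "-")
      for (i in seq_len(n)) {
        sh <- center_config(shapes[, , i])
        sh <- sh / sqrt(sum(sh^2))
        shapes[, , i] <- sh %*% optimal_rotation(sh, consensus)
      }
      # freeze sliding once settled (or after slide_iter rounds) and let
      # plain GPA polish to full convergence
      if (rms_slide < sqrt(tol) || iter >= slide_iter) do_slide <- FALSE
    }
    new_consensus <- apply(shapes, c(1L, 2L), mean)
    new_consensus <- center_config(new_consensus)
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    change <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (change < tol) break
  }
  converged <- change < tol
  if (!converged)
    warning("GPA did not converge in ", max_iter,
            " iterations (last consensus RMS change ", signif(change, 3), ")")

  # store the plain arithmetic mean of the aligned shapes as the consensus
  # (the unit-scaled version above is an internal iteration target only)
  consensus <- center_config(apply(shapes, c(1L, 2L), mean))
  R <- canonical_rotation(consensus)
  consensus <- consensus %*% R
  for (i in seq_len(n)) shapes[, , i] <- shapes[, , i] %*% R

  if (!is.null(metadata)) {
    if (!is.null(metadata$specimen_id) &&
        all(ids %in% metadata$specimen_id)) {
      metadata <- metadata[match(ids, metadata$specimen_id), , drop = FALSE]
      rownames(metadata) <- NULL
    } else if (nrow(metadata) != n) {
      stop("metadata rows do not match specimens")
    }
    metadata$centroid_size <- cs
  }
  structure(list(shapes = shapes, consensus = consensus,
                 centroid_sizes = stats::setNames(cs, ids),
                 sliders = sliders, metadata = metadata,
                 iterations = iter, converged = converged,
                 slide_bending_energy = slide_be),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  d <- dim(x$shapes)
  cat("GPA-aligned dataset: ", d[3], " specimens, ", d[1], " landmarks (",
      nrow(x$sliders), " semilandmarks), ", x$iterations, " iterations",
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' Thin-plate-spline bending energy matrix
#'
#' Builds the standard 2D TPS bending energy matrix of a reference shape:
#' with kernel `U(r) = r^2 log(r)` (`U(0) = 0`), assemble
#' `L = [[K, Q], [Q', 0]]` where `K_ij = U(|p_i - p_j|)` and
#' `Q = [1, x, y]`; the bending energy matrix is the upper-left `k x k`
#' block of `L^-1`, numerically symmetrized. It is positive semidefinite
#' and annihilates affine deformations (three null directions in 2D).
#'
#' @param reference `k x 2` coordinate matrix with no coincident landmarks.
#' @return Symmetric `k x k` matrix.
#' @export
bending_energy_matrix <- function(reference) {
  reference <- as.matrix(reference)
  k <- nrow(reference)
  d <- as.matrix(stats::dist(reference))
  if (any(d[upper.tri(d)] == 0)) {
    pair <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1L, ]
    stop("coincident landmarks ", pair[1L], " and ", pair[2L],
         " make the TPS system singular")
  }
  K <- ifelse(d > 0, d^2 * log(d), 0)
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Linv <- solve(L)
  B <- Linv[seq_len(k), seq_len(k)]
  (B + t(B)) / 2
}

# Total TPS bending energy of shapes relative to a reference (sums both
# coordinate axes). `shapes` may be k x 2 or k x 2 x n.
bending_energy <- function(shapes, reference, B = NULL) {
  if (is.null(B)) B <- bending_energy_matrix(reference)
  one <- function(sh) sum(sh[, 1L] * (B %*% sh[, 1L])) +
    sum(sh[, 2L] * (B %*% sh[, 2L]))
  if (length(dim(shapes)) == 3L)
    vapply(seq_len(dim(shapes)[3]), function(i) one(shapes[, , i]), numeric(1))
  else one(shapes)
}

#' Slide semilandmarks to minimize bending energy
#'
#' Each semilandmark is displaced along its tangent direction (the unit
#' chord from its `before` to its `after` neighbour in the current shape);
#' displacement magnitudes solve the linear least-squares problem that
#' minimizes the TPS bending energy of the shape relative to the reference.
#' Bending energy relative to the reference never increases.
#'
#' @param shapes `k x 2 x n` array (or single `k x 2` matrix) of shapes
#'   comparable to `reference`.
#' @param reference `k x 2` reference shape (typically the GPA consensus).
#' @param sliders Integer `m x 3` slider triples, 1-indexed.
#' @return Array (or matrix) of the same shape with semilandmarks slid.
#' @export
slide_semilandmarks <- function(shapes, reference, sliders) {
  single <- length(dim(shapes)) != 3L
  if (single) shapes <- array(shapes, c(dim(shapes), 1L))
  if (nrow(sliders) == 0L) return(if (single) shapes[, , 1L] else shapes)
  B <- bending_energy_matrix(reference)
  s_idx <- sliders[, 2L]
  m <- length(s_idx)
  for (i in seq_len(dim(shapes)[3])) {
    sh <- shapes[, , i]
    tang <- sh[sliders[, 3L], , drop = FALSE] - sh[sliders[, 1L], , drop = FALSE]
    len <- sqrt(rowSums(tang^2))
    if (any(len == 0))
      stop("zero-length tangent for slider at landmark ",
           s_idx[which(len == 0)[1L]])
    tang <- tang / len
    Bss <- B[s_idx, s_idx, drop = FALSE]
    # M[a,b] = t_a . t_b * B[s_a, s_b] restricted per axis
    M <- Bss * (tang[, 1L] %o% tang[, 1L]) + Bss * (tang[, 2L] %o% tang[, 2L])
    g <- (B %*% sh[, 1L])[s_idx] * tang[, 1L] +
         (B %*% sh[, 2L])[s_idx] * tang[, 2L]
    lambda <- tryCatch(solve(M, -g),
                       error = function(e) qr.solve(M + diag(1e-12, m), -g))
    sh[s_idx, ] <- sh[s_idx, ] + as.vector(lambda) * tang
    shapes[, , i] <- sh
  }
  if (single) shapes[, , 1L] else shapes
}

#' Principal warps and partial-warp scores
#'
#' Eigendecomposes the bending energy matrix of the consensus, discards the
#' three null (affine) eigenvectors, and projects each aligned shape's
#' deviation from the consensus onto the remaining principal warps, per
#' coordinate axis. Eigenvalues are returned in ascending order (large-scale
#' to localized deformation). Scores on the null-space basis are kept as the
#' affine (uniform) component so that consensus + warps + uniform
#' reconstructs every shape exactly.
#'
#' @param aligned An `aligned_dataset` from [gpa_align()].
#' @return An object of class `tps_basis` with elements `reference`,
#'   `bending_energies` (`k - 3` ascending eigenvalues), `principal_warps`
#'   (`k x (k-3)` orthonormal columns), `scores` (`n x (k-3) x 2`),
#'   `uniform_basis` (`k x 3`), `uniform_scores` (`n x 3 x 2`).
#' @export
partial_warp_scores <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  ref <- aligned$consensus
  k <- nrow(ref)
  B <- bending_energy_matrix(ref)
  ev <- eigen(B, symmetric = TRUE)
  ord <- order(ev$values)            # ascending
  vals <- ev$values[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  null_idx <- seq_len(3L)            # three affine null directions in 2D
  warp_idx <- setdiff(seq_len(k), null_idx)
  warps <- vecs[, warp_idx, drop = FALSE]
  uniform <- vecs[, null_idx, drop = FALSE]
  be <- pmax(vals[warp_idx], 0)
  n <- dim(aligned$shapes)[3]
  scores <- array(NA_real_, c(n, k - 3L, 2L))
  uscores <- array(NA_real_, c(n, 3L, 2L))
  for (i in seq_len(n)) {
    dev <- aligned$shapes[, , i] - ref
    scores[i, , ] <- crossprod(warps, dev)
    uscores[i, , ] <- crossprod(uniform, dev)
  }
  structure(list(reference = ref, bending_energies = be,
                 principal_warps = warps, scores = scores,
                 uniform_basis = uniform, uniform_scores = uscores),
            class = "tps_basis")
}

#' @export
print.tps_basis <- function(x, ...) {
  cat("TPS basis: ", length(x$bending_energies), " principal warps, BE in [",
      signif(min(x$bending_energies), 3), ", ",
      signif(max(x$bending_energies), 3), "]\n", sep = "")
  invisible(x)
}
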