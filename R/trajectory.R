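# Phenotypic trajectory analysis: per-group sequences of stage means with
# magnitude, direction and shape attributes, compared by RRPP permutation.

# Cell means of Y (n x p) for every group x stage combination.
# Returns a list per group of (n_stages x p) matrices, stage-ordered.
cell_means <- function(Y, group, stage) {
  lv_g <- levels(group); lv_s <- levels(stage)
  out <- vector("list", length(lv_g)); names(out) <- lv_g
  for (g in lv_g) {
    M <- matrix(NA_real_, length(lv_s), ncol(Y),
                dimnames = list(lv_s, NULL))
    for (s in lv_s) {
      idx <- group == g & stage == s
      if (!any(idx)) stop("empty cell: group '", g, "', stage '", s, "'")
      M[s, ] <- colMeans(Y[idx, , drop = FALSE])
    }
    out[[g]] <- M
  }
  out
}

trajectory_attributes <- function(means) {
  q <- nrow(means)
  steps <- means[-1L, , drop = FALSE] - means[-q, , drop = FALSE]
  path_length <- sum(sqrt(rowSums(steps^2)))
  degenerate <- path_length < 1e-12
  direction <- rep(NA_real_, ncol(means))
  if (!degenerate) {
    dev <- sweep(means, 2L, colMeans(means), "-")
    sv <- svd(dev, nu = 0, nv = 1)
    direction <- sv$v[, 1L]
    endpoint <- means[q, ] - means[1L, ]
    if (sum(direction * endpoint) < 0) direction <- -direction
  }
  shape <- sweep(means, 2L, colMeans(means), "-")
  nrm <- sqrt(sum(shape^2))
  if (nrm > 0) shape <- shape / nrm
  list(path_length = path_length, direction = direction,
       trajectory_shape = shape, degenerate = degenerate)
}

#' Build phenotypic trajectories across ontogenetic stages
#'
#' Computes, for every group, the ordered sequence of stage mean shapes
#' (least-squares means of the group-by-stage factorial, which for a fully
#' crossed design are the cell means) and the derived trajectory
#' attributes: magnitude (`path_length`, the summed Euclidean distances
#' between consecutive stage means), direction (the leading principal axis
#' of the stage means, oriented from the first toward the last stage), and
#' trajectory shape (the stage means treated as a point configuration,
#' centered and scaled to unit size).
#'
#' @param aligned An `aligned_dataset` with metadata.
#' @param group,stage Metadata column names (defaults `"species"`,
#'   `"ontogenetic_stage"`).
#' @return Object of class `trajectory_set`: per-group summaries plus the
#'   data needed by [compare_trajectories()].
#' @export
build_trajectories <- function(aligned, group = "species",
                               stage = "ontogenetic_stage") {
  Y <- arr_to_matrix(aligned$shapes)
  md <- aligned$metadata
  if (is.null(md) || is.null(md[[group]]) || is.null(md[[stage]]))
    stop("metadata must contain columns '", group, "' and '", stage, "'")
  g <- factor(md[[group]])
  s <- factor(md[[stage]], levels = sort(unique(md[[stage]])))
  means <- cell_means(Y, g, s)
  summaries <- lapply(names(means), function(nm) {
    att <- trajectory_attributes(means[[nm]])
    c(list(group = nm, stage_means = means[[nm]]), att)
  })
  names(summaries) <- names(means)
  structure(list(summaries = summaries, Y = Y, group = g, stage = s),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Phenotypic trajectories (", nlevels(x$group), " groups x ",
      nlevels(x$stage), " stages)\n", sep = "")
  for (s in x$summaries)
    cat("  ", s$group, ": path length ", signif(s$path_length, 4),
        if (s$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

# Procrustes distance between two centered, unit-size trajectory shapes,
# with the orthogonal rotation computed in their joint span.
trajectory_shape_distance <- function(Z1, Z2) {
  span <- qr(t(rbind(Z1, Z2)))
  Qs <- qr.Q(span)[, seq_len(span$rank), drop = FALSE]
  A <- Z1 %*% Qs
  Bm <- Z2 %*% Qs
  sv <- svd(crossprod(Bm, A))
  R <- sv$u %*% t(sv$v)
  sqrt(sum((A - Bm %*% R)^2))
}

trajectory_stats <- function(means_list) {
  atts <- lapply(means_list, trajectory_attributes)
  nm <- names(means_list)
  ng <- length(nm)
  theta <- D <- mag <- matrix(0, ng, ng, dimnames = list(nm, nm))
  for (a in seq_len(ng)) for (b in seq_len(ng)) if (a < b) {
    if (atts[[a]]$degenerate || atts[[b]]$degenerate) {
      theta[a, b] <- theta[b, a] <- NA_real_
      D[a, b] <- D[b, a] <- NA_real_
    } else {
      theta[a, b] <- theta[b, a] <-
        vector_angle(atts[[a]]$direction, atts[[b]]$direction, absolute = TRUE)
      D[a, b] <- D[b, a] <-
        trajectory_shape_distance(atts[[a]]$trajectory_shape,
                                  atts[[b]]$trajectory_shape)
    }
    mag[a, b] <- mag[b, a] <- abs(atts[[a]]$path_length - atts[[b]]$path_length)
  }
  list(theta = theta, D = D, magnitude = mag)
}

#' Compare phenotypic trajectories between groups
#'
#' Pairwise differences in trajectory direction (angle between leading
#' axes, folded to 0-90 degrees since principal-axis sign is arbitrary),
#' trajectory shape (Procrustes distance between the superimposed
#' stage-mean configurations) and magnitude (absolute path-length
#' difference). Null distributions for all three attributes share one RRPP
#' permutation stream: residuals of the additive model lacking the
#' group-by-stage interaction (`shape ~ group + stage`) are permuted and
#' the trajectories rebuilt. Pairs involving a degenerate (zero-length)
#' trajectory are reported as `NA` for angle and shape.
#'
#' @param trajectories A `trajectory_set` from [build_trajectories()].
#' @param n_perm,seed Permutation count and seed.
#' @return Object of class `trajectory_comparison` with matrices `theta`,
#'   `D`, `magnitude` and per-attribute `Z_*` and `p_*` matrices.
#' @export
compare_trajectories <- function(trajectories, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  Y <- trajectories$Y
  g <- trajectories$group
  s <- trajectories$stage
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  means <- cell_means(Y, g, s)
  obs <- trajectory_stats(means)

  X0 <- stats::model.matrix(~ g + s)
  q0 <- qr(X0)
  fitted0 <- qr.fitted(q0, Y)
  resid0 <- Y - fitted0
  n <- nrow(Y)
  perms <- permutation_indices(n, n_perm, seed)
  ng <- nlevels(g)
  null_theta <- null_D <- null_mag <- array(NA_real_, c(n_perm, ng, ng))
  for (p in seq_len(n_perm)) {
    Yp <- fitted0 + resid0[perms[, p], , drop = FALSE]
    st <- trajectory_stats(cell_means(Yp, g, s))
    null_theta[p, , ] <- st$theta
    null_D[p, , ] <- st$D
    null_mag[p, , ] <- st$magnitude
  }
  mk <- function(nullarr, obsmat) {
    Zm <- pm <- matrix(NA_real_, ng, ng, dimnames = dimnames(obsmat))
    for (a in seq_len(ng)) for (b in seq_len(ng)) if (a < b) {
      ob <- obsmat[a, b]
      if (is.na(ob)) next
      nll <- nullarr[, a, b]
      nll <- nll[!is.na(nll)]
      pm[a, b] <- pm[b, a] <- perm_pvalue(nll, ob, "upper")
      Zm[a, b] <- Zm[b, a] <- perm_zscore(nll, ob)
    }
    list(Z = Zm, p = pm)
  }
  th <- mk(null_theta, obs$theta)
  dd <- mk(null_D, obs$D)
  mm <- mk(null_mag, obs$magnitude)
  structure(list(theta = obs$theta, D = obs$D, magnitude = obs$magnitude,
                 Z_theta = th$Z, p_theta = th$p,
                 Z_D = dd$Z, p_D = dd$p,
                 Z_magnitude = mm$Z, p_magnitude = mm$p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat("Trajectory comparison (", x$n_perm, " permutations)\n", sep = "")
  print(trajectory_comparison_table(x), row.names = FALSE)
  invisible(x)
}

#' Long-format table of pairwise trajectory comparisons
#'
#' One row per group pair with columns pair, theta, Z_theta, p_theta, D,
#' Z_D, p_D, magnitude_diff, Z_magnitude, p_magnitude.
#'
#' @param x A `trajectory_comparison`.
#' @return A data frame.
#' @export
trajectory_comparison_table <- function(x) {
  lv <- rownames(x$theta)
  rows <- list()
  for (a in seq_along(lv)) for (b in seq_along(lv)) if (a < b) {
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(lv[a], lv[b], sep = " - "),
      theta = x$theta[a, b], Z_theta = x$Z_theta[a, b],
      p_theta = x$p_theta[a, b],
      D = x$D[a, b], Z_D = x$Z_D[a, b], p_D = x$p_D[a, b],
      magnitude_diff = x$magnitude[a, b],
      Z_magnitude = x$Z_magnitude[a, b],
      p_magnitude = x$p_magnitude[a, b],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
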