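# Modularity (covariance ratio, CR) and global integration (GI).

# Landmark-block squared-covariance sums: LS[i, j] = sum of squared
# entries of the 2 x 2 (x, y) covariance block between landmarks i and j.
landmark_block_sums <- function(S, k) {
  xs <- 2 * seq_len(k) - 1L
  ys <- xs + 1L
  S[xs, xs]^2 + S[xs, ys]^2 + S[ys, xs]^2 + S[ys, ys]^2
}

cr_from_blocks <- function(LS, partition) {
  lv <- unique(partition)
  # exclude diagonal (within-landmark x-y blocks) from all sums
  LS0 <- LS
  diag(LS0) <- 0
  pair_cr <- function(a, b) {
    ia <- partition == a; ib <- partition == b
    between <- sum(LS0[ia, ib])
    wa <- sum(LS0[ia, ia]); wb <- sum(LS0[ib, ib])
    if (wa <= 0 || wb <= 0) return(NA_real_)
    sqrt(between / sqrt(wa * wb))
  }
  crs <- c()
  for (a in seq_along(lv)) for (b in seq_along(lv)) if (a < b)
    crs <- c(crs, pair_cr(lv[a], lv[b]))
  mean(crs)
}

#' Covariance ratio (CR) test of modularity
#'
#' With `S` the `2k x 2k` covariance matrix of landmark coordinates, CR is
#' the square root of the ratio of the summed squared between-module
#' covariances to the geometric mean of the summed squared within-module
#' covariances, where within-landmark (x, y) blocks and diagonals are
#' excluded from all sums. CR < 1 indicates relatively modular structure.
#' The null distribution — centered on 1 for non-modular data — is built
#' by randomly reassigning whole landmarks (x and y travel together) to
#' modules of the same sizes; significance is the proportion of null CR
#' values at or below the observed one, with the `(1 + count)/(1 + n_perm)`
#' convention. For more than two modules the average of pairwise CRs is
#' used.
#'
#' @param shapes `k x 2 x n` array, `n x 2k` matrix, or `aligned_dataset`
#'   (typically the shapes of one group).
#' @param partition Character vector of module labels, one per landmark;
#'   each module needs at least 3 landmarks.
#' @param n_perm,seed Permutation count and seed.
#' @return Object of class `cr_result` with `CR`, `null`, `p`,
#'   `partition`, `n_perm`, `seed`.
#' @export
covariance_ratio <- function(shapes, partition, n_perm = 1000L, seed = 1L) {
  Y <- if (inherits(shapes, "aligned_dataset")) arr_to_matrix(shapes$shapes)
       else if (length(dim(shapes)) == 3L) arr_to_matrix(shapes)
       else as.matrix(shapes)
  k <- ncol(Y) %/% 2L
  if (length(partition) != k)
    stop("partition length (", length(partition),
         ") does not match landmark count (", k, ")")
  validate_partition(partition)
  if (nrow(Y) < 3L) stop("need at least 3 specimens")
  S <- stats::cov(Y)
  LS <- landmark_block_sums(S, k)
  cr_obs <- cr_from_blocks(LS, partition)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(p)
    cr_from_blocks(LS, sample(partition)), numeric(1))
  p <- perm_pvalue(null[!is.na(null)], cr_obs, "lower")
  structure(list(CR = cr_obs, null = null, p = p, partition = partition,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "cr_result")
}

#' @export
print.cr_result <- function(x, ...) {
  cat("Covariance ratio CR = ", signif(x$CR, 4), " (null mean ",
      signif(mean(x$null, na.rm = TRUE), 3), ", p = ", signif(x$p, 4),
      ", ", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Global integration (GI) coefficient
#'
#' Regresses the log variance of each partial warp (summed over the x and
#' y score variances across specimens) on the log of its bending energy.
#' The slope describes how deformation variance scales with localization:
#' a slope of -1 is self-similarity, below -1 indicates integration
#' (variance concentrated in large-scale deformation), above -1
#' disintegration (localized shape variation). The slope is invariant to a
#' global rescaling of bending energies, so TPS kernel conventions do not
#' affect it. Warps with zero variance are dropped with a warning.
#'
#' @param tps_basis A `tps_basis` from [partial_warp_scores()], or an
#'   `aligned_dataset` (the basis is then computed from its consensus).
#' @param self_similar_band Half-width of the slope band around -1
#'   classified as self-similar (default 0.05).
#' @return Object of class `gi_result` with `slope`, `intercept`,
#'   `n_warps`, `classification`, and the per-warp `log_be` / `log_var`.
#' @export
global_integration <- function(tps_basis, self_similar_band = 0.05) {
  if (inherits(tps_basis, "aligned_dataset"))
    tps_basis <- partial_warp_scores(tps_basis)
  stopifnot(inherits(tps_basis, "tps_basis"))
  be <- tps_basis$bending_energies
  v <- apply(tps_basis$scores[, , 1L, drop = FALSE], 2L, stats::var) +
       apply(tps_basis$scores[, , 2L, drop = FALSE], 2L, stats::var)
  keep <- v > 0 & be > 0
  if (any(v == 0))
    warning(sum(v == 0), " partial warp(s) with zero variance dropped")
  if (sum(keep) < 2L)
    stop("need at least 2 partial warps with positive variance")
  lv <- log(v[keep]); lb <- log(be[keep])
  fit <- stats::lm(lv ~ lb)
  slope <- unname(stats::coef(fit)[2L])
  classification <-
    if (abs(slope + 1) <= self_similar_band) "self_similar"
    else if (slope < -1) "integrated" else "disintegrated"
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 n_warps = sum(keep), classification = classification,
                 log_be = lb, log_var = lv,
                 self_similar_band = self_similar_band),
            class = "gi_result")
}

#' @export
print.gi_result <- function(x, ...) {
  cat("Global integration: slope = ", signif(x$slope, 4), " (",
      x$classification, ", ", x$n_warps, " partial warps)\n", sep = "")
  invisible(x)
}

#' CR and GI profiles by group and stage
#'
#' Convenience wrapper computing the covariance ratio and the global
#' integration slope separately for every group-by-stage cell, as used to
#' trace integration and modularity along an ontogenetic series. The GPA
#' alignment and consensus of the full dataset are reused, so the TPS
#' basis is common to all cells and the profiles are comparable.
#'
#' @param aligned An `aligned_dataset` with metadata.
#' @param partition Module labels per landmark (for CR).
#' @param group,stage Metadata column names.
#' @param n_perm,seed Permutation count and base seed (one child seed per
#'   cell).
#' @return Data frame with one row per group-by-stage cell: `n`, `CR`,
#'   `p_CR`, `GI_slope`, `GI_class`.
#' @export
integration_profiles <- function(aligned, partition, group = "species",
                                 stage = "ontogenetic_stage",
                                 n_perm = 999L, seed = 1L) {
  md <- aligned$metadata
  g <- factor(md[[group]])
  s <- factor(md[[stage]], levels = sort(unique(md[[stage]])))
  rows <- list()
  for (gl in levels(g)) for (sl in levels(s)) {
    idx <- which(g == gl & s == sl)
    cell <- paste(gl, sl, sep = ":")
    if (length(idx) < 4L) {
      warning("cell ", cell, " has fewer than 4 specimens; skipped")
      next
    }
    sub <- aligned
    sub$shapes <- aligned$shapes[, , idx, drop = FALSE]
    cr <- covariance_ratio(sub$shapes, partition, n_perm = n_perm,
                           seed = derive_seed(seed, cell))
    gi <- tryCatch(global_integration(partial_warp_scores(sub)),
                   error = function(e) NULL)
    rows[[cell]] <- data.frame(
      group = gl, stage = sl, n = length(idx),
      CR = cr$CR, p_CR = cr$p,
      GI_slope = if (is.null(gi)) NA_real_ else gi$slope,
      GI_class = if (is.null(gi)) NA_character_ else gi$classification,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
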