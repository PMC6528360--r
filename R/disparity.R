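# Morphological disparity as Procrustes variance, with pairwise
# permutation tests.

#' Procrustes variance of a group of shapes
#'
#' The trace of the group covariance matrix with divisor `n` — equivalently
#' the mean squared deviation of group members from the group mean shape:
#' `sum(|shape_i - mean|^2) / n`.
#'
#' @param shapes `k x 2 x n` array, `n x 2k` matrix, or `aligned_dataset`.
#' @return Non-negative scalar; 0 iff all members share one shape
#'   (and for `n = 1`).
#' @export
procrustes_variance <- function(shapes) {
  Y <- if (inherits(shapes, "aligned_dataset")) arr_to_matrix(shapes$shapes)
       else if (length(dim(shapes)) == 3L) arr_to_matrix(shapes)
       else as.matrix(shapes)
  dev <- sweep(Y, 2L, colMeans(Y), "-")
  sum(dev^2) / nrow(Y)
}

group_variances <- function(Y, group) {
  vapply(levels(group), function(g)
    procrustes_variance(Y[group == g, , drop = FALSE]), numeric(1))
}

#' Morphological disparity test
#'
#' Procrustes variance per group with pairwise permutation tests of the
#' absolute variance differences. The null is built by permuting the
#' group-mean-centered residual vectors among groups (size structure of
#' the groups is preserved) and recomputing the variances; `p = (1 +
#' #null >= observed) / (1 + n_perm)`. Groups with fewer than 2 specimens
#' are excluded with a warning.
#'
#' @param aligned An `aligned_dataset` with metadata (or an `n x 2k`
#'   matrix, with `grouping` then a factor).
#' @param grouping Metadata column name(s) — e.g. `"species"`,
#'   `"ontogenetic_stage"` or `c("species", "ontogenetic_stage")` for the
#'   interaction — or a factor of length `n`.
#' @param n_perm,seed Permutation count and seed.
#' @return Object of class `disparity_result` with `variances`, pairwise
#'   `difference` and `p` matrices, `n_perm`, `seed`.
#' @export
disparity_test <- function(aligned, grouping = "species", n_perm = 10000L,
                           seed = 1L) {
  if (inherits(aligned, "aligned_dataset")) {
    Y <- arr_to_matrix(aligned$shapes)
    if (is.character(grouping)) {
      md <- aligned$metadata
      if (is.null(md) || !all(grouping %in% names(md)))
        stop("metadata must contain column(s): ",
             paste(grouping, collapse = ", "))
      grouping <- interaction(md[grouping], drop = TRUE, sep = ":")
    }
  } else {
    Y <- as.matrix(aligned)
  }
  g <- factor(grouping)
  small <- names(which(table(g) < 2L))
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 specimens: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    Y <- Y[keep, , drop = FALSE]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stop("need at least 2 groups with n >= 2")
  pv <- group_variances(Y, g)
  lv <- levels(g)
  obs <- abs(outer(pv, pv, "-"))

  # group-mean-centered residual vectors, permuted among groups
  fitted <- rowsum(Y, g)[g, , drop = FALSE] / as.vector(table(g)[g])
  resid <- Y - fitted
  n <- nrow(Y)
  perms <- permutation_indices(n, n_perm, seed)
  pm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  counts <- matrix(0, length(lv), length(lv))
  for (p in seq_len(n_perm)) {
    Rp <- resid[perms[, p], , drop = FALSE]
    pv_null <- group_variances(Rp, g)
    counts <- counts + (abs(outer(pv_null, pv_null, "-")) >= obs)
  }
  pm <- (1 + counts) / (1 + n_perm)
  diag(pm) <- NA_real_
  dimnames(pm) <- list(lv, lv)
  structure(list(variances = pv, difference = obs, p = pm,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("Procrustes variance per group (", x$n_perm, " permutations)\n",
      sep = "")
  print(signif(x$variances, 5))
  cat("pairwise p-values:\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Stage-wise disparity profiles
#'
#' Per ontogenetic stage, the intra-group Procrustes variance for every
#' group and two flavours of inter-group disparity: `total` (Procrustes
#' variance of all specimens of the stage pooled) and `among_means`
#' (Procrustes variance of the group mean shapes of the stage, divisor =
#' number of groups).
#'
#' @param aligned An `aligned_dataset` with metadata.
#' @param group,stage Metadata column names.
#' @return Data frame with one row per stage: per-group variances,
#'   `total`, `among_means`.
#' @export
stage_disparity <- function(aligned, group = "species",
                            stage = "ontogenetic_stage") {
  Y <- arr_to_matrix(aligned$shapes)
  md <- aligned$metadata
  g <- factor(md[[group]])
  s <- factor(md[[stage]], levels = sort(unique(md[[stage]])))
  out <- data.frame(stage = levels(s), stringsAsFactors = FALSE)
  for (gl in levels(g))
    out[[gl]] <- vapply(levels(s), function(sl)
      procrustes_variance(Y[g == gl & s == sl, , drop = FALSE]), numeric(1))
  out$total <- vapply(levels(s), function(sl)
    procrustes_variance(Y[s == sl, , drop = FALSE]), numeric(1))
  out$among_means <- vapply(levels(s), function(sl) {
    M <- do.call(rbind, lapply(levels(g), function(gl)
      colMeans(Y[g == gl & s == sl, , drop = FALSE])))
    procrustes_variance(M)
  }, numeric(1))
  out
}
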