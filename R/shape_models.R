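# Shape PCA, Procrustes ANOVA with residual randomization permutation
# (RRPP) tests, and pairwise allometric-slope comparison.

#' Principal component analysis of shape
#'
#' Singular value decomposition of the centered `n x 2k` shape matrix.
#' Components beyond `min(n - 1, 2k - 4)` (the dimensions consumed by
#' superimposition) or with numerically zero variance are dropped; percent
#' variance is reported over the retained nonzero components and sums
#' to 100.
#'
#' @param aligned An `aligned_dataset` or an `n x 2k` shape matrix.
#' @return Object of class `shape_pca` with `scores`, `eigenvalues`,
#'   `percent`, `loadings` and `center`.
#' @export
shape_pca <- function(aligned) {
  Y <- if (inherits(aligned, "aligned_dataset")) arr_to_matrix(aligned$shapes) else as.matrix(aligned)
  n <- nrow(Y)
  if (n < 2L) stop("PCA needs at least 2 specimens")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, ctr, "-")
  sv <- svd(Yc)
  eig <- sv$d^2 / (n - 1)
  r_max <- min(n - 1L, ncol(Y) - 4L)
  # absolute floor relative to the coordinate scale guards the
  # zero-variance (identical shapes) case
  floor_abs <- 1e-14 * max(1, sum(Y^2) / n)
  keep <- which(eig > max(eig[1] * 1e-12, floor_abs))
  keep <- keep[keep <= r_max]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  if (length(keep)) colnames(scores) <- paste0("PC", seq_along(keep))
  rownames(scores) <- rownames(Y)
  structure(list(scores = scores,
                 eigenvalues = eig[keep],
                 percent = if (length(keep)) 100 * eig[keep] / sum(eig[keep]) else numeric(0),
                 loadings = sv$v[, keep, drop = FALSE],
                 center = ctr),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA: ", length(x$eigenvalues), " components\n", sep = "")
  if (length(x$percent))
    cat("  PC1-PC", min(3L, length(x$percent)), ": ",
        paste(sprintf("%.2f%%", utils::head(x$percent, 3L)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# Build the model frame for ANOVA-type fits from an aligned dataset.
# Adds `csize` (centroid size) and `log_csize` to the metadata columns.
model_frame <- function(aligned) {
  md <- aligned$metadata
  if (is.null(md)) md <- data.frame(row.names = seq_along(aligned$centroid_sizes))
  md$csize <- as.numeric(aligned$centroid_sizes)
  md$log_csize <- log(md$csize)
  md
}

# Sequential (type I) decomposition of a multivariate linear model via one
# QR of the full design; returns per-term orthonormal bases Q_j such that
# SS_j(Y) = ||Q_j' Y||_F^2, plus residual basis info.
sequential_decomposition <- function(formula, data) {
  tf <- stats::terms(formula)
  labels <- attr(tf, "term.labels")
  if (length(labels) == 0L) stop("model has no terms")
  X_parts <- list(matrix(1, nrow(data), 1L))
  for (j in seq_along(labels)) {
    f <- stats::reformulate(labels[seq_len(j)])
    X_parts[[j + 1L]] <- stats::model.matrix(f, data)
  }
  X_full <- X_parts[[length(X_parts)]]
  qrf <- qr(X_full)
  if (qrf$rank < ncol(X_full)) {
    est <- qrf$pivot[seq_len(qrf$rank)]
    aliased <- colnames(X_full)[setdiff(seq_len(ncol(X_full)), est)]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  Q <- qr.Q(qrf)
  dfs <- vapply(X_parts, ncol, 1L)
  term_cols <- lapply(seq_along(labels), function(j)
    seq.int(dfs[j] + 1L, dfs[j + 1L]))
  list(labels = labels, Q = Q, term_cols = term_cols,
       df = diff(dfs), rank = qrf$rank, X_parts = X_parts)
}

#' Procrustes ANOVA with residual randomization
#'
#' Fits a sequential (type I) multivariate linear model to the `n x 2k`
#' shape matrix and evaluates each term with a residual randomization
#' permutation procedure (RRPP): for every term, the residuals of the
#' reduced model containing all prior terms are permuted across specimens,
#' the term's Procrustes sum of squares is recomputed, and the p-value is
#' `(1 + #permuted SS >= observed) / (1 + n_perm)`. Effect sizes `Z` are
#' standard deviates of the observed statistic against its permutation
#' null, computed on the log-SS scale by default (permutation SS
#' distributions are right-skewed). Centroid size is available in formulas
#' as `csize` and `log_csize`.
#'
#' @param aligned An `aligned_dataset` with metadata.
#' @param model One-sided formula over metadata columns, e.g.
#'   `~ log_csize + species * life_stage`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @param log_z Compute `Z` on log-transformed SS (default `TRUE`).
#' @return Object of class `procrustes_anova`: data frame `table` with
#'   columns term, df, SS, MS, F, Z, p (plus residual and total rows),
#'   `n_perm`, `seed` and the per-term permutation null `null_ss`.
#' @export
procrustes_anova <- function(aligned, model, n_perm = 10000L, seed = 1L,
                             log_z = TRUE) {
  stopifnot(n_perm >= 1L)
  Y <- arr_to_matrix(aligned$shapes)
  data <- model_frame(aligned)
  dec <- sequential_decomposition(model, data)
  n <- nrow(Y)
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  ss_total <- sum(Yc^2)
  QtY <- crossprod(dec$Q, Y)
  ss_terms <- vapply(dec$term_cols, function(cols)
    sum(QtY[cols, , drop = FALSE]^2), numeric(1))
  ss_resid <- sum(Y^2) - sum(QtY^2)
  df_res <- n - dec$rank
  ms_res <- ss_resid / df_res
  ms <- ss_terms / dec$df
  Fs <- ms / ms_res

  perms <- permutation_indices(n, n_perm, seed)
  null_ss <- matrix(NA_real_, n_perm, length(dec$labels),
                    dimnames = list(NULL, dec$labels))
  for (j in seq_along(dec$labels)) {
    # reduced-model residuals: Y minus projection on columns before term j
    prior <- seq_len(min(dec$term_cols[[j]]) - 1L)
    Qp <- dec$Q[, prior, drop = FALSE]
    R <- Y - Qp %*% crossprod(Qp, Y)
    Qj <- dec$Q[, dec$term_cols[[j]], drop = FALSE]
    for (p in seq_len(n_perm)) {
      Rp <- R[perms[, p], , drop = FALSE]
      null_ss[p, j] <- sum(crossprod(Qj, Rp)^2)
    }
  }
  pvals <- vapply(seq_along(dec$labels), function(j)
    perm_pvalue(null_ss[, j], ss_terms[j], "upper"), numeric(1))
  zs <- vapply(seq_along(dec$labels), function(j)
    perm_zscore(null_ss[, j], ss_terms[j], log = log_z), numeric(1))

  tab <- data.frame(term = c(dec$labels, "Residuals", "Total"),
                    df = c(dec$df, df_res, n - 1L),
                    SS = c(ss_terms, ss_resid, ss_total),
                    MS = c(ms, ms_res, NA),
                    F = c(Fs, NA, NA),
                    Z = c(zs, NA, NA),
                    p = c(pvals, NA, NA),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), log_z = log_z,
                 null_ss = null_ss),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, digits = 4, ...) {
  cat("Procrustes ANOVA (RRPP, ", x$n_perm, " permutations, seed ",
      x$seed, ")\n", sep = "")
  tab <- x$table
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

# Per-group multivariate regression vectors of shape on (log) size.
group_slopes <- function(Y, group, size_val) {
  lv <- levels(group)
  out <- matrix(NA_real_, length(lv), ncol(Y), dimnames = list(lv, NULL))
  for (g in lv) {
    idx <- group == g
    x <- size_val[idx]
    if (length(unique(x)) < 2L)
      stop("size is constant within group '", g, "'")
    xc <- x - mean(x)
    Yg <- Y[idx, , drop = FALSE]
    out[g, ] <- crossprod(xc, sweep(Yg, 2L, colMeans(Yg), "-")) / sum(xc^2)
  }
  out
}

pairwise_angles <- function(slopes, absolute = FALSE) {
  lv <- rownames(slopes)
  ang <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in seq_along(lv)) for (b in seq_along(lv)) if (a < b) {
    th <- vector_angle(slopes[a, ], slopes[b, ], absolute = absolute)
    ang[a, b] <- ang[b, a] <- th
  }
  ang
}

#' Pairwise comparison of allometric slopes
#'
#' Estimates each group's multivariate allometric vector (the regression of
#' shape on log centroid size, or raw size with `log_size = FALSE`) and the
#' pairwise angles between those vectors in degrees. Significance is
#' assessed by RRPP under the common-slope (no size-by-group interaction)
#' null model: residuals of `shape ~ group + size` are permuted, group
#' slopes refit, and angles recomputed; `p = (1 + #null angle >= observed)
#' / (1 + n_perm)` with `Z` on the angle scale.
#'
#' @param aligned An `aligned_dataset` with metadata.
#' @param group Name of the metadata column defining groups (default
#'   `"species"`).
#' @param n_perm,seed Permutation count and seed.
#' @param log_size Regress on `log(centroid size)` (default) or raw size.
#' @return Object of class `slope_comparison` with matrices `angle`, `Z`,
#'   `p`, the per-group `slopes`, and the settings used.
#' @export
compare_allometric_slopes <- function(aligned, group = "species",
                                      n_perm = 10000L, seed = 1L,
                                      log_size = TRUE) {
  Y <- arr_to_matrix(aligned$shapes)
  data <- model_frame(aligned)
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 3L))
    stop("each group needs at least 3 specimens")
  size_val <- if (log_size) data$log_csize else data$csize
  slopes <- group_slopes(Y, g, size_val)
  obs <- pairwise_angles(slopes)

  # common-slope null model: shape ~ group + size
  X0 <- stats::model.matrix(~ g + size_val)
  q0 <- qr(X0)
  fitted0 <- qr.fitted(q0, Y)
  resid0 <- Y - fitted0
  n <- nrow(Y)
  perms <- permutation_indices(n, n_perm, seed)
  lv <- levels(g)
  null_ang <- array(NA_real_, c(n_perm, length(lv), length(lv)))
  for (p in seq_len(n_perm)) {
    Yp <- fitted0 + resid0[perms[, p], , drop = FALSE]
    null_ang[p, , ] <- pairwise_angles(group_slopes(Yp, g, size_val))
  }
  Zm <- pm <- matrix(NA_real_, length(lv), length(lv), dimnames = dimnames(obs))
  for (a in seq_along(lv)) for (b in seq_along(lv)) if (a < b) {
    nll <- null_ang[, a, b]
    pm[a, b] <- pm[b, a] <- perm_pvalue(nll, obs[a, b], "upper")
    Zm[a, b] <- Zm[b, a] <- perm_zscore(nll, obs[a, b])
  }
  structure(list(angle = obs, Z = Zm, p = pm, slopes = slopes,
                 group = group, log_size = log_size,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, digits = 3, ...) {
  cat("Pairwise allometric slope comparison (", x$n_perm,
      " permutations)\nAngles (degrees):\n", sep = "")
  print(round(x$angle, digits))
  cat("p-values:\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Export an ANOVA table to CSV
#'
#' Fixed column order: term, df, SS, MS, F, Z, p.
#' @param x A `procrustes_anova` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_anova_csv <- function(x, path) {
  stopifnot(inherits(x, "procrustes_anova"))
  utils::write.csv(x$table[, c("term", "df", "SS", "MS", "F", "Z", "p")],
                   path, row.names = FALSE)
  invisible(path)
}
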