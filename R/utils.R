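# Internal helpers shared across modules.

#' Convert a landmark array to a two-dimensional data matrix
#'
#' Flattens a `k x 2 x n` array of landmark configurations into an
#' `n x 2k` matrix in landmark-major order (`x1, y1, x2, y2, ...`), the
#' layout used by all linear-model machinery in the package.
#'
#' @param shapes Numeric array, `k x 2 x n`.
#' @return Numeric matrix, `n x 2k`, with specimen names as rownames when
#'   the array carries them.
#' @seealso [matrix_to_arr()] for the inverse.
#' @export
arr_to_matrix <- function(shapes) {
  stopifnot(is.array(shapes), length(dim(shapes)) == 3L, dim(shapes)[2] == 2L)
  k <- dim(shapes)[1]
  n <- dim(shapes)[3]
  out <- t(apply(shapes, 3, function(m) as.vector(t(m))))
  dim(out) <- c(n, 2L * k)
  rownames(out) <- dimnames(shapes)[[3]]
  out
}

#' Convert a flat data matrix back to a landmark array
#'
#' @param Y Numeric matrix, `n x 2k`, landmark-major order.
#' @return Numeric array, `k x 2 x n`.
#' @export
matrix_to_arr <- function(Y) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) %% 2L == 0L)
  k <- ncol(Y) %/% 2L
  n <- nrow(Y)
  out <- array(NA_real_, dim = c(k, 2L, n),
               dimnames = list(NULL, c("x", "y"), rownames(Y)))
  for (i in seq_len(n)) out[, , i] <- matrix(Y[i, ], ncol = 2L, byrow = TRUE)
  out
}

# Center a k x 2 configuration at the origin.
center_config <- function(coords) {
  sweep(coords, 2L, colMeans(coords), "-")
}

# Stable deterministic seed stream: derive a child seed from a parent seed
# and a character tag, staying inside 32-bit signed range.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Draw a matrix of permutation indices (n x n_perm) under a fixed seed.
permutation_indices <- function(n, n_perm, seed) {
  set.seed(seed)
  matrix(replicate(n_perm, sample.int(n)), nrow = n)
}

# Permutation p-value with the (1 + count) / (1 + n_perm) convention.
perm_pvalue <- function(null, observed, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  hits <- if (tail == "upper") sum(null >= observed) else sum(null <= observed)
  (1 + hits) / (1 + length(null))
}

# Effect size of an observed statistic against its permutation null.
# log = TRUE computes Z on the log scale (guards against right skew of SS).
perm_zscore <- function(null, observed, log = FALSE) {
  if (log) {
    keep <- null > 0
    if (observed <= 0 || sum(keep) < 2) return(NA_real_)
    null <- base::log(null[keep])
    observed <- base::log(observed)
  }
  s <- stats::sd(null)
  if (!is.finite(s) || s == 0) return(NA_real_)
  (observed - mean(null)) / s
}

# Angle in degrees between two vectors; absolute = TRUE folds to [0, 90]
# (sign-invariant convention for principal-axis directions).
vector_angle <- function(a, b, absolute = FALSE) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  cc <- sum(a * b) / (na * nb)
  if (absolute) cc <- abs(cc)
  cc <- min(1, max(-1, cc))
  acos(cc) * 180 / pi
}
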