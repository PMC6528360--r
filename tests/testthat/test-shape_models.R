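test_that("shape PCA handles degenerate input and normalizes variance", {
  Y <- matrix(rep(c(0, 0, 1, 0, 0.5, 1), 4), nrow = 4, byrow = TRUE)
  p0 <- shape_pca(Y)
  expect_length(p0$eigenvalues, 0L)
  expect_error(shape_pca(Y[1, , drop = FALSE]), "at least 2")

  sim <- generate_dataset(ontogeny_sim_config(n_per_cell = 3, seed = 31))
  al <- gpa_align(sim$configs, metadata = sim$metadata)
  p <- shape_pca(al)
  expect_equal(sum(p$percent), 100, tolerance = 1e-6)
  expect_lte(length(p$eigenvalues),
             min(dim(al$shapes)[3] - 1L, 2L * dim(al$shapes)[1] - 4L))
})

test_that("PCA scores match an SVD oracle up to sign", {
  set.seed(32)
  Y <- matrix(rnorm(5 * 8), 5, 8)
  p <- shape_pca(Y)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(Yc)
  for (j in seq_along(p$eigenvalues)) {
    oracle <- sv$u[, j] * sv$d[j]
    expect_lt(min(max(abs(p$scores[, j] - oracle)),
                  max(abs(p$scores[, j] + oracle))), 1e-10)
  }
})

test_that("Procrustes ANOVA SS and F match a projection-matrix oracle", {
  set.seed(33)
  Y <- matrix(rnorm(6 * 6), 6, 6)
  md <- data.frame(specimen_id = paste0("s", 1:6),
                   species = rep(c("A", "B"), each = 3),
                   life_stage = "juvenile")
  al <- make_aligned(Y, md)
  fit <- procrustes_anova(al, ~ species, n_perm = 99, seed = 1)
  or <- anova_oracle_one_term(Y, factor(md$species))
  expect_equal(fit$table$SS[1], or$SS, tolerance = 1e-10)
  expect_equal(fit$table$SS[2], or$RSS, tolerance = 1e-10)
  expect_equal(fit$table$F[1], or$F, tolerance = 1e-10)
  # SS decomposition adds up
  expect_equal(sum(fit$table$SS[1:2]), fit$table$SS[3], tolerance = 1e-8)
  expect_true(all(fit$table$p[1] >= 1 / 100 & fit$table$p[1] <= 1))
})

test_that("huge separation saturates the permutation p-value", {
  set.seed(34)
  Y <- matrix(rnorm(20 * 10), 20, 10)
  Y[11:20, 1] <- Y[11:20, 1] + 50
  md <- data.frame(specimen_id = paste0("s", 1:20),
                   species = rep(c("A", "B"), each = 10),
                   life_stage = "juvenile")
  fit <- procrustes_anova(make_aligned(Y, md), ~ species,
                          n_perm = 199, seed = 3)
  expect_equal(fit$table$p[1], 1 / 200)
})

test_that("ANOVA is reproducible under a fixed seed and invariant to
          specimen order", {
  set.seed(35)
  Y <- matrix(rnorm(24 * 10), 24, 10)
  md <- data.frame(specimen_id = paste0("s", 1:24),
                   species = rep(c("A", "B", "C"), each = 8),
                   life_stage = rep(c("juvenile", "adult"), 12))
  al <- make_aligned(Y, md)
  f1 <- procrustes_anova(al, ~ species + life_stage, n_perm = 199, seed = 7)
  f2 <- procrustes_anova(al, ~ species + life_stage, n_perm = 199, seed = 7)
  expect_identical(f1$table, f2$table)
  expect_identical(f1$null_ss, f2$null_ss)

  ord <- sample(24)
  al_perm <- make_aligned(Y[ord, ], md[ord, ])
  f3 <- procrustes_anova(al_perm, ~ species + life_stage, n_perm = 9, seed = 7)
  expect_equal(f3$table$SS, f1$table$SS, tolerance = 1e-10)

  expect_error(procrustes_anova(al, ~ species + I(as.numeric(species == "A")),
                                n_perm = 9, seed = 1), "rank-deficient")
})

test_that("the size F statistic is F-distributed under zero allometry", {
  set.seed(36)
  n <- 15; p <- 6
  fs <- vapply(1:500, function(i) {
    Y <- matrix(rnorm(n * p), n, p)
    md <- data.frame(specimen_id = paste0("s", 1:n), species = "A",
                     life_stage = "juvenile")
    al <- make_aligned(Y, md, csize = exp(rnorm(n)))
    procrustes_anova(al, ~ log_csize, n_perm = 1, seed = i)$table$F[1]
  }, numeric(1))
  ks <- stats::ks.test(fs, stats::pf, df1 = p, df2 = p * (n - 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("allometric slope comparison recovers constructed geometry", {
  set.seed(37)
  n <- 25; p <- 12
  x <- runif(2 * n, -1, 1)
  b1 <- c(1, rep(0, p - 1)); b2 <- c(0, 1, rep(0, p - 2))
  Y <- outer(x, c(rep(0, p))) + 0.01 * matrix(rnorm(2 * n * p), 2 * n, p)
  Y[1:n, ] <- Y[1:n, ] + outer(x[1:n], b1)
  Y[(n + 1):(2 * n), ] <- Y[(n + 1):(2 * n), ] + outer(x[(n + 1):(2 * n)], b2)
  md <- data.frame(specimen_id = paste0("s", 1:(2 * n)),
                   species = rep(c("A", "B"), each = n),
                   life_stage = "juvenile")
  al <- make_aligned(Y, md, csize = exp(x))
  cmp <- compare_allometric_slopes(al, n_perm = 199, seed = 5)
  expect_equal(cmp$angle["A", "B"], 90, tolerance = 2)
  expect_equal(cmp$angle, t(cmp$angle))
  expect_equal(diag(cmp$angle), c(A = 0, B = 0))
  expect_lte(cmp$p["A", "B"], 0.05)

  # identical allometric vectors: small angle, non-significant
  Y2 <- outer(x, b1) + 0.01 * matrix(rnorm(2 * n * p), 2 * n, p)
  al2 <- make_aligned(Y2, md, csize = exp(x))
  cmp2 <- compare_allometric_slopes(al2, n_perm = 199, seed = 6)
  expect_lt(cmp2$angle["A", "B"], 10)
  expect_gt(cmp2$p["A", "B"], 0.05)

  md$species <- "A"
  expect_error(compare_allometric_slopes(make_aligned(Y, md, csize = exp(x))),
               "at least 2 groups")
  mdc <- data.frame(specimen_id = paste0("s", 1:(2 * n)),
                    species = rep(c("A", "B"), each = n),
                    life_stage = "juvenile")
  expect_error(compare_allometric_slopes(make_aligned(Y, mdc,
                                                      csize = rep(2, 2 * n))),
               "constant within group")
})
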