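sim_metric_matrix <- function(n = 50, p = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- metric_names()[seq_len(p)]
  x
}

test_that("PCA extremes: rank-1 structure and isotropic noise", {
  set.seed(2)
  f <- rnorm(60)
  w <- runif(10, 0.5, 2)
  x1 <- outer(f, w)
  colnames(x1) <- metric_names()
  m1 <- fit_pca(x1)
  expect_equal(m1$pct_variance[1], 1, tolerance = 1e-10)

  x0 <- sim_metric_matrix(n = 6000, seed = 3)
  m0 <- fit_pca(x0)
  expect_true(all(abs(m0$pct_variance - 0.1) < 0.02))
})

test_that("PCA matches an independent eigen-solver up to column signs", {
  x <- sim_metric_matrix(seed = 4)
  m <- fit_pca(x)
  ref <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (k in 1:10) {
    a <- m$loadings[, k]; b <- ref$rotation[, k]
    s <- sign(sum(a * b))
    expect_equal(a, s * b, tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(m$eigenvalues, ref$sdev^2, tolerance = 1e-8)
  # sign convention: the dominant entry of every column is positive
  for (k in 1:10)
    expect_gt(m$loadings[which.max(abs(m$loadings[, k])), k], 0)
  expect_error(fit_pca(cbind(x, const = 1)), "constant column")
  expect_error(fit_pca(x[1:5, ]), "more rows")
})

test_that("PC model invariants: variance budget and reconstruction", {
  x <- sim_metric_matrix(seed = 5)
  m <- fit_pca(x)
  expect_equal(sum(m$pct_variance), 1, tolerance = 1e-10)
  expect_equal(m$scores, scale(x) %*% m$loadings, ignore_attr = TRUE,
               tolerance = 1e-10)
  cc <- stats::cor(m$scores)
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-8))
  expect_equal(unname(colSums(m$loadings^2)), rep(1, 10),
               tolerance = 1e-10)
})

test_that("permutation test flags constructed factors and is reproducible", {
  set.seed(6)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(sapply(1:2, function(i) f1 + rnorm(n, 0, 0.4)),
             sapply(1:2, function(i) f2 + rnorm(n, 0, 0.4)),
             matrix(rnorm(n * 6), n, 6))
  colnames(x) <- metric_names()
  m <- permutation_significance(x, B = 299, seed = 11)
  expect_true(all(m$significant_pcs[1:2]))
  expect_false(any(m$significant_pcs[4:10]))
  # factor members load about 1/sqrt(2) across the two leading PCs (which
  # factor lands on which PC is rotation-dependent); some member clears the
  # permuted-loading quantile, the pure-noise columns never do
  expect_true(any(m$significant_loadings[1:4, 1:2]))
  expect_false(any(m$significant_loadings[5:10, 1:2] &
                     abs(m$loadings[5:10, 1:2]) < 0.3))
  m2 <- permutation_significance(x, B = 299, seed = 11)
  expect_identical(m$significant_pcs, m2$significant_pcs)
  expect_error(permutation_significance(x, B = 50), "too small")
})

test_that("loading interpretation applies the strict |0.4| cutoff", {
  x <- sim_metric_matrix(seed = 7)
  m <- fit_pca(x)
  m$significant_pcs <- c(TRUE, rep(FALSE, 9))
  m$significant_loadings[] <- TRUE
  m$loadings[, 1] <- 0
  m$loadings[1:3, 1] <- c(0.39, 0.41, -0.515)
  out <- interpret_loadings(m, cutoff = 0.4)
  expect_named(out, "PC1")
  expect_setequal(out$PC1$variable, metric_names()[2:3])
  expect_equal(out$PC1$loading[out$PC1$variable == metric_names()[3]],
               -0.515)
  m$loadings[, 1] <- 0.1
  expect_warning(interpret_loadings(m, cutoff = 0.4), "no loading")
})

test_that("PC3 orientation anchors on the longest hallway sequence", {
  x <- sim_metric_matrix(seed = 8)
  m <- fit_pca(x)
  m$loadings["longest_hallway_sequence", 3] <- -abs(
    m$loadings["longest_hallway_sequence", 3])
  flipped <- orient_pc3(m)
  expect_gt(flipped$loadings["longest_hallway_sequence", 3], 0)
  expect_equal(flipped$orientation[3], -1)
  expect_equal(flipped$scores[, 3], -m$scores[, 3], ignore_attr = TRUE)
  # idempotent
  again <- orient_pc3(flipped)
  expect_identical(again$loadings, flipped$loadings)
  expect_identical(again$orientation, flipped$orientation)
})

test_that("success-on-PC regression recovers signal and matches the oracle", {
  x <- sim_metric_matrix(n = 60, seed = 9)
  m <- fit_pca(x)
  tab <- data.frame(group = rep(c("young", "midlife"), 30))
  tab$wayfinding_success <- 0.3 + 0.2 * m$scores[, 1]
  # a noiseless construction: lm warns that the fit is perfect, as intended
  r <- suppressWarnings(regress_success_on_pcs(tab, m, "young", pcs = 1:3))
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_equal(r$coefficients$beta[r$coefficients$term == "PC1"], 0.2,
               tolerance = 1e-10)

  set.seed(10)
  tab$wayfinding_success <- tab$wayfinding_success + rnorm(60, 0, 0.1)
  r2 <- regress_success_on_pcs(tab, m, "midlife", pcs = 1:2)
  sel <- tab$group == "midlife"
  X <- cbind(1, m$scores[sel, 1:2])
  beta <- solve(t(X) %*% X, t(X) %*% tab$wayfinding_success[sel])
  expect_equal(r2$coefficients$beta, as.vector(beta), tolerance = 1e-8)
  expect_error(regress_success_on_pcs(tab[1:10, ], m, "young"),
               "not aligned")
})

test_that("group-specific coupling shows up only in that group's model", {
  # success tracks PC1-like coverage in midlife only
  x <- sim_metric_matrix(n = 120, seed = 12)
  m <- fit_pca(x)
  grp <- rep(c("young", "midlife"), 60)
  set.seed(13)
  succ <- ifelse(grp == "midlife", 0.3 + 0.15 * m$scores[, 1],
                 0.5 + 0 * m$scores[, 1]) + rnorm(120, 0, 0.05)
  tab <- data.frame(group = grp, wayfinding_success = succ)
  r_mid <- regress_success_on_pcs(tab, m, "midlife", pcs = 1:3)
  r_yng <- regress_success_on_pcs(tab, m, "young", pcs = 1:3)
  p_mid <- r_mid$coefficients$p[r_mid$coefficients$term == "PC1"]
  p_yng <- r_yng$coefficients$p[r_yng$coefficients$term == "PC1"]
  expect_lt(p_mid, 0.001)
  expect_gt(p_yng, 0.05)
  expect_gt(r_mid$coefficients$beta[r_mid$coefficients$term == "PC1"], 0)
})
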