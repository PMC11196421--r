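test_that("skew rule picks the transform matching the moment skewness", {
  g1 <- function(x) mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  set.seed(101)
  x_sym <- rnorm(400)
  expect_lte(abs(g1(x_sym)), 0.5)
  expect_equal(skew_transform(x_sym)$transform, "none")

  x_exp <- rexp(400)  # skewness near 2
  expected <- if (abs(g1(x_exp)) <= 1) "sqrt" else
    if (abs(g1(x_exp)) <= 2) "log" else "inverse"
  expect_equal(skew_transform(x_exp)$transform, expected)

  x_heavy <- rlnorm(400, sdlog = 1.6)
  expect_gt(abs(g1(x_heavy)), 2)
  expect_equal(skew_transform(x_heavy)$transform, "inverse")

  cst <- skew_transform(rep(3, 10))
  expect_true(cst$degenerate)
  expect_equal(cst$transform, "none")
  expect_identical(cst$x, rep(3, 10))
})

test_that("negative skew is reflected and nonpositive values shifted", {
  set.seed(5)
  x_neg <- -rexp(400)
  tr <- skew_transform(x_neg)
  expect_true(tr$reflected)
  expect_true(all(is.finite(tr$x)))
  # reflection reverses order, the inverse transform reverses it again, so
  # the result is strictly monotone in the input either way
  rho <- stats::cor(tr$x, x_neg, method = "spearman")
  expect_equal(abs(rho), 1)
  expect_equal(rho, if (tr$transform == "inverse") 1 else -1)

  x_zero <- c(0, rexp(200))  # log/inverse would fail at 0 without a shift
  expect_true(all(is.finite(skew_transform(x_zero)$x)))
  expect_error(skew_transform(c(1, 2)), "at least 3")
})

test_that("ANCOVA: null case, oracle agreement, and invariances", {
  # identical value sets in both groups: the group effect is exactly zero
  d0 <- data.frame(group = rep(c("young", "midlife"), each = 6),
                   sex = rep(c("F", "M"), 6),
                   y = rep(c(1, 2, 3, 4, 5, 6), 2))
  r0 <- ancova_group(d0, "y", transform = FALSE)
  expect_equal(r0$F, 0, tolerance = 1e-12)
  expect_equal(r0$eta_p2, 0, tolerance = 1e-12)

  set.seed(7)
  n <- 40
  d <- data.frame(group = factor(rep(c("young", "midlife"), each = n / 2),
                                 levels = c("young", "midlife")),
                  sex = factor(sample(c("F", "M"), n, TRUE)))
  d$y <- rnorm(n) + 0.8 * (d$group == "midlife") + 0.3 * (d$sex == "M")
  r <- ancova_group(d, "y", transform = FALSE)
  # oracle: explicit normal-equations solve and extra-sum-of-squares F
  X_full <- cbind(1, d$group == "midlife", d$sex == "M")
  X_red <- X_full[, c(1, 3)]
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% d$y)
    sum((d$y - X %*% beta)^2)
  }
  rss_f <- rss(X_full); rss_r <- rss(X_red)
  F_oracle <- (rss_r - rss_f) / (rss_f / (n - 3))
  expect_equal(r$F, F_oracle, tolerance = 1e-8)
  expect_equal(r$df2, n - 3)
  expect_equal(r$eta_p2, (rss_r - rss_f) / rss_r, tolerance = 1e-8)
  expect_equal(r$eta_p2, r$F * r$df1 / (r$F * r$df1 + r$df2),
               tolerance = 1e-10)

  # relabeling the reference group changes nothing
  d_flip <- d
  d_flip$group <- factor(d_flip$group, levels = c("midlife", "young"))
  r_flip <- ancova_group(d_flip, "y", transform = FALSE)
  expect_equal(r_flip$F, r$F)
  expect_equal(r_flip$p, r$p)

  expect_error(ancova_group(d[d$group == "young", ], "y"), "both groups")
})

test_that("ANCOVA on the calibrated cohort finds midlife covering less", {
  tab <- generate_cohort(cohort_spec(seed = 6))
  r <- ancova_group(tab, "distance_traveled")
  expect_lt(r$p, 0.05)
  expect_equal(r$direction, -1)  # midlife lower
})

test_that("block mixed model recovers exact and noisy block effects", {
  base <- data.frame(participant_id = rep(sprintf("p%02d", 1:16), each = 2),
                     sex = rep(rep(c("F", "M"), each = 2), 8),
                     block = rep(1:2, 16))
  set.seed(13)
  subj <- rep(rnorm(16), each = 2)

  same <- base; same$y <- subj
  r_same <- suppressWarnings(suppressMessages(lmm_block(same, "y")))
  expect_equal(r_same$estimate, 0, tolerance = 1e-10)

  shifted <- base; shifted$y <- subj + 0.7 * (base$block == 2)
  r_shift <- suppressWarnings(suppressMessages(lmm_block(shifted, "y")))
  expect_equal(r_shift$estimate, 0.7, tolerance = 1e-8)

  noisy <- base; noisy$y <- subj + 0.5 * (base$block == 2) + rnorm(32, 0, 0.4)
  r_noisy <- suppressWarnings(suppressMessages(lmm_block(noisy, "y")))
  paired <- with(noisy, y[block == 2] - y[block == 1])
  expect_lt(abs(r_noisy$estimate - mean(paired)), 2 * r_noisy$se)
  expect_equal(r_noisy$eta_p2,
               r_noisy$F * r_noisy$df1 / (r_noisy$F * r_noisy$df1 +
                                            r_noisy$df2))
  incomplete <- base[-1, ]
  incomplete$y <- 1
  expect_error(lmm_block(incomplete, "y"), "exactly 2 blocks")
})

test_that("rank-sum test against chance: separation, ties, exactness", {
  strong <- wilcoxon_vs_chance(rep(0.5, 10), chance = 0.11)
  expect_equal(strong$W, 100)  # complete separation: maximal U
  expect_lt(strong$p, 0.001)

  flat <- wilcoxon_vs_chance(rep(0.11, 10))
  expect_true(flat$degenerate)
  expect_equal(flat$p, 0.5)

  # n = 8: exact enumeration oracle built from pair counting, not ranks
  x <- c(0.25, 0.05, 0.4, 0.11, 0.3, 0.0, 0.6, 0.2)
  got <- wilcoxon_vs_chance(x, chance = 0.11)
  pooled <- c(x, rep(0.11, 8))
  U_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U_obs <- U_of(1:8)
  expect_equal(got$W, U_obs)
  combos <- utils::combn(16, 8)
  U_all <- apply(combos, 2, U_of)
  expect_equal(got$p, mean(U_all >= U_obs))

  expect_error(wilcoxon_vs_chance(c(0.5, 0.5)), "at least 5")
})

test_that("large-sample rank-sum p agrees with wilcox.test", {
  set.seed(3)
  x <- round(runif(40, 0, 1), 2)
  got <- wilcoxon_vs_chance(x, chance = 0.11)
  ref <- suppressWarnings(stats::wilcox.test(
    x, rep(0.11, 40), alternative = "greater", exact = FALSE,
    correct = TRUE))
  expect_equal(got$W, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("two-factor sex ANOVA matches the balanced closed form", {
  cells <- expand.grid(sex = c("F", "M"), group = c("young", "midlife"),
                       rep = 1:8)
  set.seed(23)
  d <- data.frame(sex = cells$sex, group = cells$group)
  d$y <- 0.5 * (d$sex == "M") + 1.2 * (d$group == "midlife") + rnorm(32)
  a <- sex_anova(d, "y", transform = FALSE)
  # balanced two-way ANOVA: SS from cell and marginal means
  ybar <- mean(d$y)
  ms <- tapply(d$y, d$sex, mean); gs <- tapply(d$y, d$group, mean)
  cellm <- tapply(d$y, interaction(d$sex, d$group), mean)
  ss_sex <- 16 * sum((ms - ybar)^2)
  ss_group <- 16 * sum((gs - ybar)^2)
  cell_of <- interaction(d$sex, d$group)
  ss_res <- sum((d$y - cellm[cell_of])^2)
  ss_int <- sum((d$y - ybar)^2) - ss_sex - ss_group - ss_res
  expect_equal(a["sex", "F"], (ss_sex / 1) / (ss_res / 28),
               tolerance = 1e-8)
  expect_equal(a["group", "F"], (ss_group / 1) / (ss_res / 28),
               tolerance = 1e-8)
  expect_equal(a["sex:group", "F"], (ss_int / 1) / (ss_res / 28),
               tolerance = 1e-8)

  # near-pure interaction: main effects stay negligible, interaction huge
  d2 <- d
  set.seed(29)
  d2$y <- ifelse(xor(d2$sex == "M", d2$group == "midlife"), 1, -1) +
    rnorm(32, 0, 0.05)
  a2 <- sex_anova(d2, "y", transform = FALSE)
  expect_lt(a2["sex", "F"], 10)
  expect_lt(a2["group", "F"], 10)
  expect_gt(a2["sex:group", "F"], 1000)

  d3 <- d[d$sex == "F" | d$group == "young", ]
  d3 <- d3[!(d3$sex == "M" & d3$group == "midlife"), ]
  expect_error(sex_anova(d3, "y"), "empty")
})

test_that("sex-by-group chi-square uses the continuity correction", {
  res <- chi_square_sex(rbind(c(64, 23), c(26, 24)))
  expect_equal(res$statistic, 5.629, tolerance = 5e-4)
  expect_equal(res$df, 1)
  expect_equal(chi_square_sex(matrix(10, 2, 2))$statistic, 0)
  set.seed(17)
  for (i in 1:20) {
    tb <- matrix(sample(5:40, 4, TRUE), 2, 2)
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    oracle <- sum(pmax(abs(tb - E) - 0.5, 0)^2 / E)
    expect_equal(chi_square_sex(tb)$statistic, oracle, tolerance = 1e-10)
  }
  expect_error(chi_square_sex(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi_square_sex(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})
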