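#' Normalizing transform chosen by the magnitude of skew
#'
#' Moment skewness `g1 = m3 / m2^(3/2)` decides the transform:
#' `|g1| <= 0.5` none, `<= 1` square root, `<= 2` natural log, `> 2`
#' inverse. Negative skew is handled by reflecting the variable
#' (`max + 1 - x`) before transforming; a location shift is applied when
#' nonpositive values would break the root/log/inverse. A constant vector
#' has undefined skew and is returned untransformed with a warning flag.
#'
#' @param x numeric vector, length >= 3
#' @return list with `x` (transformed values), `transform` (one of
#'   `"none"`, `"sqrt"`, `"log"`, `"inverse"`), `skew` (of the input),
#'   `reflected`, `shift` and `degenerate`
#' @export
skew_transform <- function(x) {
  if (length(x) < 3) stop("need at least 3 observations")
  m2 <- mean((x - mean(x))^2)
  if (m2 < .Machine$double.eps) {
    return(list(x = x, transform = "none", skew = NA_real_,
                reflected = FALSE, shift = 0, degenerate = TRUE))
  }
  g1 <- mean((x - mean(x))^3) / m2^1.5
  a <- abs(g1)
  trans <- if (a <= 0.5) "none" else if (a <= 1) "sqrt" else
    if (a <= 2) "log" else "inverse"
  reflected <- FALSE
  y <- x
  if (trans != "none" && g1 < 0) {
    y <- max(x) + 1 - x
    reflected <- TRUE
  }
  shift <- 0
  if (trans %in% c("log", "inverse") && min(y) <= 0)
    shift <- 1 - min(y)
  if (trans == "sqrt" && min(y) < 0)
    shift <- -min(y)
  y <- y + shift
  y <- switch(trans, none = y, sqrt = sqrt(y), log = log(y),
              inverse = 1 / y)
  list(x = y, transform = trans, skew = g1, reflected = reflected,
       shift = shift, degenerate = FALSE)
}

#' Sex-adjusted group ANCOVA for one variable
#'
#' Linear model `variable ~ group + sex` after the skew-based normalizing
#' transform; reports the type-III F test for the group term and its
#' partial eta-squared `SS_group / (SS_group + SS_residual)`.
#'
#' @param tab cohort data.frame with `group`, `sex` and the variable
#' @param variable column name
#' @param transform apply [skew_transform()] first (default TRUE)
#' @return list of class `ancova_result`: `variable`, `F`, `df1`, `df2`,
#'   `p`, `eta_p2`, `transform_used`, `direction` (sign of the
#'   midlife-minus-young difference in adjusted means)
#' @export
ancova_group <- function(tab, variable, transform = TRUE) {
  stopifnot(variable %in% names(tab))
  if (nlevels(droplevels(factor(tab$group))) != 2)
    stop("both groups must be present")
  if (min(table(tab$group)) < 2)
    stop("each group needs at least 2 observations")
  tr <- if (transform) skew_transform(tab[[variable]]) else
    list(x = tab[[variable]], transform = "none", reflected = FALSE)
  g <- factor(tab$group)
  if (setequal(levels(g), c("young", "midlife")))
    g <- factor(g, levels = c("young", "midlife"))
  d <- data.frame(y = tr$x, group = g, sex = factor(tab$sex))
  fit <- stats::lm(y ~ group + sex, data = d)
  a <- stats::anova(stats::lm(y ~ sex + group, data = d))  # group last
  ss_group <- a["group", "Sum Sq"]
  ss_res <- a["Residuals", "Sum Sq"]
  Fv <- a["group", "F value"]
  # direction of the second group level on the raw scale: reflection and the
  # inverse transform each reverse order
  dir_trans <- sign(stats::coef(fit)[[paste0("group", levels(g)[2])]]) *
    (if (isTRUE(tr$reflected)) -1 else 1) *
    (if (tr$transform == "inverse") -1 else 1)
  structure(list(variable = variable, F = Fv,
                 df1 = a["group", "Df"], df2 = a["Residuals", "Df"],
                 p = a["group", "Pr(>F)"],
                 eta_p2 = ss_group / (ss_group + ss_res),
                 transform_used = tr$transform,
                 direction = dir_trans),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA (group | sex) for %s: F(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.3f [transform: %s]\n",
              x$variable, x$df1, x$df2, x$F, x$p, x$eta_p2,
              x$transform_used))
  invisible(x)
}

#' Block-effect linear mixed model within one group
#'
#' Random-intercept model `variable ~ block + sex + (1 | participant)` on
#' the two-block long table of a single group; reports the block
#' fixed-effect estimate, its Satterthwaite F test and partial eta-squared
#' `F df1 / (F df1 + df2)`.
#'
#' @param per_block long-format data.frame with columns `participant_id`,
#'   `sex`, `block` (1/2) and the variable (one group only)
#' @param variable column name
#' @return list with `estimate`, `se`, `F`, `df1`, `df2`, `p`, `eta_p2`
#' @export
lmm_block <- function(per_block, variable) {
  stopifnot(variable %in% names(per_block))
  nb <- table(per_block$participant_id)
  if (any(nb != 2))
    stop("every participant needs exactly 2 blocks; offending: ",
         paste(names(nb)[nb != 2], collapse = ", "))
  d <- data.frame(y = per_block[[variable]],
                  block = as.numeric(per_block$block),
                  sex = factor(per_block$sex),
                  id = factor(per_block$participant_id))
  form <- if (nlevels(d$sex) > 1) y ~ block + sex + (1 | id) else
    y ~ block + (1 | id)
  fit <- suppressMessages(lmerTest::lmer(form, data = d))
  a <- stats::anova(fit)  # Satterthwaite
  co <- summary(fit)$coefficients
  Fv <- a["block", "F value"]
  df1 <- a["block", "NumDF"]; df2 <- a["block", "DenDF"]
  list(estimate = co["block", "Estimate"],
       se = co["block", "Std. Error"],
       F = Fv, df1 = df1, df2 = df2, p = a["block", "Pr(>F)"],
       eta_p2 = Fv * df1 / (Fv * df1 + df2))
}

#' One-tailed rank-sum test of wayfinding success against chance
#'
#' Mann-Whitney rank-sum comparison of the observed success proportions
#' with an equal-length constant vector at chance level (ties mid-ranked).
#' With 20 or fewer pooled values the p-value is computed by exact
#' enumeration of all group labelings; otherwise by normal approximation
#' with tie correction and continuity correction.
#'
#' @param success numeric vector of success proportions (n >= 5)
#' @param chance chance level (default [chance_level()], 0.11)
#' @param side `"greater"` (above chance, default), `"less"` or
#'   `"two.sided"`
#' @return list with `W` (Mann-Whitney U of the observed sample), `p`, and
#'   `degenerate` (TRUE when every value ties with chance; `p` is then the
#'   0.5 boundary)
#' @export
wilcoxon_vs_chance <- function(success, chance = chance_level(),
                               side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  n <- length(success)
  if (n < 5) stop("need at least 5 observations")
  y <- rep(chance, n)
  pooled <- c(success, y)
  W <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  if (all(success == chance))
    return(list(W = W, p = 0.5, degenerate = TRUE))
  N <- 2 * n
  if (N <= 20) {
    combos <- utils::combn(N, n)
    r <- rank(pooled)
    Ws <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    p <- switch(side,
                greater = mean(Ws >= W),
                less = mean(Ws <= W),
                two.sided = min(1, 2 * min(mean(Ws >= W), mean(Ws <= W))))
  } else {
    ties <- table(pooled)
    mu <- n * n / 2
    sigma <- sqrt((n * n / 12) *
                    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    z_g <- (W - mu - 0.5) / sigma
    z_l <- (W - mu + 0.5) / sigma
    p <- switch(side,
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l),
                two.sided = min(1, 2 * min(
                  stats::pnorm(z_g, lower.tail = FALSE),
                  stats::pnorm(z_l))))
  }
  list(W = W, p = p, degenerate = FALSE)
}

#' Two-factor sex-by-group ANOVA for one variable
#'
#' Type-III tests (sum-to-zero contrasts) for sex, group and their
#' interaction.
#'
#' @inheritParams ancova_group
#' @return data.frame with rows `sex`, `group`, `sex:group` and columns
#'   `F`, `df1`, `df2`, `p`
#' @export
sex_anova <- function(tab, variable, transform = TRUE) {
  stopifnot(variable %in% names(tab))
  cells <- table(tab$sex, tab$group)
  if (any(cells == 0))
    stop("empty sex-by-group cell")
  tr <- if (transform) skew_transform(tab[[variable]]) else
    list(x = tab[[variable]])
  d <- data.frame(y = tr$x, group = factor(tab$group), sex = factor(tab$sex))
  fit <- stats::lm(y ~ sex * group, data = d,
                   contrasts = list(sex = "contr.sum", group = "contr.sum"))
  a <- car::Anova(fit, type = 3)
  terms <- c("sex", "group", "sex:group")
  data.frame(term = terms,
             F = a[terms, "F value"],
             df1 = a[terms, "Df"],
             df2 = a["Residuals", "Df"],
             p = a[terms, "Pr(>F)"],
             row.names = terms)
}

#' Chi-square test of sex-by-group independence
#'
#' Yates-corrected 2x2 chi-square test of independence used as the
#' demographics check on the cohort's sex counts.
#'
#' @param counts 2x2 matrix of nonnegative integer counts (rows: groups,
#'   columns: sexes)
#' @return list with `statistic`, `df`, `p`
#' @examples
#' chi_square_sex(rbind(midlife = c(64, 23), young = c(26, 24)))
#' @export
chi_square_sex <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("need a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in the 2x2 table")
  ct <- stats::chisq.test(counts, correct = TRUE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
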