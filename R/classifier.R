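#' Binary logistic classifier of age group
#'
#' Maximum-likelihood logistic regression of group membership on one or
#' more predictors, reporting odds ratios (`exp` of coefficients) and Wald
#' p-values. Perfect separation is detected per predictor and raised as an
#' error naming it.
#'
#' @param data data.frame containing the predictors and the outcome
#' @param predictors character vector of predictor column names
#' @param outcome outcome column name (default `"group"`); its second
#'   factor level is modeled as the positive class
#' @return list of class `logistic_fit`: `model` (the [stats::glm()] fit),
#'   `odds_ratio`, `p` (named, per predictor), `fitted` (probabilities of
#'   the positive class), `positive` (the positive class label)
#' @export
fit_logistic <- function(data, predictors, outcome = "group") {
  stopifnot(all(c(predictors, outcome) %in% names(data)))
  y <- factor(data[[outcome]])
  if (nlevels(droplevels(y)) != 2) stop("outcome must have two classes")
  yy <- as.integer(y == levels(y)[2])
  for (pr in predictors) {
    v <- data[[pr]]
    if (is.numeric(v) && length(unique(v)) > 1) {
      if (max(v[yy == 0]) < min(v[yy == 1]) ||
          max(v[yy == 1]) < min(v[yy == 0]))
        stop("perfect separation on predictor: ", pr)
    }
  }
  d <- data.frame(.y = yy, data[predictors])
  fit <- stats::glm(.y ~ ., family = stats::binomial(), data = d)
  if (fit$rank < length(predictors) + 1) stop("rank-deficient design")
  if (any(abs(stats::coef(fit)[-1]) > 15))
    stop("quasi-separation: diverging coefficient for ",
         paste(names(which(abs(stats::coef(fit)[-1]) > 15)),
               collapse = ", "))
  co <- summary(fit)$coefficients[-1, , drop = FALSE]
  structure(list(model = fit,
                 odds_ratio = stats::setNames(exp(co[, 1]), rownames(co)),
                 p = stats::setNames(co[, 4], rownames(co)),
                 fitted = stats::fitted(fit), positive = levels(y)[2]),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic classifier (positive class: ", x$positive, ")\n", sep = "")
  for (nm in names(x$odds_ratio))
    cat(sprintf("  %s: OR = %.3f, p = %.4g\n", nm, x$odds_ratio[nm],
                x$p[nm]))
  invisible(x)
}

#' ROC curve and AUC
#'
#' The curve enumerates all distinct score thresholds; the AUC is computed
#' through the Mann-Whitney identity with mid-rank tie handling, which
#' equals the trapezoidal integral of the curve.
#'
#' @param scores numeric classifier scores (higher = more positive)
#' @param labels binary labels (logical, 0/1 or 2-level factor; the second
#'   level / TRUE / 1 is positive)
#' @return object of class `roc_curve`: `fpr`, `tpr`, `thresholds`, `auc`,
#'   plus the `scores` and `labels` (kept for [delong_test()])
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(as.integer(labels))
  if (length(unique(labels)) < 2)
    stop("both classes must be present in labels")
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) mean(scores[labels] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(scores[!labels] >= th), numeric(1))
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc,
                 scores = scores, labels = labels),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, sum(x$labels), sum(!x$labels)))
  invisible(x)
}

# DeLong structural components: V10 over positives, V01 over negatives
delong_components <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  v10 <- vapply(sp, function(s)
    mean((s > sn) + 0.5 * (s == sn)), numeric(1))
  v01 <- vapply(sn, function(s)
    mean((sp > s) + 0.5 * (sp == s)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong's test for two paired ROC curves
#'
#' Nonparametric comparison of two correlated AUCs computed from the same
#' participants, using the structural-components covariance estimate;
#' two-sided p for the AUC difference. Comparing a model with itself gives
#' a difference of 0 and p = 1 exactly.
#'
#' @param curve_a,curve_b [roc_auc()] objects built on identical labels
#' @return list with `auc_a`, `auc_b`, `delta` (a minus b), `z`, `p`
#' @export
delong_test <- function(curve_a, curve_b) {
  if (length(curve_a$labels) != length(curve_b$labels) ||
      any(curve_a$labels != curve_b$labels))
    stop("curves are not paired: labels differ")
  la <- curve_a$labels
  n1 <- sum(la); n0 <- sum(!la)
  ca <- delong_components(curve_a$scores, la)
  cb <- delong_components(curve_b$scores, la)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- curve_a$auc - curve_b$auc
  if (v < 1e-16) {
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(v)
  }
  list(auc_a = curve_a$auc, auc_b = curve_b$auc, delta = delta, z = z,
       p = if (z == 0) 1 else 2 * stats::pnorm(-abs(z)))
}

#' Compare exploration-PC and wayfinding-success age classifiers
#'
#' Fits (i) a logistic model of group on the first three PC scores,
#' refitted on the Wald-significant PCs only (p < 0.05, the combined
#' model), and (ii) a logistic model of group on wayfinding success alone;
#' builds both ROC curves and compares them with [delong_test()].
#'
#' @param tab cohort data.frame (rows aligned with the PCA input)
#' @param m a `pc_model` fitted on this cohort
#' @return list with `fit_pcs_full`, `kept_pcs`, `fit_pcs` (refit),
#'   `fit_success`, `roc_pcs`, `roc_success`, `delong`
#' @export
classify_age <- function(tab, m) {
  if (nrow(tab) != nrow(m$scores))
    stop("cohort table and PC scores are not aligned")
  d <- data.frame(group = factor(tab$group, levels = c("young", "midlife")),
                  wayfinding_success = tab$wayfinding_success,
                  m$scores[, 1:3])
  full <- fit_logistic(d, c("PC1", "PC2", "PC3"))
  kept <- names(full$p)[full$p < 0.05]
  refit <- if (length(kept) > 0 && length(kept) < 3)
    fit_logistic(d, kept) else full
  if (length(kept) == 0) kept <- c("PC1", "PC2", "PC3")
  fs <- fit_logistic(d, "wayfinding_success")
  roc_pcs <- roc_auc(refit$fitted, d$group)
  roc_succ <- roc_auc(fs$fitted, d$group)
  list(fit_pcs_full = full, kept_pcs = kept, fit_pcs = refit,
       fit_success = fs, roc_pcs = roc_pcs, roc_success = roc_succ,
       delong = delong_test(roc_pcs, roc_succ))
}
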