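#' Linear causal mediation of the age effect on wayfinding success
#'
#' Product-of-coefficients mediation with linear, no-interaction models:
#' `M ~ X` (slope `a`) and `Y ~ X + M` (slopes `c'` and `b`). The average
#' causal mediation effect is `ACME = a b`, the average direct effect
#' `ADE = c'`, and the total effect their sum (an identity in this model
#' class). Uncertainty comes from a nonparametric bootstrap: participants
#' are resampled with replacement, the three effects recomputed, and
#' percentile 95% intervals and two-sided bootstrap p-values reported.
#'
#' @param tab cohort data.frame
#' @param mediator column name of the mediating exploration measure
#' @param exposure column name of the exposure (default `"age"`, in years)
#' @param outcome column name of the outcome (default
#'   `"wayfinding_success"`)
#' @param B bootstrap resamples (>= 500; default 999)
#' @param seed integer seed
#' @param adjust_sex also adjust both models for sex (default FALSE)
#' @return list of class `mediation_result`: `mediator`, `acme`, `ade`,
#'   `total`, each `_ci` (length-2), each `_p`, `B`, and
#'   `inconsistent` (TRUE when ACME and ADE have opposite signs)
#' @export
mediate_linear <- function(tab, mediator, exposure = "age",
                           outcome = "wayfinding_success", B = 999,
                           seed = 1, adjust_sex = FALSE) {
  stopifnot(all(c(mediator, exposure, outcome) %in% names(tab)))
  if (B < 500) stop("B must be at least 500")
  x <- tab[[exposure]]; m <- tab[[mediator]]; y <- tab[[outcome]]
  if (stats::sd(m) < .Machine$double.eps)
    stop("degenerate mediator (zero variance): ", mediator)
  n <- length(x)
  covar <- if (adjust_sex) stats::model.matrix(~sex, tab)[, -1, drop = FALSE]
  else NULL
  eff <- function(idx) {
    xx <- x[idx]; mm <- m[idx]; yy <- y[idx]
    cv <- if (is.null(covar)) NULL else covar[idx, , drop = FALSE]
    Xm <- cbind(1, xx, cv)
    a <- stats::.lm.fit(Xm, mm)$coefficients[2]
    Xy <- cbind(1, xx, mm, cv)
    cb <- stats::.lm.fit(Xy, yy)$coefficients
    c(acme = a * cb[3], ade = cb[2])
  }
  obs <- eff(seq_len(n))
  set.seed(seed)
  boot <- matrix(NA_real_, B, 2)
  for (b in seq_len(B))
    boot[b, ] <- eff(sample.int(n, n, replace = TRUE))
  boot_total <- rowSums(boot)
  ci <- function(v) unname(stats::quantile(v, c(0.025, 0.975)))
  pv <- function(v) min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  structure(list(mediator = mediator,
                 acme = unname(obs["acme"]), ade = unname(obs["ade"]),
                 total = unname(obs["acme"] + obs["ade"]),
                 acme_ci = ci(boot[, 1]), ade_ci = ci(boot[, 2]),
                 total_ci = ci(boot_total),
                 acme_p = pv(boot[, 1]), ade_p = pv(boot[, 2]),
                 total_p = pv(boot_total), B = B,
                 inconsistent = sign(obs["acme"]) != sign(obs["ade"]) &&
                   obs["acme"] != 0),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation through %s (B = %d):\n", x$mediator, x$B))
  cat(sprintf("  ACME  %+.4g [%.4g, %.4g], p = %.3g\n",
              x$acme, x$acme_ci[1], x$acme_ci[2], x$acme_p))
  cat(sprintf("  ADE   %+.4g [%.4g, %.4g], p = %.3g\n",
              x$ade, x$ade_ci[1], x$ade_ci[2], x$ade_p))
  cat(sprintf("  Total %+.4g [%.4g, %.4g], p = %.3g%s\n",
              x$total, x$total_ci[1], x$total_ci[2], x$total_p,
              if (isTRUE(x$inconsistent)) "  (inconsistent mediation)" else ""))
  invisible(x)
}

#' Run one mediation model per candidate mediator
#'
#' One [mediate_linear()] fit for each exploration measure (typically those
#' with a significant group difference from the ANCOVA step).
#'
#' @inheritParams mediate_linear
#' @param mediators nonempty character vector of measure names
#' @return data.frame with one row per mediator (effects, CI bounds,
#'   p-values, inconsistency flag); the full `mediation_result` objects are
#'   attached as attribute `"results"`
#' @export
run_mediation_battery <- function(tab, mediators, exposure = "age",
                                  outcome = "wayfinding_success", B = 999,
                                  seed = 1, adjust_sex = FALSE) {
  if (length(mediators) == 0) stop("empty mediator list")
  res <- lapply(seq_along(mediators), function(i)
    mediate_linear(tab, mediators[i], exposure, outcome, B,
                   seed = seed + i - 1, adjust_sex = adjust_sex))
  out <- do.call(rbind, lapply(res, function(r)
    data.frame(mediator = r$mediator, acme = r$acme,
               acme_lo = r$acme_ci[1], acme_hi = r$acme_ci[2],
               acme_p = r$acme_p, ade = r$ade, ade_lo = r$ade_ci[1],
               ade_hi = r$ade_ci[2], ade_p = r$ade_p, total = r$total,
               total_p = r$total_p, inconsistent = r$inconsistent)))
  attr(out, "results") <- res
  out
}
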