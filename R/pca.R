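#' Correlation-matrix PCA of the exploration measures
#'
#' Principal components of the pooled (both groups) participant-by-measure
#' matrix. Because the ten measures have incommensurate units, columns are
#' z-scored and the eigendecomposition is of the correlation matrix.
#' Deterministic sign convention: each loading column is flipped so that
#' its largest-magnitude entry is positive (any later domain-specific
#' orientation, see [orient_pc3()], is applied on top and recorded).
#'
#' @param x numeric matrix or data.frame, participants by measures
#'   (`n > ncol`)
#' @return object of class `pc_model`: `loadings` (p x p, unit-norm
#'   columns), `scores` (n x p, z-scored data times loadings),
#'   `eigenvalues`, `pct_variance` (proportions, summing to 1),
#'   `orientation` (per-PC sign applied by [orient_pc3()]),
#'   `significant_pcs` / `significant_loadings` (filled by
#'   [permutation_significance()])
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x))
    stop("need more rows than columns for a stable PCA")
  sds <- apply(x, 2, stats::sd)
  if (any(sds < .Machine$double.eps))
    stop("constant column: ",
         paste(colnames(x)[sds < .Machine$double.eps], collapse = ", "))
  z <- scale(x)
  ei <- eigen(stats::cor(x), symmetric = TRUE)
  load <- ei$vectors
  for (k in seq_len(ncol(load))) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) load[, k] <- -load[, k]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  scores <- z %*% load
  structure(list(loadings = load, scores = scores,
                 eigenvalues = ei$values,
                 pct_variance = ei$values / sum(ei$values),
                 orientation = rep(1, ncol(load)),
                 significant_pcs = rep(NA, ncol(load)),
                 significant_loadings = matrix(NA, nrow(load), ncol(load),
                                               dimnames = dimnames(load))),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  k <- min(4, length(x$pct_variance))
  cat("PCA (correlation matrix), ", nrow(x$loadings), " measures, ",
      nrow(x$scores), " participants\n", sep = "")
  cat("  variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k),
                     100 * x$pct_variance[seq_len(k)]), collapse = ", "),
      "...\n")
  if (!anyNA(x$significant_pcs))
    cat("  significant PCs:",
        paste(which(x$significant_pcs), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation significance of PCs and loadings
#'
#' Each of `B` permutations shuffles every column of the data
#' independently, destroying between-measure correlation while keeping the
#' marginals. PC `k` exceeds its null when its observed variance proportion
#' is above the `1 - alpha` quantile of the permuted proportions of the
#' same rank; following the usual sequential convention for component
#' retention, a PC is reported significant only when it and every earlier
#' PC exceed their nulls (significant PCs form a prefix, and the familywise
#' null rate is governed by PC1 alone). Loading `(j, k)` is significant
#' when its observed magnitude exceeds the `1 - alpha` quantile of the
#' permuted `|loading|` at that position.
#'
#' @param x the data matrix given to [fit_pca()]
#' @param B number of permutations (>= 199; default 999)
#' @param alpha significance level (default 0.05)
#' @param seed integer seed
#' @return the fitted `pc_model` with `significant_pcs` and
#'   `significant_loadings` filled in
#' @export
permutation_significance <- function(x, B = 999, alpha = 0.05, seed = 1) {
  if (B < 199 || (B + 1) * alpha < 1)
    stop("B too small to resolve alpha = ", alpha)
  x <- as.matrix(x)
  m <- fit_pca(x)
  p <- ncol(x)
  set.seed(seed)
  perm_pct <- matrix(NA_real_, B, p)
  perm_absload <- array(NA_real_, c(p, p, B))
  for (b in seq_len(B)) {
    xp <- apply(x, 2, sample)
    ei <- eigen(stats::cor(xp), symmetric = TRUE)
    perm_pct[b, ] <- ei$values / sum(ei$values)
    perm_absload[, , b] <- abs(ei$vectors)
  }
  thr_pct <- apply(perm_pct, 2, stats::quantile, probs = 1 - alpha)
  exceeds <- m$pct_variance > thr_pct
  m$significant_pcs <- exceeds & cumprod(exceeds) > 0  # sequential prefix
  thr_load <- apply(perm_absload, c(1, 2), stats::quantile,
                    probs = 1 - alpha)
  m$significant_loadings <- abs(m$loadings) > thr_load
  m$B <- B
  m$alpha <- alpha
  m
}

#' Interpret PC loadings above a magnitude cutoff
#'
#' For each significant PC, lists the measures whose loading is both
#' permutation-significant and strictly larger than `cutoff` in magnitude
#' (the conventional `|0.4|` rule), with its sign.
#'
#' @param m a `pc_model` after [permutation_significance()]
#' @param cutoff loading magnitude threshold (default 0.4, strict)
#' @return named list (one element per significant PC) of data.frames with
#'   `variable` and `loading`; empty elements carry a warning
#' @export
interpret_loadings <- function(m, cutoff = 0.4) {
  sig_pcs <- which(if (anyNA(m$significant_pcs))
    rep(TRUE, ncol(m$loadings)) else m$significant_pcs)
  out <- lapply(sig_pcs, function(k) {
    keep <- (if (anyNA(m$significant_loadings[, k]))
      rep(TRUE, nrow(m$loadings)) else m$significant_loadings[, k]) &
      abs(m$loadings[, k]) > cutoff
    data.frame(variable = rownames(m$loadings)[keep],
               loading = unname(m$loadings[keep, k]))
  })
  names(out) <- colnames(m$loadings)[sig_pcs]
  if (any(vapply(out, nrow, integer(1)) == 0))
    warning("some significant PCs have no loading above |", cutoff, "|")
  out
}

#' Orient PC3 so that higher scores mean more edge exploration
#'
#' When the `longest_hallway_sequence` loading on PC3 is negative, PC3
#' scores and loadings are multiplied by -1 so that higher PC3 values
#' represent more exploration of the maze's graph edges; the flip is
#' recorded in `orientation`. Idempotent.
#'
#' @param m a `pc_model` with at least 3 PCs
#' @param variable anchor measure (default `"longest_hallway_sequence"`)
#' @return the reoriented `pc_model`
#' @export
orient_pc3 <- function(m, variable = "longest_hallway_sequence") {
  if (ncol(m$loadings) < 3) stop("need at least 3 PCs")
  if (!variable %in% rownames(m$loadings))
    stop("unknown anchor variable: ", variable)
  if (m$loadings[variable, 3] < 0) {
    m$loadings[, 3] <- -m$loadings[, 3]
    m$scores[, 3] <- -m$scores[, 3]
    m$orientation[3] <- -m$orientation[3]
  }
  m
}

#' Per-group OLS of wayfinding success on PC scores
#'
#' Ordinary least squares of wayfinding success on the (significant) PC
#' scores, fitted separately within one group; scores come from the pooled
#' PCA fit, whose rows must align with the cohort table.
#'
#' @param tab cohort data.frame (rows aligned with the PCA input)
#' @param m a `pc_model`
#' @param group `"young"` or `"midlife"`
#' @param pcs integer vector of PC indices (default: the significant PCs,
#'   or 1:3 when significance was not assessed)
#' @return list with `coefficients` (data.frame: term, beta, se, t, p),
#'   `r_squared`, `f`, `model_p`, `n`
#' @export
regress_success_on_pcs <- function(tab, m, group, pcs = NULL) {
  if (nrow(tab) != nrow(m$scores))
    stop("cohort table and PC scores are not aligned")
  if (is.null(pcs))
    pcs <- if (anyNA(m$significant_pcs)) 1:3 else which(m$significant_pcs)
  sel <- tab$group == group
  if (sum(sel) < length(pcs) + 2)
    stop("group ", group, " too small for ", length(pcs), " predictors")
  d <- data.frame(success = tab$wayfinding_success[sel],
                  m$scores[sel, pcs, drop = FALSE])
  fit <- stats::lm(success ~ ., data = d)
  if (fit$rank < length(pcs) + 1) stop("rank-deficient design")
  s <- summary(fit)
  co <- s$coefficients
  fstat <- s$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(coefficients = data.frame(term = rownames(co), beta = co[, 1],
                                 se = co[, 2], t = co[, 3], p = co[, 4],
                                 row.names = NULL),
       r_squared = s$r.squared,
       f = unname(if (is.null(fstat)) NA_real_ else fstat[1]),
       model_p = unname(model_p), n = sum(sel), group = group)
}
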