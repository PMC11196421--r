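#' Default pipeline configuration
#'
#' A run is fully described by its configuration: the maze (the shipped
#' default or a maze file path), the synthetic cohort specification (or,
#' for real data, a metrics CSV path), Monte Carlo sizes, the significance
#' level and the output directory. Identical configurations (including
#' seeds) produce identical output tables.
#'
#' @param seed master seed for the whole run
#' @param out_dir output directory (created if missing)
#' @param maze `"default"` or a maze file path for [load_maze()]
#' @param cohort a [cohort_spec()] (defaults to the study-sized cohort
#'   seeded from `seed`)
#' @param B_perm PCA permutations
#' @param B_boot mediation bootstrap resamples
#' @param alpha significance level
#' @return list of class `run_config`
#' @export
default_config <- function(seed = 1L, out_dir = file.path(tempdir(), "mazexplore-run"),
                           maze = "default", cohort = cohort_spec(seed = seed),
                           B_perm = 999, B_boot = 999, alpha = 0.05) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, maze = maze,
                 cohort = cohort, B_perm = B_perm, B_boot = B_boot,
                 alpha = alpha),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> metrics -> the four inference steps:
#' sex-adjusted group ANCOVAs with block-wise mixed models and chance-level
#' tests; mediation of the age effect on wayfinding success through each
#' group-different measure; permutation-tested PCA with per-group
#' regressions; and the logistic age classifiers compared by DeLong's
#' test. All tables are written as CSV under `cfg$out_dir` together with a
#' JSON run manifest.
#'
#' @param cfg a [default_config()] list
#' @return (invisibly) the report bundle: a list with the cohort table and
#'   every result object, plus `files` naming the outputs written
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  maze <- with_stage("maze", {
    if (identical(cfg$maze, "default")) default_maze() else load_maze(cfg$maze)
  })
  tab <- with_stage("simulate", {
    generate_cohort(cfg$cohort, maze, per_block = TRUE)
  })
  if (min(table(tab$group)) < 15)
    warning("low n: a group has fewer than 15 participants")
  files <- c(metrics = file.path(cfg$out_dir, "metrics.csv"))
  with_stage("metrics", write_metrics_csv(tab, files["metrics"]))

  demo <- with_stage("demographics", chi_square_sex(table(tab$group, tab$sex)))

  vars <- c(metric_names(), "wayfinding_success")
  anc <- with_stage("ancova", {
    do.call(rbind, lapply(vars, function(v) {
      r <- ancova_group(tab, v)
      data.frame(variable = v, F = r$F, df1 = r$df1, df2 = r$df2, p = r$p,
                 eta_p2 = r$eta_p2, transform = r$transform_used,
                 direction_midlife = r$direction)
    }))
  })
  files["ancova"] <- file.path(cfg$out_dir, "ancova.csv")
  utils::write.csv(anc, files["ancova"], row.names = FALSE)

  pb <- attr(tab, "per_block")
  block_tab <- with_stage("blocks", {
    do.call(rbind, lapply(levels(pb$group), function(g) {
      sub <- pb[pb$group == g, ]
      do.call(rbind, lapply(metric_names(), function(v) {
        r <- lmm_block(sub, v)
        b1 <- sub[[v]][sub$block == 1]; b2 <- sub[[v]][sub$block == 2]
        data.frame(group = g, variable = v,
                   block1_mean = mean(b1), block1_sd = stats::sd(b1),
                   block1_median = stats::median(b1),
                   block2_mean = mean(b2), block2_sd = stats::sd(b2),
                   block2_median = stats::median(b2),
                   estimate = r$estimate, p = r$p, eta_p2 = r$eta_p2)
      }))
    }))
  })
  files["blocks"] <- file.path(cfg$out_dir, "block_effects.csv")
  utils::write.csv(block_tab, files["blocks"], row.names = FALSE)

  chance <- with_stage("chance", {
    lapply(stats::setNames(nm = levels(tab$group)), function(g)
      wilcoxon_vs_chance(tab$wayfinding_success[tab$group == g]))
  })

  sexdiff <- with_stage("sex-anova", {
    do.call(rbind, lapply(vars, function(v)
      cbind(variable = v, sex_anova(tab, v))))
  })
  files["sex_anova"] <- file.path(cfg$out_dir, "sex_anova.csv")
  utils::write.csv(sexdiff, files["sex_anova"], row.names = FALSE)

  mediators <- anc$variable[anc$p < cfg$alpha &
                              anc$variable != "wayfinding_success"]
  med <- with_stage("mediation", {
    if (length(mediators) == 0) NULL else
      run_mediation_battery(tab, mediators, B = cfg$B_boot,
                            seed = cfg$seed)
  })
  if (!is.null(med)) {
    files["mediation"] <- file.path(cfg$out_dir, "mediation.csv")
    utils::write.csv(med, files["mediation"], row.names = FALSE)
  }

  pca <- with_stage("pca", {
    m <- permutation_significance(as.matrix(tab[, metric_names()]),
                                  B = cfg$B_perm, alpha = cfg$alpha,
                                  seed = cfg$seed)
    orient_pc3(m)
  })
  loadings_tab <- with_stage("pca", {
    do.call(rbind, lapply(seq_len(ncol(pca$loadings)), function(k)
      data.frame(pc = colnames(pca$loadings)[k],
                 variable = rownames(pca$loadings),
                 loading = pca$loadings[, k],
                 pc_significant = pca$significant_pcs[k],
                 loading_significant = pca$significant_loadings[, k],
                 passes_cutoff = abs(pca$loadings[, k]) > 0.4,
                 pct_variance = pca$pct_variance[k],
                 row.names = NULL)))
  })
  files["loadings"] <- file.path(cfg$out_dir, "pca_loadings.csv")
  utils::write.csv(loadings_tab, files["loadings"], row.names = FALSE)
  files["scores"] <- file.path(cfg$out_dir, "pca_scores.csv")
  utils::write.csv(data.frame(participant_id = tab$participant_id,
                              pca$scores),
                   files["scores"], row.names = FALSE)
  interp <- interpret_loadings(pca)

  regs <- with_stage("regression", {
    pcs <- if (any(pca$significant_pcs)) which(pca$significant_pcs) else 1:3
    lapply(stats::setNames(nm = levels(tab$group)), function(g)
      regress_success_on_pcs(tab, pca, g, pcs = pcs))
  })
  files["regression"] <- file.path(cfg$out_dir, "regressions.csv")
  utils::write.csv(do.call(rbind, lapply(regs, function(r)
    cbind(group = r$group, r$coefficients, r_squared = r$r_squared,
          model_p = r$model_p))), files["regression"], row.names = FALSE)

  cls <- with_stage("classifier", classify_age(tab, pca))
  files["roc"] <- file.path(cfg$out_dir, "roc_points.csv")
  utils::write.csv(rbind(
    data.frame(model = "exploration_pcs", fpr = cls$roc_pcs$fpr,
               tpr = cls$roc_pcs$tpr),
    data.frame(model = "wayfinding_success", fpr = cls$roc_success$fpr,
               tpr = cls$roc_success$tpr)), files["roc"], row.names = FALSE)
  files["classifier"] <- file.path(cfg$out_dir, "classifier.json")
  jsonlite::write_json(list(
    kept_pcs = cls$kept_pcs,
    auc_exploration = cls$roc_pcs$auc,
    auc_success = cls$roc_success$auc,
    delong_p = cls$delong$p), files["classifier"], auto_unbox = TRUE,
    digits = NA)

  files["manifest"] <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(list(
    package = "mazexplore",
    version = as.character(utils::packageVersion("mazexplore")),
    seed = cfg$seed, maze = cfg$maze,
    cohort = unclass(cfg$cohort[c("n_young", "n_midlife",
                                  "prop_female_young",
                                  "prop_female_midlife", "seed")]),
    young_profile = unclass(cfg$cohort$young_profile),
    midlife_profile = unclass(cfg$cohort$midlife_profile),
    B_perm = cfg$B_perm, B_boot = cfg$B_boot, alpha = cfg$alpha),
    files["manifest"], auto_unbox = TRUE, digits = NA)

  invisible(structure(list(config = cfg, maze = maze, cohort = tab,
                           demographics = demo, ancova = anc,
                           blocks = block_tab, chance = chance,
                           sex_anova = sexdiff, mediation = med,
                           pca = pca, loadings = loadings_tab,
                           interpretation = interp, regressions = regs,
                           classifier = cls, files = files),
                      class = "report_bundle"))
}

#' Render a human-readable Markdown report from a bundle
#'
#' Writes a report summarizing every pipeline stage, with violin-style
#' group comparison figures, PC-versus-success scatter plots and the ROC
#' overlay (written as PNG next to the report when `figures = TRUE`).
#'
#' @param bundle a [run_pipeline()] result
#' @param path output file (default `report.md` in the run directory)
#' @param figures also render the PNG figures (default TRUE)
#' @return `path` invisibly
#' @export
render_report <- function(bundle,
                          path = file.path(bundle$config$out_dir, "report.md"),
                          figures = TRUE) {
  needed <- c("cohort", "demographics", "ancova", "blocks", "chance",
              "pca", "regressions", "classifier")
  miss <- needed[!vapply(needed, function(n)
    !is.null(bundle[[n]]), logical(1))]
  if (length(miss) > 0)
    stop("bundle is missing member(s): ", paste(miss, collapse = ", "))
  tab <- bundle$cohort
  fig_dir <- dirname(path)
  lines <- c("# Maze exploration analysis report", "",
             sprintf("Cohort: %d young, %d midlife participants (seed %d).",
                     sum(tab$group == "young"), sum(tab$group == "midlife"),
                     bundle$config$seed), "",
             "## Demographics",
             sprintf("Sex-by-group chi-square (Yates): X2 = %.3f, df = %d, p = %.3g.",
                     bundle$demographics$statistic, bundle$demographics$df,
                     bundle$demographics$p), "",
             "## Group differences (ANCOVA, sex-adjusted)", "",
             paste(utils::capture.output(print(bundle$ancova,
                                               row.names = FALSE)),
                   collapse = "\n"), "",
             "## Test phase vs chance (0.11)",
             paste(vapply(names(bundle$chance), function(g)
               sprintf("- %s: W = %.0f, one-tailed p = %.3g", g,
                       bundle$chance[[g]]$W, bundle$chance[[g]]$p), ""),
               collapse = "\n"), "",
             "## Principal components",
             sprintf("Significant PCs: %s; variance explained: %s.",
                     paste(which(bundle$pca$significant_pcs),
                           collapse = ", "),
                     paste(sprintf("%.1f%%",
                                   100 * bundle$pca$pct_variance[1:3]),
                           collapse = ", ")), "",
             "## Success-on-PC regressions",
             paste(vapply(bundle$regressions, function(r)
               sprintf("- %s: R2 = %.3f, model p = %.3g", r$group,
                       r$r_squared, r$model_p), ""), collapse = "\n"), "",
             "## Age classification",
             sprintf("Exploration-PC model (kept: %s): AUC = %.3f; wayfinding-success model: AUC = %.3f; DeLong p = %.3g.",
                     paste(bundle$classifier$kept_pcs, collapse = "+"),
                     bundle$classifier$roc_pcs$auc,
                     bundle$classifier$roc_success$auc,
                     bundle$classifier$delong$p), "")
  if (!is.null(bundle$mediation)) {
    lines <- c(lines, "## Mediation of the age effect", "",
               paste(utils::capture.output(print(bundle$mediation,
                                                 row.names = FALSE)),
                     collapse = "\n"), "")
  }
  if (figures) {
    lines <- c(lines, "## Figures",
               "![group comparisons](fig_group_violin.png)",
               "![success vs PCs](fig_pc_scatter.png)",
               "![ROC overlay](fig_roc.png)", "")
    long <- stats::reshape(
      tab[, c("participant_id", "group", metric_names(),
              "wayfinding_success")],
      direction = "long",
      varying = c(metric_names(), "wayfinding_success"),
      v.names = "value", timevar = "variable",
      times = c(metric_names(), "wayfinding_success"))
    gp <- ggplot2::ggplot(long, ggplot2::aes(x = group,
                                             y = value,
                                             fill = group)) +
      ggplot2::geom_violin(alpha = 0.6) +
      ggplot2::stat_summary(fun = mean, geom = "point", color = "red") +
      ggplot2::facet_wrap(~variable, scales = "free_y") +
      ggplot2::theme_minimal() + ggplot2::theme(legend.position = "none")
    ggplot2::ggsave(file.path(fig_dir, "fig_group_violin.png"), gp,
                    width = 9, height = 7, dpi = 120)
    pcs <- if (any(bundle$pca$significant_pcs))
      which(bundle$pca$significant_pcs) else 1:3
    sc <- do.call(rbind, lapply(pcs, function(k)
      data.frame(pc = colnames(bundle$pca$scores)[k],
                 score = bundle$pca$scores[, k],
                 success = tab$wayfinding_success, group = tab$group)))
    gs <- ggplot2::ggplot(sc, ggplot2::aes(x = score,
                                           y = success,
                                           color = group)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_smooth(method = "lm", se = FALSE,
                           formula = y ~ x) +
      ggplot2::facet_wrap(~pc) + ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(fig_dir, "fig_pc_scatter.png"), gs,
                    width = 9, height = 3.5, dpi = 120)
    rocd <- rbind(
      data.frame(model = sprintf("exploration PCs (AUC %.3f)",
                                 bundle$classifier$roc_pcs$auc),
                 fpr = bundle$classifier$roc_pcs$fpr,
                 tpr = bundle$classifier$roc_pcs$tpr),
      data.frame(model = sprintf("wayfinding success (AUC %.3f)",
                                 bundle$classifier$roc_success$auc),
                 fpr = bundle$classifier$roc_success$fpr,
                 tpr = bundle$classifier$roc_success$tpr))
    gr <- ggplot2::ggplot(rocd, ggplot2::aes(x = fpr, y = tpr,
                                             color = model)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dashed", color = "grey") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(fig_dir, "fig_roc.png"), gr,
                    width = 6, height = 4.5, dpi = 120)
  }
  writeLines(lines, path)
  invisible(path)
}
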