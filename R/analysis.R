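#' Run the full drawing-style analysis
#'
#' Executes the complete statistical workflow on a per-drawing metrics
#' table (see [compute_metrics()]):
#'
#' 1. correlation screen of the eleven quantitative variables;
#' 2. PCA with eigenvalue > 1 retention (optional Varimax rotation);
#' 3. *inter-individual arm*: per retained dimension, Kruskal-Wallis
#'    across individuals with BH-adjusted pairwise Wilcoxon post hocs;
#'    the same test per raw variable; chi-square of main colour per
#'    individual;
#' 4. *longitudinal arm* (drawings of the `longitudinal` individual only):
#'    a separate PCA, then per retained dimension a permutation linear
#'    model `score ~ season + period` with generalized VIFs and, for
#'    significant season terms, pairwise permutation post hocs between
#'    seasons; the same per raw variable; chi-square of main colour per
#'    season.
#'
#' The inter-individual arm is skipped (with a note) when the table holds
#' a single individual; the longitudinal arm is skipped when the flagged
#' individual is absent or has fewer than 2 periods.
#'
#' @param metrics metrics data frame with the columns produced by
#'   [compute_metrics()].
#' @param config list: `B` (permutations, default 10000), `alpha` (0.05),
#'   `eigen_threshold` (1), `correlation_threshold` (0.8), `rotation`
#'   (`"none"`), `seed` (1), `longitudinal` (`"Molly"`).
#' @return An object of class `drawing_analysis`: list with elements
#'   `screen`, `pca`, `individual_tests` (per dimension), `variable_tests`,
#'   `colour_by_individual`, `longitudinal` (list with `pca`, `lm` per
#'   dimension, `lm_variables`, `posthoc_season`, `colour_by_season`),
#'   `config`, `log` (character vector).
#' @export
run_full_analysis <- function(metrics, config = list()) {
  cfg <- utils::modifyList(
    list(B = 10000, alpha = 0.05, eigen_threshold = 1,
         correlation_threshold = 0.8, rotation = "none", seed = 1,
         longitudinal = "Molly"), config)
  req <- c("drawing_id", "individual", "season", "period",
           quantitative_metrics(), "main_colour")
  missing_cols <- setdiff(req, names(metrics))
  if (length(missing_cols))
    stop("metrics table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))
  say("analysis seed %d, B = %d permutations", cfg$seed, cfg$B)
  say("%d drawings, %d individuals", nrow(metrics),
      length(unique(metrics$individual)))

  qm <- as.matrix(metrics[, quantitative_metrics()])
  constant <- colnames(qm)[apply(qm, 2, sd) == 0]
  if (length(constant)) {
    say("constant variable(s) dropped from PCA and tests: %s",
        paste(constant, collapse = ", "))
    qm <- qm[, setdiff(colnames(qm), constant), drop = FALSE]
  }
  active <- colnames(qm)
  screen <- correlation_screen(qm, cfg$correlation_threshold)
  say("correlation screen: %d pair(s) above %.2f", nrow(screen$flagged),
      cfg$correlation_threshold)

  pca <- pca_fit(qm, rotation = cfg$rotation,
                 eigen_threshold = cfg$eigen_threshold)
  say("PCA: %d retained dimension(s), %.1f%% of variance",
      length(pca$retained), sum(pca$variance_pct[pca$retained]))

  seeds <- derive_seeds(cfg$seed, 200)
  si <- 0
  next_seed <- function() {
    si <<- si + 1
    seeds[si]
  }

  # -- inter-individual arm -------------------------------------------------
  individual_tests <- NULL
  variable_tests <- NULL
  colour_by_individual <- NULL
  if (length(unique(metrics$individual)) >= 2) {
    individual_tests <- lapply(pca$retained, function(d)
      kruskal_with_posthoc(pca$scores[, d], metrics$individual, cfg$alpha))
    names(individual_tests) <- paste0("dim", pca$retained)
    variable_tests <- lapply(active, function(v)
      kruskal_with_posthoc(metrics[[v]], metrics$individual, cfg$alpha))
    names(variable_tests) <- active
    colour_by_individual <- chisq_main_colour(metrics$main_colour,
                                              metrics$individual)
  } else {
    say("single individual: inter-individual arm skipped")
  }

  # -- longitudinal arm -----------------------------------------------------
  longitudinal <- NULL
  lmet <- metrics[metrics$individual == cfg$longitudinal, ]
  if (nrow(lmet) >= 20 && length(unique(lmet$period)) >= 2 &&
      length(unique(lmet$season)) >= 2) {
    lqm <- as.matrix(lmet[, quantitative_metrics()])
    lconst <- colnames(lqm)[apply(lqm, 2, sd) == 0]
    if (length(lconst))
      say("longitudinal arm: constant variable(s) dropped: %s",
          paste(lconst, collapse = ", "))
    lqm <- lqm[, setdiff(colnames(lqm), lconst), drop = FALSE]
    lactive <- colnames(lqm)
    lpca <- pca_fit(lqm, rotation = cfg$rotation,
                    eigen_threshold = cfg$eigen_threshold)
    say("longitudinal PCA (%s, n = %d): %d retained dimension(s)",
        cfg$longitudinal, nrow(lmet), length(lpca$retained))
    lms <- lapply(lpca$retained, function(d)
      permutation_lm(lpca$scores[, d], lmet$season, lmet$period,
                     B = cfg$B, seed = next_seed()))
    names(lms) <- paste0("dim", lpca$retained)
    lm_vars <- lapply(lactive, function(v)
      permutation_lm(lmet[[v]], lmet$season, lmet$period,
                     B = cfg$B, seed = next_seed()))
    names(lm_vars) <- lactive
    posthoc <- vector("list", length(lms))
    names(posthoc) <- names(lms)
    for (k in seq_along(lms)) {
      tl <- lms[[k]]$terms
      if (tl$p_perm[tl$term == "season"] < cfg$alpha)
        posthoc[[k]] <- pairwise_permutation_posthoc(
          lpca$scores[, lpca$retained[k]], lmet$season,
          B = cfg$B, seed = next_seed())
    }
    longitudinal <- list(pca = lpca, lm = lms, lm_variables = lm_vars,
                         posthoc_season = posthoc,
                         colour_by_season = chisq_main_colour(
                           lmet$main_colour, lmet$season),
                         individual = cfg$longitudinal, n = nrow(lmet))
  } else {
    say("longitudinal arm skipped (individual '%s' absent or too sparse)",
        cfg$longitudinal)
  }

  structure(list(screen = screen, pca = pca,
                 individual_tests = individual_tests,
                 variable_tests = variable_tests,
                 colour_by_individual = colour_by_individual,
                 longitudinal = longitudinal,
                 config = cfg, log = logline),
            class = "drawing_analysis")
}

#' @export
print.drawing_analysis <- function(x, ...) {
  cat("drawing-style analysis\n")
  cat(sprintf("  %s\n", x$log))
  if (!is.null(x$individual_tests)) {
    for (d in names(x$individual_tests)) {
      t <- x$individual_tests[[d]]
      cat(sprintf("  %s: KW chi2 = %.2f (df %d), p = %s\n", d,
                  t$statistic, t$df, format.pval(t$p_value, digits = 3)))
    }
  }
  if (!is.null(x$longitudinal)) {
    for (d in names(x$longitudinal$lm)) {
      t <- x$longitudinal$lm[[d]]$terms
      cat(sprintf("  longitudinal %s: season p = %s, period p = %s\n", d,
                  format.pval(t$p_perm[t$term == "season"], digits = 3),
                  format.pval(t$p_perm[t$term == "period"], digits = 3)))
    }
  }
  invisible(x)
}

#' Write analysis reports to disk
#'
#' Writes the standard report bundle of a [run_full_analysis()] result:
#' `pca_loadings.csv`, `pca_scores.csv`, `group_tests.json`,
#' `perm_lm.json`, `colour_tests.json` and `run_log.txt`.
#'
#' @param analysis a `drawing_analysis`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_analysis_reports <- function(analysis, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create ", dir)
  pca <- analysis$pca
  ld <- data.frame(variable = pca$variables,
                   pca$loadings[, pca$retained, drop = FALSE])
  write.csv(ld, file.path(dir, "pca_loadings.csv"), row.names = FALSE)
  write.csv(data.frame(pca$scores[, pca$retained, drop = FALSE]),
            file.path(dir, "pca_scores.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(analysis$individual_tests, function(t)
      list(statistic = t$statistic, df = t$df, p_value = t$p_value,
           pairwise = as.data.frame(t$pairwise), letters = as.list(t$letters))),
    file.path(dir, "group_tests.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    if (!is.null(analysis$longitudinal))
      lapply(analysis$longitudinal$lm, function(f)
        list(terms = f$terms, vif = as.list(f$vif), B = f$B, seed = f$seed)),
    file.path(dir, "perm_lm.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(by_individual = analysis$colour_by_individual,
         by_season = if (!is.null(analysis$longitudinal))
           analysis$longitudinal$colour_by_season),
    file.path(dir, "colour_tests.json"), auto_unbox = TRUE, digits = NA)
  writeLines(analysis$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
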