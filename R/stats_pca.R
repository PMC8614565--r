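#' Screen drawing variables for high correlations
#'
#' Computes the pairwise Pearson correlation matrix of the quantitative
#' drawing variables and flags pairs exceeding the threshold in absolute
#' value (strictly greater). The screen only reports; no variable is
#' dropped automatically. Constant columns have undefined correlations and
#' are reported as such.
#'
#' @param x numeric matrix or data frame of variables (rows = drawings).
#' @param threshold flag |r| strictly above this (default 0.8).
#' @return An object of class `correlation_screen`: list with `correlation`
#'   (matrix), `flagged` (data frame of flagged pairs), `undefined`
#'   (character vector of constant variables), `threshold`.
#' @export
correlation_screen <- function(x, threshold = 0.8) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3)
  sds <- apply(x, 2, sd)
  undefined <- colnames(x)[sds == 0]
  r <- suppressWarnings(cor(x))
  pairs <- which(upper.tri(r) & !is.na(r) & abs(r) > threshold,
                 arr.ind = TRUE)
  flagged <- data.frame(
    var1 = colnames(x)[pairs[, 1]],
    var2 = colnames(x)[pairs[, 2]],
    r = r[pairs],
    stringsAsFactors = FALSE)
  structure(list(correlation = r, flagged = flagged, undefined = undefined,
                 threshold = threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("correlation screen of %d variables (flag |r| > %g):\n",
              ncol(x$correlation), x$threshold))
  if (nrow(x$flagged) == 0) cat("  no strongly correlated pair\n")
  else print(x$flagged)
  if (length(x$undefined))
    cat("  undefined (constant):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Principal component analysis with eigenvalue-based retention
#'
#' PCA on the correlation matrix (variables centred and scaled), retaining
#' the dimensions whose eigenvalue exceeds `eigen_threshold` (Kaiser rule,
#' default 1). Loadings are variable-dimension correlations (eigenvector
#' times the square root of the eigenvalue); per-drawing scores are
#' returned for every component so downstream group tests can use them.
#' An optional Varimax rotation is applied to the retained loadings.
#'
#' @param x numeric matrix/data frame of quantitative variables.
#' @param rotation `"none"` or `"varimax"`.
#' @param eigen_threshold retention threshold on the eigenvalue.
#' @return An object of class `pca_model`: list with `eigenvalues`,
#'   `variance_pct` (percent of total variance per component, summing to
#'   100), `retained` (indices), `loadings` (all components),
#'   `rotated_loadings` (retained, if rotated), `scores`, `variables`,
#'   `rotation`, `n`.
#' @export
pca_fit <- function(x, rotation = c("none", "varimax"),
                    eigen_threshold = 1) {
  rotation <- match.arg(rotation)
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2)
  if (anyNA(x)) stop("missing values in PCA input")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  if (nrow(x) < ncol(x))
    warning("fewer drawings than variables; PCA computed anyway")
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2
  loadings <- sweep(fit$rotation, 2, fit$sdev, `*`)
  retained <- which(ev > eigen_threshold)
  rotated <- NULL
  if (rotation == "varimax" && length(retained) >= 2) {
    vm <- varimax(loadings[, retained, drop = FALSE])
    rotated <- unclass(vm$loadings)
  }
  structure(list(eigenvalues = ev,
                 variance_pct = 100 * ev / sum(ev),
                 retained = retained,
                 loadings = loadings,
                 rotated_loadings = rotated,
                 scores = fit$x,
                 eigenvectors = fit$rotation,
                 center = fit$center, scale = fit$scale,
                 variables = colnames(x),
                 rotation = rotation, n = nrow(x)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, digits = 2, ...) {
  k <- length(x$retained)
  cat(sprintf("PCA of %d variables on %d drawings: %d dimension(s) with eigenvalue > 1\n",
              length(x$variables), x$n, k))
  for (i in x$retained)
    cat(sprintf("  dim %d: eigenvalue %.2f, %.1f%% of variance\n",
                i, x$eigenvalues[i], x$variance_pct[i]))
  cat(sprintf("  retained dimensions describe %.1f%% of the variance\n",
              sum(x$variance_pct[x$retained])))
  invisible(x)
}

#' Simulate metrics with a planted latent factor structure
#'
#' Generates an n x 11 variable matrix driven by `k` independent standard
#' normal latent factors: each variable loads `loading` on its own factor
#' (variables are split evenly over the factors, mimicking the
#' filling / colour / shape block structure of drawing metrics) plus
#' unit-variance noise. Used to check that eigenvalue-based retention
#' recovers the planted dimensionality.
#'
#' @param n rows (drawings).
#' @param k latent factors (default 3).
#' @param p variables (default 11).
#' @param loading common loading of a variable on its own factor.
#' @param seed RNG seed.
#' @return list with `x` (matrix) and `factor_of` (planted assignment).
#' @export
simulate_factor_metrics <- function(n = 790, k = 3, p = 11, loading = 0.75,
                                    seed = 1) {
  with_seed(seed, {
    fac <- matrix(rnorm(n * k), n, k)
    assign_f <- rep(seq_len(k), length.out = p)
    noise_sd <- sqrt(1 - loading^2)
    x <- fac[, assign_f] * loading +
      matrix(rnorm(n * p, sd = noise_sd), n, p)
    colnames(x) <- paste0("v", seq_len(p))
    list(x = x, factor_of = assign_f)
  })
}
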