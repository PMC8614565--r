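#' Kruskal-Wallis comparison with pairwise Wilcoxon post hocs
#'
#' Omnibus Kruskal-Wallis rank test (tie-corrected) across groups, followed
#' by all pairwise two-sided Wilcoxon rank-sum tests with
#' Benjamini-Hochberg adjustment across the pairs, and a compact
#' letter-style grouping summary at level `alpha` (groups sharing a letter
#' are not significantly different).
#'
#' @param y numeric response (e.g. per-drawing dimension scores).
#' @param groups group labels (e.g. individuals).
#' @param alpha level used for the letter grouping.
#' @return An object of class `group_test`: list with `statistic`, `df`,
#'   `p_value`, `pairwise` (matrix of BH-adjusted p), `letters`, `groups`,
#'   `n`.
#' @export
kruskal_with_posthoc <- function(y, groups, alpha = 0.05) {
  groups <- as.character(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("group(s) with <2 observations excluded: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    y <- y[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  g <- factor(groups)
  kw <- kruskal.test(y, g)
  pw <- suppressWarnings(
    pairwise.wilcox.test(y, g, p.adjust.method = "BH", exact = FALSE))
  pmat <- full_pair_matrix(pw$p.value, levels(g))
  structure(list(statistic = unname(kw$statistic),
                 df = unname(kw$parameter),
                 p_value = kw$p.value,
                 pairwise = pmat,
                 letters = letter_groups(pmat, alpha),
                 groups = levels(g), n = as.vector(table(g))),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.2f, df = %d, p = %s\n",
              x$statistic, x$df, format.pval(x$p_value, digits = 3)))
  cat("letter groups:",
      paste(sprintf("%s:%s", names(x$letters), x$letters), collapse = "  "),
      "\n")
  invisible(x)
}

# lower-triangular pairwise.wilcox p matrix -> full symmetric matrix
full_pair_matrix <- function(p, levels) {
  m <- matrix(NA_real_, length(levels), length(levels),
              dimnames = list(levels, levels))
  for (i in rownames(p)) for (j in colnames(p))
    if (!is.na(p[i, j])) m[i, j] <- m[j, i] <- p[i, j]
  diag(m) <- 1
  m
}

# Compact letter display: greedy insert-and-absorb over the adjusted
# pairwise p matrix. Groups sharing a letter are not distinguishable at
# `alpha`.
letter_groups <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  sets <- list()
  for (gi in g) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (all(pmat[gi, sets[[k]]] >= alpha, na.rm = TRUE)) {
        sets[[k]] <- c(sets[[k]], gi)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- gi
  }
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) for (b in seq_along(sets))
    if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]))
      keep[a] <- FALSE
  sets <- sets[keep]
  out <- setNames(rep("", length(g)), g)
  for (k in seq_along(sets))
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters[k])
  out
}

#' Permutation-based multifactorial linear model
#'
#' Fits `y ~ season + period` by least squares and tests each term with a
#' partial F statistic whose null distribution is built by Monte Carlo
#' permutation of the response: the rows of `y` are permuted `B` times,
#' the model refitted, and `p = (1 + #{F* >= F_obs}) / (1 + B)` (the +1
#' convention, so p is never exactly 0 and never below `1/(B+1)`).
#' Collinearity of the predictors is summarized by generalized variance
#' inflation factors.
#'
#' @param y numeric response (dimension scores or a single metric).
#' @param season factor with the four seasons.
#' @param period numeric period index (1..19), entered as a linear trend.
#' @param B number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return An object of class `perm_lm`: list with `coefficients`,
#'   `t_values`, `r_squared`, `terms` (data frame: term, df, F, p_perm),
#'   `vif`, `B`, `seed`, `n`.
#' @export
permutation_lm <- function(y, season, period, B = 10000, seed = 1) {
  stopifnot(B >= 1, length(y) == length(season),
            length(y) == length(period))
  if (anyNA(y) || anyNA(season) || anyNA(period))
    stop("missing values in permutation LM input")
  season <- factor(as.character(season))
  if (nlevels(season) < 2)
    stop("rank-deficient design (aliased term: season)")
  dat <- data.frame(y = y, season = season, period = as.numeric(period))
  X_full <- model.matrix(~ season + period, dat)
  if (qr(X_full)$rank < ncol(X_full)) {
    bad <- if (nlevels(season) < 2) "season" else "design"
    stop("rank-deficient design (aliased term: ", bad, ")")
  }
  X_season <- model.matrix(~ period, dat)       # reduced: drop season
  X_period <- model.matrix(~ season, dat)       # reduced: drop period
  n <- length(y)
  qf <- qr(X_full); qs <- qr(X_season); qp <- qr(X_period)
  rss <- function(qrx, Y) colSums(qr.resid(qrx, Y)^2)
  Y0 <- matrix(y, n, 1)
  rss_full <- rss(qf, Y0)
  df_res <- n - ncol(X_full)
  df_season <- nlevels(season) - 1
  df_period <- 1
  f_stat <- function(rss_red, df_term, rss_f)
    ((rss_red - rss_f) / df_term) / (rss_f / df_res)
  F_obs <- c(season = f_stat(rss(qs, Y0), df_season, rss_full),
             period = f_stat(rss(qp, Y0), df_period, rss_full))

  perm_ge <- with_seed(seed, {
    ge <- c(season = 0L, period = 0L)
    block <- 2000L                     # permutations per matrix block
    done <- 0L
    while (done < B) {
      nb <- min(block, B - done)
      Y <- matrix(y[unlist(lapply(seq_len(nb), function(i)
        sample.int(n)))], n, nb)
      rf <- rss(qf, Y)
      Fs <- f_stat(rss(qs, Y), df_season, rf)
      Fp <- f_stat(rss(qp, Y), df_period, rf)
      ge["season"] <- ge["season"] + sum(Fs >= F_obs["season"])
      ge["period"] <- ge["period"] + sum(Fp >= F_obs["period"])
      done <- done + nb
    }
    ge
  })
  p_perm <- (1 + perm_ge) / (1 + B)

  fit <- lm(y ~ season + period, dat)
  sm <- summary(fit)
  structure(list(
    coefficients = coef(fit),
    t_values = sm$coefficients[, "t value"],
    r_squared = sm$r.squared,
    terms = data.frame(term = c("season", "period"),
                       df = c(df_season, df_period),
                       F = unname(F_obs), p_perm = unname(p_perm),
                       stringsAsFactors = FALSE),
    vif = vif_design(~ season + period, dat),
    B = B, seed = seed, n = n),
    class = "perm_lm")
}

#' @export
print.perm_lm <- function(x, ...) {
  cat(sprintf("permutation LM (n = %d, B = %d):\n", x$n, x$B))
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("  %s: F = %.2f (df %d), permutation p = %s\n",
                x$terms$term[i], x$terms$F[i], x$terms$df[i],
                format.pval(x$terms$p_perm[i], digits = 3)))
  cat(sprintf("  VIF: %s\n",
              paste(sprintf("%s %.2f", names(x$vif), x$vif), collapse = ", ")))
  invisible(x)
}

#' Generalized variance inflation factors
#'
#' Collinearity diagnostic for a model formula: for a single-column term,
#' the classical `1 / (1 - R^2)` of that predictor regressed on the others;
#' for a multi-column term (a factor), the generalized VIF of Fox &
#' Monette, `det(R11) det(R22) / det(R)`, computed from the correlation
#' matrix of the model-matrix columns. Perfectly collinear terms are
#' reported as `Inf`.
#'
#' @param formula right-hand-side formula of predictors (no response
#'   needed, e.g. `~ season + period`).
#' @param data data frame with the predictors.
#' @return named numeric vector of (G)VIFs, one per term.
#' @export
vif_design <- function(formula, data) {
  X <- model.matrix(formula, data)
  assign <- attr(X, "assign")
  X <- X[, assign != 0, drop = FALSE]
  assign <- assign[assign != 0]
  terms_lab <- attr(stats::terms(formula, data = data), "term.labels")
  if (length(unique(assign)) < 2) stop("need at least 2 predictor terms")
  R <- suppressWarnings(cor(X))
  detR <- det(R)
  out <- vapply(unique(assign), function(a) {
    i <- which(assign == a)
    if (detR <= .Machine$double.eps) return(Inf)
    det(R[i, i, drop = FALSE]) *
      det(R[-i, -i, drop = FALSE]) / detR
  }, numeric(1))
  setNames(out, terms_lab[unique(assign)])
}

#' Pairwise permutation post hoc tests
#'
#' For every pair of groups, a two-sided permutation test on the
#' difference in means: group labels are permuted `B` times within the
#' pair, `p = (1 + #{|d*| >= |d_obs|}) / (1 + B)`, then BH adjustment
#' across all pairs.
#'
#' @param y numeric response.
#' @param groups group labels.
#' @param B permutations per pair.
#' @param seed RNG seed.
#' @return An object of class `pairwise_perm`: list with `pairwise`
#'   (symmetric matrix of BH-adjusted p), `raw` (unadjusted), `B`, `seed`.
#' @export
pairwise_permutation_posthoc <- function(y, groups, B = 10000, seed = 1) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need at least 2 groups")
  pairs <- combn(lev, 2)
  raw <- numeric(ncol(pairs))
  seeds <- derive_seeds(seed, ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- y[groups == pairs[1, k]]
    b <- y[groups == pairs[2, k]]
    pooled <- c(a, b)
    n1 <- length(a); n <- length(pooled)
    d_obs <- abs(mean(a) - mean(b))
    raw[k] <- with_seed(seeds[k], {
      ge <- 0L
      for (blk in split_blocks(B, 2000L)) {
        idx <- matrix(unlist(lapply(seq_len(blk), function(i)
          sample.int(n))), n, blk)
        P <- matrix(pooled[idx], n, blk)
        d <- abs(colMeans(P[seq_len(n1), , drop = FALSE]) -
                   colMeans(P[-seq_len(n1), , drop = FALSE]))
        ge <- ge + sum(d >= d_obs - 1e-12)
      }
      (1 + ge) / (1 + B)
    })
  }
  adj <- p.adjust(raw, "BH")
  m <- matrix(NA_real_, length(lev), length(lev),
              dimnames = list(lev, lev))
  mr <- m
  for (k in seq_len(ncol(pairs))) {
    m[pairs[1, k], pairs[2, k]] <- m[pairs[2, k], pairs[1, k]] <- adj[k]
    mr[pairs[1, k], pairs[2, k]] <- mr[pairs[2, k], pairs[1, k]] <- raw[k]
  }
  diag(m) <- diag(mr) <- 1
  structure(list(pairwise = m, raw = mr, B = B, seed = seed),
            class = "pairwise_perm")
}

split_blocks <- function(B, size) {
  full <- B %/% size
  rest <- B %% size
  c(rep(size, full), if (rest > 0) rest)
}

#' Chi-square analysis of the main colour
#'
#' Per group (individual or season), a goodness-of-fit chi-square of the
#' observed main-colour counts against a uniform distribution over the
#' colour categories observed anywhere in the dataset ("is the colour
#' choice non-random?"). The modal colour and its share are reported. A
#' group in which some expected count falls below 5 carries a small-sample
#' warning flag.
#'
#' @param main_colour vector of main-colour ids/names per drawing (NA =
#'   empty drawing, dropped).
#' @param groups group labels.
#' @return An object of class `colour_test`: a data frame with one row per
#'   group: `group`, `n`, `categories`, `statistic`, `df`, `p_value`,
#'   `modal_colour`, `modal_share`, `small_sample`.
#' @export
chisq_main_colour <- function(main_colour, groups) {
  keep <- !is.na(main_colour)
  main_colour <- as.character(main_colour[keep])
  groups <- as.character(groups[keep])
  cats <- sort(unique(main_colour))
  rows <- lapply(sort(unique(groups)), function(g) {
    cnt <- table(factor(main_colour[groups == g], levels = cats))
    n <- sum(cnt)
    expected <- n / length(cats)
    cs <- if (length(cats) < 2) {
      # a single colour category carries no degrees of freedom
      list(statistic = 0, parameter = 0, p.value = NA_real_)
    } else {
      suppressWarnings(chisq.test(cnt, p = rep(1 / length(cats),
                                               length(cats))))
    }
    modal <- names(cnt)[which.max(cnt)]
    data.frame(group = g, n = n, categories = length(cats),
               statistic = unname(cs$statistic),
               df = unname(cs$parameter),
               p_value = cs$p.value,
               modal_colour = modal,
               modal_share = max(cnt) / n,
               small_sample = expected < 5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("colour_test", "data.frame")
  out
}
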