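test_that("correlation screen flags only strictly excessive correlations", {
  set.seed(101)
  x <- matrix(rnorm(300), 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  x <- cbind(x, d = x[, "a"])                       # exact duplicate
  sc <- correlation_screen(x)
  expect_equal(nrow(sc$flagged), 1)
  expect_equal(sort(unlist(sc$flagged[1, c("var1", "var2")], use.names = FALSE)),
               c("a", "d"))
  expect_equal(sc$flagged$r[1], 1)

  # r exactly at the threshold is not flagged (strict >)
  n <- 1000
  u <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ u))     # exactly orthogonal noise
  r <- 0.8
  y2 <- u * r / sd(u) + e * sqrt(1 - r^2) / sd(e)
  z <- cbind(p = u, q = y2)
  expect_equal(cor(z)[1, 2], 0.8, tolerance = 1e-12)
  expect_equal(nrow(correlation_screen(z, 0.8)$flagged), 0)

  # independent columns are not flagged at n = 1000
  big <- matrix(rnorm(11000), 1000, 11)
  colnames(big) <- paste0("v", 1:11)
  expect_equal(nrow(correlation_screen(big)$flagged), 0)

  const <- cbind(x[, 1:2], k = rep(2, 100))
  expect_equal(correlation_screen(const)$undefined, "k")
})

test_that("PCA retains eigenvalue > 1 dimensions and reproduces scores", {
  set.seed(102)
  a <- rnorm(200)
  two <- cbind(x = a, y = 2 * a + 3)            # perfectly correlated pair
  fit <- pca_fit(two)
  expect_equal(fit$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(fit$retained, 1L)
  expect_equal(sum(fit$variance_pct), 100, tolerance = 1e-6)

  sim <- simulate_factor_metrics(n = 400, seed = 9)
  fit2 <- pca_fit(sim$x)
  expect_equal(sum(fit2$variance_pct), 100, tolerance = 1e-6)
  expect_true(all(diff(fit2$eigenvalues) <= 1e-12))
  # scores are the standardized data projected on the eigenvectors
  z <- scale(sim$x)
  expect_equal(unname(fit2$scores), unname(z %*% fit2$eigenvectors),
               tolerance = 1e-8)
  # loadings are eigenvector columns scaled to correlation size
  expect_equal(unname(colSums(fit2$loadings^2)), fit2$eigenvalues,
               tolerance = 1e-8)

  expect_error(pca_fit(cbind(a, k = rep(1, 200))), "zero-variance")
  expect_warning(pca_fit(matrix(rnorm(3 * 11), 3, 11,
                                dimnames = list(NULL, paste0("v", 1:11)))),
                 "fewer")
})

test_that("varimax rotation is applied to the retained loadings", {
  sim <- simulate_factor_metrics(n = 500, seed = 10)
  fit <- pca_fit(sim$x, rotation = "varimax")
  expect_false(is.null(fit$rotated_loadings))
  expect_equal(ncol(fit$rotated_loadings), length(fit$retained))
  # rotation preserves total communality of the retained block
  expect_equal(sum(fit$rotated_loadings^2),
               sum(fit$loadings[, fit$retained]^2), tolerance = 1e-8)
})

test_that("Kruskal-Wallis omnibus and post hocs behave at the extremes", {
  y0 <- rep(c(1, 2, 3, 4, 5), 2)
  g0 <- rep(c("A", "B"), each = 5)
  t0 <- kruskal_with_posthoc(y0, g0)
  expect_equal(t0$statistic, 0, tolerance = 1e-9)
  expect_gt(t0$p_value, 0.99)
  expect_equal(unname(substr(t0$letters["A"], 1, 1)),
               unname(substr(t0$letters["B"], 1, 1)))

  set.seed(103)
  k <- 5
  y <- rnorm(150) + rep(seq(0, 12, by = 3), each = 30)
  g <- rep(paste0("G", 1:k), each = 30)
  t1 <- kruskal_with_posthoc(y, g)
  expect_equal(t1$df, k - 1)           # five groups -> chi-squared on 4 df
  expect_lt(t1$p_value, 1e-3)
  off <- t1$pairwise[upper.tri(t1$pairwise)]
  expect_true(all(off < 0.05))
  expect_equal(length(unique(t1$letters)), k)

  expect_warning(
    kruskal_with_posthoc(c(1, 2, 3, 4, 8, 9, 10, 11, 5),
                         c(rep("A", 4), rep("B", 4), "C")),
    "excluded")
})

test_that("BH adjustment matches the step-up definition and is monotone", {
  set.seed(104)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  praw <- c(0.001, 0.01, 0.02, 0.2, 0.8)
  padj <- p.adjust(praw, "BH")
  expect_true(all(padj >= praw))
  expect_true(all(diff(padj[order(praw)]) >= -1e-12))
})

test_that("permutation LM reaches its p-value floor and reproduces by seed", {
  set.seed(105)
  n <- 80
  period <- rep(1:19, length.out = n)
  season <- season_of_period(period)
  y <- 2 * period + rnorm(n, sd = 0.2)        # overwhelming period effect
  B <- 199
  fit <- permutation_lm(y, season, period, B = B, seed = 7)
  expect_equal(fit$terms$p_perm[fit$terms$term == "period"], 1 / (B + 1))
  fit2 <- permutation_lm(y, season, period, B = B, seed = 7)
  expect_identical(fit$terms, fit2$terms)
  expect_true(all(fit$vif >= 1))
  expect_error(permutation_lm(y, rep("winter", n), period, B = 9, seed = 1),
               "rank-deficient")
})

test_that("permutation p-values stabilize across seeds at large B", {
  set.seed(106)
  n <- 120
  period <- rep(1:19, length.out = n)
  season <- season_of_period(period)
  y <- rnorm(n) + 0.05 * period
  f1 <- permutation_lm(y, season, period, B = 10000, seed = 1)
  f2 <- permutation_lm(y, season, period, B = 10000, seed = 2)
  expect_lt(max(abs(f1$terms$p_perm - f2$terms$p_perm)), 0.01)
})

test_that("generalized VIF agrees with the standard implementation", {
  set.seed(107)
  n <- 200
  d <- data.frame(period = runif(n, 1, 19),
                  season = factor(sample(season_levels, n, TRUE)),
                  x = rnorm(n))
  d$y <- rnorm(n)
  got <- vif_design(~ season + period + x, d)
  skip_if_not_installed("car")
  want <- car::vif(lm(y ~ season + period + x, d))
  want_g <- if (is.matrix(want)) want[, "GVIF"] else want
  expect_equal(unname(got[c("season", "period", "x")]),
               unname(want_g[c("season", "period", "x")]), tolerance = 1e-8)

  orth <- data.frame(a = rep(c(-1, 1), 50), b = rep(c(-1, -1, 1, 1), 25))
  expect_equal(unname(vif_design(~ a + b, orth)), c(1, 1), tolerance = 1e-12)

  dup <- data.frame(a = rnorm(50))
  dup$b <- dup$a
  expect_true(is.infinite(max(vif_design(~ a + b, dup))))
})

test_that("pairwise permutation post hocs separate only shifted groups", {
  set.seed(108)
  y <- c(rnorm(25), rnorm(25), rnorm(25), rnorm(25) + 4)
  g <- rep(c("a", "b", "c", "d"), each = 25)
  ph <- pairwise_permutation_posthoc(y, g, B = 499, seed = 3)
  p <- ph$pairwise
  expect_true(all(p["d", c("a", "b", "c")] < 0.05))
  expect_true(all(p["a", c("b", "c")] > 0.2))
  same <- pairwise_permutation_posthoc(rep(1:10, 3),
                                       rep(c("a", "b", "c"), each = 10),
                                       B = 199, seed = 4)
  expect_true(all(same$pairwise[upper.tri(same$pairwise)] > 0.5))
})

test_that("main-colour chi-square tests uniformity over observed colours", {
  cols <- rep(c("red", "green", "blue", "rose"), each = 10)
  grp <- rep("A", 40)
  t0 <- chisq_main_colour(cols, grp)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$df, 3)

  one <- chisq_main_colour(c(rep("red", 40), "green", "blue"),
                           c(rep("A", 40), "B", "B"))
  one <- one[one$group == "A", ]
  expect_equal(one$modal_share, 1)
  expect_lt(one$p_value, 1e-3)
  # all mass on one of the observed categories; df counts the categories
  mixed <- chisq_main_colour(c(rep("red", 40), "green"),
                             rep(c("A", "B"), c(40, 1)))
  expect_lt(mixed$p_value[mixed$group == "A"], 1e-3)

  set.seed(109)
  w <- c(0.4, rep(0.6 / 11, 11))
  draws <- sample(c("red", paste0("c", 1:11)), 200, TRUE, prob = w)
  t2 <- chisq_main_colour(draws, rep("A", 200))
  expect_equal(t2$modal_colour, "red")
  expect_equal(t2$modal_share, 0.4, tolerance = 0.3)
  expect_lt(t2$p_value, 0.001)
})
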