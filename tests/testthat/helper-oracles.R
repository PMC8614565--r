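# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths: plain R loops and textbook formulas.

# Per-cell pixel tally by looping over the 100 cells and slicing the label
# matrix directly (pixel centre -> cell under the half-open mm convention).
oracle_cell_tally <- function(labels, px_per_mm, sheet_w = 272, sheet_h = 242,
                              rows = 10, cols = 10) {
  H <- nrow(labels); W <- ncol(labels)
  x_mm <- (seq_len(W) - 0.5) / px_per_mm
  y_mm <- (seq_len(H) - 0.5) / px_per_mm
  cell_of_x <- pmin(floor(x_mm / (sheet_w / cols)), cols - 1)
  cell_of_y <- pmin(floor(y_mm / (sheet_h / rows)), rows - 1)
  out <- data.frame(row = integer(0), col = integer(0), marked = integer(0),
                    total = integer(0), n_colours = integer(0))
  for (r in 0:(rows - 1)) {
    for (cc in 0:(cols - 1)) {
      block <- labels[cell_of_y == r, cell_of_x == cc, drop = FALSE]
      out <- rbind(out, data.frame(
        row = r + 1L, col = cc + 1L,
        marked = sum(block > 0), total = length(block),
        n_colours = length(unique(block[block > 0]))))
    }
  }
  out
}

# Coverage / overlap / solid-colour rates recomputed from the oracle tally.
oracle_rates <- function(tal) {
  covered <- tal$marked > 0
  list(coverage = mean(covered),
       overlap = if (!any(covered)) 0 else
         100 * sum(tal$n_colours >= 2) / sum(covered),
       solid = mean(tal$marked / tal$total >= 0.5))
}

# All-pairs segment intersection scan, scalar arithmetic, no shortcuts.
oracle_self_intersections <- function(p) {
  n <- nrow(p) - 1
  hits <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      a <- p[i, ]; b <- p[i + 1, ]; cc <- p[j, ]; d <- p[j + 1, ]
      r1 <- b - a; r2 <- d - cc
      den <- r1[1] * r2[2] - r1[2] * r2[1]
      if (abs(den) < 1e-12) next
      q <- cc - a
      t <- (q[1] * r2[2] - q[2] * r2[1]) / den
      u <- (q[1] * r1[2] - q[2] * r1[1]) / den
      if (t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9)
        hits <- rbind(hits, c(i, j, t, u))
    }
  }
  hits
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Minimum-area enclosing ellipse centre via Khachiyan's barycentric
# iteration (independent of cluster::ellipsoidhull).
oracle_mvee_centre <- function(P, tol = 1e-5, max_iter = 20000) {
  n <- nrow(P)
  Q <- t(cbind(P, 1))
  u <- rep(1 / n, n)
  ctr <- as.numeric(t(P) %*% u)
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))
    j <- which.max(M)
    step <- (M[j] - 3) / (3 * (M[j] - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
    new_ctr <- as.numeric(t(P) %*% u)
    if (it %% 50 == 0) {
      if (sqrt(sum((new_ctr - ctr)^2)) < tol) { ctr <- new_ctr; break }
      ctr <- new_ctr
    }
  }
  as.numeric(t(P) %*% u)
}

# Angle-scan over raw polyline vertices (no resampling): interior angles.
oracle_vertex_turns <- function(p) {
  n <- nrow(p)
  out <- numeric(0)
  for (i in 2:(n - 1)) {
    a <- p[i, ] - p[i - 1, ]
    b <- p[i + 1, ] - p[i, ]
    out <- c(out, atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)) * 180 / pi)
  }
  out
}

# A tiny in-memory drawing around a given stroke list.
wrap_drawing <- function(strokes, sheet = apedraw::sheet()) {
  structure(list(strokes = strokes, sheet = sheet,
                 meta = list(drawing_id = "t", individual = "T",
                             date = as.Date("2007-06-15"),
                             season = "summer", period = 6L)),
            class = "vector_drawing")
}

empty_drawing <- function() wrap_drawing(list())

# Deterministic single-stroke drawing helpers
dot_stroke <- function(x, y, colour_id = 1, width_mm = 3, pressure = 1) {
  stroke_path(rbind(c(x, y), c(x + 0.4, y)), colour_id, width_mm, pressure)
}

hline_stroke <- function(y, x0 = 20, x1 = 250, colour_id = 1, width_mm = 4,
                         pressure = 1) {
  stroke_path(rbind(c(x0, y), c(x1, y)), colour_id, width_mm, pressure)
}
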