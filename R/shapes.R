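#' Turning angles along a resampled stroke
#'
#' Resamples a stroke polyline at uniform arc-length spacing and returns
#' the signed turning angle (degrees, positive = left turn in the
#' y-down sheet frame, in (-180, 180]) at every interior vertex. Uniform
#' resampling makes the angles comparable between strokes digitized at
#' different densities and filters vertex-level noise below the resampling
#' scale. Resampled segments shorter than a quarter of the spacing (which
#' arise when a sample lands almost exactly on a sharp reversal) are merged
#' into their neighbour before angles are measured.
#'
#' @param path a [stroke_path()] or an n x 2 point matrix (mm).
#' @param resample_mm arc-length spacing (default 2 mm).
#' @return numeric vector of turning angles (degrees); empty if the
#'   resampled path has fewer than 3 vertices.
#' @export
turning_angles <- function(path, resample_mm = 2) {
  p <- resample_path(path, resample_mm)
  path_turns(p)
}

resample_path <- function(path, resample_mm = 2) {
  p <- if (inherits(path, "stroke_path")) path$points else as.matrix(path)
  if (nrow(p) < 2) stop("degenerate path")
  seg <- sqrt(rowSums(diff(p)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate (zero-length) path")
  s <- c(0, cumsum(seg))
  grid <- seq(0, L, by = resample_mm)
  if (grid[length(grid)] < L) grid <- c(grid, L)
  xi <- stats::approx(s, p[, 1], xout = grid, ties = "ordered")$y
  yi <- stats::approx(s, p[, 2], xout = grid, ties = "ordered")$y
  q <- cbind(xi, yi)
  # merge segments much shorter than the spacing (sample landed on a spike)
  keep <- c(TRUE, sqrt(rowSums(diff(q)^2)) > resample_mm / 4)
  keep[length(keep)] <- TRUE
  q <- q[keep, , drop = FALSE]
  dup <- c(TRUE, rowSums(abs(diff(q))) > 1e-12)
  q[dup, , drop = FALSE]
}

path_turns <- function(q) {
  if (nrow(q) < 3) return(numeric(0))
  d <- diff(q)
  a <- d[-nrow(d), , drop = FALSE]
  b <- d[-1, , drop = FALSE]
  atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1],
        a[, 1] * b[, 1] + a[, 2] * b[, 2]) * 180 / pi
}

# Clusters of consecutive same-sign turning angles, each vertex at least
# `floor_deg`, whose summed turn reaches `total_min`.  A sharp feature of a
# digitized stroke rarely falls on a single resampled vertex; clustering
# makes corner detection independent of where the samples land.
path_events <- function(turns, floor_deg = 30, total_min = 60) {
  events <- list()
  i <- 1
  n <- length(turns)
  while (i <= n) {
    if (abs(turns[i]) >= floor_deg) {
      s <- sign(turns[i])
      j <- i
      while (j < n && abs(turns[j + 1]) >= floor_deg &&
             sign(turns[j + 1]) == s) j <- j + 1
      tot <- sum(turns[i:j])
      if (abs(tot) >= total_min)
        events[[length(events) + 1]] <-
          list(from = i, to = j, total = tot,
               at = i - 1 + which.max(abs(turns[i:j])))
      i <- j + 1
    } else i <- i + 1
  }
  events
}

# Direction reversals: vertices where the cumulative turn over a rolling
# window of up to 3 resampled vertices reaches `thr` degrees; overlapping
# hits merge into one reversal.  The windowed sum captures a reversal even
# when resampling splits it over neighbouring vertices.
reversal_positions <- function(turns, thr) {
  n <- length(turns)
  if (n == 0) return(integer(0))
  tt <- c(0, cumsum(turns))
  w <- min(n, 3)
  roll <- abs(tt[(1 + w):(n + 1)] - tt[1:(n + 1 - w)])
  hit <- which(roll >= thr)
  if (!length(hit)) return(integer(0))
  runs <- split(hit, cumsum(c(1, diff(hit) > 3)))
  vapply(runs, function(r) r[1] + 1L, 1L)
}

#' Count fan round trips and detect fan patterns
#'
#' A fan pattern is a stroke making at least three out-and-back passes
#' ("round trips") whose legs subtend at most `max_fan_angle` degrees. A
#' direction reversal is a point where the stroke turns by at least
#' `180 - max_fan_angle` degrees (measured over a short rolling window of
#' resampled vertices, so the reversal is found wherever the samples
#' land); `r` reversal points delimit `floor((r + 1) / 2)` out-and-back
#' passes.
#'
#' @inheritParams turning_angles
#' @param max_fan_angle maximal angle (degrees) subtended by the legs of a
#'   pass (default 45).
#' @return `count_fan_round_trips()`: integer number of passes;
#'   `detect_fan()`: logical.
#' @export
count_fan_round_trips <- function(path, max_fan_angle = 45,
                                  resample_mm = 2) {
  turns <- turning_angles(path, resample_mm)
  r <- length(reversal_positions(turns, 180 - max_fan_angle))
  if (r == 0) return(0L)
  as.integer((r + 1) %/% 2)
}

#' @rdname count_fan_round_trips
#' @export
detect_fan <- function(path, max_fan_angle = 45, resample_mm = 2) {
  count_fan_round_trips(path, max_fan_angle, resample_mm) >= 3
}

#' Self-intersections of a stroke
#'
#' All transverse crossings between non-adjacent segments of the stroke
#' polyline, each with the positions (segment index + interpolation
#' parameter) on both branches and the incidence angle between them.
#' Endpoint touches are excluded: a stroke revisiting a vertex exactly (as
#' an ideal fan does at its apex) does not cross itself there.
#'
#' @param path a [stroke_path()] or point matrix.
#' @return data frame with columns `seg_i`, `seg_j`, `t_i`, `t_j`,
#'   `angle` (degrees, 0 to 90); zero rows if the stroke never crosses
#'   itself.
#' @export
self_intersections <- function(path) {
  p <- if (inherits(path, "stroke_path")) path$points else as.matrix(path)
  m <- seg_intersections_cpp(p)
  as.data.frame(m)
}

#' Classify a closed stroke as circle, loop or triangle
#'
#' Follows the geometric definitions used for ape scribbles: the stroke
#' must close on itself (at least one self-intersection, or end within
#' `gap_mm` of its start); corners are resampled vertices turning at least
#' `corner_angle_min` degrees. No corner gives a *circle*, exactly one a
#' *loop*, three or more corners joined by near-straight sides a
#' *triangle*; anything else (open arcs, two-corner or wiggly-sided closed
#' strokes) is `"none"`.
#'
#' @inheritParams turning_angles
#' @param corner_angle_min minimal turning angle of a "distinct angle"
#'   (default 60 degrees).
#' @param gap_mm endpoint-closure tolerance (default 3 mm).
#' @param max_side_turn maximal turning angle tolerated inside a triangle
#'   side before it stops counting as straight (default 35 degrees).
#' @return one of `"circle"`, `"loop"`, `"triangle"`, `"none"`.
#' @export
classify_closed <- function(path, corner_angle_min = 60, gap_mm = 3,
                            resample_mm = 2, max_side_turn = 35) {
  p <- if (inherits(path, "stroke_path")) path$points else as.matrix(path)
  cross <- seg_intersections_cpp(p)
  gap <- sqrt(sum((p[1, ] - p[nrow(p), ])^2))
  if (nrow(cross) == 0 && gap > gap_mm) return("none")
  turns <- turning_angles(p, resample_mm)
  ev <- path_events(turns, floor_deg = 30, total_min = corner_angle_min)
  if (length(ev) == 0) return("circle")
  if (length(ev) == 1) return("loop")
  if (length(ev) >= 3) {
    # between corners the path must stay near-straight
    inside <- unlist(lapply(ev, function(e) e$from:e$to))
    side <- setdiff(seq_along(turns), inside)
    if (all(abs(turns[side]) <= max_side_turn)) return("triangle")
  }
  "none"
}

#' Count the shapes of a drawing
#'
#' Classifies every stroke of a vector drawing and aggregates the four
#' shape counts. Different strokes of one drawing contribute
#' independently, so a drawing can hold fans and circles at once; within a
#' single stroke, however, the fan class takes precedence over the closed
#' classes: a hand-drawn zigzag grazes itself along its legs, producing
#' dozens of incidental self-intersections that would otherwise read as
#' closed shapes.
#'
#' @param drawing a `vector_drawing`.
#' @param config list of thresholds: `max_fan_angle`, `corner_angle_min`,
#'   `gap_mm`, `resample_mm`, `max_side_turn`.
#' @return named integer vector `c(fan, circle, triangle, loop)`.
#' @export
count_shapes <- function(drawing, config = list()) {
  cfg <- utils::modifyList(
    list(max_fan_angle = 45, corner_angle_min = 60, gap_mm = 3,
         resample_mm = 2, max_side_turn = 35), config)
  counts <- c(fan = 0L, circle = 0L, triangle = 0L, loop = 0L)
  for (s in drawing$strokes) {
    if (detect_fan(s, cfg$max_fan_angle, cfg$resample_mm)) {
      counts[["fan"]] <- counts[["fan"]] + 1L
      next
    }
    closed <- classify_closed(s, cfg$corner_angle_min, cfg$gap_mm,
                              cfg$resample_mm, cfg$max_side_turn)
    if (closed != "none")
      counts[[closed]] <- counts[[closed]] + 1L
  }
  counts
}
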