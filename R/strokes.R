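#' Stroke polylines
#'
#' A stroke is an ordered polyline on the sheet with a crayon colour, a
#' physical width and a pressure. Pressure is modelled as opacity over
#' white paper: a mark at pressure p renders as `p * colour + (1-p) * white`,
#' so light pressure gives a pale mark.
#'
#' @param points a numeric matrix with two columns (x_mm, y_mm), at least
#'   two rows, consecutive points distinct.
#' @param colour_id palette index in 1..16.
#' @param width_mm stroke width (crayon contact width) in mm.
#' @param pressure fraction in (0, 1]; 1 is a fully saturated mark.
#' @param sheet the [sheet()] the stroke must fit on.
#' @return An object of class `stroke_path`.
#' @export
stroke_path <- function(points, colour_id, width_mm = 4, pressure = 1,
                        sheet = apedraw::sheet()) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2) stop("a stroke needs at least 2 points")
  dup <- rowSums(abs(diff(points))) == 0
  if (any(dup)) points <- points[c(TRUE, !dup), , drop = FALSE]
  if (nrow(points) < 2) stop("a stroke needs at least 2 distinct points")
  if (any(points[, 1] < 0) || any(points[, 1] > sheet$width_mm) ||
      any(points[, 2] < 0) || any(points[, 2] > sheet$height_mm))
    stop("stroke leaves the sheet bounds")
  if (!(colour_id %in% 1:16)) stop("colour_id must be in 1..16")
  if (pressure <= 0 || pressure > 1) stop("pressure must be in (0, 1]")
  structure(list(points = unname(points), colour_id = as.integer(colour_id),
                 width_mm = width_mm, pressure = pressure),
            class = "stroke_path")
}

#' @export
print.stroke_path <- function(x, ...) {
  cat(sprintf("stroke: %d points, colour %d, width %.1f mm, pressure %.2f\n",
              nrow(x$points), x$colour_id, x$width_mm, x$pressure))
  invisible(x)
}

path_length <- function(points) sum(sqrt(rowSums(diff(points)^2)))

# Subdivide a polyline so no segment exceeds `step` mm.
densify <- function(points, step = 2) {
  out <- list(points[1, , drop = FALSE])
  for (i in seq_len(nrow(points) - 1)) {
    a <- points[i, ]; b <- points[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step))
    t <- seq_len(k) / k
    out[[i + 1]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

# Smooth hand-tremor perturbation: a low-frequency sinusoid applied
# perpendicular to the local direction, plus mild white noise. Amplitude 0
# returns the path untouched.
apply_jitter <- function(points, amplitude_mm, wavelength_mm = 40) {
  if (amplitude_mm <= 0 || nrow(points) < 3) return(points)
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  phase <- runif(1, 0, 2 * pi)
  off <- amplitude_mm * sin(2 * pi * s / wavelength_mm + phase) +
    rnorm(length(s), sd = amplitude_mm / 5)
  # perpendicular direction at each vertex (neighbour-averaged tangent)
  d <- diff(points)
  tang <- rbind(d[1, , drop = FALSE], (d[-1, , drop = FALSE] +
                                         d[-nrow(d), , drop = FALSE]) / 2,
                d[nrow(d), , drop = FALSE])
  nrm <- sqrt(rowSums(tang^2)); nrm[nrm == 0] <- 1
  perp <- cbind(-tang[, 2], tang[, 1]) / nrm
  points + off * perp
}

clamp_to_sheet <- function(points, sheet, margin = 0.5) {
  points[, 1] <- pmin(pmax(points[, 1], margin), sheet$width_mm - margin)
  points[, 2] <- pmin(pmax(points[, 2], margin), sheet$height_mm - margin)
  points
}

#' Construct a fan-pattern stroke
#'
#' A fan pattern is a single stroke making repeated out-and-back passes
#' ("round trips") from an apex, the successive legs subtending at most
#' `spread_angle` degrees. The constructed polyline visits
#' `apex, tip1, apex, tip2, ..., tip_k, apex`, so it has `2k - 1` interior
#' direction-reversal vertices for `k` round trips.
#'
#' @param anchor apex position `c(x_mm, y_mm)`; must lie on the sheet.
#' @param leg_length_mm length of each pass.
#' @param round_trips number of out-and-back passes (>= 1).
#' @param spread_angle_deg total angular spread of the passes (<= 45).
#' @param direction_deg centre direction of the fan; `NULL` draws one
#'   uniformly from the current RNG stream.
#' @param jitter_mm smooth tremor amplitude (0 = geometric construction).
#' @param colour_id,width_mm,pressure,sheet stroke attributes.
#' @return a [stroke_path()].
#' @export
make_fan_stroke <- function(anchor, leg_length_mm = 60, round_trips = 3,
                            spread_angle_deg = 30, direction_deg = NULL,
                            jitter_mm = 0, colour_id = 1, width_mm = 4,
                            pressure = 1, sheet = apedraw::sheet()) {
  stopifnot(round_trips >= 1, leg_length_mm > 0, spread_angle_deg <= 45)
  if (anchor[1] < 0 || anchor[1] > sheet$width_mm ||
      anchor[2] < 0 || anchor[2] > sheet$height_mm)
    stop("invalid geometry: fan anchor outside the sheet")
  if (is.null(direction_deg)) direction_deg <- runif(1, 0, 360)
  k <- as.integer(round_trips)
  th0 <- direction_deg * pi / 180
  sp <- spread_angle_deg * pi / 180
  th <- if (k == 1) th0 else th0 + seq(-sp / 2, sp / 2, length.out = k)
  # shrink legs so every tip stays on the sheet
  for (i in seq_len(k)) {
    tip <- anchor + leg_length_mm * c(cos(th[i]), sin(th[i]))
    fr <- 1
    if (tip[1] < 1 || tip[1] > sheet$width_mm - 1)
      fr <- min(fr, abs((ifelse(tip[1] < 1, 1, sheet$width_mm - 1) - anchor[1]) /
                          (tip[1] - anchor[1])))
    if (tip[2] < 1 || tip[2] > sheet$height_mm - 1)
      fr <- min(fr, abs((ifelse(tip[2] < 1, 1, sheet$height_mm - 1) - anchor[2]) /
                          (tip[2] - anchor[2])))
    leg_length_mm <- min(leg_length_mm, max(5, fr * leg_length_mm))
  }
  pts <- matrix(anchor, 1, 2)
  for (i in seq_len(k)) {
    tip <- anchor + leg_length_mm * c(cos(th[i]), sin(th[i]))
    pts <- rbind(pts, tip, anchor)
  }
  pts <- densify(pts, 2)
  pts <- clamp_to_sheet(apply_jitter(pts, jitter_mm), sheet)
  stroke_path(pts, colour_id, width_mm, pressure, sheet)
}

#' Construct a closed-shape stroke (circle, loop or triangle)
#'
#' Builds a stroke realizing one of the three closed shape classes used in
#' drawing analysis: a *circle* is a curved stroke whose ends cross without
#' any distinct corner (drawn as a slightly spiralling arc overshooting a
#' full turn); a *loop* is a curved self-intersecting stroke with exactly
#' one distinct corner (a straight lead-in leg joined at a sharp angle to a
#' near-circular arc that returns across the leg); a *triangle* is a closed
#' flat path of three near-straight sides and three corners.
#'
#' @param kind one of `"circle"`, `"loop"`, `"triangle"`.
#' @param anchor shape centre `c(x_mm, y_mm)`.
#' @param size_mm approximate shape diameter.
#' @param rotation_deg orientation; `NULL` draws one uniformly from the
#'   current RNG stream.
#' @inheritParams make_fan_stroke
#' @return a [stroke_path()].
#' @export
make_closed_shape <- function(kind, anchor, size_mm = 40, rotation_deg = NULL,
                              jitter_mm = 0, colour_id = 1, width_mm = 4,
                              pressure = 1, sheet = apedraw::sheet()) {
  kind <- match.arg(kind, c("circle", "loop", "triangle"))
  if (is.null(rotation_deg)) rotation_deg <- runif(1, 0, 360)
  rot <- rotation_deg * pi / 180
  R <- size_mm / 2
  if (kind == "circle") {
    # exact closed circle: the stroke ends where it began, well within the
    # endpoint-closure tolerance, and carries no corner anywhere
    th <- seq(0, 2 * pi, by = 2 / R)
    if (th[length(th)] < 2 * pi) th <- c(th, 2 * pi)
    pts <- cbind(anchor[1] + R * cos(th + rot), anchor[2] + R * sin(th + rot))
  } else if (kind == "loop") {
    # straight lead-in leg to a sharp corner (105 degree turn) at C, a short
    # stub, then a gentle circular arc swinging back across the leg; the
    # corner angle and the arc curvature are decoupled so the single
    # distinct angle survives resampling at any shape size
    L <- 0.9 * size_mm
    u <- c(cos(rot), sin(rot))
    S <- anchor - 0.5 * L * u
    C <- S + L * u
    d0 <- rot + 105 * pi / 180
    C2 <- C + 4 * c(cos(d0), sin(d0))
    rho <- 0.42 * size_mm
    ctr <- C2 + rho * c(cos(d0 + pi / 2), sin(d0 + pi / 2))
    a0 <- atan2(C2[2] - ctr[2], C2[1] - ctr[1])
    th <- seq(0, 300 * pi / 180, by = 2 / rho)
    arc <- cbind(ctr[1] + rho * cos(a0 + th), ctr[2] + rho * sin(a0 + th))
    pts <- rbind(S, C, C2, arc[-1, ])
  } else {
    # closed triangle traversed from the midpoint of one side
    ang <- rot + c(0, 2 * pi / 3, 4 * pi / 3) + runif(1, -0.15, 0.15)
    V <- cbind(anchor[1] + R * cos(ang), anchor[2] + R * sin(ang))
    M <- (V[1, ] + V[2, ]) / 2
    pts <- rbind(M, V[2, ], V[3, ], V[1, ], M)
  }
  pts <- densify(pts, 2)
  pts <- clamp_to_sheet(apply_jitter(pts, jitter_mm), sheet)
  stroke_path(pts, colour_id, width_mm, pressure, sheet)
}

# A smooth meandering stroke with no planted shape: a random open curve
# obtained by integrating a slowly varying heading.
make_meander_stroke <- function(anchor, length_mm = 80, wander = 0.25,
                                jitter_mm = 0, colour_id = 1, width_mm = 4,
                                pressure = 1, sheet = apedraw::sheet()) {
  n <- max(3L, ceiling(length_mm / 2))
  heading <- runif(1, 0, 2 * pi) + cumsum(rnorm(n, sd = wander))
  step <- length_mm / n
  pts <- cbind(anchor[1] + c(0, cumsum(step * cos(heading))),
               anchor[2] + c(0, cumsum(step * sin(heading))))
  pts <- clamp_to_sheet(apply_jitter(pts, jitter_mm), sheet)
  pts <- pts[rowSums(abs(diff(rbind(pts[1, ] - 1, pts)))) > 1e-9, , drop = FALSE]
  stroke_path(pts, colour_id, width_mm, pressure, sheet)
}

# Rigid motion of a stroke (used by invariance tests and tooling).
transform_stroke <- function(stroke, dx = 0, dy = 0, angle_deg = 0,
                             centre = NULL, sheet = apedraw::sheet()) {
  p <- stroke$points
  if (angle_deg != 0) {
    if (is.null(centre)) centre <- colMeans(p)
    a <- angle_deg * pi / 180
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    p <- sweep(sweep(p, 2, centre) %*% t(rot), 2, centre, `+`)
  }
  p[, 1] <- p[, 1] + dx
  p[, 2] <- p[, 2] + dy
  stroke_path(p, stroke$colour_id, stroke$width_mm, stroke$pressure, sheet)
}
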