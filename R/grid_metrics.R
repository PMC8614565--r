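#' Label each pixel with its crayon colour
#'
#' Assigns every pixel of a raster drawing to the background (paper) or to
#' one of the 16 reference crayons. A pixel within `bg_delta` RGB units of
#' white is background; any other pixel is assigned the crayon whose
#' white-to-colour blend ray passes nearest to the pixel in RGB space.
#' Because crayon marks are rendered (and, physically, appear) as convex
#' blends of a pigment with the white paper, the nearest-ray rule recovers
#' the pigment exactly for a pure mark at any pressure, and degrades
#' gracefully for mixed pixels. Per-pixel luminance is the standard
#' Rec. 601 grey conversion `0.299 R + 0.587 G + 0.114 B`, scaled to the unit interval.
#'
#' @param raster a `raster_drawing` (see [rasterize()], [read_png_drawing()]).
#' @param palette a [crayon_palette()].
#' @param bg_delta background threshold in RGB units (default 30).
#' @return An object of class `label_map`: list with `labels` (integer
#'   matrix, 0 = background, 1-16 = colour id), `luminance` (numeric matrix
#'   in the unit interval), `px_per_mm`, `sheet`.
#' @export
build_label_map <- function(raster, palette = crayon_palette(),
                            bg_delta = 30) {
  if (is.null(raster$r) || is.null(raster$g) || is.null(raster$b))
    stop("raster is not an RGB image")
  out <- label_pixels_full_cpp(raster$r, raster$g, raster$b,
                               palette_rgb(palette), bg_delta)
  structure(list(labels = out$labels, luminance = out$luminance,
                 lum_mean = out$lum_mean, lum_sd = out$lum_sd,
                 row_min = out$row_min, row_max = out$row_max,
                 px_per_mm = raster$px_per_mm, sheet = raster$sheet),
            class = "label_map")
}

#' Summarize a label map over the analysis grid
#'
#' Applies the 10 x 10 (in general `grid_rows` x `grid_cols`) analysis grid
#' to a labelled drawing and tallies each cell: whether it contains any
#' stroke pixel, which colours are present, and the fraction of its pixels
#' covered by strokes. A pixel belongs to the cell containing its centre;
#' cells partition the sheet under the half-open convention.
#'
#' @param labels a `label_map`.
#' @param sheet the [sheet()] (defaults to the one carried by `labels`).
#' @return An object of class `cell_summary`: data frame with one row per
#'   cell and columns `row`, `col`, `covered`, `n_colours`, `colours`
#'   (list), `fraction`.
#' @export
summarize_cells <- function(labels, sheet = labels$sheet) {
  tal <- cell_tally_cpp(labels$labels, sheet$width_mm, sheet$height_mm,
                        labels$px_per_mm, sheet$grid_rows, sheet$grid_cols,
                        FALSE)
  present <- tal$counts[, -1, drop = FALSE] > 0    # drop background column
  out <- data.frame(
    row = rep(seq_len(sheet$grid_rows), each = sheet$grid_cols),
    col = rep(seq_len(sheet$grid_cols), times = sheet$grid_rows),
    covered = tal$marked > 0,
    n_colours = rowSums(present),
    colours = I(apply(present, 1, which, simplify = FALSE)),
    fraction = tal$marked / tal$total)
  attr(out, "label_counts") <- colSums(tal$counts)[-1]   # pixels per crayon
  class(out) <- c("cell_summary", "data.frame")
  out
}

#' Grid-based drawing variables
#'
#' The quantitative per-drawing variables measured on the analysis grid and
#' the label map:
#'
#' * `coverage_rate()`: number of cells containing at least one stroke
#'   pixel, divided by the total number of cells (fraction between 0 and 1).
#' * `overlap_rate()`: percentage of *covered* cells whose pixels carry at
#'   least two different crayon colours (0 when nothing is covered). The
#'   denominator is the covered-cell count, so single-colour drawings score
#'   0 and a two-colour drawing whose colours co-occur everywhere scores 100.
#' * `solid_colour_rate()`: number of cells at least half covered by stroke
#'   pixels, divided by the total number of cells.
#' * `count_colours()`: number of crayons with at least `min_pixels`
#'   labelled pixels.
#' * `main_colour()`: the crayon with the largest labelled-pixel area
#'   (`NA` for an empty drawing; ties broken by lowest colour id).
#' * `colour_spectrum_stats()`: mean and standard deviation of per-pixel
#'   luminance over the whole sheet. A blank sheet gives (1, 0); filling
#'   lowers the mean, strong dark-on-white contrast raises the sd.
#'
#' @param cells a `cell_summary`.
#' @return `coverage_rate`, `solid_colour_rate`: fraction between 0 and 1;
#'   `overlap_rate`: percent between 0 and 100; `count_colours`: integer;
#'   `main_colour`: colour id or `NA`; `colour_spectrum_stats`: named
#'   vector `c(mean, sd)`.
#' @export
coverage_rate <- function(cells) {
  mean(cells$covered)
}

#' @rdname coverage_rate
#' @export
overlap_rate <- function(cells) {
  nc <- sum(cells$covered)
  if (nc == 0) return(0)
  100 * sum(cells$n_colours >= 2) / nc
}

#' @rdname coverage_rate
#' @export
solid_colour_rate <- function(cells) {
  mean(cells$fraction >= 0.5)
}

#' @rdname coverage_rate
#' @param labels a `label_map`.
#' @param min_pixels minimum labelled pixels for a colour to count.
#' @export
count_colours <- function(labels, min_pixels = 1) {
  stopifnot(min_pixels >= 1)
  counts <- tabulate(labels$labels[labels$labels > 0], nbins = 16)
  sum(counts >= min_pixels)
}

#' @rdname coverage_rate
#' @export
main_colour <- function(labels) {
  counts <- tabulate(labels$labels[labels$labels > 0], nbins = 16)
  if (sum(counts) == 0) return(NA_integer_)
  which.max(counts)   # ties: lowest colour id
}

#' @rdname coverage_rate
#' @export
colour_spectrum_stats <- function(labels) {
  if (!is.null(labels$lum_mean))
    return(c(mean = labels$lum_mean, sd = labels$lum_sd))
  x <- labels$luminance
  n <- length(x)
  m <- mean(x)
  # population sd (the spectrum is the full pixel population, not a sample)
  c(mean = m, sd = sqrt(sum((x - m)^2) / n))
}

#' Distance from the marked area to the sheet centre
#'
#' Fits the minimum-area enclosing ellipse of all non-background pixel
#' centres ("an ellipse surrounding the design") and returns the Euclidean
#' distance, in mm, from the ellipse centre to the sheet centre. An empty
#' drawing scores 0 by convention; degenerate mark sets (a single dot, a
#' perfectly straight stroke) use the midpoint of the two most distant
#' marked pixels, the limit of the enclosing ellipse.
#'
#' The ellipse is computed on the convex hull of the marked pixels (the
#' enclosing ellipse of a point set depends only on its hull), via the
#' exact ellipsoid-hull fit of \code{cluster::ellipsoidhull}.
#'
#' @param labels a `label_map`.
#' @param sheet the [sheet()].
#' @return distance in mm (scalar).
#' @export
distance_to_centre <- function(labels, sheet = labels$sheet) {
  ppm <- labels$px_per_mm
  if (!is.null(labels$row_min)) {
    # the hull of the marked pixels equals the hull of each row's extremes
    rows <- which(!is.na(labels$row_min))
    if (length(rows) == 0) return(0)
    px <- (c(labels$row_min[rows], labels$row_max[rows]) - 0.5) / ppm
    py <- (c(rows, rows) - 0.5) / ppm
  } else {
    idx <- which(labels$labels > 0)
    if (length(idx) == 0) return(0)
    H <- nrow(labels$labels)
    px <- ((idx - 1L) %/% H + 0.5) / ppm    # x mm of pixel centre
    py <- ((idx - 1L) %% H + 0.5) / ppm     # y mm
  }
  ctr <- enclosing_ellipse_centre(cbind(px, py))
  sc <- sheet_centre(sheet)
  unname(sqrt((ctr[1] - sc[1])^2 + (ctr[2] - sc[2])^2))
}

enclosing_ellipse_centre <- function(xy) {
  hull <- grDevices::chull(xy)
  h <- xy[hull, , drop = FALSE]
  if (nrow(h) == 1) return(h[1, ])
  # collinear or two-point sets: ellipse degenerates to the longest chord
  if (nrow(h) <= 2 || abs(det(cbind(h[1:3, ] , 1))) < 1e-9) {
    d <- as.matrix(stats::dist(h))
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    return((h[ij[1], ] + h[ij[2], ]) / 2)
  }
  fit <- tryCatch(cluster::ellipsoidhull(h), error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$loc))) {
    d <- as.matrix(stats::dist(h))
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    return((h[ij[1], ] + h[ij[2], ]) / 2)
  }
  fit$loc
}

#' Extract the full metric vector of one drawing
#'
#' Assembles the twelve per-drawing variables: the seven grid/colour
#' variables from the raster, the four shape counts from the vector
#' strokes, and the main colour.
#'
#' @param raster a `raster_drawing`.
#' @param drawing the matching `vector_drawing` (for shape counts); `NULL`
#'   leaves shape counts `NA`.
#' @param palette a [crayon_palette()].
#' @param sheet the [sheet()].
#' @param config list of thresholds: `bg_delta`, `min_pixels`, plus the
#'   shape-classifier settings understood by [count_shapes()].
#' @return a one-row data frame (class `metric_vector`) with columns
#'   `coverage_rate, overlap_rate, n_colours, fan, circle, triangle, loop,
#'   colour_mean, colour_sd, dist_centre_mm, solid_colour_rate, main_colour`.
#' @export
extract_metrics <- function(raster, drawing = NULL,
                            palette = crayon_palette(),
                            sheet = raster$sheet, config = list()) {
  cfg <- utils::modifyList(list(bg_delta = 30, min_pixels = 1), config)
  lab <- build_label_map(raster, palette, cfg$bg_delta)
  cells <- summarize_cells(lab, sheet)
  spec <- colour_spectrum_stats(lab)
  shapes <- if (!is.null(drawing)) {
    count_shapes(drawing, config = cfg)
  } else {
    c(fan = NA_integer_, circle = NA_integer_, triangle = NA_integer_,
      loop = NA_integer_)
  }
  cc <- attr(cells, "label_counts")       # per-crayon pixel counts
  out <- data.frame(
    coverage_rate = coverage_rate(cells),
    overlap_rate = overlap_rate(cells),
    n_colours = sum(cc >= cfg$min_pixels),
    fan = shapes[["fan"]], circle = shapes[["circle"]],
    triangle = shapes[["triangle"]], loop = shapes[["loop"]],
    colour_mean = unname(spec["mean"]), colour_sd = unname(spec["sd"]),
    dist_centre_mm = distance_to_centre(lab, sheet),
    solid_colour_rate = solid_colour_rate(cells),
    main_colour = if (sum(cc) == 0) NA_integer_ else which.max(cc))
  rownames(out) <- NULL
  class(out) <- c("metric_vector", "data.frame")
  out
}

#' Metric names entering the quantitative analysis
#'
#' The eleven quantitative variables (the qualitative main colour is
#' analysed separately by chi-square).
#' @return character vector.
#' @export
quantitative_metrics <- function() {
  c("coverage_rate", "overlap_rate", "n_colours", "fan", "circle",
    "triangle", "loop", "colour_mean", "colour_sd", "dist_centre_mm",
    "solid_colour_rate")
}

#' Compute the metrics table of a dataset
#'
#' Runs [extract_metrics()] over every drawing of a generated (or loaded)
#' dataset and returns the per-drawing metrics table in the standard
#' column order. Drawings flagged in an optional manifest column
#' `damaged` are skipped (torn or stained sheets are not measurable).
#'
#' @param dataset result of [make_dataset()] (needs rasters).
#' @param config thresholds passed to [extract_metrics()].
#' @param progress print a dot every 50 drawings.
#' @return data frame with columns `drawing_id, individual, season, period,
#'   coverage_rate, overlap_rate, n_colours, fan, circle, triangle, loop,
#'   colour_mean, colour_sd, dist_centre_mm, solid_colour_rate, main_colour`.
#' @export
compute_metrics <- function(dataset, config = list(), progress = FALSE) {
  man <- dataset$manifest
  keep <- if ("damaged" %in% names(man)) !man$damaged else rep(TRUE, nrow(man))
  if (any(!keep))
    message(sum(!keep), " damaged drawing(s) excluded from metrics")
  rows <- vector("list", sum(keep))
  j <- 0
  for (i in which(keep)) {
    d <- dataset$drawings[[i]]
    if (is.null(d$raster))
      stop("dataset has no rasters; regenerate with rasterize = TRUE")
    m <- extract_metrics(d$raster, d$drawing, config = config)
    j <- j + 1
    rows[[j]] <- cbind(
      data.frame(drawing_id = man$drawing_id[i],
                 individual = man$individual[i],
                 season = man$season[i], period = man$period[i],
                 stringsAsFactors = FALSE),
      m)
    if (progress && j %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("drawing_id", "individual", "season", "period",
          "coverage_rate", "overlap_rate", "n_colours", "fan", "circle",
          "triangle", "loop", "colour_mean", "colour_sd", "dist_centre_mm",
          "solid_colour_rate", "main_colour")]
}
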