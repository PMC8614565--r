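test_that("an all-white sheet is pure background with blank-sheet statistics", {
  ras <- rasterize(empty_drawing())
  lab <- build_label_map(ras)
  expect_true(all(lab$labels == 0))
  expect_equal(unname(colour_spectrum_stats(lab)), c(1, 0))
  cells <- summarize_cells(lab)
  expect_equal(nrow(cells), 100)
  expect_equal(coverage_rate(cells), 0)
  expect_equal(overlap_rate(cells), 0)
  expect_equal(solid_colour_rate(cells), 0)
  expect_equal(count_colours(lab), 0)
  expect_true(is.na(main_colour(lab)))
  expect_equal(distance_to_centre(lab), 0)
})

test_that("a dot strictly inside one cell covers exactly that cell", {
  # cell (row 5, col 8) spans x in [190.4, 217.6), y in [96.8, 121)
  d <- wrap_drawing(list(dot_stroke(204, 109)))
  lab <- build_label_map(rasterize(d))
  cells <- summarize_cells(lab)
  expect_equal(sum(cells$covered), 1)
  expect_equal(cells[cells$covered, c("row", "col")],
               data.frame(row = 5L, col = 8L), ignore_attr = TRUE)
  expect_equal(coverage_rate(cells), 0.01)
})

test_that("grid rates agree exactly with the brute-force pixel oracle", {
  set.seed(50)
  profs <- default_profiles()
  for (s in 1:6) {
    prof <- profs[[(s - 1) %% 5 + 1]]
    d <- sample_drawing(prof, as.Date("2008-09-01"), seed = 500 + s)
    lab <- build_label_map(d$raster)
    cells <- summarize_cells(lab)
    tal <- oracle_cell_tally(lab$labels, lab$px_per_mm)
    rates <- oracle_rates(tal)
    expect_identical(coverage_rate(cells), rates$coverage)
    expect_identical(overlap_rate(cells), rates$overlap)
    expect_identical(solid_colour_rate(cells), rates$solid)
    expect_equal(cells$fraction, tal$marked / tal$total)
  }
})

test_that("overlap rate follows its covered-cell denominator", {
  # a narrow band over a wide one: both colours show in every covered cell
  d <- wrap_drawing(list(hline_stroke(121, colour_id = 1, width_mm = 8),
                         hline_stroke(121, colour_id = 6, width_mm = 4)))
  cells <- summarize_cells(build_label_map(rasterize(d)))
  expect_equal(overlap_rate(cells), 100)
  # a single-colour drawing scores 0 however much it covers
  d1 <- wrap_drawing(list(hline_stroke(60), hline_stroke(180)))
  expect_equal(overlap_rate(summarize_cells(build_label_map(rasterize(d1)))), 0)
})

test_that("solid colour rate counts only cells at least half covered", {
  # paint one cell fully and another thinly
  full <- stroke_path(rbind(c(30, 36.3), c(50, 36.3)), 2, width_mm = 25)
  thin <- stroke_path(rbind(c(100, 36.3), c(120, 36.3)), 2, width_mm = 2)
  cells <- summarize_cells(build_label_map(rasterize(wrap_drawing(
    list(full, thin)))))
  expect_equal(solid_colour_rate(cells), 0.01)
  expect_gt(coverage_rate(cells), 0.01)
})

test_that("a half-black sheet yields luminance mean .5 and sd .5", {
  ras <- rasterize(empty_drawing())
  ras$r[, 1:272] <- 0L             # ideal black on the left half
  ras$g[, 1:272] <- 0L
  ras$b[, 1:272] <- 0L
  st <- colour_spectrum_stats(build_label_map(ras))
  expect_equal(unname(st["mean"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(st["sd"]), 0.5, tolerance = 1e-9)
})

test_that("luminance statistics match a direct pixel computation", {
  d <- sample_drawing(default_profiles()$Gypsy, as.Date("2008-02-02"),
                      seed = 77)
  ras <- d$raster
  lab <- build_label_map(ras)
  lum <- (0.299 * ras$r + 0.587 * ras$g + 0.114 * ras$b) / 255
  expect_equal(lab$lum_mean, mean(lum), tolerance = 1e-12)
  expect_equal(lab$lum_sd, sqrt(mean((lum - mean(lum))^2)), tolerance = 1e-9)
  expect_equal(lab$luminance, lum, ignore_attr = TRUE)
})

test_that("the colour-spectrum mean decreases as pressure rises", {
  base <- sample_drawing(default_profiles()$Yuki, as.Date("2009-05-05"),
                         seed = 12, rasterize = FALSE)$drawing
  means <- vapply(c(0.4, 0.55, 0.7, 0.85, 1), function(p) {
    d <- base
    d$strokes <- lapply(d$strokes, function(s) { s$pressure <- p; s })
    colour_spectrum_stats(build_label_map(rasterize(d)))[["mean"]]
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("distance to centre is zero for centre-symmetric marks", {
  d <- wrap_drawing(list(dot_stroke(100, 100), dot_stroke(172, 142),
                         dot_stroke(100, 142), dot_stroke(172, 100)))
  lab <- build_label_map(rasterize(d))
  expect_lt(distance_to_centre(lab), 0.5)   # within half a pixel in mm
})

test_that("a single dot's ellipse degenerates to the dot", {
  d <- wrap_drawing(list(dot_stroke(36, 121)))
  lab <- build_label_map(rasterize(d))
  expect_equal(distance_to_centre(lab), 100, tolerance = 0.01)
})

test_that("the ellipse centre matches an independent minimal-ellipse solver", {
  set.seed(60)
  for (s in 1:4) {
    d <- sample_drawing(default_profiles()$Molly, as.Date("2007-10-01"),
                        seed = 600 + s)
    lab <- build_label_map(d$raster)
    idx <- which(lab$labels > 0)
    H <- nrow(lab$labels)
    pts <- cbind(((idx - 1) %/% H + 0.5) / 2, ((idx - 1) %% H + 0.5) / 2)
    hull <- pts[grDevices::chull(pts), ]
    ctr <- oracle_mvee_centre(hull)
    got <- distance_to_centre(lab)
    want <- sqrt(sum((ctr - c(136, 121))^2))
    expect_equal(got, want, tolerance = 0.5)   # 1 px equivalent
  }
})

test_that("distance to centre is translation-covariant", {
  base <- wrap_drawing(list(
    make_closed_shape("circle", c(90, 90), 30, rotation_deg = 0),
    dot_stroke(120, 70)))
  lab0 <- build_label_map(rasterize(base))
  c0 <- apedraw:::enclosing_ellipse_centre(local({
    rows <- which(!is.na(lab0$row_min))
    cbind((c(lab0$row_min[rows], lab0$row_max[rows]) - 0.5) / 2,
          (c(rows, rows) - 0.5) / 2)
  }))
  for (shift in list(c(30, 0), c(0, 40), c(25, 35))) {
    moved <- base
    moved$strokes <- lapply(base$strokes, transform_stroke,
                            dx = shift[1], dy = shift[2])
    labs <- build_label_map(rasterize(moved))
    cs <- apedraw:::enclosing_ellipse_centre(local({
      rows <- which(!is.na(labs$row_min))
      cbind((c(labs$row_min[rows], labs$row_max[rows]) - 0.5) / 2,
            (c(rows, rows) - 0.5) / 2)
    }))
    expect_equal(unname(cs - c0), shift, tolerance = 0.6)
  }
})

test_that("extract_metrics keeps its internal consistency invariants", {
  set.seed(70)
  profs <- default_profiles()
  for (s in 1:10) {
    d <- sample_drawing(profs[[(s - 1) %% 5 + 1]], as.Date("2008-03-03"),
                        seed = 700 + s)
    m <- extract_metrics(d$raster, d$drawing)
    expect_lte(m$solid_colour_rate, m$coverage_rate)
    if (m$n_colours <= 1) expect_equal(m$overlap_rate, 0)
    expect_lte(m$dist_centre_mm, sqrt(272^2 + 242^2) / 2)
    expect_true(all(unlist(m[, c("fan", "circle", "triangle", "loop")]) >= 0))
  }
})
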