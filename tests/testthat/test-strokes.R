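test_that("stroke paths validate their geometry", {
  expect_error(stroke_path(rbind(c(1, 1)), 1), "at least 2")
  expect_error(stroke_path(rbind(c(-5, 1), c(10, 10)), 1), "bounds")
  expect_error(stroke_path(rbind(c(1, 1), c(2, 2)), 17), "colour_id")
  expect_error(stroke_path(rbind(c(1, 1), c(2, 2)), 1, pressure = 0), "pressure")
  # consecutive duplicated points are dropped silently
  s <- stroke_path(rbind(c(1, 1), c(1, 1), c(5, 5)), 1)
  expect_equal(nrow(s$points), 2)
})

test_that("fan strokes carry the constructed reversal structure", {
  a <- c(100, 100)
  f3 <- make_fan_stroke(a, 60, round_trips = 3, spread_angle_deg = 30,
                        direction_deg = 20)
  # 2k - 1 = 5 sharp reversals survive densification: scan raw vertex turns
  raw <- oracle_vertex_turns(f3$points)
  expect_equal(sum(abs(raw) >= 135), 5)
  expect_true(detect_fan(f3))
  expect_equal(count_fan_round_trips(f3), 3L)

  f1 <- make_fan_stroke(a, 60, round_trips = 1, direction_deg = 50)
  expect_false(detect_fan(f1))

  f4 <- make_fan_stroke(a, 55, round_trips = 4, spread_angle_deg = 45,
                        direction_deg = 290)
  expect_equal(count_fan_round_trips(f4), 4L)
  expect_error(make_fan_stroke(c(-10, 50), 40), "invalid geometry")
})

test_that("closed-shape strokes round-trip through the classifier", {
  set.seed(31)
  for (i in 1:10) {
    anc <- c(runif(1, 70, 200), runif(1, 70, 170))
    expect_equal(classify_closed(make_closed_shape("circle", anc, 40)),
                 "circle")
    expect_equal(classify_closed(make_closed_shape("loop", anc, 40)), "loop")
    expect_equal(classify_closed(make_closed_shape("triangle", anc, 40)),
                 "triangle")
  }
  expect_error(make_closed_shape("square", c(100, 100), 40))
})

test_that("a constructed triangle has exactly three sharp vertices", {
  tr <- make_closed_shape("triangle", c(120, 120), 45, rotation_deg = 10)
  raw <- oracle_vertex_turns(tr$points)
  expect_equal(sum(abs(raw) >= 60), 3)
})

test_that("a constructed loop crosses itself exactly once", {
  set.seed(5)
  for (i in 1:8) {
    lp <- make_closed_shape("loop", c(runif(1, 80, 190), runif(1, 80, 160)),
                            runif(1, 25, 55))
    hits <- oracle_self_intersections(lp$points)
    expect_equal(nrow(hits), 1)
  }
})

test_that("open arcs classify as none", {
  th <- seq(0, pi, length.out = 40)
  arc <- stroke_path(cbind(120 + 40 * cos(th), 120 + 40 * sin(th)), 1)
  expect_equal(classify_closed(arc), "none")
  expect_false(detect_fan(arc))
})

test_that("drawing sampling is deterministic and honours degenerate profiles", {
  prof <- default_profiles()$Yuki
  d1 <- sample_drawing(prof, as.Date("2008-05-10"), seed = 99,
                       rasterize = FALSE)
  d2 <- sample_drawing(prof, as.Date("2008-05-10"), seed = 99,
                       rasterize = FALSE)
  expect_identical(d1$drawing, d2$drawing)
  expect_identical(d1$truth$planted, d2$truth$planted)

  empty_prof <- style_profile("none", strokes_mean = 0,
                              shape_rates = c(fan = 0, circle = 0,
                                              triangle = 0, loop = 0))
  e <- sample_drawing(empty_prof, as.Date("2008-05-10"), seed = 1)
  expect_equal(length(e$drawing$strokes), 0)
  expect_equal(nrow(e$truth$planted), 0)
  m <- extract_metrics(e$raster, e$drawing)
  expect_equal(m$coverage_rate, 0)

  onehot <- style_profile("red", strokes_mean = 5,
                          colour_weights = c(1, rep(0, 15)))
  r <- sample_drawing(onehot, as.Date("2008-05-10"), seed = 7,
                      rasterize = FALSE)
  expect_equal(r$truth$colours, 1L)
})

test_that("planted shape counts in ground truth match the stroke list", {
  set.seed(8)
  prof <- default_profiles()$Molly
  for (s in c(11, 23, 35)) {
    d <- sample_drawing(prof, as.Date("2007-02-10"), seed = s,
                        rasterize = FALSE)
    tr <- d$truth
    cnt <- table(factor(tr$planted$kind, levels = names(tr$shape_counts)))
    expect_equal(as.integer(tr$shape_counts), as.integer(cnt))
    expect_true(all(tr$planted$stroke <= length(d$drawing$strokes)))
  }
})
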