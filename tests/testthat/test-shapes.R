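test_that("turning angles behave on canonical paths", {
  line <- cbind(seq(10, 100, by = 1), 50)
  expect_true(all(abs(turning_angles(line)) < 1e-9))
  square <- rbind(c(50, 50), c(90, 50), c(90, 90), c(50, 90))
  turns <- turning_angles(square)
  expect_equal(sum(abs(abs(turns) - 90) < 1e-6), 2)  # two interior corners
  expect_error(turning_angles(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("fan reversal vertices turn by at least 180 minus the spread", {
  f <- make_fan_stroke(c(136, 121), 60, round_trips = 4,
                       spread_angle_deg = 30, direction_deg = 10)
  turns <- turning_angles(f)
  expect_equal(sum(abs(turns) >= 150), 7)   # 2k - 1 reversals
})

test_that("a hand-counted zigzag with 7 reversals gives 4 round trips", {
  a <- c(136, 121)
  zig <- a
  for (i in 1:4) {
    ang <- (i - 1) * 10 * pi / 180
    zig <- rbind(zig, a + 60 * c(cos(ang), sin(ang)), a)
  }
  s <- stroke_path(zig, 1)   # 4 out-and-back passes: 7 interior reversals
  expect_equal(count_fan_round_trips(s), 4L)
  expect_true(detect_fan(s))
})

test_that("circles produce no fan reversals", {
  circ <- make_closed_shape("circle", c(136, 121), 50, rotation_deg = 0)
  expect_false(detect_fan(circ))
  expect_equal(count_fan_round_trips(circ), 0L)
})

test_that("self-intersections match the all-pairs brute-force oracle", {
  line <- cbind(seq(10, 100, by = 2), 30)
  expect_equal(nrow(self_intersections(line)), 0)
  eight <- rbind(c(50, 50), c(100, 100), c(100, 50), c(50, 100), c(50, 50))
  expect_equal(nrow(self_intersections(eight)), 1)

  set.seed(123)
  n_mismatch <- 0
  for (rep in 1:1000) {
    nv <- sample(4:50, 1)
    p <- cbind(cumsum(rnorm(nv, sd = 8)) + 136,
               cumsum(rnorm(nv, sd = 8)) + 121)
    got <- self_intersections(p)
    want <- oracle_self_intersections(p)
    nw <- if (is.null(want)) 0 else nrow(want)
    if (nrow(got) != nw) n_mismatch <- n_mismatch + 1
    else if (nw > 0 &&
             !isTRUE(all.equal(as.matrix(got[, 1:4]), want,
                               check.attributes = FALSE, tolerance = 1e-9)))
      n_mismatch <- n_mismatch + 1
  }
  expect_equal(n_mismatch, 0)
})

test_that("crossing incidence angles are reported in degrees 0..90", {
  cross <- self_intersections(rbind(c(0, 50), c(100, 50), c(50, 0),
                                    c(50, 100)) + 50)
  expect_equal(nrow(cross), 1)
  expect_equal(cross$angle, 90, tolerance = 1e-9)
  obl <- self_intersections(rbind(c(0, 0), c(100, 100), c(100, 0),
                                  c(0, 30)) + 60)
  expect_true(all(obl$angle >= 0 & obl$angle <= 90))
})

test_that("shape counts are invariant under rigid motions", {
  set.seed(33)
  strokes <- list(
    make_fan_stroke(c(110, 110), 45, 3, 35, direction_deg = 70,
                    jitter_mm = 0.5),
    make_closed_shape("loop", c(170, 140), 35, rotation_deg = 120,
                      jitter_mm = 0.5),
    make_closed_shape("triangle", c(90, 170), 40, rotation_deg = 10,
                      jitter_mm = 0.5))
  base <- count_shapes(wrap_drawing(strokes))
  expect_equal(unname(base), c(1L, 0L, 1L, 1L))
  for (tr in list(c(20, 10, 30), c(-25, 15, 115), c(5, -20, 250))) {
    moved <- lapply(strokes, transform_stroke, dx = tr[1], dy = tr[2],
                    angle_deg = tr[3], centre = c(136, 121))
    expect_equal(count_shapes(wrap_drawing(moved)), base)
  }
})

test_that("planted shapes keep their class across a 4x size range", {
  set.seed(34)
  for (sc in c(0.5, 1, 2)) {
    expect_equal(classify_closed(make_closed_shape("circle", c(136, 121),
                                                   40 * sc)), "circle")
    expect_equal(classify_closed(make_closed_shape("loop", c(136, 121),
                                                   36 * sc)), "loop")
    expect_equal(classify_closed(make_closed_shape("triangle", c(136, 121),
                                                   40 * sc)), "triangle")
    f <- make_fan_stroke(c(136, 121), 50 * sc, 3, 30)
    expect_true(detect_fan(f))
  }
})

test_that("per-drawing counts aggregate stroke classes", {
  expect_equal(unname(count_shapes(empty_drawing())), c(0L, 0L, 0L, 0L))
  d <- wrap_drawing(list(
    make_fan_stroke(c(80, 80), 50, 3, 30, direction_deg = 20),
    make_fan_stroke(c(190, 160), 45, 4, 40, direction_deg = 200),
    make_closed_shape("circle", c(140, 190), 35, rotation_deg = 0)))
  expect_equal(unname(count_shapes(d)), c(2L, 1L, 0L, 0L))
})
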