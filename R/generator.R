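#' Style profile of a drawing individual
#'
#' A style profile collects the distributional parameters from which
#' synthetic drawings of one individual are sampled: how many strokes a
#' drawing has, which crayons the individual prefers, how hard they press,
#' which shapes they produce and how the drawing spreads over the sheet.
#' Optional temporal terms let an individual's filling behaviour drift
#' across 3-month periods and differ between seasons.
#'
#' The per-drawing generative model is hierarchical: a latent filling
#' intensity `F = exp(N(0, fill_sd) + trend * (period - 10) + season)`
#' multiplies the expected meander-stroke count, a latent shape propensity
#' multiplies the shape rates, and a dominant crayon drawn from
#' `colour_weights` claims most of the strokes while a Poisson number of
#' accent crayons add colour diversity.
#'
#' @param individual individual identifier (unique within a dataset).
#' @param strokes_mean expected number of plain (meander) strokes.
#' @param stroke_len_mm mean meander stroke length.
#' @param colour_weights numeric vector of length 16, nonnegative, summing
#'   to 1: probability that a crayon is the drawing's dominant colour.
#' @param colours_mean expected number of *extra* (accent) colours beyond
#'   the dominant one.
#' @param pressure_mean,pressure_sd mean and spread of crayon pressure;
#'   pressures are truncated to `[0.35, 1]` (fainter marks are treated as
#'   not reliably attributable).
#' @param shape_rates named numeric: expected `fan`, `circle`, `triangle`,
#'   `loop` counts per drawing.
#' @param spread_mm sd of stroke anchors around the sheet centre (mm).
#' @param fill_sd,shape_sd lognormal sd of the per-drawing filling and
#'   shape-propensity latents.
#' @param trend per-period log-linear drift of filling (0 = stationary).
#' @param season_effect named numeric of log offsets for
#'   `winter, spring, summer, autumn` (default all 0).
#' @param jitter_mm smooth hand-tremor amplitude applied to every stroke.
#' @return An object of class `style_profile`.
#' @export
style_profile <- function(individual,
                          strokes_mean = 8,
                          stroke_len_mm = 120,
                          colour_weights = rep(1 / 16, 16),
                          colours_mean = 2,
                          pressure_mean = 0.8,
                          pressure_sd = 0.1,
                          shape_rates = c(fan = 1.5, circle = 0.05,
                                          triangle = 0.2, loop = 0.6),
                          spread_mm = 45,
                          fill_sd = 0.6,
                          shape_sd = 0.5,
                          trend = 0,
                          season_effect = c(winter = 0, spring = 0,
                                            summer = 0, autumn = 0),
                          jitter_mm = 0.8) {
  colour_weights <- as.numeric(colour_weights)
  stopifnot(length(colour_weights) == 16, all(colour_weights >= 0))
  if (abs(sum(colour_weights) - 1) > 1e-8)
    stop("colour_weights must sum to 1")
  stopifnot(all(shape_rates >= 0),
            all(c("fan", "circle", "triangle", "loop") %in% names(shape_rates)),
            all(season_levels %in% names(season_effect)))
  structure(list(individual = individual, strokes_mean = strokes_mean,
                 stroke_len_mm = stroke_len_mm,
                 colour_weights = colour_weights, colours_mean = colours_mean,
                 pressure_mean = pressure_mean, pressure_sd = pressure_sd,
                 shape_rates = shape_rates[c("fan", "circle", "triangle", "loop")],
                 spread_mm = spread_mm, fill_sd = fill_sd, shape_sd = shape_sd,
                 trend = trend,
                 season_effect = season_effect[season_levels],
                 jitter_mm = jitter_mm),
            class = "style_profile")
}

#' @export
print.style_profile <- function(x, ...) {
  cat(sprintf("style profile '%s': %.1f strokes, shapes (%s), trend %.3f\n",
              x$individual, x$strokes_mean,
              paste(sprintf("%s %.2f", names(x$shape_rates), x$shape_rates),
                    collapse = ", "), x$trend))
  invisible(x)
}

weight_vec <- function(...) {
  w <- rep(0.5, 16)
  names(w) <- crayon_palette()$name
  dots <- c(...)
  w[names(dots)] <- dots
  unname(w / sum(w))
}

#' Default style profiles of the five emulated individuals
#'
#' Profiles emulating the drawing styles of five captive orang-utans: one
#' prolific individual ("Molly") with heavy filling, low crayon pressure, a
#' green/rose colour preference, frequent loops, a negative longitudinal
#' trend in filling and a winter deficit; and four occasional drawers with
#' distinct colour preferences and filling habits, among them a minimalist
#' hard-pressing individual ("Kiki"). Population means of the resulting
#' metrics sit near coverage ~0.5, overlap ~20% of covered cells and ~3
#' colours per drawing.
#'
#' @return A named list of [style_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    Molly = style_profile(
      "Molly", strokes_mean = 11, stroke_len_mm = 150,
      colour_weights = weight_vec(green = 4.5, rose = 3.2, magenta = 1.6,
                                  violet = 1.6, red = 1.2),
      colours_mean = 3.0, pressure_mean = 0.55, pressure_sd = 0.2,
      shape_rates = c(fan = 1.9, circle = 0.09, triangle = 0.25, loop = 0.8),
      spread_mm = 46, fill_sd = 0.55, shape_sd = 0.9,
      trend = -0.045,
      season_effect = c(winter = -0.55, spring = 0, summer = 0.05,
                        autumn = 0)),
    Gypsy = style_profile(
      "Gypsy", strokes_mean = 5, stroke_len_mm = 100,
      colour_weights = weight_vec(red = 6.5, orange = 1.5, blue = 1.2),
      colours_mean = 2.2, pressure_mean = 0.85, pressure_sd = 0.16,
      shape_rates = c(fan = 0.8, circle = 0.05, triangle = 0.1, loop = 0.3),
      spread_mm = 62, fill_sd = 0.5, shape_sd = 0.9),
    Julie = style_profile(
      "Julie", strokes_mean = 6, stroke_len_mm = 110,
      colour_weights = weight_vec(red = 4.5, gold = 1.5, azure = 1.4),
      colours_mean = 2.6, pressure_mean = 0.75, pressure_sd = 0.16,
      shape_rates = c(fan = 1.2, circle = 0.07, triangle = 0.15, loop = 0.5),
      spread_mm = 55, fill_sd = 0.55, shape_sd = 0.9),
    Yuki = style_profile(
      "Yuki", strokes_mean = 8, stroke_len_mm = 120,
      colour_weights = weight_vec(red = 5.5, violet = 1.6, green = 1.3),
      colours_mean = 2.8, pressure_mean = 0.8, pressure_sd = 0.16,
      shape_rates = c(fan = 1.8, circle = 0.08, triangle = 0.2, loop = 0.7),
      spread_mm = 50, fill_sd = 0.55, shape_sd = 0.9),
    Kiki = style_profile(
      "Kiki", strokes_mean = 3, stroke_len_mm = 80,
      colour_weights = weight_vec(green = 4.2, blue = 1.3, black = 1.2),
      colours_mean = 0.7, pressure_mean = 0.95, pressure_sd = 0.06,
      shape_rates = c(fan = 0.5, circle = 0.03, triangle = 0.08, loop = 0.2),
      spread_mm = 68, fill_sd = 0.5, shape_sd = 0.9)
  )
}

#' Default per-individual drawing counts
#'
#' The per-individual numbers of analysed drawings that the default dataset
#' reproduces: 26 (Gypsy), 16 (Julie), 32 (Yuki), 60 (Kiki) and 656 (Molly),
#' 790 in total, the prolific individual's drawings being balanced over 19
#' three-month periods.
#'
#' @return named integer vector.
#' @export
default_counts <- function() {
  c(Molly = 656L, Gypsy = 26L, Julie = 16L, Yuki = 32L, Kiki = 60L)
}

#' Census of the emulated drawing archive
#'
#' Bookkeeping of the original archive that the synthetic generator
#' emulates: per individual, the number of drawings collected over the whole
#' archive and the number retained for analysis (torn or damaged sheets
#' excluded; the prolific individual subsampled to balance 3-month periods).
#' Note the analysed counts sum to 790 while parts of the source material
#' also quote a total of 749; the per-individual counts are authoritative
#' here.
#'
#' @return data frame with columns `individual`, `collected`, `analysed`,
#'   and `share_pct` (integer-rounded percentage of the collected total).
#' @export
drawing_collection_summary <- function() {
  d <- data.frame(
    individual = c("Molly", "Gypsy", "Julie", "Yuki", "Kiki"),
    collected = c(1299L, 26L, 16L, 32L, 60L),
    analysed = c(656L, 26L, 16L, 32L, 60L),
    stringsAsFactors = FALSE)
  d$share_pct <- as.integer(round(100 * d$collected / sum(d$collected)))
  d
}

# Sample pressure truncated to [0.35, 1]
sample_pressure <- function(n, mean, sd) {
  pmin(1, pmax(0.35, rnorm(n, mean, sd)))
}

truncnorm2 <- function(mu, sd, lo, hi) {
  pmin(hi, pmax(lo, rnorm(2, mu, sd)))
}

#' Sample one synthetic drawing with ground truth
#'
#' Draws a vector drawing from a [style_profile()] and records complete
#' ground truth: every planted shape with the index of the stroke that
#' realizes it, the set of crayons used, and (when `rasterize = TRUE`)
#' per-grid-cell coverage derived from the order-independent stroke mask of
#' the rendered image.
#'
#' @param profile a [style_profile()].
#' @param date drawing date (`Date`); determines season and period.
#' @param seed integer seed making the drawing reproducible.
#' @param drawing_id identifier stored in the metadata.
#' @param sheet the [sheet()] drawn on.
#' @param px_per_mm rendering resolution for the ground-truth raster.
#' @param rasterize if `FALSE`, skip rendering (vector truth only).
#' @return a list with elements `drawing` (class `vector_drawing`), `truth`
#'   (class `ground_truth`) and, if rendered, `raster` (class
#'   `raster_drawing`).
#' @export
sample_drawing <- function(profile, date, seed, drawing_id = "d1",
                           sheet = apedraw::sheet(), px_per_mm = 2,
                           rasterize = TRUE) {
  force(sheet)
  with_seed(seed, {
    season <- season_of_date(date)
    period <- period_of_date(date)
    per_for_trend <- min(max(period, 1L), 19L)
    lf <- rnorm(1, 0, profile$fill_sd) +
      profile$trend * (per_for_trend - 10) +
      profile$season_effect[[season]]
    F_lat <- exp(lf)
    S_lat <- exp(rnorm(1, 0, profile$shape_sd))

    n_meander <- rpois(1, profile$strokes_mean * F_lat)
    n_shapes <- rpois(4, profile$shape_rates * S_lat)
    names(n_shapes) <- names(profile$shape_rates)

    n_str <- n_meander + sum(n_shapes)
    strokes <- list()
    planted <- data.frame(kind = character(0), stroke = integer(0),
                          stringsAsFactors = FALSE)
    if (n_str > 0) {
      dominant <- sample.int(16, 1, prob = profile$colour_weights)
      n_accent <- min(rpois(1, profile$colours_mean), 15L)
      w <- profile$colour_weights
      w[dominant] <- 0
      accents <- integer(0)
      if (n_accent > 0 && sum(w) > 0)
        accents <- sample.int(16, min(n_accent, sum(w > 0)), prob = w)
      # dominant crayon claims the first stroke and ~70% of the rest
      pool <- c(dominant, accents)
      probs <- c(0.7, rep(0.3 / max(1, length(accents)), length(accents)))
      cols <- c(dominant,
                pool[sample.int(length(pool), n_str - 1, replace = TRUE,
                                prob = probs)])
      # heavy-filling drawings are pressed more lightly (fast scribbling
      # covers much paper with faint marks), which keeps the luminance
      # statistics from being a pure mirror of the filling variables
      press_draw <- min(1, max(0.4, rnorm(1, profile$pressure_mean - 0.32 * lf,
                                          profile$pressure_sd)))
      press <- sample_pressure(n_str, press_draw, 0.05)
      width_draw <- runif(1, 3.5, 7)      # some drawings thin, some broad
      widths <- pmax(2.5, width_draw + runif(n_str, -0.7, 0.7))
      anchors <- cbind(
        pmin(pmax(rnorm(n_str, sheet$width_mm / 2, profile$spread_mm),
                  12), sheet$width_mm - 12),
        pmin(pmax(rnorm(n_str, sheet$height_mm / 2,
                        profile$spread_mm * sheet$height_mm / sheet$width_mm),
                  12), sheet$height_mm - 12))
      si <- 0L
      for (kind in names(n_shapes)) {
        for (k in seq_len(n_shapes[[kind]])) {
          si <- si + 1L
          strokes[[si]] <- if (kind == "fan") {
            make_fan_stroke(anchors[si, ],
                            leg_length_mm = runif(1, 40, 90) * sqrt(F_lat),
                            round_trips = 3 + rpois(1, 1.2),
                            spread_angle_deg = runif(1, 20, 44),
                            jitter_mm = profile$jitter_mm,
                            colour_id = cols[si], width_mm = widths[si],
                            pressure = press[si], sheet = sheet)
          } else {
            make_closed_shape(kind, anchors[si, ],
                              size_mm = runif(1, 25, 55),
                              jitter_mm = profile$jitter_mm,
                              colour_id = cols[si], width_mm = widths[si],
                              pressure = press[si], sheet = sheet)
          }
          planted <- rbind(planted,
                           data.frame(kind = kind, stroke = si,
                                      stringsAsFactors = FALSE))
        }
      }
      for (k in seq_len(n_meander)) {
        si <- si + 1L
        strokes[[si]] <- make_meander_stroke(
          anchors[si, ],
          length_mm = pmax(20, rnorm(1, profile$stroke_len_mm * sqrt(F_lat),
                                     25)),
          wander = 0.22, jitter_mm = profile$jitter_mm,
          colour_id = cols[si], width_mm = widths[si],
          pressure = press[si], sheet = sheet)
      }
    }

    drawing <- structure(
      list(strokes = strokes, sheet = sheet,
           meta = list(drawing_id = drawing_id,
                       individual = profile$individual,
                       date = date, season = season, period = period)),
      class = "vector_drawing")

    truth <- structure(
      list(planted = planted,
           colours = sort(unique(vapply(strokes, `[[`, 1L, "colour_id"))),
           shape_counts = n_shapes,
           cells = NULL),
      class = "ground_truth")

    out <- list(drawing = drawing, truth = truth)
    if (rasterize) {
      ras <- rasterize(drawing, px_per_mm)
      truth$cells <- truth_cells(ras, sheet)
      out$truth <- truth
      out$raster <- ras
    }
    out
  })
}

#' @export
print.vector_drawing <- function(x, ...) {
  cat(sprintf("drawing %s by %s (%s, %s, period %d): %d strokes\n",
              x$meta$drawing_id, x$meta$individual,
              format(x$meta$date), x$meta$season, x$meta$period,
              length(x$strokes)))
  invisible(x)
}

#' Generate a dataset and measure it in one streaming pass
#'
#' Equivalent to [make_dataset()] followed by [compute_metrics()], but each
#' drawing is rasterized, measured and discarded immediately, so the memory
#' footprint stays flat regardless of dataset size (a full 790-drawing
#' study holds ~3 GB of rasters if kept; this keeps one). The drawing
#' stream is seeded identically to [make_dataset()], so the metrics agree
#' drawing for drawing.
#'
#' @inheritParams make_dataset
#' @param config metric thresholds passed to [extract_metrics()].
#' @return list with `metrics` (data frame, one row per drawing) and
#'   `manifest`.
#' @export
generate_metrics <- function(profiles = default_profiles(),
                             counts = default_counts(),
                             seed = 1, longitudinal = "Molly",
                             px_per_mm = 2, config = list(),
                             sheet = apedraw::sheet()) {
  plan <- dataset_plan(profiles, counts, seed, longitudinal)
  prof_by_id <- setNames(profiles, vapply(profiles, `[[`, "", "individual"))
  rows <- vector("list", nrow(plan$plan))
  for (i in seq_len(nrow(plan$plan))) {
    d <- sample_drawing(prof_by_id[[plan$plan$individual[i]]],
                        date = plan$plan$date[i], seed = plan$seeds[i],
                        drawing_id = plan$plan$drawing_id[i],
                        sheet = sheet, px_per_mm = px_per_mm,
                        rasterize = TRUE)
    m <- extract_metrics(d$raster, d$drawing, sheet = sheet, config = config)
    rows[[i]] <- cbind(
      data.frame(drawing_id = plan$plan$drawing_id[i],
                 individual = plan$plan$individual[i],
                 season = plan$manifest$season[i],
                 period = plan$plan$period[i],
                 stringsAsFactors = FALSE),
      m)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics[, c(
    "drawing_id", "individual", "season", "period", "coverage_rate",
    "overlap_rate", "n_colours", "fan", "circle", "triangle", "loop",
    "colour_mean", "colour_sd", "dist_centre_mm", "solid_colour_rate",
    "main_colour")],
    manifest = plan$manifest)
}

#' Generate a synthetic drawing dataset
#'
#' Samples a full multi-individual dataset. The longitudinal individual
#' (the one flagged by `longitudinal`) is balanced over the 19 three-month
#' periods (counts split as evenly as possible, e.g. 656 drawings fall as
#' 34 or 35 per period); the other individuals draw on uniformly random
#' periods. With `out_dir` the dataset is also written to disk: a PNG and a
#' stroke JSON per drawing, a ground-truth JSON, and a manifest CSV with
#' columns `drawing_id, individual, date, season, period`.
#'
#' @param profiles named list of [style_profile()]s (names must be unique).
#' @param counts named integer vector of drawings per individual; defaults
#'   to [default_counts()] for the default profiles.
#' @param seed master seed; the dataset is a pure function of it.
#' @param longitudinal name of the period-balanced individual.
#' @param out_dir optional output directory.
#' @param px_per_mm raster resolution.
#' @param rasterize render rasters (needed for raster metrics/ground-truth
#'   cells); `FALSE` gives a fast vector-only dataset.
#' @param sheet the [sheet()].
#' @return list with `drawings` (list of [sample_drawing()] results) and
#'   `manifest` (data frame).
#' @export
make_dataset <- function(profiles = default_profiles(),
                         counts = default_counts(),
                         seed = 1, longitudinal = "Molly",
                         out_dir = NULL, px_per_mm = 2, rasterize = TRUE,
                         sheet = apedraw::sheet()) {
  pl <- dataset_plan(profiles, counts, seed, longitudinal)
  if (nrow(pl$plan) == 0) {
    if (!is.null(out_dir)) write_dataset(list(), pl$manifest, out_dir)
    return(list(drawings = list(), manifest = pl$manifest))
  }
  prof_by_id <- setNames(profiles, vapply(profiles, `[[`, "", "individual"))
  drawings <- vector("list", nrow(pl$plan))
  for (i in seq_len(nrow(pl$plan))) {
    drawings[[i]] <- sample_drawing(prof_by_id[[pl$plan$individual[i]]],
                                    date = pl$plan$date[i],
                                    seed = pl$seeds[i],
                                    drawing_id = pl$plan$drawing_id[i],
                                    sheet = sheet, px_per_mm = px_per_mm,
                                    rasterize = rasterize)
  }
  if (!is.null(out_dir)) {
    write_dataset(drawings, pl$manifest, out_dir)
  }
  list(drawings = drawings, manifest = pl$manifest)
}

# Shared sampling plan of a dataset: who draws when, with which seed.
dataset_plan <- function(profiles, counts, seed, longitudinal) {
  ids <- vapply(profiles, `[[`, "", "individual")
  if (anyDuplicated(ids)) stop("duplicate individual ids in profiles")
  if (is.null(names(counts))) stop("counts must be named by individual")
  stopifnot(all(counts >= 0), all(names(counts) %in% ids))

  plan <- do.call(rbind, lapply(names(counts), function(ind) {
    n <- counts[[ind]]
    if (n == 0) return(NULL)
    if (identical(ind, longitudinal)) {
      # balanced over the 19 periods: counts differ by at most one
      base <- n %/% 19L
      extra <- n %% 19L
      per <- rep(seq_len(19L), times = base + (seq_len(19L) <= extra))[seq_len(n)]
    } else {
      per <- rep(NA_integer_, n)   # filled below with random periods
    }
    data.frame(individual = rep(ind, n), period = per,
               stringsAsFactors = FALSE)
  }))
  if (is.null(plan)) {
    manifest <- data.frame(drawing_id = character(0),
                           individual = character(0), date = character(0),
                           season = character(0), period = integer(0))
    return(list(plan = data.frame(), manifest = manifest,
                seeds = numeric(0)))
  }
  rownames(plan) <- NULL

  n_tot <- nrow(plan)
  seeds <- derive_seeds(seed, n_tot + 1L)
  plan$period <- with_seed(seeds[n_tot + 1L], {
    p <- plan$period
    p[is.na(p)] <- sample.int(19L, sum(is.na(p)), replace = TRUE)
    p
  })
  plan$date <- with_seed(seeds[n_tot + 1L] + 1, {
    random_date_in_period(plan$period)
  })
  plan$drawing_id <- sprintf("%s_%04d", plan$individual,
                             stats::ave(seq_len(n_tot), plan$individual,
                                        FUN = seq_along))
  manifest <- data.frame(
    drawing_id = plan$drawing_id,
    individual = plan$individual,
    date = format(plan$date),
    season = season_of_period(plan$period),
    period = plan$period,
    stringsAsFactors = FALSE)
  list(plan = plan, manifest = manifest, seeds = seeds)
}
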