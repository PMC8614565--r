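#' The 16-crayon reference palette
#'
#' Reference colours for the box of 16 wax crayons offered with each drawing
#' sheet. Fifteen chromatic crayons are spaced evenly around the HSV hue
#' wheel (saturation 0.9, value 0.85) and the sixteenth is black. The hues
#' are deliberately chosen so that the straight line ("blend ray") from
#' paper white to each crayon colour in RGB space is angularly well
#' separated from every other crayon's ray: a crayon mark rendered at any
#' pressure lies exactly on its own ray, which is what makes per-pixel
#' colour attribution well-posed (see [build_label_map()]).
#'
#' @return An object of class `crayon_palette`: a data frame with columns
#'   `colour_id` (1-16), `name`, and reference `r`, `g`, `b` (0-255), plus
#'   attribute `background` (paper white, `c(255, 255, 255)`).
#' @examples
#' pal <- crayon_palette()
#' nrow(pal)  # 16
#' @export
crayon_palette <- function() {
  hues <- (0:14) / 15
  rgb15 <- t(col2rgb(hsv(hues, s = 0.9, v = 0.85)))
  rgb16 <- rbind(rgb15, c(40L, 40L, 40L))
  nm <- c("red", "orange", "gold", "yellow", "chartreuse", "green",
          "emerald", "teal", "cyan", "azure", "blue", "indigo",
          "violet", "magenta", "rose", "black")
  out <- data.frame(colour_id = 1:16, name = nm,
                    r = as.integer(rgb16[, 1]),
                    g = as.integer(rgb16[, 2]),
                    b = as.integer(rgb16[, 3]),
                    stringsAsFactors = FALSE)
  attr(out, "background") <- c(255L, 255L, 255L)
  class(out) <- c("crayon_palette", "data.frame")
  out
}

# 16 x 3 numeric RGB matrix of a palette
palette_rgb <- function(palette = crayon_palette()) {
  as.matrix(palette[, c("r", "g", "b")])
}

#' Drawing sheet geometry
#'
#' The physical sheet and the analysis grid laid over it. The default is the
#' 272 x 242 mm paperboard with a 10 x 10 grid of equal cells. Coordinates
#' are in mm with the origin at the top-left corner, x rightward and y
#' downward; grid cell (row, col) covers the half-open rectangle
#' `[col-1, col) * width/10` by `[row-1, row) * height/10`.
#'
#' @param width_mm,height_mm sheet dimensions in mm.
#' @param grid_rows,grid_cols analysis grid dimensions.
#' @return An object of class `sheet`.
#' @examples
#' sh <- sheet()
#' sheet_centre(sh)  # c(136, 121)
#' @export
sheet <- function(width_mm = 272, height_mm = 242,
                  grid_rows = 10, grid_cols = 10) {
  stopifnot(width_mm > 0, height_mm > 0, grid_rows >= 1, grid_cols >= 1)
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "sheet")
}

#' @rdname sheet
#' @param x a `sheet`.
#' @export
sheet_centre <- function(x) c(x = x$width_mm / 2, y = x$height_mm / 2)

#' @export
print.sheet <- function(x, ...) {
  cat(sprintf("sheet %g x %g mm, %d x %d analysis grid\n",
              x$width_mm, x$height_mm, x$grid_rows, x$grid_cols))
  invisible(x)
}

# -- calendar ---------------------------------------------------------------
# The longitudinal record is divided into 19 consecutive 3-month periods
# aligned with meteorological seasons, period 1 = spring (Mar-May) 2006.

period_start <- as.Date("2006-03-01")

season_levels <- c("winter", "spring", "summer", "autumn")

#' Season and period calendar
#'
#' Dates map to meteorological seasons (Dec-Feb = winter, Mar-May = spring,
#' Jun-Aug = summer, Sep-Nov = autumn) and to 3-month periods aligned with
#' those seasons, period 1 starting 1 March 2006. With this alignment every
#' date of a period falls in a single season, matching a sampling design in
#' which 3-month periods correspond to seasons.
#'
#' @param date a `Date` vector.
#' @return `season_of_date()`: a character vector of seasons;
#'   `period_of_date()`: an integer period index (1-based);
#'   `season_of_period()`: the season of a period index;
#'   `random_date_in_period()`: one uniform random date inside a period
#'   (uses the current RNG stream).
#' @export
season_of_date <- function(date) {
  m <- as.integer(format(date, "%m"))
  season_levels[c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 1)[m]]
}

#' @rdname season_of_date
#' @export
period_of_date <- function(date) {
  m <- 12L * (as.integer(format(date, "%Y")) - 2006L) +
    as.integer(format(date, "%m")) - 3L
  as.integer(m %/% 3L) + 1L
}

#' @rdname season_of_date
#' @param period integer period index.
#' @export
season_of_period <- function(period) {
  season_levels[c(2, 3, 4, 1)[(period - 1L) %% 4L + 1L]]
}

#' @rdname season_of_date
#' @export
random_date_in_period <- function(period) {
  out <- as.Date(vapply(period, function(p) {
    a <- seq(period_start, by = "3 months", length.out = p)[p]
    b <- seq(a, by = "3 months", length.out = 2)[2] - 1
    as.numeric(sample(seq(a, b, by = "day"), 1))
  }, numeric(1)), origin = "1970-01-01")
  out
}
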