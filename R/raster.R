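#' Render a vector drawing to a raster image
#'
#' Paints each stroke as a disc-swept polyline of its width onto a white
#' sheet at `px_per_mm` resolution. A mark at pressure p is rendered as
#' `p * colour + (1 - p) * white`; strokes are painted in list order (last
#' on top). Alongside the RGB channels, a per-pixel bitmask records every
#' stroke colour that touched each pixel regardless of paint order, which
#' is what downstream overlap ground truth is built from.
#'
#' @param drawing a `vector_drawing`.
#' @param px_per_mm resolution (default 2, i.e. 544 x 484 px for the
#'   standard sheet).
#' @return An object of class `raster_drawing`: list with integer matrices
#'   `r`, `g`, `b` (0-255), `mask` (colour bitmask), plus `px_per_mm` and
#'   the `sheet`.
#' @export
rasterize <- function(drawing, px_per_mm = 2) {
  stopifnot(px_per_mm > 0)
  sh <- drawing$sheet
  pts <- lapply(drawing$strokes, `[[`, "points")
  cid <- vapply(drawing$strokes, `[[`, 1L, "colour_id")
  wid <- vapply(drawing$strokes, `[[`, 1, "width_mm")
  prs <- vapply(drawing$strokes, `[[`, 1, "pressure")
  out <- paint_strokes_cpp(pts, cid, wid, prs, palette_rgb(),
                           sh$width_mm, sh$height_mm, px_per_mm)
  structure(list(r = out$r, g = out$g, b = out$b, mask = out$mask,
                 px_per_mm = px_per_mm, sheet = sh),
            class = "raster_drawing")
}

#' @export
print.raster_drawing <- function(x, ...) {
  cat(sprintf("raster drawing %d x %d px (%.1f px/mm), %.1f%% pixels marked\n",
              ncol(x$r), nrow(x$r), x$px_per_mm,
              100 * mean(x$mask != 0)))
  invisible(x)
}

# Ground-truth per-cell table from the order-independent stroke mask:
# covered flag, colour-id set (from the OR of bitmasks) and the exact
# stroke-pixel fraction.
truth_cells <- function(raster, sheet = raster$sheet) {
  tal <- cell_tally_cpp(raster$mask, sheet$width_mm, sheet$height_mm,
                        raster$px_per_mm, sheet$grid_rows, sheet$grid_cols,
                        TRUE)
  ncell <- sheet$grid_rows * sheet$grid_cols
  data.frame(
    row = rep(seq_len(sheet$grid_rows), each = sheet$grid_cols),
    col = rep(seq_len(sheet$grid_cols), times = sheet$grid_rows),
    covered = tal$marked > 0,
    colours = I(lapply(tal$ormask, mask_to_ids)),
    fraction = tal$marked / tal$total)
}

mask_to_ids <- function(m) {
  which(bitwAnd(m, 2^(0:15)) != 0)
}

# -- dataset IO -------------------------------------------------------------

#' Read and write drawings on disk
#'
#' `write_dataset()` writes one PNG and one stroke JSON per drawing, one
#' ground-truth JSON, a `manifest.csv` and the palette. `read_stroke_json()`
#' restores a `vector_drawing` from its stroke file. The stroke JSON schema
#' is: `sheet` (width_mm, height_mm, grid_rows, grid_cols), `meta`
#' (drawing_id, individual, date, season, period) and `strokes`, an array
#' of objects with `points` (n x 2 array, mm), `colour_id`, `width_mm`,
#' `pressure`.
#'
#' @param drawings list of [sample_drawing()] results.
#' @param manifest manifest data frame.
#' @param dir output directory (created if missing).
#' @return `write_dataset()`: the directory, invisibly;
#'   `read_stroke_json()`: a `vector_drawing`.
#' @export
write_dataset <- function(drawings, manifest, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to ", dir)
  for (d in drawings) {
    id <- d$drawing$meta$drawing_id
    write_stroke_json(d$drawing, file.path(dir, paste0(id, ".json")))
    if (!is.null(d$raster)) {
      png::writePNG(raster_to_array(d$raster),
                    file.path(dir, paste0(id, ".png")))
    }
    truth <- d$truth
    jsonlite::write_json(
      list(planted = truth$planted, colours = truth$colours,
           shape_counts = as.list(truth$shape_counts),
           cells = if (!is.null(truth$cells))
             data.frame(row = truth$cells$row, col = truth$cells$col,
                        covered = truth$cells$covered,
                        colours = vapply(truth$cells$colours,
                                         paste, "", collapse = ";"),
                        fraction = truth$cells$fraction)),
      file.path(dir, paste0(id, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

raster_to_array <- function(raster) {
  H <- nrow(raster$r); W <- ncol(raster$r)
  a <- array(0, c(H, W, 3))
  a[, , 1] <- raster$r / 255
  a[, , 2] <- raster$g / 255
  a[, , 3] <- raster$b / 255
  a
}

# PNG (values in [0,1]) back to integer channel matrices
array_to_raster <- function(a, px_per_mm = 2, sheet = apedraw::sheet()) {
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] < 3) stop("image is not RGB")
  structure(list(r = round(a[, , 1] * 255), g = round(a[, , 2] * 255),
                 b = round(a[, , 3] * 255), mask = NULL,
                 px_per_mm = px_per_mm, sheet = sheet),
            class = "raster_drawing")
}

#' @rdname write_dataset
#' @param path file path.
#' @export
read_png_drawing <- function(path, px_per_mm = 2, sheet = apedraw::sheet()) {
  array_to_raster(png::readPNG(path), px_per_mm, sheet)
}

#' @rdname write_dataset
#' @param px_per_mm,sheet raster geometry metadata.
#' @export
write_stroke_json <- function(drawing, path) {
  sh <- drawing$sheet
  jsonlite::write_json(
    list(sheet = sh[c("width_mm", "height_mm", "grid_rows", "grid_cols")],
         meta = list(drawing_id = drawing$meta$drawing_id,
                     individual = drawing$meta$individual,
                     date = format(drawing$meta$date),
                     season = drawing$meta$season,
                     period = drawing$meta$period),
         strokes = lapply(drawing$strokes, function(s)
           list(points = s$points, colour_id = s$colour_id,
                width_mm = s$width_mm, pressure = s$pressure))),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_stroke_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sh <- sheet(j$sheet$width_mm, j$sheet$height_mm,
              j$sheet$grid_rows, j$sheet$grid_cols)
  strokes <- lapply(seq_len(max(0, nrow_safe(j$strokes))), function(i) {
    s <- if (is.data.frame(j$strokes)) {
      list(points = j$strokes$points[[i]],
           colour_id = j$strokes$colour_id[i],
           width_mm = j$strokes$width_mm[i],
           pressure = j$strokes$pressure[i])
    } else j$strokes[[i]]
    stroke_path(s$points, s$colour_id, s$width_mm, s$pressure, sh)
  })
  structure(list(strokes = strokes, sheet = sh,
                 meta = list(drawing_id = j$meta$drawing_id,
                             individual = j$meta$individual,
                             date = as.Date(j$meta$date),
                             season = j$meta$season,
                             period = as.integer(j$meta$period))),
            class = "vector_drawing")
}

nrow_safe <- function(x) {
  if (is.data.frame(x)) nrow(x) else length(x)
}
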