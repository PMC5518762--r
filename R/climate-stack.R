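#' Multi-layer gridded climate surface
#'
#' A `climate_stack` bundles the per-cell bioclimatic predictors used by the
#' SDM workflow: a named set of 2-D layers on a common lon/lat grid, a land
#' mask, and a scenario label.  The grid is stored row 1 = northernmost, in
#' geographic coordinates (decimal degrees).  Water (masked) cells carry `NA`
#' in every layer.
#'
#' Cell footprints are half-open: a cell covers `[west, east)` in longitude
#' and `(south, north]` in latitude, so a point on a shared boundary belongs
#' to exactly one cell.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param extent numeric length 4, `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param resolution cell size in degrees (the study analogue is 10' = 1/6).
#' @param mask logical matrix, `TRUE` = land.  Default: all land.
#' @param scenario_id scenario label, e.g. `"BASE"` or a warming level.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(layers, extent, resolution, mask = NULL,
                          scenario_id = "BASE") {
  if (!is.list(layers) || length(layers) == 0L)
    stop("'layers' must be a non-empty named list of matrices")
  nms <- names(layers)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("layer names must be present and unique")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same dimensions")
  nr <- unname(dims[1, 1]); nc <- unname(dims[2, 1])
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("'extent' must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax")
  if (abs((extent[2] - extent[1]) / resolution - nc) > 1e-6 ||
      abs((extent[4] - extent[3]) / resolution - nr) > 1e-6)
    stop("extent, resolution and layer dimensions are inconsistent")
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!is.logical(mask) || !identical(dim(mask), c(nr, nc)))
    stop("'mask' must be a logical matrix matching the layers")
  layers <- lapply(layers, function(m) {
    m <- m * 1.0          # force double storage
    m[!mask] <- NA_real_
    m
  })
  structure(
    list(layers = layers, extent = extent, resolution = resolution,
         mask = mask, scenario_id = as.character(scenario_id), crs = "lonlat"),
    class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  nr <- nrow(x$mask); nc <- ncol(x$mask)
  cat("climate_stack:", nr, "x", nc, "cells at", signif(x$resolution, 4),
      "deg resolution\n")
  cat("  extent    : lon [", x$extent[1], ",", x$extent[2], "]  lat [",
      x$extent[3], ",", x$extent[4], "]\n")
  cat("  scenario  :", x$scenario_id, "\n")
  cat("  layers    :", paste(names(x$layers), collapse = ", "), "\n")
  cat("  land cells:", sum(x$mask), "of", nr * nc,
      sprintf("(%.1f%%)\n", 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.climate_stack <- function(x) dim(x$mask)

#' Map lon/lat points to grid cells
#'
#' Returns, for each point, the unique grid cell whose half-open footprint
#' (`[west, east)` by `(south, north]`) contains it.  Points exactly on the
#' eastern or southern boundary of the full extent are assigned to the edge
#' cells so the closed extent is fully covered.
#'
#' @param lon,lat numeric vectors of equal length, decimal degrees.
#' @param stack a [climate_stack].
#' @return a data.frame with columns `row`, `col` (1-based, row 1 is the
#'   northernmost) and `cell_id = (row - 1) * ncols + col`.
#' @export
cell_of <- function(lon, lat, stack) {
  stopifnot(length(lon) == length(lat))
  ext <- stack$extent; res <- stack$resolution
  nr <- nrow(stack$mask); nc <- ncol(stack$mask)
  bad <- lon < ext[1] | lon > ext[2] | lat < ext[3] | lat > ext[4]
  if (any(bad))
    stop("point(s) outside the grid extent at index: ",
         paste(which(bad), collapse = ", "))
  col <- floor((lon - ext[1]) / res) + 1L
  col[col > nc] <- nc                      # lon == xmax
  ## (south, north]: a lat on an interior boundary belongs to the cell below
  row <- floor((ext[4] - lat) / res) + 1L
  row[row > nr] <- nr                      # lat == ymin
  data.frame(row = as.integer(row), col = as.integer(col),
             cell_id = (as.integer(row) - 1L) * nc + as.integer(col))
}

#' Cell-center coordinates
#'
#' @param row,col 1-based cell indices (row 1 = northernmost).
#' @param stack a [climate_stack].
#' @return data.frame with `lon`, `lat` of the cell centers.
#' @export
cell_center <- function(row, col, stack) {
  ext <- stack$extent; res <- stack$resolution
  data.frame(lon = ext[1] + (col - 0.5) * res,
             lat = ext[4] - (row - 0.5) * res)
}

## all land cells as (row, col, lon, lat); internal workhorse
land_cells <- function(stack) {
  idx <- which(stack$mask, arr.ind = TRUE)
  cc <- cell_center(idx[, 1], idx[, 2], stack)
  data.frame(row = idx[, 1], col = idx[, 2], lon = cc$lon, lat = cc$lat)
}

## predictor matrix (one row per cell, one column per layer) at given cells
stack_values <- function(stack, row, col) {
  ii <- cbind(row, col)
  out <- vapply(stack$layers, function(m) m[ii], numeric(length(row)))
  if (length(row) == 1L) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(stack$layers)))
  out
}

#' Scenario deltas: graded additive climate shifts
#'
#' A scenario is represented as a per-layer additive shift, the one property
#' the downstream analysis uses of a climate future (graded warming
#' severity).  `apply_scenario()` returns a shifted copy of the stack with
#' the mask and extent unchanged.
#'
#' @param severity scenario label (e.g. `"mild"`, `"RCP8.5"`).
#' @param shifts named numeric vector of additive per-layer shifts, in layer
#'   units; names must be layer names of the stack it is applied to.
#' @return `scenario_delta()`: an object of class `scenario_delta`.
#' @export
scenario_delta <- function(severity, shifts) {
  shifts <- unlist(shifts)
  if (length(shifts) && (is.null(names(shifts)) || any(names(shifts) == "")))
    stop("'shifts' must be a named numeric vector")
  structure(list(severity = as.character(severity),
                 shifts = shifts),
            class = "scenario_delta")
}

#' @rdname scenario_delta
#' @param stack a [climate_stack].
#' @param delta a [scenario_delta].
#' @return `apply_scenario()`: a new `climate_stack` with `scenario_id` set
#'   to the delta's severity label.
#' @export
apply_scenario <- function(stack, delta) {
  stopifnot(inherits(stack, "climate_stack"), inherits(delta, "scenario_delta"))
  unknown <- setdiff(names(delta$shifts), names(stack$layers))
  if (length(unknown))
    stop("scenario shifts name unknown layer(s): ",
         paste(unknown, collapse = ", "))
  out <- stack
  for (nm in names(delta$shifts)) {
    m <- out$layers[[nm]] + delta$shifts[[nm]]
    m[!out$mask] <- NA_real_
    out$layers[[nm]] <- m
  }
  out$scenario_id <- delta$severity
  out
}

#' Default warming scenarios of graded severity
#'
#' Three additive-shift scenarios emulating climate futures of increasing
#' forcing, applied to the six default bioclimatic layers: temperatures rise
#' (+1 / +2 / +4 degrees C on BIO5 and BIO6), seasonality increases slightly
#' and precipitation declines modestly with severity.
#'
#' @return named list of [scenario_delta] objects
#'   (`mild`, `medium`, `severe`).
#' @export
default_scenarios <- function() {
  list(
    mild = scenario_delta("mild", c(
      BIO4 = 20,  BIO5 = 1, BIO6 = 1,  BIO16 = -20,  BIO17 = -5,  BIO18 = -15)),
    medium = scenario_delta("medium", c(
      BIO4 = 40,  BIO5 = 2, BIO6 = 2,  BIO16 = -50,  BIO17 = -12, BIO18 = -35)),
    severe = scenario_delta("severe", c(
      BIO4 = 80,  BIO5 = 4, BIO6 = 4,  BIO16 = -100, BIO17 = -25, BIO18 = -70)))
}

#' Plot a climate layer or map
#'
#' @param x a [climate_stack].
#' @param layer layer name to display.
#' @param ... passed to [graphics::image()].
#' @export
plot.climate_stack <- function(x, layer = names(x$layers)[1], ...) {
  m <- x$layers[[layer]]
  if (is.null(m)) stop("no layer named '", layer, "'")
  ## image() draws column-major from the bottom; flip rows so north is up
  graphics::image(x = seq(x$extent[1], x$extent[2], length.out = ncol(m) + 1),
                  y = seq(x$extent[3], x$extent[4], length.out = nrow(m) + 1),
                  z = t(m[nrow(m):1, , drop = FALSE]),
                  xlab = "lon", ylab = "lat", main = layer, ...)
  invisible(x)
}
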