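#' Per-cell suitability and binary maps
#'
#' A `suitability_map` holds one continuous per-cell prediction (in `[0, 1]`)
#' for one species under one scenario, on the geometry of the climate stack
#' it was projected onto; a `binary_map` holds the thresholded 0/1 version.
#' Masked (water) cells are `NA` in both.
#'
#' @param values numeric matrix (binary maps: 0/1).
#' @param stack the [climate_stack] supplying geometry and mask.
#' @param species_id,scenario_id labels carried along for bookkeeping.
#' @param threshold for binary maps, the probability cutoff used.
#' @return an object of class `suitability_map` or `binary_map`
#'   (both inherit from `hr_map`).
#' @export
suitability_map <- function(values, stack, species_id = NA_character_,
                            scenario_id = stack$scenario_id) {
  new_hr_map(values, stack, "suitability", species_id, scenario_id, NA_real_)
}

#' @rdname suitability_map
#' @export
binary_map <- function(values, stack, species_id = NA_character_,
                       scenario_id = stack$scenario_id, threshold = NA_real_) {
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("binary map values must be 0/1 (or NA on masked cells)")
  new_hr_map(values, stack, "binary", species_id, scenario_id, threshold)
}

new_hr_map <- function(values, stack, kind, species_id, scenario_id, threshold) {
  stopifnot(inherits(stack, "climate_stack"))
  if (!identical(dim(values), dim(stack$mask)))
    stop("map dimensions do not match the stack grid")
  values <- values * 1.0
  values[!stack$mask] <- NA_real_
  structure(
    list(values = values, extent = stack$extent, resolution = stack$resolution,
         mask = stack$mask, species_id = species_id,
         scenario_id = scenario_id, kind = kind, threshold = threshold),
    class = c(paste0(kind, "_map"), "hr_map"))
}

#' @export
print.hr_map <- function(x, ...) {
  cat(x$kind, "map:", nrow(x$values), "x", ncol(x$values),
      "cells | species:", x$species_id, "| scenario:", x$scenario_id, "\n")
  v <- x$values[x$mask]
  if (x$kind == "binary")
    cat("  suitable cells:", sum(v == 1), "of", length(v),
        "land cells (threshold ", signif(x$threshold, 4), ")\n", sep = "")
  else
    cat("  range over land: [", signif(min(v), 4), ",", signif(max(v), 4), "]\n")
  invisible(x)
}

#' Threshold a suitability map into a binary map
#'
#' Cells with probability greater than or equal to the threshold become
#' suitable (1).
#'
#' @param map a [suitability_map].
#' @param threshold cutoff in (0, 1).
#' @return a [binary_map].
#' @export
binarize <- function(map, threshold) {
  stopifnot(inherits(map, "hr_map"), map$kind == "suitability")
  v <- (map$values >= threshold) * 1.0
  stk <- map_geometry(map)
  binary_map(v, stk, map$species_id, map$scenario_id, threshold)
}

## reconstruct a bare geometry-only stack from a map (internal)
map_geometry <- function(map) {
  climate_stack(list(.geom = map$values * 0), map$extent, map$resolution,
                mask = map$mask, scenario_id = map$scenario_id)
}

## check two maps share a grid (internal)
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$extent, b$extent)) &&
    isTRUE(all.equal(a$resolution, b$resolution)) &&
    identical(a$mask, b$mask)
}
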