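#' Species occurrence tables
#'
#' An `occurrence_table` is a data.frame of presence records with columns
#' `species_id`, `lon`, `lat` and (optionally) `source_tag`, plus a
#' `cleaned` attribute recording whether [clean_occurrences()] has been
#' applied.  Coordinates are decimal degrees.
#'
#' @param species_id,lon,lat,source_tag record fields (recycled).
#' @return an object of class `occurrence_table` (a data.frame).
#' @export
occurrence_table <- function(species_id, lon, lat, source_tag = "unknown") {
  df <- data.frame(species_id = as.character(species_id),
                   lon = as.numeric(lon), lat = as.numeric(lat),
                   source_tag = as.character(source_tag),
                   stringsAsFactors = FALSE)
  validate_coords(df)
  structure(df, cleaned = FALSE, class = c("occurrence_table", "data.frame"))
}

validate_coords <- function(df) {
  bad <- which(!is.finite(df$lon) | !is.finite(df$lat) |
                 df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90)
  if (length(bad))
    stop("invalid coordinates at row(s): ", paste(bad, collapse = ", "))
  invisible(df)
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("occurrence_table:", nrow(x), "records,",
      length(unique(x$species_id)), "species",
      if (isTRUE(attr(x, "cleaned"))) "(cleaned)" else "(raw)", "\n")
  NextMethod()
}

#' Clean occurrence records against a grid
#'
#' Collapses multiple records of a species within one grid cell to a single
#' record (the first in input order) and drops records falling on masked
#' (water) cells or outside the grid extent.  Species losing all their
#' records are reported with a warning so they can be excluded downstream.
#' The operation is idempotent.
#'
#' @param occ an [occurrence_table].
#' @param stack the [climate_stack] defining cells and the land mask.
#' @return the cleaned `occurrence_table` (attribute `cleaned = TRUE`).
#' @export
clean_occurrences <- function(occ, stack) {
  stopifnot(inherits(occ, "occurrence_table"), inherits(stack, "climate_stack"))
  if (nrow(occ) == 0L)
    return(structure(occ, cleaned = TRUE, class = class(occ)))
  ext <- stack$extent
  species_in <- unique(occ$species_id)
  inside <- occ$lon >= ext[1] & occ$lon <= ext[2] &
    occ$lat >= ext[3] & occ$lat <= ext[4]
  occ2 <- occ[inside, , drop = FALSE]
  if (nrow(occ2)) {
    cells <- cell_of(occ2$lon, occ2$lat, stack)
    on_land <- stack$mask[cbind(cells$row, cells$col)]
    occ2 <- occ2[on_land, , drop = FALSE]
    cells <- cells[on_land, , drop = FALSE]
    keep <- !duplicated(paste(occ2$species_id, cells$cell_id))
    occ2 <- occ2[keep, , drop = FALSE]
  }
  lost <- setdiff(species_in, unique(occ2$species_id))
  if (length(lost))
    warning("species with no records left after cleaning: ",
            paste(lost, collapse = ", "))
  rownames(occ2) <- NULL
  structure(occ2, cleaned = TRUE,
            class = c("occurrence_table", "data.frame"))
}
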