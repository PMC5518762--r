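#' Read and write climate stacks as plain-text multi-layer grids
#'
#' Stacks are serialized to a self-describing text format (one header block,
#' then one value block per layer, row 1 = northernmost, masked cells as the
#' declared no-data value).  The format plays the role a multi-band raster
#' file with an explicit no-data value would play in a GIS toolchain; it
#' round-trips exactly (`read_climate(write_climate(x)) == x`).
#'
#' @param stack a [climate_stack].
#' @param path file path.
#' @return `write_climate()`: `path`, invisibly.  `read_climate()`: a
#'   [climate_stack].
#' @export
write_climate <- function(stack, path) {
  stopifnot(inherits(stack, "climate_stack"))
  nodata <- -99999
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("HRSTACK 1",
           paste("nrows", nrow(stack$mask)),
           paste("ncols", ncol(stack$mask)),
           paste("extent", paste(fmt_num(stack$extent), collapse = " ")),
           paste("resolution", fmt_num(stack$resolution)),
           paste("scenario", stack$scenario_id),
           paste("nodata", nodata),
           paste("layers", paste(names(stack$layers), collapse = " ")))
  writeLines(hdr, con)
  for (nm in names(stack$layers)) {
    writeLines(paste("layer", nm), con)
    m <- stack$layers[[nm]]
    m[!stack$mask] <- nodata
    write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' @rdname write_climate
#' @export
read_climate <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 8L || !startsWith(lines[1], "HRSTACK"))
    stop("not a climate stack file (missing HRSTACK header): ", path)
  field <- function(key) {
    ln <- grep(paste0("^", key, " "), lines[1:8], value = TRUE)
    if (length(ln) != 1L) stop("malformed header: missing '", key, "'")
    sub(paste0("^", key, " "), "", ln)
  }
  nr <- as.integer(field("nrows")); nc <- as.integer(field("ncols"))
  extent <- as.numeric(strsplit(trimws(field("extent")), "\\s+")[[1]])
  res <- as.numeric(field("resolution"))
  scen <- field("scenario")
  nodata <- as.numeric(field("nodata"))
  lay_names <- strsplit(trimws(field("layers")), "\\s+")[[1]]
  body <- lines[-(1:8)]
  layers <- list()
  pos <- 1L
  for (nm in lay_names) {
    tag <- body[pos]
    if (!identical(tag, paste("layer", nm)))
      stop("format error: expected 'layer ", nm, "', found '", tag, "'")
    block <- body[(pos + 1L):(pos + nr)]
    vals <- scan(text = block, quiet = TRUE)
    if (length(vals) != nr * nc)
      stop("shape mismatch in layer '", nm, "': expected ", nr * nc,
           " values, found ", length(vals))
    layers[[nm]] <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    pos <- pos + nr + 1L
  }
  mask <- layers[[1]] != nodata
  for (nm in lay_names) {
    if (!identical(unname(layers[[nm]] != nodata), unname(mask)))
      stop("mask mismatch across layers (no-data cells differ)")
    layers[[nm]][!mask] <- NA_real_
  }
  climate_stack(layers, extent, res, mask = mask, scenario_id = scen)
}

#' Read and write occurrence tables as CSV
#'
#' CSV columns: `species_id, lon, lat[, source_tag]`, decimal degrees.
#' Rows with out-of-range coordinates are rejected with a row-indexed error.
#'
#' @param occ an [occurrence_table].
#' @param path file path.
#' @return `read_occurrences()`: an [occurrence_table] (flagged raw).
#' @export
write_occurrences <- function(occ, path) {
  stopifnot(inherits(occ, "occurrence_table"))
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("malformed occurrence CSV: need columns ",
         paste(need, collapse = ", "))
  occurrence_table(df$species_id, df$lon, df$lat,
                   if ("source_tag" %in% names(df)) df$source_tag else "file")
}

#' Taxon tables: species, genus, group and life form
#'
#' The taxon table assigns each species to a genus, a group (`"garden"` =
#' alien ornamental not yet naturalized in the study region, `"congener"` =
#' resident same-genus species), a status (`"native"`/`"naturalized"`, for
#' congeners) and a life form.  Pairing downstream is restricted to species
#' of the same genus and life form, and every garden species must have at
#' least one such congener.
#'
#' @param species_id,genus,group,status,life_form column vectors (recycled).
#' @return a data.frame of class `taxon_table`.
#' @export
taxon_table <- function(species_id, genus, group, status = NA, life_form = "herb") {
  df <- data.frame(species_id = as.character(species_id),
                   genus = as.character(genus),
                   group = as.character(group),
                   status = as.character(status),
                   life_form = as.character(life_form),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$species_id))
    stop("duplicated species_id in taxon table")
  if (!all(df$group %in% c("garden", "congener")))
    stop("'group' must be 'garden' or 'congener'")
  if (any(!nzchar(df$genus)))
    stop("empty genus")
  g <- df[df$group == "garden", ]
  c_ <- df[df$group == "congener", ]
  orphan <- !mapply(function(gen, lf)
    any(c_$genus == gen & c_$life_form == lf), g$genus, g$life_form)
  if (any(orphan))
    stop("garden species without a same-genus, same-life-form congener: ",
         paste(g$species_id[orphan], collapse = ", "))
  structure(df, class = c("taxon_table", "data.frame"))
}

#' @rdname taxon_table
#' @param path file path of a CSV with the taxon-table columns.
#' @export
read_taxa <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "genus", "group", "life_form")
  if (!all(need %in% names(df)))
    stop("malformed taxon CSV: need columns ", paste(need, collapse = ", "))
  taxon_table(df$species_id, df$genus, df$group,
              if ("status" %in% names(df)) df$status else NA, df$life_form)
}

#' Write a long-format results table
#'
#' Thin CSV writer for the pipeline's result tables (one row per species or
#' species pair per scenario).
#'
#' @param df a data.frame.
#' @param path file path.
#' @export
write_results_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
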