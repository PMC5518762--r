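## Pseudo-absence designs for presence-only SDM fitting: a large random
## background for the regression algorithms, and occurrence-matched sets
## drawn outside an exclusion radius, replicated, for the machine-learning
## algorithms.  Both schemes draw land cells and jitter a point inside the
## cell.

new_pa_set <- function(lon, lat, scheme, species_id, replicate_id = NA_integer_) {
  structure(data.frame(lon = lon, lat = lat, stringsAsFactors = FALSE),
            scheme = scheme, species_id = species_id,
            replicate_id = replicate_id,
            class = c("pa_set", "data.frame"))
}

#' @export
print.pa_set <- function(x, ...) {
  cat("pa_set:", nrow(x), "pseudo-absences | scheme:", attr(x, "scheme"),
      "| species:", attr(x, "species_id"),
      if (!is.na(attr(x, "replicate_id")))
        paste("| replicate", attr(x, "replicate_id")) else "", "\n")
  invisible(x)
}

#' Random background pseudo-absences
#'
#' Draws `n` points uniformly over the land cells of the grid (cell drawn
#' uniformly with replacement, point jittered uniformly within the cell).
#' This is the background design used for the regression-family algorithms
#' (GLM, GAM), with a default of 10,000 points drawn once per species.
#'
#' @param stack a [climate_stack] with at least one land cell.
#' @param n number of points.
#' @param seed integer RNG seed.
#' @param species_id label for bookkeeping.
#' @return a `pa_set` (data.frame of `lon`, `lat` with scheme attributes).
#' @export
sample_random_pa <- function(stack, n = 10000, seed = 1,
                             species_id = NA_character_) {
  stopifnot(inherits(stack, "climate_stack"), n >= 1)
  cells <- land_cells(stack)
  if (nrow(cells) == 0L) stop("no unmasked cells to sample from")
  with_seed(seed, {
    k <- sample.int(nrow(cells), n, replace = TRUE)
    res <- stack$resolution
    new_pa_set(cells$lon[k] - res / 2 + stats::runif(n) * res,
               cells$lat[k] + res / 2 - stats::runif(n) * res,
               "random_10k", species_id)
  })
}

#' Exclusion-radius pseudo-absences
#'
#' For the machine-learning algorithms (BRT, RF): per replicate, draws as
#' many pseudo-absences as the species has cleaned occurrences, uniformly
#' from the land cells lying outside an exclusion radius around every
#' occurrence.  Cell eligibility is judged at cell centers with an effective
#' threshold of `exclusion_km` plus half the cell diagonal, so that the
#' jittered point can never fall inside the true radius.  Replicates use
#' distinct sub-seeds derived from `seed`; the whole draw is deterministic
#' given `seed`.  Cells are drawn without replacement when enough are
#' eligible, with replacement otherwise (recorded in attribute
#' `with_replacement`).
#'
#' @param occ cleaned [occurrence_table] of a single species.
#' @param stack a [climate_stack].
#' @param exclusion_km exclusion radius in km (default 200).
#' @param replicates number of independent sets (default 10).
#' @param seed integer RNG seed.
#' @return list of `pa_set`, one per replicate, each with `nrow(occ)` points.
#' @export
sample_exclusion_pa <- function(occ, stack, exclusion_km = 200,
                                replicates = 10, seed = 1) {
  stopifnot(inherits(occ, "occurrence_table"), inherits(stack, "climate_stack"))
  if (!isTRUE(attr(occ, "cleaned")))
    stop("exclusion-scheme pseudo-absences require cleaned occurrences")
  sp <- unique(occ$species_id)
  if (length(sp) != 1L)
    stop("expected occurrences of a single species, found: ",
         paste(sp, collapse = ", "))
  n <- nrow(occ)
  if (n == 0L) stop("no occurrences for species '", sp, "'")
  cells <- land_cells(stack)
  ## min distance from each land-cell center to any occurrence
  dmin <- rep(Inf, nrow(cells))
  for (i in seq_len(n)) {
    d <- great_circle_km(cells$lon, cells$lat, occ$lon[i], occ$lat[i])
    dmin <- pmin(dmin, d)
  }
  res <- stack$resolution
  half_diag <- 0.5 * sqrt((res * 111.19 * cos(cells$lat * pi / 180))^2 +
                            (res * 111.19)^2)
  eligible <- which(dmin > exclusion_km + half_diag)
  if (length(eligible) == 0L)
    stop("no cells beyond the ", exclusion_km,
         " km exclusion radius for species '", sp, "'")
  with_replacement <- length(eligible) < n
  lapply(seq_len(replicates), function(r) {
    with_seed(sub_seed(seed, r), {
      k <- eligible[sample.int(length(eligible), n,
                               replace = with_replacement)]
      ps <- new_pa_set(cells$lon[k] - res / 2 + stats::runif(n) * res,
                       cells$lat[k] + res / 2 - stats::runif(n) * res,
                       "exclusion_radius", sp, r)
      attr(ps, "with_replacement") <- with_replacement
      ps
    })
  })
}

#' Presence/pseudo-absence case weights
#'
#' Returns weights such that the weighted sum of presences equals the
#' weighted sum of pseudo-absences: the presence weight is fixed at 1 and
#' the pseudo-absence weight is `n_presence / n_pa`, so
#' `n_p * w_p == n_a * w_a` exactly.
#'
#' @param n_presence,n_pa positive counts.
#' @return an object of class `case_weights` with fields `w_p`, `w_a`.
#' @export
compute_weights <- function(n_presence, n_pa) {
  if (n_presence < 1 || n_pa < 1) stop("both counts must be >= 1")
  structure(list(w_p = 1, w_a = n_presence / n_pa), class = "case_weights")
}

#' Export a pseudo-absence set in occurrence-CSV layout
#'
#' @param pa a `pa_set` or list of them.
#' @param path file path; columns `species_id, lon, lat, scheme, replicate`.
#' @export
write_pa <- function(pa, path) {
  if (inherits(pa, "pa_set")) pa <- list(pa)
  rows <- lapply(pa, function(p)
    data.frame(species_id = attr(p, "species_id"), lon = p$lon, lat = p$lat,
               scheme = attr(p, "scheme"), replicate = attr(p, "replicate_id")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
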