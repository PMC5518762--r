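#' Pairwise range overlap from binary maps
#'
#' Overlap between the consensus ranges of a garden plant and a congener is
#' scored two ways over the unmasked-land universe: by the TSS of the
#' confusion matrix with the congener map as the reference (`a` = both
#' suitable, `b` = garden only, `c` = congener only, `d` = neither;
#' `TSS = a/(a+c) + d/(b+d) - 1`), and by the plain count of cells suitable
#' to both.  The TSS orientation matters (the numerator is symmetric, the
#' margins are not): the package convention is congener = reference,
#' garden = prediction; `symmetrize = TRUE` averages both orientations for
#' sensitivity runs.
#'
#' @param garden,congener [binary_map]s on the same grid.
#' @param symmetrize average the two orientations of the TSS.
#' @return `overlap_tss()`: TSS in `[-1, 1]` (errors when a reference
#'   margin is empty); `overlap_cells()`: non-negative cell count;
#'   `range_size()`: count of suitable unmasked cells of one map.
#' @export
overlap_tss <- function(garden, congener, symmetrize = FALSE) {
  cm <- overlap_confusion(garden, congener)
  val <- tss(cm["a"], cm["b"], cm["c"], cm["d"])
  if (symmetrize)
    val <- (val + tss(cm["a"], cm["c"], cm["b"], cm["d"])) / 2
  unname(val)
}

overlap_confusion <- function(garden, congener) {
  stopifnot(inherits(garden, "binary_map"), inherits(congener, "binary_map"))
  if (!same_grid(garden, congener)) stop("overlap inputs on different grids")
  g <- garden$values[garden$mask]
  r <- congener$values[congener$mask]
  c(a = sum(g == 1 & r == 1), b = sum(g == 1 & r == 0),
    c = sum(g == 0 & r == 1), d = sum(g == 0 & r == 0))
}

#' @rdname overlap_tss
#' @export
overlap_cells <- function(garden, congener) {
  cm <- overlap_confusion(garden, congener)
  unname(cm["a"])
}

#' @rdname overlap_tss
#' @param map a [binary_map].
#' @export
range_size <- function(map) {
  stopifnot(inherits(map, "binary_map"))
  sum(map$values[map$mask] == 1)
}

#' All garden-congener pair overlaps under one scenario
#'
#' Forms every (garden plant, congener) pair within the same genus and life
#' form and scores both overlap metrics from the species' consensus maps.
#' Pairs whose TSS is undefined (a map all-suitable or all-unsuitable over
#' land) are excluded and reported in the `"excluded"` attribute.
#'
#' @param maps named list of consensus [binary_map]s, one per species.
#' @param taxa a [taxon_table].
#' @param scenario_id label recorded in the output.
#' @return data.frame of class `pair_overlap` with one row per valid pair:
#'   `garden_id`, `congener_id`, `genus`, `scenario_id`, `tss_overlap`,
#'   `n_overlap_cells`, `garden_range_cells`, `congener_range_cells`.
#' @export
pair_overlaps <- function(maps, taxa, scenario_id) {
  stopifnot(inherits(taxa, "taxon_table"))
  gardens <- taxa[taxa$group == "garden" & taxa$species_id %in% names(maps), ]
  congs <- taxa[taxa$group == "congener" & taxa$species_id %in% names(maps), ]
  rows <- list(); excluded <- list()
  for (i in seq_len(nrow(gardens))) {
    gid <- gardens$species_id[i]
    partners <- congs[congs$genus == gardens$genus[i] &
                        congs$life_form == gardens$life_form[i], ]
    for (cid in partners$species_id) {
      rec <- tryCatch(
        data.frame(garden_id = gid, congener_id = cid,
                   genus = gardens$genus[i], scenario_id = scenario_id,
                   tss_overlap = overlap_tss(maps[[gid]], maps[[cid]]),
                   n_overlap_cells = overlap_cells(maps[[gid]], maps[[cid]]),
                   garden_range_cells = range_size(maps[[gid]]),
                   congener_range_cells = range_size(maps[[cid]])),
        error = function(e)
          data.frame(garden_id = gid, congener_id = cid,
                     reason = conditionMessage(e)))
      if ("reason" %in% names(rec)) excluded[[length(excluded) + 1L]] <- rec
      else rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(garden_id = character(), congener_id = character(),
               genus = character(), scenario_id = character(),
               tss_overlap = numeric(), n_overlap_cells = numeric(),
               garden_range_cells = numeric(), congener_range_cells = numeric())
  structure(out, excluded = if (length(excluded)) do.call(rbind, excluded)
            else NULL,
            class = c("pair_overlap", "data.frame"))
}

#' Average overlap per garden plant
#'
#' Unweighted arithmetic means of both overlap metrics over all congeners
#' of each garden plant, separately per scenario; `n_congeners` counts the
#' valid (non-excluded) pairs behind each mean.
#'
#' @param pairs a [pair_overlaps()] result (possibly several row-bound).
#' @return data.frame with one row per (garden plant, scenario):
#'   `garden_id`, `genus`, `scenario_id`, `mean_tss_overlap`,
#'   `mean_overlap_cells`, `n_congeners`.
#' @export
summarize_per_garden <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(garden_id = character(), genus = character(),
                      scenario_id = character(), mean_tss_overlap = numeric(),
                      mean_overlap_cells = numeric(), n_congeners = integer()))
  key <- interaction(pairs$garden_id, pairs$scenario_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(pairs, key), function(d)
    data.frame(garden_id = d$garden_id[1], genus = d$genus[1],
               scenario_id = d$scenario_id[1],
               mean_tss_overlap = mean(d$tss_overlap),
               mean_overlap_cells = mean(d$n_overlap_cells),
               n_congeners = nrow(d))))
  rownames(out) <- NULL
  out
}
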