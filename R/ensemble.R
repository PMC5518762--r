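#' TSS-weighted mean of suitability maps
#'
#' Cell-wise weighted mean `sum(w_i p_i) / sum(w_i)` with weights equal to
#' the members' mean split-sample TSS.  Members with non-positive TSS are
#' dropped with a warning (a negative weight has no meaning in a weighted
#' mean); if no positive-weight member remains this is an error.
#'
#' @param maps list of [suitability_map]s on a common grid.
#' @param tss_scores numeric vector of member weights (mean TSS).
#' @return a [suitability_map].
#' @export
ensemble_weighted_mean <- function(maps, tss_scores) {
  stopifnot(length(maps) >= 1, length(maps) == length(tss_scores))
  drop <- tss_scores <= 0
  if (any(drop)) {
    warning(sum(drop), " ensemble member(s) with TSS <= 0 dropped")
    maps <- maps[!drop]; tss_scores <- tss_scores[!drop]
  }
  if (length(maps) == 0L || sum(tss_scores) <= 0)
    stop("no ensemble member with positive TSS weight")
  for (m in maps[-1])
    if (!same_grid(maps[[1]], m)) stop("ensemble members on different grids")
  acc <- maps[[1]]$values * tss_scores[1]
  if (length(maps) > 1)
    for (i in 2:length(maps)) acc <- acc + maps[[i]]$values * tss_scores[i]
  out <- maps[[1]]
  out$values <- acc / sum(tss_scores)
  out
}

#' Conservative consensus of the two family binaries
#'
#' A cell is classed climatically suitable only if both the regression and
#' the machine-learning ensemble binaries agree (cell-wise AND).
#'
#' @param reg,ml [binary_map]s on the same grid.
#' @return a [binary_map] (the consensus).
#' @export
consensus_binary <- function(reg, ml) {
  stopifnot(inherits(reg, "binary_map"), inherits(ml, "binary_map"))
  if (!same_grid(reg, ml)) stop("consensus inputs are on different grids")
  out <- reg
  out$values <- reg$values * ml$values
  out$threshold <- NA_real_
  out
}

## ensemble probability of a member set at given predictor rows (internal):
## TSS-weighted mean of per-member predictions, after dropping TSS <= 0
member_ensemble_probs <- function(fits, x) {
  wts <- vapply(fits, function(f) f$mean_tss, numeric(1))
  keep <- wts > 0
  if (!any(keep)) stop("no ensemble member with positive TSS weight")
  fits <- fits[keep]; wts <- wts[keep]
  acc <- 0
  for (i in seq_along(fits)) acc <- acc + wts[i] * predict(fits[[i]], x)
  acc / sum(wts)
}

#' Fit the full four-algorithm design for one species
#'
#' Runs the whole calibration stage of the workflow for a single species:
#' draws the 10,000-point random background once and fits GLM and GAM on it
#' (regression family); draws the exclusion-radius pseudo-absences in
#' `ml_replicates` independent sets and fits BRT and RF on each
#' (machine-learning family, `2 x ml_replicates` members); evaluates every
#' member by repeated split-sample TSS; and computes the per-family
#' TSS-maximizing thresholds on the family's pooled calibration data
#' (ensemble probabilities at the calibration points, case-weighted).
#' Thresholds are fixed at calibration and reused for every scenario
#' projection.
#'
#' @param occ cleaned [occurrence_table] of the species.
#' @param stack the baseline [climate_stack].
#' @param settings an [sdm_settings] list.
#' @param seed integer RNG seed.
#' @return an object of class `sdm_species`: fields `species_id`, `fits`
#'   (list of [fit_full()] results), `thresholds` (per family) and
#'   `eval_table` (one row per member with its split TSS scores).
#' @export
fit_species_sdm <- function(occ, stack, settings = sdm_settings(), seed = 1) {
  stopifnot(inherits(occ, "occurrence_table"))
  if (!isTRUE(attr(occ, "cleaned"))) stop("occurrences must be cleaned first")
  sp <- unique(occ$species_id)
  stopifnot(length(sp) == 1L)

  reg_pa <- sample_random_pa(stack, n = settings$n_random_pa,
                             seed = sub_seed(seed, 1), species_id = sp)
  reg_train <- training_set(occ, reg_pa, stack)
  ml_pa <- sample_exclusion_pa(occ, stack,
                               exclusion_km = settings$exclusion_km,
                               replicates = settings$ml_replicates,
                               seed = sub_seed(seed, 2))
  ml_trains <- lapply(ml_pa, function(pa) training_set(occ, pa, stack))

  fits <- list()
  k <- 0L
  for (alg in c("GLM", "GAM")) {
    k <- k + 1L
    fits[[k]] <- fit_full(reg_train, alg, settings,
                          seed = sub_seed(seed, 100 + k))
  }
  for (alg in c("BRT", "RF")) for (r in seq_along(ml_trains)) {
    k <- k + 1L
    fits[[k]] <- fit_full(ml_trains[[r]], alg, settings,
                          seed = sub_seed(seed, 100 + k))
  }

  family_threshold <- function(fam_fits, trains) {
    x <- do.call(rbind, lapply(trains, `[[`, "x"))
    y <- unlist(lapply(trains, `[[`, "y"))
    w <- unlist(lapply(trains, `[[`, "w"))
    p <- member_ensemble_probs(fam_fits, x)
    as.numeric(maxtss_threshold(p, y, w))
  }
  fams <- vapply(fits, `[[`, character(1), "family")
  thresholds <- c(
    regression = family_threshold(fits[fams == "regression"],
                                  list(reg_train)),
    machine_learning = family_threshold(fits[fams == "machine_learning"],
                                        ml_trains))

  eval_table <- do.call(rbind, lapply(fits, function(f)
    data.frame(species_id = f$species_id, algorithm = f$algorithm,
               family = f$family, replicate = f$replicate_id,
               split = seq_along(f$eval_tss), tss = f$eval_tss)))

  structure(list(species_id = sp, fits = fits, thresholds = thresholds,
                 eval_table = eval_table, settings = settings, seed = seed),
            class = "sdm_species")
}

#' @export
print.sdm_species <- function(x, ...) {
  fams <- vapply(x$fits, `[[`, character(1), "family")
  mtss <- vapply(x$fits, `[[`, numeric(1), "mean_tss")
  cat("sdm_species:", x$species_id, "|", length(x$fits), "members (",
      sum(fams == "regression"), "regression,",
      sum(fams == "machine_learning"), "machine-learning )\n")
  cat("  mean member TSS:", round(mean(mtss), 3),
      "| thresholds: reg", round(x$thresholds["regression"], 3),
      "/ ml", round(x$thresholds["machine_learning"], 3), "\n")
  invisible(x)
}

#' Build the two family ensembles on a grid
#'
#' Projects every member over the stack, aggregates each family to its
#' TSS-weighted mean map, binarizes at the family's stored maxTSS threshold
#' and returns both ensemble results.
#'
#' @param species_fit an [fit_species_sdm()] result.
#' @param stack a [climate_stack] (baseline or scenario-shifted).
#' @return named list of two `ensemble_result`s (`regression`,
#'   `machine_learning`), each with `mean_map`, `threshold`, `binary`.
#' @export
build_family_ensembles <- function(species_fit, stack) {
  stopifnot(inherits(species_fit, "sdm_species"))
  fams <- vapply(species_fit$fits, `[[`, character(1), "family")
  out <- lapply(c(regression = "regression",
                  machine_learning = "machine_learning"), function(fam) {
    members <- species_fit$fits[fams == fam]
    maps <- lapply(members, project, stack = stack)
    wts <- vapply(members, `[[`, numeric(1), "mean_tss")
    mean_map <- ensemble_weighted_mean(maps, wts)
    thr <- species_fit$thresholds[[fam]]
    bin <- binarize(mean_map, thr)
    bin$species_id <- mean_map$species_id <- species_fit$species_id
    structure(list(family = fam, mean_map = mean_map, threshold = thr,
                   binary = bin), class = "ensemble_result")
  })
  out
}

#' Project a species' consensus map under one scenario
#'
#' Convenience wrapper: builds both family ensembles on the stack and
#' returns their conservative consensus together with the family results.
#'
#' @inheritParams build_family_ensembles
#' @return list with elements `consensus` (a [binary_map]), `regression`
#'   and `machine_learning` (the `ensemble_result`s).
#' @export
project_species <- function(species_fit, stack) {
  ens <- build_family_ensembles(species_fit, stack)
  cons <- consensus_binary(ens$regression$binary, ens$machine_learning$binary)
  cons$species_id <- species_fit$species_id
  list(consensus = cons, regression = ens$regression,
       machine_learning = ens$machine_learning)
}
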