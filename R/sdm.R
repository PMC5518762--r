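#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1 = a/(a+c) + d/(b+d) - 1`, where `a`
#' = true positives, `b` = false positives, `c` = false negatives, `d` =
#' true negatives.  Bounded in `[-1, 1]`; insensitive to prevalence.  Both
#' margins must be non-empty; an empty margin is an error, never a silent
#' `NaN`.
#'
#' @param a,b,c,d confusion-matrix counts (or weighted counts).
#' @return the TSS value.
#' @export
#' @examples
#' tss(50, 0, 0, 50)   #  1: perfect agreement
#' tss(0, 50, 50, 0)   # -1: perfect disagreement
tss <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("confusion counts must be non-negative")
  if ((a + c) <= 0) stop("undefined TSS: no positives in the reference (a + c = 0)")
  if ((b + d) <= 0) stop("undefined TSS: no negatives in the reference (b + d = 0)")
  a / (a + c) + d / (b + d) - 1
}

#' Threshold maximizing the TSS
#'
#' Scans the observed unique predicted probabilities as the candidate
#' threshold set (prediction is "suitable" when `p >= threshold`), computes
#' the (optionally case-weighted) TSS at each candidate, and returns the
#' smallest candidate achieving the maximum.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 observed labels.
#' @param weights optional case weights (default: all 1).
#' @return the threshold, with the achieved TSS in attribute `"tss"`.
#' @export
maxtss_threshold <- function(probs, labels, weights = NULL) {
  stopifnot(length(probs) == length(labels))
  if (is.null(weights)) weights <- rep(1, length(probs))
  wp <- sum(weights[labels == 1]); wn <- sum(weights[labels == 0])
  if (wp <= 0 || wn <= 0)
    stop("degenerate labels: both classes must be present")
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]; y <- labels[ord]; w <- weights[ord]
  cum_pos <- cumsum(w * (y == 1))
  cum_neg <- cumsum(w * (y == 0))
  ## last index of each run of equal probabilities = all rows with p >= that value
  last <- which(p != c(p[-1], NA) | seq_along(p) == length(p))
  tss_vals <- cum_pos[last] / wp + (wn - cum_neg[last]) / wn - 1
  cand <- p[last]
  best <- max(tss_vals)
  thr <- min(cand[tss_vals >= best - 1e-12])
  structure(thr, tss = best)
}

#' Assemble an SDM training set
#'
#' Extracts the climate-layer values at the grid cells of the presences and
#' pseudo-absences, attaches the 0/1 response and the case weights that make
#' the weighted sums of the two classes equal.  Rows with any missing
#' predictor (points on masked cells) are dropped and counted.
#'
#' @param occ cleaned [occurrence_table] of one species.
#' @param pa a `pa_set` from [sample_random_pa()] or [sample_exclusion_pa()].
#' @param stack the [climate_stack] supplying the predictors.
#' @return a list of class `training_set` with elements `x` (matrix), `y`,
#'   `w`, `species_id`, `scheme`, `replicate_id`, `n_dropped`.
#' @export
training_set <- function(occ, pa, stack) {
  stopifnot(inherits(occ, "occurrence_table"), inherits(pa, "pa_set"),
            inherits(stack, "climate_stack"))
  pres_cells <- cell_of(occ$lon, occ$lat, stack)
  pa_cells <- cell_of(pa$lon, pa$lat, stack)
  x <- rbind(stack_values(stack, pres_cells$row, pres_cells$col),
             stack_values(stack, pa_cells$row, pa_cells$col))
  y <- c(rep(1, nrow(occ)), rep(0, nrow(pa)))
  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  cw <- compute_weights(sum(y == 1), sum(y == 0))
  w <- ifelse(y == 1, cw$w_p, cw$w_a)
  structure(list(x = x, y = y, w = w,
                 species_id = unique(occ$species_id)[1],
                 scheme = attr(pa, "scheme"),
                 replicate_id = attr(pa, "replicate_id"),
                 n_dropped = n_dropped),
            class = "training_set")
}

## stratified calibration/evaluation split of a training set; weights are
## recomputed inside each part so the weighted class sums stay equal
split_training <- function(train, calib_frac) {
  pos <- which(train$y == 1); neg <- which(train$y == 0)
  cal <- c(sample(pos, max(1L, floor(calib_frac * length(pos)))),
           sample(neg, max(1L, floor(calib_frac * length(neg)))))
  ev <- setdiff(seq_along(train$y), cal)
  part <- function(idx) {
    y <- train$y[idx]
    if (length(unique(y)) < 2L) return(NULL)
    cw <- compute_weights(sum(y == 1), sum(y == 0))
    list(x = train$x[idx, , drop = FALSE], y = y,
         w = ifelse(y == 1, cw$w_p, cw$w_a))
  }
  list(calib = part(cal), eval = part(ev))
}

#' Repeated split-sample evaluation by TSS
#'
#' Repeats (default three times): stratified 80/20 split of the training
#' set, fit on the calibration part, predict the held-out part, binarize at
#' the TSS-maximizing threshold found on the held-out predictions, and
#' record the (case-weighted) TSS.  A split leaving a part single-class is
#' redrawn with the next sub-seed (at most 10 attempts).  Deterministic
#' given `seed`.
#'
#' @param train a [training_set].
#' @param algorithm `"GLM"`, `"GAM"`, `"BRT"` or `"RF"`.
#' @param reps,calib_frac evaluation design (default 3 times 80/20).
#' @param seed integer RNG seed.
#' @param settings an [sdm_settings] list.
#' @return numeric vector of `reps` TSS scores.
#' @export
split_sample_eval <- function(train, algorithm, reps = 3, calib_frac = 0.8,
                              seed = 1, settings = sdm_settings()) {
  stopifnot(inherits(train, "training_set"))
  vapply(seq_len(reps), function(r) {
    for (attempt in 0:10) {
      sp <- with_seed(sub_seed(seed, 13 * r + 1000 * attempt),
                      split_training(train, calib_frac))
      if (!is.null(sp$calib) && !is.null(sp$eval)) {
        fit <- fit_algorithm(algorithm, sp$calib$x, sp$calib$y, sp$calib$w,
                             settings, seed = sub_seed(seed, 17 * r + 3))
        pred <- predict_algorithm(fit, sp$eval$x)
        thr <- maxtss_threshold(pred, sp$eval$y, sp$eval$w)
        return(as.numeric(attr(thr, "tss")))
      }
    }
    stop("could not obtain a two-class 80/20 split after 10 attempts")
  }, numeric(1))
}

#' Fit one SDM on the full training set
#'
#' Refits the algorithm on every row with the case weights, attaching the
#' split-sample TSS scores.  The resulting `sdm_fit` predicts a probability
#' in `[0, 1]` for any climate vector and can be projected over a grid with
#' [project()].
#'
#' @param train a [training_set].
#' @param algorithm `"GLM"`, `"GAM"`, `"BRT"` or `"RF"`.
#' @param settings an [sdm_settings] list.
#' @param seed integer RNG seed (used by the stochastic tree learners).
#' @param eval_tss optional precomputed split-sample scores; computed via
#'   [split_sample_eval()] when `NULL`.
#' @return an object of class `sdm_fit` with fields `algorithm`, `family`,
#'   `eval_tss`, `mean_tss`, `species_id`, `replicate_id`.
#' @export
fit_full <- function(train, algorithm, settings = sdm_settings(), seed = 1,
                     eval_tss = NULL) {
  stopifnot(inherits(train, "training_set"))
  algorithm <- match.arg(algorithm, c("GLM", "GAM", "BRT", "RF"))
  if (is.null(eval_tss))
    eval_tss <- split_sample_eval(train, algorithm, reps = settings$eval_reps,
                                  calib_frac = settings$calib_frac,
                                  seed = sub_seed(seed, 7),
                                  settings = settings)
  fit <- tryCatch(
    fit_algorithm(algorithm, train$x, train$y, train$w, settings,
                  seed = sub_seed(seed, 11)),
    error = function(e) stop(algorithm, " fit failed for species '",
                             train$species_id, "': ", conditionMessage(e)))
  structure(list(algorithm = algorithm, family = algorithm_family(algorithm),
                 fit = fit, vars = colnames(train$x),
                 eval_tss = eval_tss, mean_tss = mean(eval_tss),
                 species_id = train$species_id,
                 replicate_id = train$replicate_id,
                 scheme = train$scheme),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat("sdm_fit:", x$algorithm, "(", x$family, ") | species:", x$species_id,
      if (!is.na(x$replicate_id)) paste("| PA replicate", x$replicate_id) else "",
      "\n  split-sample TSS:", paste(round(x$eval_tss, 3), collapse = ", "),
      "| mean:", round(x$mean_tss, 3), "\n")
  invisible(x)
}

#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[, object$vars])
  predict_algorithm(object$fit, newdata)
}

#' Project a fitted SDM over a climate grid
#'
#' Evaluates the fitted probability surface on every unmasked cell of the
#' stack (current or scenario-shifted climate); masked cells stay no-data.
#'
#' @param fit an [sdm_fit].
#' @param stack a [climate_stack] containing every training variable.
#' @return a [suitability_map].
#' @export
project <- function(fit, stack) {
  stopifnot(inherits(fit, "sdm_fit"), inherits(stack, "climate_stack"))
  miss <- setdiff(fit$vars, names(stack$layers))
  if (length(miss))
    stop("stack lacks training variable(s): ", paste(miss, collapse = ", "))
  cells <- land_cells(stack)
  x <- stack_values(stack, cells$row, cells$col)
  p <- predict_algorithm(fit$fit, x)
  v <- matrix(NA_real_, nrow(stack$mask), ncol(stack$mask))
  v[cbind(cells$row, cells$col)] <- p
  suitability_map(v, stack, species_id = fit$species_id)
}
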