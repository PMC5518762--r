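## Algorithm layer for the four SDMs.  GLM (linear + quadratic terms) and
## GAM (thin-plate smooths) come from stats/mgcv; BRT and RF are built on
## the package's compiled weighted CART learner because no tree-ensemble
## package is available in the target environment.

#' SDM workflow settings
#'
#' Collects the tunable knobs of the model-fitting stage.  Defaults follow
#' common SDM practice: 10,000 random background points for the regression
#' family, occurrence-matched exclusion-radius pseudo-absences (200 km,
#' 10 replicates) for the machine-learning family, three 80/20 split-sample
#' evaluations, and library-default-like tree hyperparameters.
#'
#' @param n_random_pa random background points for GLM/GAM.
#' @param exclusion_km,ml_replicates exclusion radius (km) and number of
#'   pseudo-absence replicates for BRT/RF.
#' @param eval_reps,calib_frac split-sample evaluation design.
#' @param gam_k basis dimension of each GAM smooth.
#' @param rf_trees,rf_mtry,rf_max_depth,rf_min_obs random-forest knobs
#'   (`rf_mtry = NULL` means `floor(sqrt(p))`).
#' @param brt_trees,brt_shrinkage,brt_depth,brt_min_obs,brt_bag boosting
#'   knobs (trees, learning rate, interaction depth, minimum leaf size,
#'   bag fraction).
#' @return a list of class `sdm_settings`.
#' @export
sdm_settings <- function(n_random_pa = 10000, exclusion_km = 200,
                         ml_replicates = 10, eval_reps = 3, calib_frac = 0.8,
                         gam_k = 4,
                         rf_trees = 100, rf_mtry = NULL, rf_max_depth = 12,
                         rf_min_obs = 5,
                         brt_trees = 100, brt_shrinkage = 0.1, brt_depth = 3,
                         brt_min_obs = 10, brt_bag = 0.75) {
  structure(as.list(environment()), class = "sdm_settings")
}

#' @export
print.sdm_settings <- function(x, ...) {
  cat("sdm_settings:\n")
  for (nm in names(x)) cat(" ", nm, "=",
                           if (is.null(x[[nm]])) "auto" else x[[nm]], "\n")
  invisible(x)
}

#' Algorithm families
#'
#' GLM and GAM form the regression family; BRT and RF the machine-learning
#' family.  The two families are ensembled separately and only their
#' agreement enters the consensus map.
#'
#' @param algorithm one of `"GLM"`, `"GAM"`, `"BRT"`, `"RF"`.
#' @return `"regression"` or `"machine_learning"`.
#' @export
algorithm_family <- function(algorithm) {
  switch(match.arg(algorithm, c("GLM", "GAM", "BRT", "RF")),
         GLM = "regression", GAM = "regression",
         BRT = "machine_learning", RF = "machine_learning")
}

## fit one algorithm on a numeric predictor matrix; returns an internal
## model object understood by predict_algorithm()
fit_algorithm <- function(algorithm, x, y, w, settings, seed = NULL) {
  vars <- colnames(x)
  model <- switch(
    algorithm,
    GLM = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rhs <- paste(c(vars, sprintf("I(`%s`^2)", vars)), collapse = " + ")
      fml <- stats::as.formula(paste(".y ~", rhs))
      ## non-integer weighted binomial counts warn harmlessly
      fit <- suppressWarnings(
        stats::glm(fml, family = stats::binomial(), data = df, weights = w,
                   control = stats::glm.control(maxit = 100)))
      ## complete separation drives coefficients to infinity without formal
      ## convergence but the fitted classifier is perfectly usable
      separated <- all(fit$fitted.values > 0.999 | fit$fitted.values < 0.001)
      if (!fit$converged && !separated) stop("GLM did not converge")
      fit
    },
    GAM = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      k <- settings$gam_k
      rhs <- paste(sprintf("s(`%s`, k = %d)", vars, k), collapse = " + ")
      fml <- stats::as.formula(paste(".y ~", rhs))
      ## bam(discrete) for large backgrounds: same model, much faster
      fit <- suppressWarnings(
        if (length(y) > 4000)
          mgcv::bam(fml, family = stats::binomial(), data = df, weights = w,
                    discrete = TRUE)
        else
          mgcv::gam(fml, family = stats::binomial(), data = df, weights = w))
      if (!fit$converged) stop("GAM did not converge")
      fit
    },
    RF = with_seed(seed, {
      mtry <- if (is.null(settings$rf_mtry)) max(1L, floor(sqrt(ncol(x))))
      else settings$rf_mtry
      .rf_grow(x, y, w, settings$rf_trees, mtry,
               settings$rf_max_depth, settings$rf_min_obs)
    }),
    BRT = with_seed(seed, {
      .brt_grow(x, y, w, settings$brt_trees, settings$brt_shrinkage,
                settings$brt_depth, settings$brt_min_obs, settings$brt_bag)
    }),
    stop("unknown algorithm: ", algorithm))
  structure(list(algorithm = algorithm, model = model, vars = vars),
            class = "sdm_algorithm_fit")
}

## probabilities in [0,1] for new predictor rows
predict_algorithm <- function(fit, x) {
  x <- x[, fit$vars, drop = FALSE]
  p <- switch(
    fit$algorithm,
    GLM = stats::predict(fit$model,
                         newdata = as.data.frame(x, check.names = FALSE),
                         type = "response"),
    GAM = as.numeric(stats::predict(fit$model,
                                    newdata = as.data.frame(x, check.names = FALSE),
                                    type = "response")),
    RF = .forest_predict(fit$model, as.matrix(x)),
    BRT = .brt_predict(fit$model, as.matrix(x)))
  pmin(pmax(as.numeric(p), 0), 1)
}
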