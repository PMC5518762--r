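#' Log ratio of a metric under scenario change
#'
#' Natural logarithm of `future / current`; positive values mean an
#' increase under the scenario, negative a decrease.  Both inputs must be
#' strictly positive — zero or negative metrics cannot enter a log ratio
#' and must be excluded (and counted) by the caller; this function refuses
#' them rather than returning NaN silently.
#'
#' @param current,future metric values under the baseline and the scenario.
#' @return `log(future / current)` (vectorized).
#' @export
#' @examples
#' log_ratio(10, 20)   # log 2
log_ratio <- function(current, future) {
  if (any(!is.finite(current)) || any(!is.finite(future)) ||
      any(current <= 0) || any(future <= 0))
    stop("log_ratio needs strictly positive, finite inputs; ",
         "exclude zero-metric records upstream")
  log(future / current)
}

#' Build change records from per-garden summaries
#'
#' Joins the baseline and one future scenario's per-garden summaries and
#' computes the log ratio of the chosen metric.  Records with a
#' non-positive metric in either period are excluded and counted, so
#' `n_input = n_used + n_excluded` always holds.
#'
#' @param summaries data.frame from [summarize_per_garden()] covering the
#'   baseline and the future scenario (row-bound).
#' @param scenario_id the future scenario label.
#' @param metric column to compare (`"mean_overlap_cells"` or
#'   `"mean_tss_overlap"`).
#' @param base_scenario baseline label (default `"BASE"`).
#' @return data.frame of class `change_records` with columns `garden_id`,
#'   `genus`, `scenario_id`, `metric`, `current`, `future`, `log_ratio`;
#'   attributes `n_input`, `n_excluded`.
#' @export
change_records <- function(summaries, scenario_id,
                           metric = "mean_overlap_cells",
                           base_scenario = "BASE") {
  stopifnot(metric %in% names(summaries))
  cur <- summaries[summaries$scenario_id == base_scenario, ]
  fut <- summaries[summaries$scenario_id == scenario_id, ]
  m <- merge(cur[, c("garden_id", "genus", metric)],
             fut[, c("garden_id", metric)],
             by = "garden_id", suffixes = c(".cur", ".fut"))
  cv <- m[[paste0(metric, ".cur")]]
  fv <- m[[paste0(metric, ".fut")]]
  ok <- is.finite(cv) & is.finite(fv) & cv > 0 & fv > 0
  out <- data.frame(garden_id = m$garden_id[ok], genus = m$genus[ok],
                    scenario_id = rep(scenario_id, sum(ok)),
                    metric = rep(metric, sum(ok)),
                    current = cv[ok], future = fv[ok],
                    log_ratio = log(fv[ok] / cv[ok]))
  structure(out, n_input = nrow(m), n_excluded = sum(!ok),
            class = c("change_records", "data.frame"))
}

#' Intercept-only linear mixed model with a genus random effect
#'
#' Fits `y_ij = mu + u_i + e_ij`, `u_i ~ N(0, sigma_g^2)`,
#' `e_ij ~ N(0, sigma^2)` by REML, where observations are per-garden-plant
#' log ratios and `i` indexes genus (a random intercept absorbs the fact
#' that some genera contribute several garden plants).  The null hypothesis
#' `mu = 0` (no systematic change under the scenario) is tested by a Wald
#' z-test; the 95% CI is `mu +/- 1.96 SE`.  A boundary fit
#' (`sigma_g^2 = 0`) is reported with `singular = TRUE`, not an error.
#'
#' @param records a [change_records] data.frame (or any data.frame with
#'   `log_ratio` and `genus` columns).
#' @return an object of class `lmm_intercept`: `intercept`, `se`,
#'   `p_value`, `ci` (95%), `var_genus`, `var_resid`, `n_obs`, `n_genera`,
#'   `singular`, plus the exclusion counts carried over from the records.
#' @export
lmm_intercept_test <- function(records) {
  stopifnot(all(c("log_ratio", "genus") %in% names(records)))
  y <- records$log_ratio
  genus <- factor(records$genus)
  if (length(y) < 3L) stop("need at least 3 observations")
  if (nlevels(genus) < 2L) stop("need at least 2 genera")
  est <- tryCatch(suppressWarnings({
    fit <- lme4::lmer(y ~ 1 + (1 | genus),
                      data = data.frame(y = y, genus = genus),
                      REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore", calc.derivs = FALSE))
    out <- list(est = unname(lme4::fixef(fit)[1]),
                se = sqrt(as.numeric(stats::vcov(fit)[1, 1])),
                vc = as.data.frame(lme4::VarCorr(fit)),
                singular = lme4::isSingular(fit))
    if (!is.finite(out$se)) stop("degenerate mixed fit")
    out
  }), error = function(e) e)
  if (inherits(est, "error")) {
    ## boundary cases (one observation per genus, or an exactly constant
    ## response) are unidentifiable for the mixed fit; report the
    ## zero-genus-variance boundary estimate, flagged
    lmfit <- stats::lm(y ~ 1)
    s_lm <- suppressWarnings(summary(lmfit))
    est <- list(est = unname(stats::coef(lmfit)[1]),
                se = unname(s_lm$coefficients[1, 2]),
                vc = NULL, singular = TRUE)
    var_genus <- 0
    var_resid <- s_lm$sigma^2
  } else {
    var_genus <- est$vc$vcov[est$vc$grp == "genus"]
    var_resid <- est$vc$vcov[est$vc$grp == "Residual"]
  }
  se <- est$se
  singular <- est$singular
  est <- est$est
  z <- est / se
  structure(list(intercept = est, se = se,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 ci = c(lower = est - 1.96 * se, upper = est + 1.96 * se),
                 var_genus = var_genus, var_resid = var_resid,
                 n_obs = length(y), n_genera = nlevels(genus),
                 singular = singular,
                 n_excluded = attr(records, "n_excluded")),
            class = "lmm_intercept")
}

#' @export
print.lmm_intercept <- function(x, ...) {
  cat("Intercept-only LMM (genus random effect), REML\n")
  cat(sprintf("  mu = %.4f  (SE %.4f, 95%% CI [%.4f, %.4f])\n",
              x$intercept, x$se, x$ci["lower"], x$ci["upper"]))
  cat(sprintf("  Wald test mu = 0: p = %.4g\n", x$p_value))
  cat(sprintf("  var(genus) = %.4g, var(resid) = %.4g%s\n",
              x$var_genus, x$var_resid,
              if (isTRUE(x$singular)) "  [boundary fit: genus variance ~ 0]"
              else ""))
  cat("  n =", x$n_obs, "garden plants in", x$n_genera, "genera",
      if (!is.null(x$n_excluded) && x$n_excluded > 0)
        paste0("(", x$n_excluded, " excluded: zero metric)") else "", "\n")
  invisible(x)
}

#' Headline summary tables across scenarios
#'
#' Condenses the pipeline outputs into the figure-analogue tables:
#' per-scenario mean and sd of the two per-garden overlap metrics
#' (`overlap_means`); per-scenario, per-group mean and sd of range size
#' (`range_by_group`); per-garden log ratios of overlap cells for each
#' future scenario (`log_ratios`); and one intercept LMM per future
#' scenario and overlap metric (`lmm`).
#'
#' @param summaries row-bound [summarize_per_garden()] output over all
#'   scenarios.
#' @param ranges data.frame with `species_id`, `group`, `scenario_id`,
#'   `range_cells` for every species and scenario.
#' @param taxa a [taxon_table].
#' @param base_scenario baseline scenario label.
#' @return a list of class `scenario_summary` with the four tables.
#' @export
scenario_summary <- function(summaries, ranges, taxa,
                             base_scenario = "BASE") {
  scen_order <- unique(summaries$scenario_id)
  future <- setdiff(scen_order, base_scenario)

  overlap_means <- do.call(rbind, lapply(scen_order, function(s) {
    d <- summaries[summaries$scenario_id == s, ]
    data.frame(scenario_id = s,
               mean_tss_overlap = mean(d$mean_tss_overlap),
               sd_tss_overlap = stats::sd(d$mean_tss_overlap),
               mean_overlap_cells = mean(d$mean_overlap_cells),
               sd_overlap_cells = stats::sd(d$mean_overlap_cells),
               n_garden = nrow(d))
  }))

  range_by_group <- do.call(rbind, lapply(scen_order, function(s) {
    do.call(rbind, lapply(c("garden", "congener"), function(g) {
      d <- ranges[ranges$scenario_id == s & ranges$group == g, ]
      data.frame(scenario_id = s, group = g,
                 mean_range_cells = mean(d$range_cells),
                 sd_range_cells = stats::sd(d$range_cells), n = nrow(d))
    }))
  }))

  records <- list(); lmm <- list()
  for (s in future) for (met in c("mean_overlap_cells", "mean_tss_overlap")) {
    rec <- change_records(summaries, s, metric = met,
                          base_scenario = base_scenario)
    records[[paste(s, met, sep = ".")]] <- rec
    lmm[[paste(s, met, sep = ".")]] <-
      tryCatch(lmm_intercept_test(rec), error = function(e) NULL)
  }
  log_ratios <- do.call(rbind, c(records, list(make.row.names = FALSE)))

  structure(list(overlap_means = overlap_means,
                 range_by_group = range_by_group,
                 log_ratios = log_ratios, lmm = lmm,
                 base_scenario = base_scenario),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("Per-scenario mean overlap (per garden plant):\n")
  print(x$overlap_means, row.names = FALSE, digits = 4)
  cat("\nRange size by group:\n")
  print(x$range_by_group, row.names = FALSE, digits = 4)
  cat("\nIntercept LMMs on log ratios (vs", x$base_scenario, "):\n")
  for (nm in names(x$lmm)) {
    cat("--", nm, "--\n")
    if (is.null(x$lmm[[nm]])) cat("  (not estimable)\n") else print(x$lmm[[nm]])
  }
  invisible(x)
}
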