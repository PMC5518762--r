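## Synthetic stand-ins for the gridded climate and presence-only occurrence
## data a real study would download: gradient-structured bioclimatic layers
## with a contiguous land mask, additive warming scenarios, and virtual
## species with known Gaussian niches so that every downstream stage can be
## validated against a known truth.

## run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## deterministic sub-seed derivation, kept below 2^31
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 65011 + 1) * 31013 + 977 * k) %% 2147483647L
}

## smooth Gaussian random field via separable kernel smoothing of white noise,
## rescaled to unit sd (edge-normalized)
smooth_field <- function(nr, nc, sigma = 4) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (d in -half:half) {
      i <- seq_len(n); j <- i + d
      ok <- j >= 1 & j <= n
      m[cbind(i[ok], j[ok])] <- k[d + half + 1]
    }
    m / rowSums(m)
  }
  s <- band(nr) %*% z %*% t(band(nc))
  s / stats::sd(s)
}

## largest 4-connected component of a logical matrix (BFS)
largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L; best <- 0L; best_lab <- 0L
  queue <- integer(nr * nc)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    qh <- 1L; qt <- 1L; queue[1L] <- start; lab[start] <- cur; size <- 1L
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
      for (nb in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                   if (cc > 1L) p - nr, if (cc < nc) p + nr)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur; qt <- qt + 1L; queue[qt] <- nb; size <- size + 1L
        }
      }
    }
    if (size > best) { best <- size; best_lab <- cur }
  }
  lab == best_lab
}

#' Generate a synthetic bioclimatic climate stack
#'
#' Builds the six default bioclimatic layers on a lon/lat grid: two
#' temperature layers (`BIO5`, max temperature of the warmest month;
#' `BIO6`, min temperature of the coldest month) with a dominant latitudinal
#' gradient, one temperature-seasonality layer (`BIO4`, increasing with
#' latitude), and three precipitation layers (`BIO16`, `BIO17`, `BIO18`)
#' with a longitudinal gradient, each plus smooth spatial noise.  A
#' contiguous land mask covering roughly 70--95% of cells is carved out of a
#' smooth random field.  Deterministic given `seed`.
#'
#' @param nrows,ncols grid size in cells (at least 10 each).
#' @param seed integer RNG seed.
#' @param resolution cell size in degrees; default 1/6 (10 arc-minutes).
#' @param origin south-west corner `c(lon, lat)` of the grid.
#' @param temp_noise_sd,precip_noise_sd standard deviation of the smooth
#'   spatial noise added to temperature (deg C) and precipitation (mm)
#'   layers; set to 0 for purely deterministic gradients.
#' @param water_frac fraction of cells initially carved out as water before
#'   the largest land component is kept.
#' @return a [climate_stack] with `scenario_id = "BASE"`.
#' @export
make_climate <- function(nrows = 100, ncols = 100, seed = 1,
                         resolution = 1 / 6, origin = c(0, 35),
                         temp_noise_sd = 0.8, precip_noise_sd = 30,
                         water_frac = 0.12) {
  stopifnot(nrows >= 10, ncols >= 10)
  with_seed(seed, {
    ext <- c(origin[1], origin[1] + ncols * resolution,
             origin[2], origin[2] + nrows * resolution)
    lat <- ext[4] - (seq_len(nrows) - 0.5) * resolution   # row 1 = north
    lon <- ext[1] + (seq_len(ncols) - 0.5) * resolution
    flat <- (lat - ext[3]) / (ext[4] - ext[3])            # 1 at north pole side
    flon <- (lon - ext[1]) / (ext[2] - ext[1])
    lat_g <- matrix(flat, nrows, ncols)                   # by row
    lon_g <- matrix(flon, nrows, ncols, byrow = TRUE)
    noise <- function(sd, sigma = 4)
      if (sd > 0) sd * smooth_field(nrows, ncols, sigma) else 0
    layers <- list(
      BIO4  = 450 + 350 * lat_g + noise(precip_noise_sd / 2),
      BIO5  = 36 - 26 * lat_g + noise(temp_noise_sd),
      BIO6  = 15 - 26 * lat_g + noise(temp_noise_sd),
      ## pmax(matrix, 0): keep the matrix first so dim is preserved
      BIO16 = pmax(950 - 600 * lon_g + noise(precip_noise_sd), 0),
      BIO17 = pmax(280 - 200 * lon_g + noise(precip_noise_sd / 2), 0),
      BIO18 = pmax(550 - 380 * lon_g + noise(precip_noise_sd), 0))
    wf <- water_frac
    repeat {
      field <- smooth_field(nrows, ncols, sigma = 8)
      land <- field > stats::quantile(field, wf)
      land <- largest_component(land)
      cover <- mean(land)
      if (cover >= 0.70 && cover <= 0.95) break
      wf <- if (cover < 0.70) wf / 2 else wf * 1.5
    }
    climate_stack(layers, ext, resolution, mask = land, scenario_id = "BASE")
  })
}

#' Virtual-species niches: Gaussian product suitability
#'
#' A `niche_spec` defines a known climatic niche as a product of Gaussian
#' response curves: `s(x) = s_max * exp(-sum_j (x_j - mu_j)^2 / (2 sigma_j^2))`,
#' where `mu` is the per-variable optimum and `sigma > 0` the breadth.
#' `true_suitability()` evaluates it on every unmasked cell, giving the
#' ground truth that SDM recovery is judged against.
#'
#' @param optimum named numeric vector of per-variable optima (layer units).
#' @param breadth named numeric vector of per-variable breadths (> 0).
#' @param s_max maximum suitability in (0, 1].
#' @return `niche_spec()`: an object of class `niche_spec`.
#' @export
niche_spec <- function(optimum, breadth, s_max = 1) {
  optimum <- unlist(optimum); breadth <- unlist(breadth)
  if (is.null(names(optimum)) || is.null(names(breadth)) ||
      !setequal(names(optimum), names(breadth)))
    stop("'optimum' and 'breadth' must be named over the same variables")
  breadth <- breadth[names(optimum)]
  if (any(breadth <= 0)) stop("niche breadths must be positive")
  if (s_max <= 0 || s_max > 1) stop("'s_max' must be in (0, 1]")
  structure(list(optimum = optimum, breadth = breadth, s_max = s_max),
            class = "niche_spec")
}

#' @rdname niche_spec
#' @param niche a `niche_spec`.
#' @param stack a [climate_stack] containing every niche variable.
#' @return `true_suitability()`: a [suitability_map].
#' @export
true_suitability <- function(niche, stack) {
  stopifnot(inherits(niche, "niche_spec"), inherits(stack, "climate_stack"))
  miss <- setdiff(names(niche$optimum), names(stack$layers))
  if (length(miss))
    stop("niche variables missing from stack: ", paste(miss, collapse = ", "))
  q <- 0
  for (v in names(niche$optimum))
    q <- q + ((stack$layers[[v]] - niche$optimum[[v]]) / niche$breadth[[v]])^2
  suitability_map(niche$s_max * exp(-q / 2), stack, species_id = "truth")
}

#' Sample presence-only occurrences from a known niche
#'
#' Draws `n_occ` records with cell probabilities proportional to the true
#' suitability over land (a multinomial draw with replacement, so duplicate
#' cells are possible pre-cleaning, as in aggregated occurrence databases),
#' then jitters one point uniformly inside each drawn cell.  Deterministic
#' given `seed`.
#'
#' @param niche a [niche_spec].
#' @param stack a [climate_stack].
#' @param n_occ number of records (>= 1); the study analogue keeps only
#'   species with more than 50 records, so realistic designs use >= 51.
#' @param seed integer RNG seed.
#' @param species_id label for the records.
#' @return an [occurrence_table] (raw, not cleaned).
#' @export
sample_occurrences <- function(niche, stack, n_occ = 300, seed = 1,
                               species_id = "virtual") {
  stopifnot(n_occ >= 1)
  suit <- true_suitability(niche, stack)
  cells <- land_cells(stack)
  p <- suit$values[cbind(cells$row, cells$col)]
  if (sum(p) <= 0)
    stop("all-zero suitability over land for species '", species_id, "'")
  with_seed(seed, {
    k <- sample.int(nrow(cells), n_occ, replace = TRUE, prob = p)
    res <- stack$resolution
    lon <- cells$lon[k] - res / 2 + stats::runif(n_occ) * res
    lat <- cells$lat[k] + res / 2 - stats::runif(n_occ) * res
    occurrence_table(species_id, lon, lat, source_tag = "synthetic")
  })
}

#' Genus-structured virtual study designs
#'
#' A `study_design` describes the shape of a synthetic study: how many
#' genera, how many garden (alien ornamental) and congener (resident)
#' species per genus, how many occurrence records per species, and the
#' niche-parameter ranges the species are drawn from.  It mirrors, scaled
#' down, a study of 16 genera with 34 garden plants and 173 congeners; the
#' default desk-scale design is 4 genera x (2 garden + 4 congeners) = 24
#' species with 300 records each on a 100 x 100 grid.
#'
#' Temperature optima are genus-structured (niche conservatism): each genus
#' draws a base optimum, congeners scatter around it, and — when
#' `warm_bias = TRUE` (default) — garden species are systematically
#' warm-shifted relative to their congeners, placing their optima at or
#' beyond the warmest climate available at baseline.  This encodes the
#' mechanism whereby ornamentals native to warm regions hold truncated
#' ranges at the warm edge of the study area and gain suitable area as
#' warming relaxes their cold constraint.  The first congener of each genus
#' is forced to be cold-adapted (emulating montane/alpine members of the
#' resident flora, whose ranges shrink off the cold edge under warming).
#'
#' @param n_genera number of genera.
#' @param garden_per_genus,congener_per_genus species counts per genus.
#' @param n_occ occurrence records per species.
#' @param warm_bias logical; warm-shift garden optima (see above).
#' @param temp_base range (deg C) of the genus-level BIO5 base optimum.
#' @param garden_shift,congener_shift,cold_shift ranges (deg C) of the
#'   species-level offset from the genus base for garden species, ordinary
#'   congeners and the forced-cold first congener (subtracted).
#' @param temp_sigma range of temperature niche breadths (deg C).
#' @param precip_opt,precip_sigma ranges (mm) of the genus-level BIO16 base
#'   optimum (species scatter +/- 100 mm around it) and of the (broad)
#'   precipitation breadth.
#' @param s_max maximum suitability for every species.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_genera = 4, garden_per_genus = 2,
                         congener_per_genus = 4, n_occ = 300,
                         warm_bias = TRUE,
                         temp_base = c(24, 30),
                         garden_shift = c(6, 9),
                         congener_shift = c(-6, 3),
                         cold_shift = c(10, 14),
                         temp_sigma = c(2.5, 4),
                         precip_opt = c(450, 750),
                         precip_sigma = c(250, 400),
                         s_max = 1) {
  stopifnot(n_genera >= 1, garden_per_genus >= 1, congener_per_genus >= 1,
            n_occ >= 1)
  structure(list(n_genera = n_genera, garden_per_genus = garden_per_genus,
                 congener_per_genus = congener_per_genus, n_occ = n_occ,
                 warm_bias = warm_bias, temp_base = temp_base,
                 garden_shift = garden_shift,
                 congener_shift = congener_shift, cold_shift = cold_shift,
                 temp_sigma = temp_sigma, precip_opt = precip_opt,
                 precip_sigma = precip_sigma, s_max = s_max),
            class = "study_design")
}

#' Realize a virtual study: taxa, niches and occurrences
#'
#' Draws the niche of every species per the design, builds the taxon table
#' (genus, group, status, life form; life form is shared within a genus),
#' and samples one raw occurrence table per species.  All niche truths are
#' returned so recovery can be scored later.  Deterministic given `seed`.
#'
#' @param design a [study_design].
#' @param stack a [climate_stack].
#' @param seed integer RNG seed.
#' @return a list of class `hr_study` with elements `taxa` (a
#'   [taxon_table]), `occurrences` (named list of [occurrence_table]),
#'   `niches` (named list of [niche_spec] truths) and `design`.
#' @export
make_study <- function(design, stack, seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(stack, "climate_stack"))
  with_seed(seed, {
    taxa <- list(); niches <- list(); occ_seeds <- integer()
    runif2 <- function(r) stats::runif(1, r[1], r[2])
    for (g in seq_len(design$n_genera)) {
      genus <- sprintf("Genus%02d", g)
      life_form <- if (g %% 2 == 1) "herb" else "woody"
      t_base <- runif2(design$temp_base)
      p_base <- runif2(design$precip_opt)
      add_species <- function(id, group, status, shift) {
        niches[[id]] <<- niche_spec(
          optimum = c(BIO5 = t_base + shift,
                      BIO16 = max(50, p_base + stats::runif(1, -100, 100))),
          breadth = c(BIO5 = runif2(design$temp_sigma),
                      BIO16 = runif2(design$precip_sigma)),
          s_max = design$s_max)
        taxa[[id]] <<- data.frame(species_id = id, genus = genus,
                                  group = group, status = status,
                                  life_form = life_form)
      }
      for (s in seq_len(design$garden_per_genus))
        add_species(sprintf("%s_garden%d", genus, s), "garden", NA,
                    runif2(if (design$warm_bias) design$garden_shift
                           else design$congener_shift))
      for (s in seq_len(design$congener_per_genus))
        add_species(sprintf("%s_cong%d", genus, s), "congener",
                    if (stats::runif(1) < 0.75) "native" else "naturalized",
                    if (s == 1 && design$warm_bias) -runif2(design$cold_shift)
                    else runif2(design$congener_shift))
    }
    taxa <- do.call(rbind, taxa)
    occurrences <- lapply(seq_len(nrow(taxa)), function(i)
      sample_occurrences(niches[[taxa$species_id[i]]], stack,
                         n_occ = design$n_occ,
                         seed = sub_seed(seed, i),
                         species_id = taxa$species_id[i]))
    names(occurrences) <- taxa$species_id
    structure(list(
      taxa = taxon_table(taxa$species_id, taxa$genus, taxa$group,
                         taxa$status, taxa$life_form),
      occurrences = occurrences, niches = niches, design = design),
      class = "hr_study")
  })
}

#' @export
print.hr_study <- function(x, ...) {
  tab <- table(x$taxa$group)
  cat("hr_study:", nrow(x$taxa), "virtual species in",
      length(unique(x$taxa$genus)), "genera (",
      tab[["garden"]], "garden,", tab[["congener"]], "congener )\n")
  cat("  records per species:", x$design$n_occ,
      "| warm_bias:", x$design$warm_bias, "\n")
  invisible(x)
}
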