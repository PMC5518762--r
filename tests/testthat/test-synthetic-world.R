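# Synthetic climate, scenarios, virtual niches and occurrence sampling.

test_that("climate generation is deterministic and gradient-structured", {
  a <- make_climate(20, 20, seed = 5)
  b <- make_climate(20, 20, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, make_climate(20, 20, seed = 6)))
  # temperature declines strictly with latitude before noise is added
  g <- make_climate(20, 20, seed = 5, temp_noise_sd = 0, precip_noise_sd = 0)
  for (lay in c("BIO5", "BIO6")) {
    rm_ <- rowMeans(g$layers[[lay]], na.rm = TRUE)   # row 1 = northernmost
    expect_true(all(diff(rm_) > 0))
  }
  # every layer varies over land
  for (lay in names(a$layers))
    expect_gt(stats::var(a$layers[[lay]][a$mask]), 0)
  # land mask: 70-95% coverage, single connected component
  expect_gte(mean(a$mask), 0.70)
  expect_lte(mean(a$mask), 0.95)
  expect_identical(hybridrange:::largest_component(a$mask), a$mask)
})

test_that("scenario deltas shift layers additively and label the stack", {
  st <- make_climate(15, 15, seed = 2)
  zero <- scenario_delta("null", c(BIO5 = 0))
  st0 <- apply_scenario(st, zero)
  expect_equal(st0$layers, st$layers)
  plus2 <- scenario_delta("warm2", c(BIO5 = 2))
  st2 <- apply_scenario(st, plus2)
  expect_equal(st2$layers$BIO5[st$mask], st$layers$BIO5[st$mask] + 2)
  expect_identical(st2$mask, st$mask)
  expect_identical(st2$scenario_id, "warm2")
  # composition: +1 twice equals +2 once
  plus1 <- scenario_delta("warm1", c(BIO5 = 1))
  expect_equal(apply_scenario(apply_scenario(st, plus1), plus1)$layers,
               st2$layers)
  expect_error(apply_scenario(st, scenario_delta("x", c(NOPE = 1))),
               "unknown layer")
})

test_that("true suitability is the Gaussian product kernel", {
  st <- toy_stack()
  v5 <- st$layers$BIO5[4, 6]; v16 <- st$layers$BIO16[4, 6]
  n <- niche_spec(c(BIO5 = v5, BIO16 = v16), c(BIO5 = 2, BIO16 = 100))
  s <- true_suitability(n, st)
  expect_equal(s$values[4, 6], 1.0)                    # exact optimum
  expect_true(all(s$values[st$mask] <= 1 + 1e-12))
  # one sigma away in exactly one variable -> exp(-1/2)
  n2 <- niche_spec(c(BIO5 = v5 + 2, BIO16 = v16), c(BIO5 = 2, BIO16 = 100))
  expect_equal(true_suitability(n2, st)$values[4, 6], exp(-0.5),
               tolerance = 1e-12)
  # bounded by s_max
  n3 <- niche_spec(c(BIO5 = v5, BIO16 = v16), c(BIO5 = 2, BIO16 = 100),
                   s_max = 0.7)
  expect_equal(max(true_suitability(n3, st)$values, na.rm = TRUE), 0.7)
  # invariant under permutation of the variable order
  n4 <- niche_spec(c(BIO16 = v16, BIO5 = v5), c(BIO16 = 100, BIO5 = 2))
  expect_equal(true_suitability(n4, st)$values, s$values)
  expect_error(true_suitability(
    niche_spec(c(XX = 0), c(XX = 1)), st), "missing from stack")
})

test_that("occurrence sampling follows the suitability distribution", {
  st <- flat_stack(10, 10)       # constant layers -> uniform suitability
  n <- niche_spec(c(BIO5 = 20), c(BIO5 = 5))
  occ <- sample_occurrences(n, st, n_occ = 10000, seed = 21, species_id = "u")
  expect_identical(occ,
                   sample_occurrences(n, st, n_occ = 10000, seed = 21,
                                      species_id = "u"))
  # chi-square goodness of fit against the uniform multinomial over cells
  cells <- cell_of(occ$lon, occ$lat, st)
  counts <- tabulate(cells$cell_id, nbins = 100)
  expect_gt(stats::chisq.test(counts, p = rep(1 / 100, 100))$p.value, 1e-3)
  # degenerate support: vanishing breadth confines draws to the optimum cell
  st2 <- toy_stack()
  opt <- c(BIO5 = st2$layers$BIO5[3, 3], BIO16 = st2$layers$BIO16[3, 3])
  sharp <- niche_spec(opt, c(BIO5 = 1e-4, BIO16 = 1e-4))
  occ2 <- sample_occurrences(sharp, st2, n_occ = 50, seed = 3)
  cc <- cell_of(occ2$lon, occ2$lat, st2)
  expect_true(all(cc$row == 3 & cc$col == 3))
  # all-zero suitability over land is an error
  st3 <- toy_stack(water = cbind(3, 3))
  expect_error(sample_occurrences(sharp, st3, n_occ = 10, seed = 1),
               "all-zero suitability")
})

test_that("study realization has the designed shape and warm bias", {
  st <- make_climate(30, 30, seed = 9)
  d <- study_design(n_genera = 2, garden_per_genus = 1,
                    congener_per_genus = 2, n_occ = 60)
  stu <- make_study(d, st, seed = 14)
  expect_equal(nrow(stu$taxa), 6L)
  expect_length(stu$occurrences, 6L)
  expect_length(stu$niches, 6L)
  expect_setequal(names(stu$niches), stu$taxa$species_id)
  expect_true(all(vapply(stu$occurrences, nrow, integer(1)) == 60L))
  # warm bias: garden temperature optima above the congeners' on average
  opt5 <- vapply(stu$niches, function(n) n$optimum[["BIO5"]], numeric(1))
  grp <- stu$taxa$group[match(names(opt5), stu$taxa$species_id)]
  expect_gt(mean(opt5[grp == "garden"]), mean(opt5[grp == "congener"]))
  # determinism of the whole realization
  stu2 <- make_study(d, st, seed = 14)
  expect_equal(stu$niches, stu2$niches)
  expect_equal(lapply(stu$occurrences, as.data.frame),
               lapply(stu2$occurrences, as.data.frame))
})
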