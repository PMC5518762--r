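# TSS kernel, maxTSS thresholding, split-sample evaluation, model fitting
# and grid projection.

test_that("tss follows sensitivity + specificity - 1 and refuses empty margins", {
  expect_equal(tss(50, 0, 0, 50), 1)
  expect_equal(tss(0, 50, 50, 0), -1)
  expect_equal(tss(40, 10, 20, 30), 40 / 60 + 30 / 40 - 1)
  expect_error(tss(0, 5, 0, 5), "a \\+ c")
  expect_error(tss(5, 0, 5, 0), "b \\+ d")
  set.seed(4)
  for (i in 1:200) {
    m <- sample(0:100, 4, replace = TRUE)
    if ((m[1] + m[3]) == 0 || (m[2] + m[4]) == 0) next
    v <- tss(m[1], m[2], m[3], m[4])
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("maxTSS threshold equals a brute-force scan and is rank-invariant", {
  thr <- maxtss_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(as.numeric(thr), 0.8)
  expect_equal(attr(thr, "tss"), 1)
  thr2 <- maxtss_threshold(c(0.6, 0.4), c(0, 1))
  expect_equal(as.numeric(thr2), 0.4)
  expect_lte(attr(thr2, "tss"), 0)
  # brute-force oracle on random instances (unweighted and weighted)
  brute <- function(p, y, w) {
    cand <- sort(unique(p))
    tvals <- vapply(cand, function(t) {
      pos <- p >= t
      a <- sum(w[pos & y == 1]); b <- sum(w[pos & y == 0])
      c_ <- sum(w[!pos & y == 1]); d <- sum(w[!pos & y == 0])
      a / (a + c_) + d / (b + d) - 1
    }, numeric(1))
    best <- max(tvals)
    list(thr = min(cand[tvals >= best - 1e-12]), tss = best)
  }
  set.seed(12)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    p <- if (i %% 2) runif(n) else round(runif(n), 1)  # force ties sometimes
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    w <- if (i %% 3) rep(1, n) else runif(n, 0.1, 2)
    got <- maxtss_threshold(p, y, w)
    want <- brute(p, y, w)
    expect_equal(as.numeric(got), want$thr)
    expect_equal(attr(got, "tss"), want$tss, tolerance = 1e-9)
  }
  # adding a constant below the smallest gap shifts the threshold, not the TSS
  p <- c(0.9, 0.7, 0.3, 0.1); y <- c(1, 0, 1, 0)
  t0 <- maxtss_threshold(p, y)
  t1 <- maxtss_threshold(p + 0.05, y)
  expect_equal(as.numeric(t1), as.numeric(t0) + 0.05)
  expect_equal(attr(t1, "tss"), attr(t0, "tss"))
  expect_error(maxtss_threshold(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("split-sample evaluation scores a separable GLM perfectly", {
  tr <- separable_train()
  ev <- split_sample_eval(tr, "GLM", seed = 5)
  expect_length(ev, 3L)
  expect_equal(ev, c(1, 1, 1))
  expect_identical(ev, split_sample_eval(tr, "GLM", seed = 5))
})

test_that("evaluation of label-independent data matches a permutation oracle", {
  # the held-out maxTSS step optimizes the threshold, so even null data
  # score slightly above zero; the proper reference is the permutation null
  tr <- null_train(n = 600, seed = 2)
  obs <- mean(split_sample_eval(tr, "GLM", seed = 3))
  set.seed(17)
  null_means <- replicate(15, {
    tp <- tr
    tp$y <- sample(tp$y)
    mean(split_sample_eval(tp, "GLM", seed = sample.int(1e6, 1)))
  })
  expect_lte(obs, max(null_means) + 0.05)
  expect_lte(abs(obs), 0.15)   # and close to zero in absolute terms
})

test_that("full fits separate the separable fixture and expose TSS metadata", {
  tr <- separable_train()
  for (alg in c("GLM", "BRT", "RF")) {
    f <- fit_full(tr, alg, seed = 31)
    expect_s3_class(f, "sdm_fit")
    expect_identical(f$family, algorithm_family(alg))
    # training presences predicted suitable
    expect_true(all(predict(f, tr$x[tr$y == 1, ]) >= 0.5))
    if (alg %in% c("BRT", "RF")) expect_true(all(f$eval_tss >= 0.9))
  }
  # single-class input is rejected when assembling the training set
  st <- toy_stack()
  occ <- clean_occurrences(
    occurrence_table("z", cell_center(5, 5, st)$lon,
                     cell_center(5, 5, st)$lat), st)
  empty_pa <- structure(data.frame(lon = numeric(), lat = numeric()),
                        scheme = "random_10k", species_id = "z",
                        replicate_id = NA_integer_,
                        class = c("pa_set", "data.frame"))
  expect_error(training_set(occ, empty_pa, st), "both classes")
})

test_that("tree ensembles are seed-deterministic and weight-sensitive", {
  tr <- separable_train()
  f1 <- fit_full(tr, "RF", seed = 7, eval_tss = 1)
  f2 <- fit_full(tr, "RF", seed = 7, eval_tss = 1)
  expect_equal(predict(f1, tr$x), predict(f2, tr$x))
  f3 <- fit_full(tr, "BRT", seed = 7, eval_tss = 1)
  f4 <- fit_full(tr, "BRT", seed = 8, eval_tss = 1)
  expect_false(identical(predict(f3, tr$x), predict(f4, tr$x)))
  # a depth-1 tree recovers the best split found by an exhaustive scan
  set.seed(2)
  x <- cbind(a = runif(200), b = runif(200))
  y <- as.numeric(x[, "a"] > 0.6)
  tree <- hybridrange:::.cart_grow(x, y, rep(1, 200), 2L, 1L, 5L)
  expect_equal(tree$feature[1], 0L)          # split on column "a" (0-based)
  expect_lt(abs(tree$threshold[1] - 0.6), 0.05)
})

test_that("projection fills land cells with bounded, consistent predictions", {
  st <- toy_stack()
  # a warm-limited niche: optimum beyond the grid's warmest cell, so the
  # fitted temperature response is increasing over the whole grid
  n <- niche_spec(c(BIO5 = 40, BIO16 = 505), c(BIO5 = 6, BIO16 = 200))
  occ <- clean_occurrences(sample_occurrences(n, st, 80, seed = 2,
                                              species_id = "v"), st)
  pa <- sample_random_pa(st, 300, seed = 3, species_id = "v")
  tr <- training_set(occ, pa, st)
  f <- fit_full(tr, "GLM", seed = 4, eval_tss = c(1, 1, 1))
  m <- project(f, st)
  expect_true(all(m$values[st$mask] >= 0 & m$values[st$mask] <= 1))
  expect_true(all(is.na(m$values[!st$mask])))
  # projecting reproduces pointwise predictions at the occurrence cells
  cells <- cell_of(occ$lon, occ$lat, st)
  direct <- predict(f, hybridrange:::stack_values(st, cells$row, cells$col))
  expect_equal(m$values[cbind(cells$row, cells$col)], direct)
  # missing training variable is caught
  st1 <- climate_stack(list(BIO5 = matrix(20, 12, 12)), st$extent,
                       st$resolution)
  expect_error(project(f, st1), "lacks training variable")
  # sign argument, verified numerically: wherever the fitted temperature
  # response is increasing across the +2 shift (positive derivative of the
  # linear + quadratic term over [x, x+2]), warming cannot lower the cell
  co <- stats::coef(f$fit$model)
  b1 <- co[["BIO5"]]; b2 <- co[["I(BIO5^2)"]]
  expect_gt(b1, 0)
  warm <- apply_scenario(st, scenario_delta("w", c(BIO5 = 2)))
  m2 <- project(f, warm)
  x <- st$layers$BIO5[st$mask]
  rising <- (b1 + 2 * b2 * x > 0) & (b1 + 2 * b2 * (x + 2) > 0)
  expect_gt(sum(rising), 0)
  expect_true(all(m2$values[st$mask][rising] >=
                    m$values[st$mask][rising] - 1e-9))
})
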