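# Fixture builders shared across the suite.  Everything is generated in
# code; the expensive default-world pipeline run is computed once and cached
# for the tests that need full outputs.

# a flat all-land stack: constant layers -> uniform suitability
flat_stack <- function(nr = 10, nc = 10, value = 20, res = 1, origin = c(0, 0)) {
  layers <- list(BIO5 = matrix(value, nr, nc),
                 BIO16 = matrix(500, nr, nc))
  climate_stack(layers, c(origin[1], origin[1] + nc * res,
                          origin[2], origin[2] + nr * res), res)
}

# a small stack with a BIO5 latitudinal gradient and a water block
toy_stack <- function(nr = 12, nc = 12, res = 1 / 6, origin = c(0, 40),
                      water = NULL) {
  lat_idx <- matrix(seq_len(nr), nr, nc)          # row 1 = north
  layers <- list(BIO5 = 10 + lat_idx * 2,          # warm toward the south
                 BIO16 = matrix(500, nr, nc) + col(matrix(0, nr, nc)))
  mask <- matrix(TRUE, nr, nc)
  if (!is.null(water)) mask[water] <- FALSE
  climate_stack(layers, c(origin[1], origin[1] + nc * res,
                          origin[2], origin[2] + nr * res), res, mask = mask)
}

# binary map from a 0/1 vector filled row-wise over a stack's grid
toy_binary <- function(bits, stack, species = "sp") {
  v <- matrix(bits, nrow(stack$mask), ncol(stack$mask), byrow = TRUE)
  binary_map(v, stack, species_id = species, threshold = 0.5)
}

# a linearly separable training set: presences warm, absences cold, with a
# clean margin so every algorithm can reach TSS = 1
separable_train <- function(n = 120, seed = 1, species = "sep") {
  set.seed(seed)
  x <- rbind(cbind(BIO5 = runif(n, 25, 30), BIO16 = runif(n, 400, 600)),
             cbind(BIO5 = runif(n, 10, 18), BIO16 = runif(n, 400, 600)))
  y <- rep(c(1, 0), each = n)
  structure(list(x = x, y = y, w = rep(1, 2 * n), species_id = species,
                 scheme = "fixture", replicate_id = NA_integer_,
                 n_dropped = 0L),
            class = "training_set")
}

# training set with response independent of the predictors (null fixture)
null_train <- function(n = 1000, seed = 1) {
  set.seed(seed)
  x <- cbind(BIO5 = runif(2 * n, 10, 30), BIO16 = runif(2 * n, 300, 700))
  structure(list(x = x, y = rep(c(1, 0), each = n), w = rep(1, 2 * n),
                 species_id = "null", scheme = "fixture",
                 replicate_id = NA_integer_, n_dropped = 0L),
            class = "training_set")
}

# default-world pipeline run (the stated synthetic study), cached: several
# acceptance criteria and consensus-law checks read from the same outputs
.hr_cache <- new.env(parent = emptyenv())
pipeline_result <- function() {
  if (is.null(.hr_cache$result))
    .hr_cache$result <- run_study(seed = 1, verbose = FALSE)
  .hr_cache$result
}
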