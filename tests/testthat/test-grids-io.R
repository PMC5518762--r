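# Grid data model, geodesic distance, occurrence cleaning, file round trips.

test_that("cell_of maps points to the unique containing half-open footprint", {
  st <- flat_stack(10, 10, res = 1, origin = c(0, 0))
  # corner cells
  expect_equal(unlist(cell_of(0.5, 9.5, st)[, c("row", "col")]),
               c(row = 1, col = 1))
  expect_equal(unlist(cell_of(9.999, 0.001, st)[, c("row", "col")]),
               c(row = 10, col = 10))
  # brute-force footprint scan for an interior point: the cell covering
  # [west, east) x (south, north] must be unique and must match
  brute_cell <- function(lon, lat) {
    hits <- NULL
    for (r in 1:10) for (cc in 1:10) {
      west <- cc - 1; east <- cc; north <- 10 - r + 1; south <- 10 - r
      if (lon >= west && lon < east && lat > south && lat <= north)
        hits <- rbind(hits, c(r, cc))
    }
    hits
  }
  hit <- brute_cell(3.0, 7.0)
  expect_equal(nrow(hit), 1L)
  expect_equal(unlist(cell_of(3.0, 7.0, st)[, c("row", "col")]),
               c(row = hit[1, 1], col = hit[1, 2]))
  # property: 1,000 random points agree with the exhaustive footprint oracle
  set.seed(7)
  lon <- runif(1000, 0, 9.9999); lat <- runif(1000, 0.0001, 10)
  got <- cell_of(lon, lat, st)
  for (i in sample(1000, 60)) {       # oracle is O(cells); spot-check 60
    hit <- brute_cell(lon[i], lat[i])
    expect_equal(c(got$row[i], got$col[i]), c(hit[1, 1], hit[1, 2]))
  }
  expect_error(cell_of(11, 5, st), "outside")
})

test_that("great-circle distance is the haversine on a 6371 km sphere", {
  expect_equal(great_circle_km(0, 0, 0, 0), 0)
  expect_equal(great_circle_km(0, 0, 1, 0), 2 * pi * 6371 / 360,
               tolerance = 1e-9)                       # ~111.19 km
  expect_equal(great_circle_km(0, 0, 180, 0), pi * 6371, tolerance = 1e-9)
  # symmetry and triangle inequality on random triples
  set.seed(11)
  for (i in 1:50) {
    p <- matrix(c(runif(3, -180, 180), runif(3, -90, 90)), ncol = 2)
    d12 <- great_circle_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d21 <- great_circle_km(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    d13 <- great_circle_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    d32 <- great_circle_km(p[3, 1], p[3, 2], p[2, 1], p[2, 2])
    expect_equal(d12, d21)
    expect_lte(d12, d13 + d32 + 1e-9)
  }
  expect_error(great_circle_km(0, 95, 0, 0), "out of range")
})

test_that("occurrence cleaning deduplicates per cell and drops water records", {
  st <- toy_stack(water = cbind(2, 2))
  res <- st$resolution
  cc <- cell_center(5, 5, st)
  # 3 records of one species inside one land cell -> 1 record (first kept)
  occ <- occurrence_table("a", cc$lon + c(-0.3, 0, 0.3) * res,
                          cc$lat + c(0.3, 0, -0.3) * res,
                          source_tag = c("first", "second", "third"))
  cl <- clean_occurrences(occ, st)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$source_tag, "first")
  expect_true(attr(cl, "cleaned"))
  # a record on the water cell is dropped (and the species loss is warned)
  wc <- cell_center(2, 2, st)
  expect_warning(cl2 <- clean_occurrences(
    occurrence_table("b", wc$lon, wc$lat), st), "no records left")
  expect_equal(nrow(cl2), 0L)
  # idempotence
  expect_equal(as.data.frame(clean_occurrences(cl, st)), as.data.frame(cl))
})

test_that("cleaning matches a brute-force distinct-land-cell count", {
  st <- toy_stack(water = rbind(c(2, 2), c(7, 9)))
  set.seed(3)
  # 120 records concentrated on 25 chosen land cells + 2 water-cell records
  land <- which(st$mask, arr.ind = TRUE)
  pick <- land[sample(nrow(land), 25), ]
  reps <- sample(25, 118, replace = TRUE)
  cc <- cell_center(pick[reps, 1], pick[reps, 2], st)
  jit <- st$resolution * 0.4
  lon <- cc$lon + runif(118, -jit, jit)
  lat <- cc$lat + runif(118, -jit, jit)
  wc <- cell_center(c(2, 7), c(2, 9), st)
  occ <- occurrence_table("sp", c(lon, wc$lon), c(lat, wc$lat))
  cl <- clean_occurrences(occ, st)
  # oracle: count the distinct land cells actually hit
  cells <- cell_of(lon, lat, st)
  expect_equal(nrow(cl), length(unique(cells$cell_id)))
  expect_equal(nrow(cl), 25L)
})

test_that("climate stacks round-trip through the text format", {
  st <- make_climate(12, 15, seed = 4)
  f <- withr::local_tempfile(fileext = ".txt")
  write_climate(st, f)
  st2 <- read_climate(f)
  expect_equal(st2$layers, st$layers)
  expect_identical(st2$mask, st$mask)
  expect_equal(st2$extent, st$extent)
  expect_equal(st2$resolution, st$resolution)
  expect_identical(st2$scenario_id, st$scenario_id)
  # masked cells survive as no-data -> NA
  expect_true(all(is.na(st2$layers$BIO5[!st2$mask])))
})

test_that("table readers validate shape and coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,lon,lat", "a,10,50", "b,11,95"), f)
  expect_error(read_occurrences(f), "row\\(s\\): 2")
  writeLines(c("species,x,y", "a,10,50"), f)
  expect_error(read_occurrences(f), "malformed")
  # occurrence round trip
  occ <- occurrence_table(c("a", "b"), c(1.5, 2.5), c(44.2, 45.1), "gbif")
  write_occurrences(occ, f)
  occ2 <- read_occurrences(f)
  expect_equal(as.data.frame(occ2), as.data.frame(occ))
  # climate format errors
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a stack", g)
  expect_error(read_climate(g), "HRSTACK")
  # taxon table contract: a garden plant needs a matching congener
  expect_error(taxon_table(c("g1", "c1"), c("A", "B"),
                           c("garden", "congener")),
               "without a same-genus")
  tt <- taxon_table(c("g1", "c1"), c("A", "A"), c("garden", "congener"),
                    c(NA, "native"), "herb")
  expect_s3_class(tt, "taxon_table")
})
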