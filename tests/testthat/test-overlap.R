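# Pairwise geographic overlap metrics and per-garden aggregation.

test_that("overlap TSS scores agreement with the congener as reference", {
  st <- flat_stack(2, 2)
  a <- toy_binary(c(1, 1, 0, 0), st)
  b <- toy_binary(c(1, 0, 1, 0), st)
  expect_equal(overlap_tss(a, a), 1)                       # self-overlap
  expect_equal(overlap_tss(a, toy_binary(c(0, 0, 1, 1), st)), -1)
  # hand confusion matrix: a=1, b=1, c=1, d=1 -> 0
  expect_equal(overlap_tss(a, b), 0)
  # orientation matters: margins differ between the two orderings
  st6 <- flat_stack(2, 3)
  g <- toy_binary(c(1, 1, 1, 0, 0, 0), st6)      # a=2, b=1, c=0, d=3
  r <- toy_binary(c(1, 1, 0, 0, 0, 0), st6)
  expect_equal(overlap_tss(g, r), 2 / 2 + 3 / 4 - 1)       # 0.75
  expect_equal(overlap_tss(r, g), 2 / 3 + 3 / 3 - 1)       # 2/3
  expect_false(overlap_tss(g, r) == overlap_tss(r, g))
  # the symmetrized variant averages both orientations
  expect_equal(overlap_tss(g, r, symmetrize = TRUE), (0.75 + 2 / 3) / 2)
  # nested maps: garden covers congener -> c = 0, TSS = d/(b+d) >= 0
  expect_gte(overlap_tss(g, r), 0)
  # degenerate margins error
  expect_error(overlap_tss(a, toy_binary(rep(1, 4), st)), "b \\+ d")
})

test_that("cell overlap and range size match brute-force counts", {
  st <- flat_stack(5, 5)
  set.seed(8)
  for (i in 1:20) {
    g <- toy_binary(rbinom(25, 1, 0.5), st)
    r <- toy_binary(rbinom(25, 1, 0.5), st)
    expect_equal(overlap_cells(g, r), sum(g$values * r$values, na.rm = TRUE))
    expect_equal(overlap_cells(g, r), overlap_cells(r, g))   # symmetric
    expect_equal(range_size(g), overlap_cells(g, g))
  }
  expect_equal(range_size(toy_binary(rep(0, 25), st)), 0)
  # masked cells are outside the universe
  stw <- toy_stack(water = cbind(1, 1))
  ones <- matrix(1, 12, 12)
  expect_equal(range_size(binary_map(ones, stw)), sum(stw$mask))
})

test_that("pair scoring is restricted to genus and life form, then averaged", {
  st <- flat_stack(3, 3)
  taxa <- taxon_table(
    species_id = c("g1", "g2", "c1", "c2", "c3", "c4"),
    genus = c("A", "B", "A", "A", "B", "A"),
    group = c("garden", "garden", "congener", "congener", "congener",
              "congener"),
    status = c(NA, NA, "native", "native", "naturalized", "native"),
    life_form = c("herb", "woody", "herb", "herb", "woody", "woody"))
  maps <- list(g1 = toy_binary(c(1, 1, 1, 1, 0, 0, 0, 0, 0), st),
               g2 = toy_binary(c(1, 1, 0, 0, 1, 1, 0, 0, 0), st),
               c1 = toy_binary(c(1, 1, 1, 1, 0, 0, 0, 0, 0), st),
               c2 = toy_binary(c(0, 0, 1, 1, 1, 1, 0, 0, 0), st),
               c3 = toy_binary(c(1, 0, 0, 0, 1, 0, 1, 0, 0), st),
               c4 = toy_binary(c(0, 0, 0, 0, 0, 0, 0, 1, 1), st))
  pairs <- pair_overlaps(maps, taxa, "BASE")
  # g1 (herb, A) pairs with c1 and c2 only; c4 is woody, c3 is genus B
  expect_setequal(pairs$congener_id[pairs$garden_id == "g1"], c("c1", "c2"))
  expect_equal(pairs$congener_id[pairs$garden_id == "g2"], "c3")
  expect_equal(pairs$n_overlap_cells[pairs$garden_id == "g1" &
                                       pairs$congener_id == "c1"], 4)
  expect_equal(pairs$n_overlap_cells[pairs$garden_id == "g1" &
                                       pairs$congener_id == "c2"], 2)
  # invariant: overlap never exceeds either range
  expect_true(all(pairs$n_overlap_cells <=
                    pmin(pairs$garden_range_cells,
                         pairs$congener_range_cells)))
  s <- summarize_per_garden(pairs)
  expect_equal(s$mean_overlap_cells[s$garden_id == "g1"], 3)   # (4 + 2) / 2
  expect_equal(s$n_congeners[s$garden_id == "g1"], 2L)
  # single congener: the summary equals the pair
  expect_equal(s$mean_tss_overlap[s$garden_id == "g2"],
               pairs$tss_overlap[pairs$garden_id == "g2"])
  # bookkeeping: summary congener counts add up to the valid pairs
  expect_equal(sum(s$n_congeners), nrow(pairs))
})
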