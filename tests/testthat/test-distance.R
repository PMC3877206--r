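# distance_profile module: distance map, binning, conservation, shift
# property, and the dual-route oracle.

test_that("vessel_distance_map examples", {
  vs <- rect_mask(60, 20:40, 20:40, marker = "VS")
  d <- vessel_distance_map(vs)
  expect_equal(d[30, 41], 1)          # adjacent pixel, 1 px * 1 um
  expect_true(all(d[vs$px] == 0))
  full <- binary_mask(matrix(TRUE, 20, 20), 1)
  expect_true(all(vessel_distance_map(full) == 0))
  expect_error(vessel_distance_map(binary_mask(matrix(FALSE, 5, 5), 1)),
               "empty")
  # center of a 100 um gap between two walls -> 50 um (+- 1 px)
  walls <- binary_mask(cbind(matrix(TRUE, 120, 10),
                             matrix(FALSE, 120, 100),
                             matrix(TRUE, 120, 10)), 1, "VS")
  d2 <- vessel_distance_map(walls)
  expect_lt(abs(d2[60, 60] - 50), 1 + 1e-9)
})

test_that("profile conservation and trivial binning", {
  vs <- disk_mask(100, 50, 50, 10, marker = "VS")
  dapi <- binary_mask(dilate_um(vs$px, 4, 1), 1, "DAPI")  # all within 5 um
  tt <- binary_mask(matrix(TRUE, 100, 100), 1, "TT")
  pr <- distance_profile(dapi, tt, vessel_distance_map(vs))
  expect_equal(sum(pr$percent_per_bin), 100, tolerance = 1e-9)
  expect_equal(pr$percent_per_bin[1], 100)
  expect_equal(pr$pct_beyond_100um, 0)
  expect_error(distance_profile(binary_mask(matrix(FALSE, 100, 100), 1),
                                tt, vessel_distance_map(vs)), "no DAPI")
})

test_that("central-vessel ring masses are proportional to annulus areas", {
  n <- 400
  vs <- disk_mask(n, 200, 200, 10, marker = "VS")
  dapi <- binary_mask(matrix(TRUE, n, n), 1, "DAPI")
  tt <- dapi
  pr <- distance_profile(dapi, tt, vessel_distance_map(vs))
  # bins fully inside the field (distance << field half-width)
  total <- n * n
  for (k in 1:15) {
    # element k+1 is the band (5k, 5k+5] um, i.e. radii 10+5k .. 15+5k
    r0 <- 10 + k * 5; r1 <- 15 + k * 5
    want <- 100 * pi * (r1^2 - r0^2) / total
    expect_lt(abs(pr$percent_per_bin[k + 1] - want) / want, 0.02)
  }
})

test_that("smoothing never alters the stored raw bins", {
  vs <- disk_mask(80, 40, 40, 8, marker = "VS")
  dapi <- binary_mask(matrix(TRUE, 80, 80), 1)
  pr <- distance_profile(dapi, dapi, vessel_distance_map(vs))
  expect_equal(sum(pr$percent_per_bin), 100, tolerance = 1e-9)
  expect_false(identical(pr$smoothed, pr$percent_per_bin))
  expect_length(pr$smoothed, length(pr$percent_per_bin))
})

test_that("adding a vessel only moves mass toward lower bins", {
  spec <- small_spec(seed = 41, n_stems = 4)
  scn <- generate_scene(spec)
  res <- spec$resolution_um_per_px
  cm <- scn$gt$clean_masks
  dapi <- binary_mask(cm$DAPI, res)
  tt <- build_tt(dapi)
  vs1 <- binary_mask(cm$CD31, res, "VS")
  p1 <- distance_profile(dapi, tt, vessel_distance_map(vs1))
  vs2 <- binary_mask(cm$CD31 | disk_mask(300, 250, 250, 8)$px, res, "VS")
  p2 <- distance_profile(dapi, tt, vessel_distance_map(vs2))
  expect_lte(p2$pct_beyond_100um, p1$pct_beyond_100um)
  # cumulative mass at every distance can only grow when VS grows
  expect_true(all(cumsum(p2$percent_per_bin) >=
                  cumsum(p1$percent_per_bin) - 1e-9))
})

test_that("EDT binning and iterative enlargement agree exactly", {
  for (s in 1:3) {
    spec <- small_spec(seed = 50 + s, n_stems = 4)
    scn <- generate_scene(spec)
    res <- spec$resolution_um_per_px
    vs <- binary_mask(scn$gt$clean_masks$CD31, res, "VS")
    dapi <- binary_mask(scn$gt$clean_masks$DAPI, res)
    tt <- build_tt(dapi)
    p1 <- distance_profile(dapi, tt, vessel_distance_map(vs))
    p2 <- iterative_enlargement_oracle(vs, dapi, tt)
    expect_identical(p1$percent_per_bin, p2$percent_per_bin)
  }
  # degenerate case: everything within the first gap
  vs <- disk_mask(40, 20, 20, 10, marker = "VS")
  dapi <- binary_mask(dilate_um(vs$px, 3, 1), 1)
  tt <- binary_mask(matrix(TRUE, 40, 40), 1)
  p1 <- distance_profile(dapi, tt, vessel_distance_map(vs))
  p2 <- iterative_enlargement_oracle(vs, dapi, tt)
  expect_equal(p1$percent_per_bin[1], 100)
  expect_identical(p1$percent_per_bin, p2$percent_per_bin)
})

test_that("brute-force distance engine matches the two-pass EDT", {
  set.seed(77)
  for (k in 1:5) {
    m <- matrix(runif(60 * 60) < 0.03, 60, 60)
    if (!any(m)) m[30, 30] <- TRUE
    expect_equal(vascquant:::cpp_bruteforce_dist(m),
                 vascquant:::cpp_edt(m)$dist, tolerance = 1e-12)
  }
})
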