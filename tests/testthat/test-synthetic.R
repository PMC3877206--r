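# synthetic_data module: generator contracts, examples, invariants.

test_that("scene_spec validates its invariants", {
  expect_s3_class(scene_spec(), "scene_spec")
  expect_error(scene_spec(perfused_fraction = 1.2), "perfused_fraction")
  expect_error(scene_spec(resolution_um_per_px = 0), "resolution")
  expect_error(scene_spec(mean_diameter_um = -1), "mean_diameter_um")
  expect_error(scene_spec(hypoxia_distance_um = -5), "hypoxia")
  expect_error(scene_spec(field_width_um = 0), "field_width_um")
})

test_that("branch_prob = 0 gives junction-free two-endpoint trees", {
  spec <- small_spec(seed = 4, branch_prob = 0, n_stems = 8)
  trees <- generate_vessel_network(spec)
  expect_length(trees, 8)
  for (t in trees) {
    expect_identical(t$n_junctions, 0L)
    sk <- skeletonize_vs(binary_mask(tree_mask(t, spec), 1), prune_um = 8)
    expect_identical(sk$n_junctions, 0L)
  }
})

test_that("generation is deterministic given spec + seed", {
  spec <- small_spec(seed = 7, noise_sd = 300)
  t1 <- generate_vessel_network(spec)
  t2 <- generate_vessel_network(spec)
  expect_identical(t1, t2)
  s1 <- rasterize_scene(t1, spec)
  s2 <- rasterize_scene(t2, spec)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$gt$nuclei, s2$gt$nuclei)
  expect_identical(s1$gt$clean_masks, s2$gt$clean_masks)
})

test_that("non-overlapping stems give component count = n_stems (true MVD)", {
  spec <- scene_spec(field_width_um = 1000, field_height_um = 1000,
                     n_stems = 50, allow_overlap = FALSE, noise_sd = 0,
                     psf_sigma_um = 0, seed = 12)
  trees <- generate_vessel_network(spec)
  scn <- rasterize_scene(trees, spec)
  lab <- vascquant:::cpp_label(scn$gt$clean_masks$CD31, 8L)
  expect_identical(attr(lab, "n"), 50L)
  # true MVD uses the true TT area, recorded alongside the component count
  tm <- scn$gt$true_metrics
  expect_equal(tm$network$n_components, 50L)
  expect_equal(tm$index$mvd_per_mm2, 50 / tm$index$tt_area_mm2)
})

test_that("EF5 positivity is exactly the distance rule", {
  spec <- small_spec(seed = 5, n_stems = 3, perfused_fraction = 1)
  scn <- generate_scene(spec)
  nuc <- scn$gt$nuclei
  expect_identical(nuc$ef5, nuc$dist_perfused_um > spec$hypoxia_distance_um)
  # and with a single perfused vessel: recompute distances independently
  dmap <- distance_transform_um(
    binary_mask(scn$gt$clean_masks$CD31, spec$resolution_um_per_px))
  ii <- pmin(nrow(dmap), pmax(1, ceiling(nuc$y_um / spec$resolution_um_per_px)))
  jj <- pmin(ncol(dmap), pmax(1, ceiling(nuc$x_um / spec$resolution_um_per_px)))
  expect_equal(nuc$dist_perfused_um, dmap[cbind(ii, jj)])
})

test_that("covered_fraction = 0 empties the pericyte channels", {
  scn <- generate_scene(small_spec(seed = 2, covered_fraction = 0))
  expect_false(any(scn$gt$clean_masks$SMA))
  expect_false(any(scn$gt$clean_masks$desmin))
})

test_that("identity rendering reproduces scaled clean masks", {
  spec <- small_spec(seed = 3, noise_sd = 0, psf_sigma_um = 0)
  scn <- generate_scene(spec)
  for (ch in c("CD31", "DAPI", "EF5")) {
    rendered <- get_channel(scn$image, ch)
    expected <- spec$background_level +
      (spec$foreground_level - spec$background_level) *
      scn$gt$clean_masks[[ch]]
    expect_identical(rendered, matrix(as.integer(expected), nrow(rendered)),
                     info = ch)
  }
})

test_that("true metrics match hand-counted examples", {
  # straight single tube: centerline length known, no junctions
  spec <- small_spec(seed = 1, n_stems = 1, branch_prob = 0,
                     angle_sd_rad = 0)
  trees <- generate_vessel_network(spec)
  expect_equal(trees[[1]]$length_um,
               nrow(trees[[1]]$segments) * spec$step_um, tolerance = 1e-9)
  expect_identical(trees[[1]]$n_junctions, 0L)

  # covered-vessel fraction is flag counting: force 2 of 5 covered
  spec5 <- small_spec(seed = 9, n_stems = 5)
  trees5 <- generate_vessel_network(spec5)
  for (k in 1:5) trees5[[k]]$covered <- k <= 2
  scn <- rasterize_scene(trees5, spec5)
  expect_equal(scn$gt$true_metrics$index$covered_vessel_frequency, 40)
})

test_that("all-positive nuclei give marker area fraction = DAPI fraction in TT", {
  spec <- small_spec(seed = 6, marker_fractions = c(ki67 = 1, tunel = 0))
  scn <- generate_scene(spec)
  cm <- scn$gt$clean_masks
  expect_identical(cm$Ki67, cm$DAPI)
  tt <- dilate_um(cm$DAPI, 10, spec$resolution_um_per_px)
  expect_equal(scn$gt$true_metrics$index$ki67_index,
               sum(cm$Ki67 & tt) / sum(tt))
  expect_false(any(cm$TUNEL))
})

test_that("hypoxia is monotone non-increasing in perfused vessel density", {
  densities <- c(3, 8, 16, 30)
  means <- vapply(densities, function(n) {
    mean(vapply(1:5, function(s) {
      scn <- generate_scene(small_spec(seed = 100 + s, n_stems = n,
                                       perfused_fraction = 1,
                                       hypoxia_distance_um = 50))
      mean(scn$gt$nuclei$ef5)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("clean CD31 equals the union of per-tree rasters; nuclei records unique", {
  spec <- small_spec(seed = 8, n_stems = 6)
  trees <- generate_vessel_network(spec)
  scn <- rasterize_scene(trees, spec)
  union <- Reduce(`|`, lapply(trees, tree_mask, spec = spec))
  expect_identical(scn$gt$clean_masks$CD31, union)
  expect_identical(anyDuplicated(scn$gt$nuclei[, c("x_um", "y_um")]), 0L)
})

test_that("scene too small for a nucleus errors", {
  spec <- small_spec(nucleus_radius_um = 3)
  spec$field_width_um <- 4; spec$field_height_um <- 4
  expect_error(rasterize_scene(list(), spec), "too small")
})
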