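# vessel_network module: labelling, MVD, skeleton topology and metrics,
# cross-section profiles.

test_that("label_vessels connectivity and size filter", {
  n <- 200
  three <- Reduce(`|`, lapply(c(40, 100, 160), function(cx)
    disk_mask(n, cx, 100, 12)$px))
  expect_equal(label_vessels(binary_mask(three, 1))$n, 3L)
  # corner-to-corner touching squares merge under 8-connectivity
  px <- matrix(FALSE, 20, 20)
  px[5:8, 5:8] <- TRUE; px[9:12, 9:12] <- TRUE
  expect_equal(label_vessels(binary_mask(px, 1))$n, 1L)
  # small object dropped
  both <- three | disk_mask(n, 100, 30, 1.5)$px
  expect_equal(label_vessels(binary_mask(both, 1),
                             min_object_area_um2 = 30)$n, 3L)
  expect_equal(label_vessels(binary_mask(matrix(FALSE, 5, 5), 1))$n, 0L)
})

test_that("microvessel_density scales with tissue area", {
  expect_equal(microvessel_density(3, 1), 3)
  expect_equal(microvessel_density(3, 0.5), 6)
  expect_error(microvessel_density(3, 0), "tissue_area_mm2")
})

test_that("straight tube: topology, length, diameter, tortuosity", {
  vs <- tube_mask(100, 600, 50, 50, 550, 50, 5, marker = "VS")
  sk <- skeletonize_vs(vs, prune_um = 8)
  expect_identical(sk$n_junctions, 0L)
  expect_identical(sk$n_endpoints, 2L)
  expect_lt(abs(sk$length_um - 500) / 500, 0.05)
  nm <- network_metrics(sk, vs)
  expect_equal(nm$branch_per_mm, 0)
  expect_lt(abs(nm$mean_diameter_um - 10), 2)  # +- 2 * resolution
  expect_equal(nm$tortuosity, 1.0, tolerance = 0.02)
})

test_that("diameter tolerance shrinks with finer resolution", {
  for (res in c(1, 0.5)) {
    npx <- round(300 / res)
    vs <- tube_mask(round(60 / res), npx, 30, 30, 270, 30, 5, res = res,
                    marker = "VS")
    sk <- skeletonize_vs(vs, prune_um = 8)
    nm <- network_metrics(sk, vs)
    expect_lt(abs(nm$mean_diameter_um - 10), 2 * res + 1e-9)
  }
})

test_that("Y junction and H topology", {
  segs <- matrix(c(100, 150, 250, 150, 6,    # stem
                   250, 150, 350, 80, 6,     # branch up
                   250, 150, 350, 220, 6),   # branch down
                 ncol = 5, byrow = TRUE)
  vs <- binary_mask(vascquant:::cpp_rasterize_tubes(segs, 300, 450, 1), 1,
                    "VS")
  sk <- skeletonize_vs(vs, prune_um = 8)
  expect_identical(sk$n_junctions, 1L)
  expect_identical(sk$n_endpoints, 3L)

  # H shape: two junctions; branch_per_mm = junctions / skeleton length
  hseg <- matrix(c(100, 100, 100, 500, 6,
                   300, 100, 300, 500, 6,
                   100, 300, 300, 300, 6), ncol = 5, byrow = TRUE)
  hvs <- binary_mask(vascquant:::cpp_rasterize_tubes(hseg, 600, 400, 1), 1,
                     "VS")
  hsk <- skeletonize_vs(hvs, prune_um = 8)
  expect_identical(hsk$n_junctions, 2L)
  hnm <- network_metrics(hsk, hvs)
  expect_equal(hnm$branch_per_mm,
               2 / (hsk$length_um / 1000), tolerance = 1e-9)
  expect_equal(hnm$branch_per_mm, 2, tolerance = 0.10)  # ~2 mm of skeleton

  # empty mask -> empty graph
  esk <- skeletonize_vs(binary_mask(matrix(FALSE, 20, 20), 1))
  expect_equal(esk$length_um, 0)
  expect_equal(nrow(esk$edges), 0L)
})

test_that("skeleton stays inside VS and preserves component count", {
  spec <- small_spec(seed = 61, n_stems = 6, allow_overlap = FALSE)
  scn <- generate_scene(spec)
  vs <- binary_mask(scn$gt$clean_masks$CD31, 1, "VS")
  sk <- skeletonize_vs(vs, prune_um = 8)
  expect_true(all(vs$px[sk$skeleton]))
  ncomp_vs <- attr(vascquant:::cpp_label(vs$px, 8L), "n")
  ncomp_sk <- attr(vascquant:::cpp_label(sk$skeleton, 8L), "n")
  expect_identical(ncomp_sk, ncomp_vs)
})

test_that("cross-section profiles sample correctly", {
  nr <- 40; nc <- 60
  ramp <- matrix(rep(seq(0, 590, by = 10), each = nr), nr, nc)
  px <- array(0L, c(nr, nc, 2))
  px[, , 1] <- 500L
  px[, , 2] <- as.integer(ramp)
  img <- calibrated_image(px, c("flat", "ramp"), 1)
  pr <- cross_section_profile(img, c(0.5, 20), c(59.5, 20))
  expect_true(all(pr$flat == 500))
  # linear ramp: sampled values increase linearly at 10 counts/um
  fit <- coef(lm(pr$ramp ~ pr$distance_um))
  expect_equal(unname(fit[2]), 10, tolerance = 0.01)
  expect_error(cross_section_profile(img, c(0, 0), c(100, 0)), "outside")
  p8 <- cross_section_profile(img, c(0.5, 20), c(59.5, 20),
                              eight_bit = TRUE)
  expect_true(all(p8$ramp >= 0 & p8$ramp <= 255))
})

test_that("max projection reduces stacks", {
  a <- array(0, c(4, 4, 3)); a[1, 1, 2] <- 7; a[4, 4, 3] <- 2
  m <- max_project(a)
  expect_equal(m[1, 1], 7); expect_equal(m[4, 4], 2)
})
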