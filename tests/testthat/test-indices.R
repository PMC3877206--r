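# indices module: surface/endothelial/perivascular indices and the
# object-based covered-vessel frequency.

test_that("surface_index basic contracts", {
  region <- rect_mask(40, 11:30, 6:25)
  full <- rect_mask(40, 1:40, 1:40)
  expect_equal(surface_index(full, region, region), 1.0)
  empty <- binary_mask(matrix(FALSE, 40, 40), 1)
  expect_equal(surface_index(empty, region, region), 0.0)
  half <- rect_mask(40, 11:20, 6:25)  # covers exactly half the region rows
  expect_equal(surface_index(half, region, region), 0.5)
  expect_error(surface_index(full, region, empty), "empty")
  expect_error(surface_index(full, region, rect_mask(30, 1:2, 1:2)),
               "different grids")
})

test_that("endothelial index examples", {
  vs <- disk_mask(80, 20, 20, 8, marker = "VS")
  expect_equal(endothelial_index(vs, vs), 1.0)
  far <- disk_mask(80, 60, 60, 8)
  expect_equal(endothelial_index(far, vs), 0.0)
  # marker covering one of two equal-area vessels -> 0.5
  two <- binary_mask(disk_mask(120, 30, 30, 10)$px |
                     disk_mask(120, 90, 90, 10)$px, 1, "VS")
  one <- disk_mask(120, 30, 30, 10)
  expect_equal(endothelial_index(one, two), 0.5, tolerance = 0.01)
})

test_that("perivascular index matches the analytic annulus/disk ratio", {
  n <- 320
  vs <- disk_mask(n, 40, 40, 10, res = 0.25, marker = "VS")
  pvs <- build_pvs(vs, shell_um = 5)
  marker <- binary_mask(pvs$px, 0.25, "SMA")  # fills the full shell
  got <- perivascular_index(marker, pvs, vs)
  expect_equal(as.numeric(got), (15^2 - 10^2) / 10^2, tolerance = 0.03)
  empty <- binary_mask(matrix(FALSE, n, n), 0.25)
  expect_equal(perivascular_index(empty, pvs, vs), 0.0)
  inside <- binary_mask(vs$px, 0.25)  # only inside VS, not in the shell
  expect_equal(perivascular_index(inside, pvs, vs), 0.0)
})

test_that("covered_vessel_frequency counts per-object shells", {
  # five disk vessels; pericyte staining around exactly two of them
  n <- 300
  centers <- cbind(c(50, 150, 250, 50, 150), c(50, 50, 50, 200, 200))
  vs_px <- Reduce(`|`, lapply(1:5, function(k)
    disk_mask(n, centers[k, 1], centers[k, 2], 10)$px))
  vs <- binary_mask(vs_px, 1, "VS")
  pvs <- build_pvs(vs, 5)
  obj <- label_vessels(vs)
  expect_equal(obj$n, 5L)
  shell2 <- Reduce(`|`, lapply(1:2, function(k) {
    d <- disk_mask(n, centers[k, 1], centers[k, 2], 13)$px
    d & !disk_mask(n, centers[k, 1], centers[k, 2], 10)$px
  }))
  sma <- binary_mask(shell2, 1, "SMA")
  expect_equal(as.numeric(covered_vessel_frequency(obj, sma, sma, pvs)), 40)
  # fully sheathed -> 100; no staining -> 0
  allsh <- binary_mask(pvs$px, 1)
  expect_equal(as.numeric(covered_vessel_frequency(obj, allsh, allsh, pvs)),
               100)
  none <- binary_mask(matrix(FALSE, n, n), 1)
  expect_equal(as.numeric(covered_vessel_frequency(obj, none, none, pvs)), 0)
  expect_error(covered_vessel_frequency(label_vessels(none), none, none,
                                        pvs), "no vessel")
})

test_that("adjacent vessels never share shell pixels", {
  n <- 120
  vs_px <- disk_mask(n, 40, 60, 10)$px | disk_mask(n, 64, 60, 10)$px
  vs <- binary_mask(vs_px, 1, "VS")
  obj <- label_vessels(vs)
  pvs <- build_pvs(vs, 5)
  shells <- vessel_shells(obj, pvs)
  expect_setequal(unique(as.vector(shells[shells > 0])),
                  seq_len(max(obj$labels)))
  expect_true(all((shells > 0) == pvs$px))
})

test_that("index is additive over a partition of the field", {
  spec <- small_spec(seed = 31)
  scn <- generate_scene(spec)
  res <- spec$resolution_um_per_px
  cm <- scn$gt$clean_masks
  tt <- build_tt(binary_mask(cm$DAPI, res))
  ki <- binary_mask(cm$Ki67, res)
  top <- rect_mask(300, 1:150, 1:300, res = res)
  parts <- list(top$px, !top$px)
  whole <- surface_index(ki, tt, tt)
  weighted <- sum(vapply(parts, function(p) {
    ttp <- binary_mask(tt$px & p, res)
    if (!any(ttp$px)) return(0)
    surface_index(binary_mask(ki$px & p, res), ttp, ttp) *
      sum(ttp$px) / sum(tt$px)
  }, numeric(1)))
  expect_equal(whole, weighted, tolerance = 1e-12)
})
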