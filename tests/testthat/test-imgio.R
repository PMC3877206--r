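# imgio module: round-trips and calibration errors.

test_that("image write/read round-trips pixels, names and resolution", {
  px <- array(sample.int(65536, 3 * 40 * 30, replace = TRUE) - 1L,
              c(40, 30, 3))
  img <- calibrated_image(px, c("DAPI", "CD31", "EF5"), 0.323)
  path <- file.path(tempdir(), "rt.tif")
  write_image(img, path)
  back <- read_image(path)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$channels, img$channels)
  expect_equal(back$resolution_um_per_px, 0.323)
})

test_that("missing calibration or name mismatch is an error", {
  px <- array(0L, c(10, 10, 2))
  img <- calibrated_image(px, c("a", "b"), 1)
  path <- file.path(tempdir(), "nocal.tif")
  write_image(img, path)
  file.remove(vascquant:::sidecar_path(path))
  expect_error(read_image(path), "missing calibration")
  expect_error(read_image(path, meta = list(resolution_um_per_px = 0,
                                            channels = list("a", "b"))),
               "resolution")
  expect_error(read_image(path, meta = list(resolution_um_per_px = 1,
                                            channels = list("a"))),
               "channel-name count")
  expect_error(read_image(file.path(tempdir(), "absent.tif")),
               "does not exist")
  expect_error(calibrated_image(px, c("a", "b", "c"), 1), "channel")
  expect_error(calibrated_image(px - 1L, c("a", "b"), 1), "16-bit")
})

test_that("mask and scene-spec round-trips are lossless", {
  m <- disk_mask(32, 16, 16, 7, res = 0.5, marker = "CD31")
  p <- file.path(tempdir(), "mask.tif")
  write_mask(m, p)
  back <- read_mask(p)
  expect_identical(back$px, m$px)
  expect_equal(back$resolution_um_per_px, 0.5)
  expect_identical(back$marker, "CD31")

  spec <- small_spec(seed = 42, n_stems = 3)
  sp <- file.path(tempdir(), "spec.json")
  write_scene_spec(spec, sp)
  spec2 <- read_scene_spec(sp)
  expect_equal(unclass(spec2), unclass(spec))
})

test_that("ground truth round-trips through JSON + mask TIFF", {
  scn <- generate_scene(small_spec(seed = 13, n_stems = 3,
                                   field_width_um = 150,
                                   field_height_um = 150))
  prefix <- file.path(tempdir(), "gt")
  write_ground_truth(scn$gt, prefix)
  back <- read_ground_truth(prefix)
  expect_identical(back$clean_masks, scn$gt$clean_masks)
  expect_equal(length(back$trees), length(scn$gt$trees))
  expect_equal(back$trees[[2]]$segments, scn$gt$trees[[2]]$segments)
  expect_equal(back$trees[[2]]$radius_um, scn$gt$trees[[2]]$radius_um)
  expect_equal(back$true_metrics$index$mvd_per_mm2,
               scn$gt$true_metrics$index$mvd_per_mm2)
})

test_that("write_results is deterministic and handles empty tables", {
  idx <- data.frame(image_id = c("b", "a"), group = "g", v = c(2, 1))
  d1 <- file.path(tempdir(), "res1"); d2 <- file.path(tempdir(), "res2")
  write_results(list(index = idx), d1)
  write_results(list(index = idx[2:1, ]), d2)  # different row order in
  expect_identical(readLines(file.path(d1, "index.csv")),
                   readLines(file.path(d2, "index.csv")))
  expect_equal(length(readLines(file.path(d1, "index.csv"))), 3L)
  expect_warning(
    write_results(list(empty = idx[0, ]), file.path(tempdir(), "res3")),
    "empty")
  expect_true(file.exists(file.path(tempdir(), "res3", "empty.csv")))
})
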