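# segmentation module: background estimator, ratio rule, size filter,
# monotonicity, and exact recovery on noise-free scenes.

test_that("background estimator examples", {
  const <- matrix(137, 60, 60)
  bg <- estimate_background(const, 20, 1)
  expect_true(all(bg == 137))
  expect_true(all(estimate_background(matrix(0, 30, 30), 10, 1) == 1))
  # bright 10x10 square on constant 100, radius much larger than the square:
  # background at the square center stays ~100 (robust median)
  img <- matrix(100, 100, 100)
  img[46:55, 46:55] <- 5000
  bg <- estimate_background(img, 40, 1)
  expect_lt(abs(bg[50, 50] - 100) / 100, 0.10)
  expect_error(estimate_background(matrix(numeric(0), 0, 0), 10, 1), "empty")
})

test_that("segment_channel applies the ratio rule, floor and size filter", {
  p <- segmentation_params(background_radius_um = 30, ratio_k = 2,
                           negcontrol_floor = 150, min_object_area_um2 = 0)
  # uniform image below the floor -> empty
  m <- segment_channel(matrix(120, 50, 50), p, resolution = 1)
  expect_false(any(m$px))
  # 20x20 block at 1000 over flat 100 -> exactly that block
  img <- matrix(100, 80, 80)
  img[31:50, 31:50] <- 1000
  m <- segment_channel(img, p, resolution = 1, marker = "test")
  want <- matrix(FALSE, 80, 80); want[31:50, 31:50] <- TRUE
  expect_identical(m$px, want)
  expect_identical(m$provenance$ratio_k, 2)
  # 2-px speck removed by the size filter
  img2 <- matrix(100, 50, 50); img2[10, 10:11] <- 1000
  p2 <- segmentation_params(background_radius_um = 30, ratio_k = 2,
                            negcontrol_floor = 150, min_object_area_um2 = 3)
  expect_false(any(segment_channel(img2, p2, resolution = 1)$px))
  p0 <- segmentation_params(min_object_area_um2 = 0)
  expect_true(sum(segment_channel(img2, p0, resolution = 1)$px) == 2)
})

test_that("raising ratio_k or the floor never grows the mask", {
  set.seed(33)
  img <- matrix(100 + 400 * (matrix(runif(100 * 100), 100) < 0.2) +
                rnorm(1e4, 0, 30), 100)
  img <- pmax(img, 0)
  masks <- lapply(c(1.5, 2, 3, 4), function(k)
    segment_channel(img, segmentation_params(ratio_k = k,
                                             min_object_area_um2 = 0),
                    resolution = 1)$px)
  for (i in 1:3)
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  floors <- lapply(c(0, 200, 400, 600), function(f)
    segment_channel(img, segmentation_params(negcontrol_floor = f,
                                             min_object_area_um2 = 0),
                    resolution = 1)$px)
  for (i in 1:3)
    expect_true(all(floors[[i + 1]] <= floors[[i]]))
})

test_that("size filter is idempotent", {
  set.seed(11)
  px <- matrix(runif(90 * 90) < 0.25, 90, 90)
  f1 <- vascquant:::filter_small_objects(px, 12, 1)
  f2 <- vascquant:::filter_small_objects(f1, 12, 1)
  expect_identical(f1, f2)
})

test_that("noise-free synthetic channels segment to the clean masks (Dice >= 0.99)", {
  spec <- small_spec(seed = 19)
  scn <- generate_scene(spec)
  p <- segmentation_params(min_object_area_um2 = 0)
  for (ch in c("CD31", "DAPI", "Ki67", "SMA")) {
    m <- segment_channel(scn$image, p, marker = ch)
    expect_gte(dice_coef(m$px, scn$gt$clean_masks[[ch]]), 0.99)
  }
})

test_that("negative-control floor is the stated percentile", {
  set.seed(5)
  v <- matrix(rnorm(1e4, 500, 100), 100)
  expect_equal(negcontrol_floor_from(v, 0.999),
               as.numeric(quantile(v, 0.999, names = FALSE)))
  expect_error(segmentation_params(ratio_k = 1), "ratio_k")
})
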