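test_that("excess green hits its closed-form extremes", {
  img <- array(0, c(16, 16, 3))
  img[1, 1, ] <- c(0, 1, 0)          # pure green
  img[1, 2, ] <- c(0.5, 0.5, 0.5)    # neutral gray
  img[1, 3, ] <- c(1, 0, 0)          # pure red
  exg <- excess_green(img)
  expect_equal(exg[1, 1], 1.8)
  expect_equal(exg[1, 2], 1.8 / 3 - 2 / 3, tolerance = 1e-12)
  expect_equal(exg[1, 3], -1)
  expect_equal(exg[2, 2], 1.8 / 3 - 2 / 3, tolerance = 1e-12)  # zero-sum pixel
})

test_that("otsu matches the exhaustive between-class variance search", {
  set.seed(21)
  maps <- list(
    matrix(c(rep(-0.5, 128), rep(1, 128)), 16, 16),
    matrix(rnorm(900), 30, 30),
    matrix(c(rnorm(300, -0.2, 0.05), rnorm(300, 0.55, 0.1),
             rnorm(300, 0.1, 0.2)), 30, 30),
    excess_green(generate_scene(small_scene_spec(5))$image)
  )
  for (map in maps) {
    got <- otsu_threshold(map)
    expect_equal(got$threshold, otsu_bruteforce(map), tolerance = 1e-12)
    expect_equal(got$mask, map > got$threshold)
  }
})

test_that("a perfectly bimodal map splits exactly", {
  map <- matrix(c(rep(-0.5, 100), rep(1, 156)), 16, 16)
  got <- otsu_threshold(map)
  expect_equal(got$mask, map == 1)
})

test_that("a constant map degenerates with a warning and empty mask", {
  expect_warning(got <- otsu_threshold(matrix(0.3, 10, 10)),
                 "degenerate histogram")
  expect_false(any(got$mask))
})

test_that("morphological cleanup removes specks, fills pinholes, keeps ribbons", {
  speck <- matrix(FALSE, 20, 20); speck[10, 10] <- TRUE
  expect_false(any(morphological_cleanup(speck, 1)))
  holed <- matrix(FALSE, 30, 30); holed[5:24, 5:24] <- TRUE
  holed[12, 12] <- FALSE
  cleaned <- morphological_cleanup(holed, 1)
  expect_true(cleaned[12, 12])
  ## solid apart from the opening's rounding of the four square corners
  expect_gte(sum(cleaned), 396)
  expect_true(all(cleaned[6:23, 6:23]))
  ## 3 px wide ribbon survives a radius-1 opening with < 30% area loss
  rib <- matrix(FALSE, 30, 60); rib[14:16, 8:52] <- TRUE
  kept <- morphological_cleanup(rib, 1)
  expect_gte(sum(kept) / sum(rib), 0.7)
  ## large enclosed background pockets are not swallowed
  ring <- matrix(FALSE, 60, 60)
  ring[15:45, 15:45] <- TRUE; ring[20:40, 20:40] <- FALSE
  expect_equal(sum(morphological_cleanup(ring, 1) & !ring), 0)
})

test_that("cleanup is idempotent on real segmentation masks", {
  for (seed in c(2, 13)) {
    sc <- generate_scene(small_scene_spec(seed))
    m1 <- otsu_threshold(excess_green(sc$image))$mask
    c1 <- morphological_cleanup(m1, 1)
    expect_equal(morphological_cleanup(c1, 1), c1)
  }
})

test_that("segmentation recovers the leaf mask of a synthetic scene", {
  cfg <- run_config()
  sc <- generate_scene(scene_spec(n_plants = 150, leaf_stage = 2, seed = 23))
  rect <- rectify_target_area(sc$image, cfg)
  mask <- segment_seedlings(rect, cfg)
  truth <- warp_and_crop(matrix(as.numeric(sc$leaf_mask),
                                nrow(sc$leaf_mask)),
                         attr(rect, "homography"), cfg$target_size) > 0.5
  expect_gte(iou(mask, truth), 0.85)
})

test_that("bare soil yields almost no foreground", {
  cfg <- small_cfg()
  sc <- generate_scene(small_scene_spec(31, n_plants = 0))
  rect <- rectify_target_area(sc$image, cfg)
  mask <- segment_seedlings(rect, cfg)
  expect_lte(mean(mask), 0.01)
})

test_that("segmentation is invariant to global brightness scaling", {
  cfg <- small_cfg()
  sc <- generate_scene(small_scene_spec(17))
  rect <- rectify_target_area(sc$image, cfg)
  m1 <- segment_seedlings(rect, cfg)
  for (cscale in c(0.5, 0.8)) {
    m2 <- segment_seedlings(rect * cscale, cfg)
    expect_equal(m2, m1, ignore_attr = TRUE)
  }
})

test_that("an all-green image passes through the degenerate path", {
  img <- array(rep(c(0.1, 0.7, 0.1), each = 32 * 32), c(32, 32, 3))
  expect_warning(mask <- segment_seedlings(img, run_config()),
                 "degenerate")
  expect_false(any(mask))
})
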