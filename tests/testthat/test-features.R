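test_that("coverage degree is the foreground fraction", {
  expect_equal(coverage_degree(matrix(FALSE, 10, 10)), 0)
  expect_equal(coverage_degree(matrix(TRUE, 10, 10)), 1)
  m <- matrix(FALSE, 800, 800)
  m[seq_len(64000)] <- TRUE
  expect_equal(coverage_degree(m), 0.1)
  expect_error(coverage_degree(matrix(logical(0), 0, 0)), "zero-size")
})

test_that("harris response vanishes on flat masks and edges, peaks at corners", {
  p <- harris_params()
  expect_equal(range(harris_response(matrix(TRUE, 64, 64), p)), c(0, 0))
  ## ideal axis-aligned L corner at (32, 32)
  Lm <- matrix(FALSE, 64, 64); Lm[1:32, 1:32] <- TRUE
  r <- harris_response(Lm, p)
  peak <- which(r == max(r), arr.ind = TRUE)[1, ]
  expect_gt(max(r), 0)
  expect_lte(max(abs(peak - c(32, 32))), 3)
  expect_equal(as.integer(count_angular_points(r, p)), 1L)
  ## long straight edge: 1-D gradient structure, det = 0, trace > 0
  edge <- matrix(FALSE, 64, 64); edge[, 1:32] <- TRUE
  expect_lte(max(harris_response(edge, p)), 1e-9)
})

test_that("angular point counting separates and counts distinct corners", {
  p <- harris_params()
  expect_equal(as.integer(count_angular_points(matrix(0, 32, 32), p)), 0L)
  ## two quarter-plane corners far apart
  m <- matrix(FALSE, 128, 128)
  m[1:40, 1:40] <- TRUE
  m[89:128, 89:128] <- TRUE
  expect_equal(as.integer(count_angular_points(harris_response(m, p), p)), 2L)
  ## a rectangle exposes its four corners
  rect <- matrix(FALSE, 80, 120); rect[20:40, 10:50] <- TRUE
  expect_equal(as.integer(count_angular_points(harris_response(rect, p), p)),
               4L)
})

test_that("angular point count is invariant to whole-pixel translation", {
  p <- harris_params()
  m1 <- ribbon_bundle_mask(140, cbind(c(40, 60, 80), c(30, 40, 35)),
                           c(0.4, 1.1, 5.8))
  m2 <- matrix(FALSE, 140, 140)
  m2[16:140, 9:140] <- m1[1:125, 1:132]
  ha1 <- count_angular_points(harris_response(m1, p), p)
  ha2 <- count_angular_points(harris_response(m2, p), p)
  expect_equal(as.integer(ha1), as.integer(ha2))
})

test_that("overlap lowers coverage and raises angular points", {
  p <- harris_params()
  sep <- ribbon_bundle_mask(200, cbind(c(30, 30, 130, 130),
                                       c(30, 130, 30, 130)), rep(0.5, 4))
  ovl <- ribbon_bundle_mask(200, cbind(c(90, 100, 95, 105),
                                       c(80, 85, 90, 80)),
                            c(0.3, 1.2, 2.2, 5.5))
  expect_lt(coverage_degree(ovl), coverage_degree(sep))
  expect_gt(as.integer(count_angular_points(harris_response(ovl, p), p)),
            as.integer(count_angular_points(harris_response(sep, p), p)))
})

test_that("curling a leaf lowers coverage and raises angular points", {
  p <- harris_params()
  co_drop <- ha_rise <- logical(20)
  for (seed in 1:20) {
    flat <- leaf_mask_fixture(FALSE, seed)
    curl <- leaf_mask_fixture(TRUE, seed)
    co_drop[seed] <- coverage_degree(curl) < coverage_degree(flat)
    ha_rise[seed] <-
      count_angular_points(harris_response(curl, p), p) >
      count_angular_points(harris_response(flat, p), p)
  }
  expect_true(all(co_drop))
  expect_true(all(ha_rise))
})

test_that("coverage increases strictly with plant count at fixed seed", {
  cos <- vapply(c(10, 30, 60, 100), function(n) {
    sc <- generate_scene(scene_spec(n_plants = n, leaf_stage = 1, seed = 42))
    coverage_degree(sc$leaf_mask)
  }, numeric(1))
  expect_true(all(diff(cos) > 0))
})

test_that("feature extraction resolves the variety coefficient", {
  cfg <- run_config()
  empty <- matrix(FALSE, 64, 64)
  f <- extract_features(empty, La = 2, variety = "YM23", cfg)
  expect_equal(f$Co, 0)
  expect_equal(f$Ha, 0L)
  expect_equal(f$Va, 1.05)
  f2 <- extract_features(empty, La = 2.3, variety = "HM7", cfg)
  expect_equal(f2$Va, 0.86)
  expect_error(extract_features(empty, La = 2, variety = "XX", cfg),
               "YM23")
  expect_error(extract_features(empty, La = 5, variety = "YM23", cfg),
               "leaf age")
})

test_that("harris parameter validation enforces the documented ranges", {
  expect_error(harris_params(k = 0.1), "0.04")
  expect_error(harris_params(threshold_frac = 1.2), "threshold_frac")
  expect_error(run_config(harris_k = 0.2), "harris_k")
})
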