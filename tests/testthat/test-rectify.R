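make_frame_image <- function(n = 200, outer = NULL, band = 0.07,
                             soil = c(0.47, 0.35, 0.24)) {
  if (is.null(outer)) {
    m <- 0.12 * n
    outer <- cbind(c(m, m, n - m, n - m), c(m, n - m, n - m, m))
  }
  ctr <- colMeans(outer)
  inner <- sweep(sweep(sweep(outer, 2, ctr), 1, rep(1 - band, 4), `*`),
                 2, ctr, `+`)
  img <- array(rep(soil, each = n * n), c(n, n, 3))
  bandpx <- quad_mask(n, outer) & !quad_mask(n, inner)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[bandpx] <- 0.96
    img[, , ch] <- plane
  }
  list(img = img, inner = inner, outer = outer)
}

test_that("frame colour thresholds match the per-pixel brute force", {
  fr <- make_frame_image(120)
  mask <- extract_white_quadrangle(fr$img)
  expect_equal(mask, eq1_bruteforce(fr$img))
  ## white passes, leaf green and pale straw fail the thresholds
  probe <- array(0, c(16, 16, 3))
  probe[1, 1, ] <- c(1, 1, 1)       # white: sum 3 > 2.1, r - b = 0
  probe[1, 2, ] <- c(0.2, 0.6, 0.2) # leaf green: sum 1.0
  probe[1, 3, ] <- c(0.9, 0.8, 0.6) # straw: r - b = 0.3
  bf <- eq1_bruteforce(probe)
  expect_true(bf[1, 1])
  expect_false(bf[1, 2])
  expect_false(bf[1, 3])
})

test_that("a frameless image raises a stage-labelled error", {
  soil <- array(rep(c(0.47, 0.35, 0.24), each = 64 * 64), c(64, 64, 3))
  expect_error(rectify_target_area(soil, run_config(target_size = 64)),
               "extract_white_quadrangle")
})

test_that("square corners are recovered exactly and circles are rejected", {
  m <- matrix(FALSE, 60, 60); m[15:44, 10:39] <- TRUE
  ch <- trace_boundary(m)
  q <- detect_frame_corners(curvature_profile(ch), ch)
  truth <- cbind(c(15, 15, 44, 44), c(10, 39, 39, 10))
  expect_lte(max(abs(unclass(q) - truth)), 2)
  chc <- trace_boundary(circle_mask(30))
  expect_error(detect_frame_corners(curvature_profile(chc), chc),
               "corners not found")
})

test_that("corners of random convex quadrangles localise within 3 px", {
  set.seed(101)
  errs <- replicate(50, {
    truth <- random_convex_quad(800)
    mask <- quad_mask(800, truth)
    ch <- trace_boundary(mask)
    q <- detect_frame_corners(curvature_profile(ch), ch)
    truth_o <- order_quadrangle(truth)
    mean(sqrt(rowSums((unclass(q) - unclass(truth_o))^2)))
  })
  expect_lte(mean(errs), 3)
  expect_lte(max(errs), 6)
})

test_that("four-point perspective solving is exact on its correspondences", {
  sq <- order_quadrangle(cbind(c(1, 1, 10, 10), c(1, 10, 10, 1)))
  expect_lte(max(abs(unclass(solve_perspective(sq, sq)) - diag(3))), 1e-9)
  shifted <- order_quadrangle(unclass(sq) + rep(c(5, 7), each = 4))
  Ht <- solve_perspective(sq, shifted)
  expect_equal(apply_homography(Ht, unclass(sq)), unclass(shifted),
               ignore_attr = TRUE, tolerance = 1e-9)
  set.seed(7)
  for (rep in 1:5) {
    src <- order_quadrangle(random_convex_quad(300))
    dst <- target_square(240)
    H <- solve_perspective(src, dst)
    expect_lte(max(abs(apply_homography(H, unclass(src)) - unclass(dst))),
               1e-9)
  }
  bad <- cbind(c(1, 2, 3, 1), c(1, 2, 3, 10))  # three collinear points
  expect_error(solve_perspective(bad, unclass(target_square(10))),
               "degenerate")
})

test_that("homographies invert to numerical identity", {
  set.seed(9)
  src <- order_quadrangle(random_convex_quad(500))
  H <- solve_perspective(src, target_square(400))
  pts <- cbind(runif(100, 1, 500), runif(100, 1, 500))
  back <- apply_homography(homography_inverse(H), apply_homography(H, pts))
  expect_lte(max(abs(back - pts)), 1e-8)
})

test_that("warping with identity and quarter-turn transforms resamples exactly", {
  set.seed(3)
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  id <- structure(diag(3), class = "homography")
  expect_lte(max(abs(warp_and_crop(img, id, 48) - img)), 1e-6)
  ## quarter turn: solve the transform from corner correspondences and
  ## compare against the direct array rotation
  n <- 48
  src <- cbind(c(1, 1, n, n), c(1, n, n, 1))        # TL TR BR BL
  dst <- cbind(c(1, n, n, 1), c(n, n, 1, 1))        # TL -> TR -> BR -> BL
  H <- solve_perspective(src, dst)
  rot <- warp_and_crop(img, H, n)
  ## clockwise quarter turn: out[r, c] = in[n + 1 - c, r]
  ref <- aperm(img, c(2, 1, 3))[, n:1, , drop = FALSE]
  expect_lte(max(abs(rot - ref)), 1e-6)
})

test_that("rectification recovers the target area of synthetic scenes", {
  cfg <- run_config()   # published 800 px target
  for (seed in c(7, 11)) {
    sc <- generate_scene(scene_spec(n_plants = 150, leaf_stage = 2,
                                    seed = seed))
    rect <- rectify_target_area(sc$image, cfg)
    expect_equal(dim(rect), c(800, 800, 3))
    src <- attr(rect, "corners")
    expect_lte(max(abs(unclass(src) - unclass(sc$frame_corners))), 3)
    ## ground-truth leaf mask and pipeline mask agree after rectification
    mask <- segment_seedlings(rect, cfg)
    truth <- warp_and_crop(matrix(as.numeric(sc$leaf_mask),
                                  nrow(sc$leaf_mask)),
                           attr(rect, "homography"), 800) > 0.5
    expect_gte(iou(mask, truth), 0.9)
  }
})

test_that("an already fronto-parallel frame rectifies to its interior crop", {
  fr <- make_frame_image(240)
  cfg <- run_config(target_size = 128)
  rect <- rectify_target_area(fr$img, cfg)
  ## interior is uniform soil: the rectified tile must be almost exactly it
  expect_lte(max(abs(rect[, , 1] - 0.47)), 0.02)
  expect_lte(max(abs(rect[, , 2] - 0.35)), 0.02)
  corners <- attr(rect, "corners")
  expect_lte(max(abs(unclass(corners) - unclass(order_quadrangle(fr$inner)))),
             3)
})
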