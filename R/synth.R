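#' Specification of a synthetic field scene
#'
#' Describes one emulated field photograph: brown soil with pale straw
#' distractors, a white 1 m x 1 m frame band warped by a bounded random
#' perspective, and green tapered leaf ribbons (1-3 per plant, optional
#' curl). The default plant density (150 per frame) sits in the middle of
#' the 75-300 plants/m2 range typical of field sowing densities; leaf
#' dimensions correspond to roughly 8-9 cm long, slightly widened blades
#' at the generator's ~400 px/m scale, chosen so ribbons survive
#' rasterisation and a radius-1 morphological opening.
#'
#' @param n_plants Number of plants inside the frame.
#' @param leaf_stage Mean leaf age in `[1, 3]`; non-integer values mix
#'   `floor` and `ceiling` leaf counts per plant.
#' @param leaf_length_px,leaf_width_px Length-2 numeric `c(mean, sd)` of
#'   leaf ribbon dimensions in scene pixels.
#' @param curl_prob Probability that a leaf is rendered curled (folded).
#' @param straw_count Number of pale straw distractors.
#' @param frame_tilt Maximum corner displacement of the frame as a
#'   fraction of scene size (perspective distortion bound).
#' @param scene_px Scene side length in pixels.
#' @param seed Integer seed; scenes are deterministic given the seed.
#' @return List of class `"scene_spec"`.
#' @export
scene_spec <- function(n_plants = 150, leaf_stage = 2,
                       leaf_length_px = c(34, 6), leaf_width_px = c(5, 0.6),
                       curl_prob = 0.15, straw_count = 25,
                       frame_tilt = 0.06, scene_px = 520, seed = 1L) {
  if (n_plants < 0) abort("`n_plants` must be >= 0")
  if (leaf_stage < 1 || leaf_stage > 3) abort("`leaf_stage` must lie in [1, 3]")
  if (curl_prob < 0 || curl_prob > 1) abort("`curl_prob` must lie in [0, 1]")
  if (frame_tilt < 0 || frame_tilt > 0.12) {
    abort("`frame_tilt` must lie in [0, 0.12]")
  }
  if (scene_px < 128) abort("`scene_px` must be >= 128")
  structure(list(n_plants = as.integer(n_plants), leaf_stage = leaf_stage,
                 leaf_length_px = leaf_length_px,
                 leaf_width_px = leaf_width_px,
                 curl_prob = curl_prob, straw_count = as.integer(straw_count),
                 frame_tilt = frame_tilt, scene_px = as.integer(scene_px),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic field scene with ground truth
#'
#' Renders the scene described by a [scene_spec()] and returns both the
#' image and everything the pipeline is supposed to recover: the exact
#' inner-frame corners, the leaf mask and the plant count. Soil is
#' low-frequency brown noise; straw distractors are pale elongated
#' capsules with `r - b >= 0.1` so the frame's colour test must reject
#' them; the frame is a white quadrangle band whose corners are displaced
#' by at most `frame_tilt * scene_px`; each plant carries `floor` or
#' `ceiling` of `leaf_stage` tapered quadratic leaf ribbons, and curled
#' leaves are drawn as folded ribbons (less area, an extra sharp fold).
#'
#' @param spec A [scene_spec()].
#' @return List of class `"wheat_scene"`: `image` (`H x W x 3`),
#'   `leaf_mask` (logical, subset of the frame interior), `frame_corners`
#'   (inner 4 x 2 quadrangle, TL TR BR BL), `n_plants`,
#'   `per_plant_leaf_count`, `centers`, and the `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(n_plants = 30, scene_px = 256,
#'                                 straw_count = 8, seed = 4))
#' sc$n_plants
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  local_seeded(spec$seed, render_scene(spec))
}

render_scene <- function(spec) {
  size <- spec$scene_px
  img <- soil_background(size)

  ## straw distractors: pale, red-shifted so Eq-style white test rejects them
  straw_px <- vector("list", spec$straw_count)
  straw_col <- vector("list", spec$straw_count)
  for (i in seq_len(spec$straw_count)) {
    p0 <- runif(2, 1, size)
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, 0.03 * size, 0.1 * size)
    w <- runif(1, 1.2, 2.4)
    tt <- seq(0, 1, length.out = max(6, ceiling(len)))
    ctr <- cbind(p0[1] + tt * len * sin(ang), p0[2] + tt * len * cos(ang))
    px <- stamp_discs(size, size, ctr, rep(w / 2, length(tt)))
    shade <- runif(1, 0.85, 1.05)
    col <- pmin(c(0.84, 0.76, 0.60) * shade, 1)
    straw_px[[i]] <- px
    straw_col[[i]] <- matrix(col, length(px), 3, byrow = TRUE)
  }
  img <- paint_batch(img, unlist(straw_px), do.call(rbind, straw_col),
                     jitter_sd = 0.015)

  ## frame band: random convex quadrangle, inner contour = truth corners
  quads <- frame_quadrangles(size, spec$frame_tilt)
  grid_r <- matrix(seq_len(size), size, size)
  grid_c <- matrix(seq_len(size), size, size, byrow = TRUE)
  in_outer <- in_convex_quad(grid_r, grid_c, quads$outer)
  in_inner <- in_convex_quad(grid_r, grid_c, quads$inner)
  band <- which(in_outer & !in_inner)
  white <- pmax(pmin(0.965 + rnorm(length(band), 0, 0.006), 1), 0.9)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[band] <- white          # equal channels: r - b = 0
    img[, , ch] <- plane
  }

  ## plants: uniform inside a slightly inset interior
  inset <- shrink_quad(quads$inner, 0.96)
  area_in <- quad_area(inset)
  if (spec$n_plants * 9 > area_in) {
    abort("too many plants: placement area exhausted")
  }
  centers <- sample_in_quad(spec$n_plants, inset)
  leaf_mask <- matrix(FALSE, size, size)
  leaf_counts <- integer(spec$n_plants)
  base_stage <- floor(spec$leaf_stage)
  frac <- spec$leaf_stage - base_stage
  lmu <- spec$leaf_length_px[1]; lsd <- spec$leaf_length_px[2]
  wmu <- spec$leaf_width_px[1]; wsd <- spec$leaf_width_px[2]
  leaf_px <- list()
  leaf_col <- list()
  for (p in seq_len(spec$n_plants)) {
    n_leaves <- base_stage + (runif(1) < frac)
    leaf_counts[p] <- n_leaves
    g_c <- runif(1, 0.50, 0.62)
    s_sum <- runif(1, 0.9, 1.25)
    col <- s_sum * c(0.55 * (1 - g_c), g_c, 0.45 * (1 - g_c))
    for (l in seq_len(n_leaves)) {
      len <- max(rnorm(1, lmu, lsd), 10)
      w <- max(rnorm(1, wmu, wsd), 3)
      curled <- runif(1) < spec$curl_prob
      ctr <- leaf_ribbon(centers[p, ], len, w, curled)
      px <- stamp_discs(size, size, ctr$pos, ctr$radius)
      px <- px[in_inner[px]]      # leaves stay inside the frame interior
      leaf_mask[px] <- TRUE
      leaf_px[[length(leaf_px) + 1L]] <- px
      leaf_col[[length(leaf_col) + 1L]] <- matrix(col, length(px), 3,
                                                  byrow = TRUE)
    }
  }
  img <- paint_batch(img, unlist(leaf_px), do.call(rbind, leaf_col),
                     jitter_sd = 0.01)

  structure(list(image = img, leaf_mask = leaf_mask,
                 frame_corners = order_quadrangle(quads$inner),
                 n_plants = spec$n_plants,
                 per_plant_leaf_count = leaf_counts,
                 centers = centers, spec = spec),
            class = "wheat_scene")
}

#' @export
print.wheat_scene <- function(x, ...) {
  cat("<wheat_scene>", dim(x$image)[1], "x", dim(x$image)[2], "px,",
      x$n_plants, "plants, leaf stage", x$spec$leaf_stage,
      ", seed", x$spec$seed, "\n")
  invisible(x)
}

soil_background <- function(size) {
  base <- c(0.47, 0.35, 0.24)
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    coarse <- matrix(runif(81, -0.05, 0.05), 9, 9)
    img[, , ch] <- pmin(pmax(base[ch] + resize_bilinear(coarse, size, size) +
                               rnorm(size * size, 0, 0.01), 0), 1)
  }
  img
}

## bilinear upsampling of a small matrix to nr x nc
resize_bilinear <- function(m, nr, nc) {
  sr <- seq(1, nrow(m), length.out = nr)
  sc <- seq(1, ncol(m), length.out = nc)
  r0 <- pmin(floor(sr), nrow(m) - 1L); fr <- sr - r0
  c0 <- pmin(floor(sc), ncol(m) - 1L); fc <- sc - c0
  a <- m[cbind(rep(r0, nc), rep(c0, each = nr))]
  b <- m[cbind(rep(r0 + 1, nc), rep(c0, each = nr))]
  d <- m[cbind(rep(r0, nc), rep(c0 + 1, each = nr))]
  e <- m[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  wfr <- rep(fr, nc); wfc <- rep(fc, each = nr)
  matrix(a * (1 - wfr) * (1 - wfc) + b * wfr * (1 - wfc) +
           d * (1 - wfr) * wfc + e * wfr * wfc, nr, nc)
}

## outer and inner frame quadrangles (row, col), TL TR BR BL
frame_quadrangles <- function(size, tilt) {
  m <- 0.10 * size
  base <- cbind(row = c(m, m, size - m, size - m),
                col = c(m, size - m, size - m, m))
  for (try in 1:25) {
    outer <- base + matrix(runif(8, -tilt * size, tilt * size), 4, 2)
    if (is_convex_quad(outer)) break
  }
  ctr <- colMeans(outer)
  inner <- sweep(sweep(outer, 2, ctr), 1, rep(0.85, 4), `*`)
  inner <- sweep(inner, 2, ctr, `+`)
  list(outer = outer, inner = inner)
}

is_convex_quad <- function(q) {
  cr <- numeric(4)
  for (i in 1:4) {
    a <- q[i, ]; b <- q[(i %% 4) + 1, ]; c <- q[((i + 1) %% 4) + 1, ]
    cr[i] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }
  all(cr > 1e-9) || all(cr < -1e-9)
}

shrink_quad <- function(q, factor) {
  ctr <- colMeans(q)
  sweep(sweep(sweep(q, 2, ctr), 1, rep(factor, 4), `*`), 2, ctr, `+`)
}

## vectorised point-in-convex-quadrangle via half-plane tests
in_convex_quad <- function(r, c, q) {
  res <- matrix(0, length(r), 4)
  for (i in 1:4) {
    a <- q[i, ]; b <- q[(i %% 4) + 1, ]
    res[, i] <- (b[1] - a[1]) * (c - a[2]) - (b[2] - a[2]) * (r - a[1])
  }
  out <- (rowSums(res >= 0) == 4) | (rowSums(res <= 0) == 4)
  if (is.matrix(r)) matrix(out, nrow(r), ncol(r)) else out
}

sample_in_quad <- function(n, q) {
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  rmin <- min(q[, 1]); rmax <- max(q[, 1])
  cmin <- min(q[, 2]); cmax <- max(q[, 2])
  out <- matrix(0, 0, 2)
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 200L) abort("too many plants: placement failed")
    m <- 2L * (n - nrow(out)) + 8L
    r <- runif(m, rmin, rmax); c <- runif(m, cmin, cmax)
    ok <- in_convex_quad(r, c, q)
    out <- rbind(out, cbind(r[ok], c[ok]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

## centreline samples and taper radii of one leaf ribbon
leaf_ribbon <- function(base_pt, len, width, curled) {
  ang <- runif(1, 0, 2 * pi)
  dir <- c(sin(ang), cos(ang))
  perp <- c(dir[2], -dir[1])
  bend <- rnorm(1, 0, 0.10 * len)
  p0 <- base_pt
  p1 <- base_pt + 0.45 * len * dir + 0.7 * bend * perp
  p2 <- base_pt + len * dir + bend * perp
  nt <- max(10, ceiling(len))
  tt <- seq(0, 1, length.out = nt)
  bez <- function(t) {
    cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
          (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
  }
  if (!curled) {
    pos <- bez(tt)
    radius <- pmax(width / 2 * (1 - 0.8 * tt), 1.1)
  } else {
    ## curled blade: foreshortened to the fold point, plus a short flap
    ## folded back at a sharp angle -- less projected area, a kink corner
    ## and a second tip
    tf <- 0.55
    n_main <- ceiling(0.7 * nt)
    t_main <- seq(0, tf, length.out = n_main)
    pos_main <- bez(t_main)
    tang <- bez(tf) - bez(tf - 0.02)
    tang <- tang / max(sqrt(sum(tang^2)), 1e-9)
    flip <- sample(c(-1, 1), 1)
    ang_f <- flip * runif(1, 1.9, 2.4)     # ~110-140 degree turn
    rot <- matrix(c(cos(ang_f), -sin(ang_f), sin(ang_f), cos(ang_f)), 2, 2)
    fdir <- as.numeric(rot %*% as.numeric(tang))
    n_flap <- nt - n_main
    s <- seq(0, 0.28 * len, length.out = n_flap)
    tip <- bez(tf)
    pos_flap <- cbind(tip[1] + s * fdir[1], tip[2] + s * fdir[2])
    pos <- rbind(pos_main, pos_flap)
    radius <- c(pmax(width / 2 * (1 - 0.8 * t_main), 1.1),
                pmax(width / 2 * (1 - 0.8 * (tf + 0.45 * s / max(s))), 1.1))
  }
  list(pos = pos, radius = radius)
}

## rasterise a union of discs; returns linear pixel indices
stamp_discs <- function(nr, nc, centers, radii) {
  rmin <- max(1L, floor(min(centers[, 1] - radii)))
  rmax <- min(nr, ceiling(max(centers[, 1] + radii)))
  cmin <- max(1L, floor(min(centers[, 2] - radii)))
  cmax <- min(nc, ceiling(max(centers[, 2] + radii)))
  if (rmin > rmax || cmin > cmax) return(integer(0))
  rows <- rmin:rmax; cols <- cmin:cmax
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  hit <- rep(FALSE, length(pr))
  for (i in seq_len(nrow(centers))) {
    hit <- hit | ((pr - centers[i, 1])^2 + (pc - centers[i, 2])^2 <=
                    radii[i]^2)
  }
  (pc[hit] - 1L) * nr + pr[hit]
}

## paint pixels (linear indices, later entries win) with per-pixel colours
## in one pass; a single luminance jitter is shared across channels
paint_batch <- function(img, px, cols, jitter_sd = 0) {
  if (!length(px)) return(img)
  nrc <- dim(img)[1] * dim(img)[2]
  jit <- if (jitter_sd > 0) rnorm(length(px), 0, jitter_sd) else 0
  for (ch in 1:3) {
    img[px + (ch - 1L) * nrc] <- pmin(pmax(cols[, ch] + jit, 0), 1)
  }
  img
}

#' Build an observation table by running the pipeline on synthetic scenes
#'
#' Generates each scene, rectifies its target area, segments seedlings,
#' extracts features, and pairs them with the ground-truth plant count.
#' This is the synthetic stand-in for a field calibration campaign.
#'
#' @param specs List of [scene_spec()]s.
#' @param varieties Character vector (recycled over `specs`) naming the
#'   variety each scene belongs to; varieties modulate leaf dimensions via
#'   [variety_profiles()].
#' @param cfg A [run_config()].
#' @return Tibble with columns `image_id`, `variety`, `stage`, `La`, `Va`,
#'   `Co`, `Ha`, `SN_true`.
#' @export
generate_observation_table <- function(specs, varieties = "YM23",
                                       cfg = run_config()) {
  if (!length(specs)) abort("`specs` must be a non-empty list")
  if (inherits(specs, "scene_spec")) specs <- list(specs)
  varieties <- rep_len(varieties, length(specs))
  profs <- variety_profiles()
  rows <- purrr::map2(specs, seq_along(specs), function(sp, i) {
    variety <- varieties[i]
    if (!variety %in% names(cfg$variety_table)) {
      abort(paste0("scene ", i, ": unknown variety '", variety, "'"))
    }
    fac <- if (variety %in% names(profs)) profs[[variety]] else 1
    sp$leaf_length_px[1] <- sp$leaf_length_px[1] * fac
    sp$leaf_width_px[1] <- sp$leaf_width_px[1] * sqrt(fac)
    tryCatch({
      scene <- generate_scene(sp)
      rect <- rectify_target_area(scene$image, cfg)
      mask <- segment_seedlings(rect, cfg)
      feats <- extract_features(mask, La = sp$leaf_stage, variety, cfg)
      tibble::tibble(image_id = sprintf("scene_%03d", i),
                     variety = variety,
                     stage = as.integer(round(sp$leaf_stage)),
                     La = feats$La, Va = feats$Va,
                     Co = feats$Co, Ha = feats$Ha,
                     SN_true = scene$n_plants)
    }, error = function(e) {
      abort(paste0("scene ", i, ": ", conditionMessage(e)))
    })
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(all(out$Co >= 0 & out$Co <= 1), all(out$Ha >= 0))
  out
}

#' Leaf-size factors emulating varietal seedling habit
#'
#' Lax-habit seedlings spread more (larger coverage at equal count) than
#' half-erect ones, and erect ones the least; the generator emulates this
#' with per-variety leaf-length factors.
#'
#' @return Named list of multiplicative length factors.
#' @export
variety_profiles <- function() {
  list(YM23 = 1.00, HM7 = 1.15, YF4 = 0.88)
}
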