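## Shared fixtures and independent oracles. Everything here is generated in
## code at test time; oracles deliberately use brute-force formulations
## independent of the package's implementation paths.

square_mask <- function(n = 20, r0 = 5, side = 10) {
  m <- matrix(FALSE, n, n)
  m[r0:(r0 + side - 1), (r0 + 1):(r0 + side)] <- TRUE
  m
}

circle_mask <- function(radius = 30, pad = 10) {
  n <- 2 * (radius + pad)
  ctr <- n / 2
  m <- matrix(FALSE, n, n)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2] <- TRUE
  m
}

## rasterise a convex quadrangle given 4 (row, col) corners -- half-plane
## test written independently of the package internals
quad_mask <- function(n, corners) {
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  pos <- matrix(TRUE, n, n); neg <- matrix(TRUE, n, n)
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[(i %% 4) + 1, ]
    s <- (b[1] - a[1]) * (cc - a[2]) - (b[2] - a[2]) * (rr - a[1])
    pos <- pos & (s >= 0)
    neg <- neg & (s <= 0)
  }
  pos | neg
}

## a random convex quadrangle at a given scale, corners not too close
random_convex_quad <- function(size, margin = 0.12, tilt = 0.08) {
  m <- margin * size
  repeat {
    base <- cbind(c(m, m, size - m, size - m),
                  c(m, size - m, size - m, m))
    q <- base + matrix(runif(8, -tilt * size, tilt * size), 4, 2)
    cr <- numeric(4)
    for (i in 1:4) {
      a <- q[i, ]; b <- q[(i %% 4) + 1, ]; cc <- q[((i + 1) %% 4) + 1, ]
      cr[i] <- (b[1] - a[1]) * (cc[2] - b[2]) - (b[2] - a[2]) * (cc[1] - b[1])
    }
    if (all(cr > 0) || all(cr < 0)) return(q)
  }
}

## exhaustive Otsu oracle: try all 255 split points of the 256-bin
## histogram, computing class weights and means directly
otsu_bruteforce <- function(map, n_bins = 256) {
  lo <- min(map); hi <- max(map)
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((map - lo) / width), n_bins - 1)
  centers <- lo + (bin + 0.5) * width
  best <- -Inf; best_t <- NA
  for (t in seq_len(n_bins - 1)) {
    left <- bin < t
    n0 <- sum(left); n1 <- length(bin) - n0
    if (n0 == 0 || n1 == 0) next
    sb <- as.numeric(n0) * as.numeric(n1) *
      (mean(centers[left]) - mean(centers[!left]))^2
    if (sb > best) {
      best <- sb
      best_t <- t
    }
  }
  lo + best_t * width
}

## per-pixel double-loop evaluation of the frame colour thresholds
eq1_bruteforce <- function(img, sum_min = 2.1, rb_max = 0.05) {
  out <- matrix(FALSE, dim(img)[1], dim(img)[2])
  for (i in seq_len(dim(img)[1])) {
    for (j in seq_len(dim(img)[2])) {
      out[i, j] <- (img[i, j, 1] + img[i, j, 2] + img[i, j, 3] > sum_min) &&
        (img[i, j, 1] - img[i, j, 3] < rb_max)
    }
  }
  out
}

## a single leaf mask straight from the ribbon renderer
leaf_mask_fixture <- function(curled, seed, n = 160, len = 60, w = 6) {
  set.seed(seed)
  rib <- wheatcount:::leaf_ribbon(c(n / 2, n / 2), len, w, curled)
  m <- matrix(FALSE, n, n)
  m[wheatcount:::stamp_discs(n, n, rib$pos, rib$radius)] <- TRUE
  m
}

## ribbon bundle for overlap experiments: four identical tapered ribbons
## at given base points and angles
ribbon_bundle_mask <- function(n, bases, angles, len = 40, w = 5) {
  m <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(bases))) {
    tt <- seq(0, 1, length.out = 40)
    rr <- bases[i, 1] + tt * len * sin(angles[i])
    cc <- bases[i, 2] + tt * len * cos(angles[i])
    rad <- pmax(w / 2 * (1 - 0.8 * tt), 1.1)
    m[wheatcount:::stamp_discs(n, n, cbind(rr, cc), rad)] <- TRUE
  }
  m
}

iou <- function(a, b) sum(a & b) / sum(a | b)

small_scene_spec <- function(seed, n_plants = 40, ...) {
  scene_spec(n_plants = n_plants, scene_px = 300, straw_count = 12,
             seed = seed, ...)
}

small_cfg <- function(...) run_config(target_size = 224, ...)
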