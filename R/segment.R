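#' Excess-green index map
#'
#' Computes the greenness index `ExG = 1.8*g - r - b` on chromatic
#' (sum-normalised) coordinates `r = R/(R+G+B)` etc., which makes the index
#' invariant to global brightness scaling; pixels with zero channel sum are
#' treated as neutral (`r = g = b = 1/3`). Vegetation scores high (pure
#' green gives 1.8), neutral surfaces slightly negative (-0.0667), soil and
#' straw near or below zero.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @return Numeric `H x W` matrix of index values in `[-2, 1.8]`.
#' @export
excess_green <- function(img) {
  validate_rgb(img)
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  s <- R + G + B
  zero <- s == 0
  s[zero] <- 1
  r <- R / s; g <- G / s; b <- B / s
  r[zero] <- 1 / 3; g[zero] <- 1 / 3; b[zero] <- 1 / 3
  1.8 * g - r - b
}

#' Otsu threshold of a real-valued index map
#'
#' The map is binned into 256 equal-width bins over its value range; the
#' threshold is placed at the bin edge that maximises the between-class
#' variance of the binned histogram (ties resolved towards the lowest
#' threshold), and the foreground is every pixel strictly above it.
#'
#' @param map Numeric matrix (finite values).
#' @param n_bins Number of histogram bins (default 256).
#' @return List with `threshold` (numeric) and `mask` (logical matrix).
#'   A constant map yields a `"degenerate histogram"` warning and an
#'   all-`FALSE` mask.
#' @export
otsu_threshold <- function(map, n_bins = 256) {
  stopifnot(is.matrix(map))
  if (!all(is.finite(map))) abort("map must be finite everywhere")
  lo <- min(map); hi <- max(map)
  if (hi == lo) {
    warn("degenerate histogram: constant map, returning empty mask")
    return(list(threshold = hi, mask = map > hi))
  }
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((map - lo) / width), n_bins - 1)  # 0-based bin index
  counts <- as.numeric(tabulate(as.integer(bin) + 1L, n_bins))
  centers <- lo + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * centers)
  total_n <- w0[n_bins]
  total_m <- m0[n_bins]
  ## split after bin t (1-based t in 1..n_bins-1): classes [1..t], [t+1..]
  t <- seq_len(n_bins - 1)
  n0 <- w0[t]; n1 <- total_n - n0
  valid <- n0 > 0 & n1 > 0
  mu0 <- ifelse(valid, m0[t] / pmax(n0, 1), 0)
  mu1 <- ifelse(valid, (total_m - m0[t]) / pmax(n1, 1), 0)
  sigma_b <- ifelse(valid, n0 * n1 * (mu0 - mu1)^2, -Inf)
  tstar <- which.max(sigma_b)   # first maximum on ties
  threshold <- lo + tstar * width
  list(threshold = threshold, mask = map > threshold)
}

#' Morphological cleanup of a segmentation mask
#'
#' Opening (erosion then dilation) with a disc structuring element removes
#' specks and thin bridges left by thresholding, then small background
#' holes not 4-connected to the image border are filled so each seedling
#' region is solid. Only holes up to `hole_max_px` pixels are filled:
#' holes inside a blade (specular pinpricks, rasterisation gaps) are tiny,
#' whereas large enclosed background regions are genuine soil pockets
#' ringed by overlapping leaves and must stay background. The operation is
#' idempotent.
#'
#' @param mask Logical matrix.
#' @param radius Disc radius in pixels (>= 1).
#' @param hole_max_px Largest hole area, in pixels, that is filled.
#' @return Logical matrix.
#' @export
morphological_cleanup <- function(mask, radius = 1, hole_max_px = 64) {
  stopifnot(is.matrix(mask))
  if (radius < 1) abort("`radius` must be >= 1")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  opened <- as.matrix(EBImage::opening(m, disc_brush(radius))) > 0.5
  fill_small_holes(opened, hole_max_px)
}

## fill background components (4-connectivity) that do not touch the
## border and are at most `hole_max_px` pixels
fill_small_holes <- function(mask, hole_max_px) {
  bg <- !mask
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(bg),
                                           nrow(bg), ncol(bg))))
  storage.mode(lab) <- "integer"
  if (max(lab) == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], max(lab))
  fill <- setdiff(which(sizes <= hole_max_px), border)
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}

## Euclidean disc structuring element: offsets with dr^2 + dc^2 <= radius^2
## (radius 1 is the 4-neighbour cross; EBImage's "disc" brush is wider)
disc_brush <- function(radius) {
  r <- as.integer(radius)
  d <- seq(-r, r)
  matrix(as.numeric(outer(d, d, function(a, b) a^2 + b^2) <= radius^2),
         2 * r + 1, 2 * r + 1)
}

#' Segment seedlings in a rectified target-area image
#'
#' Composition of [excess_green()], [otsu_threshold()] and
#' [morphological_cleanup()]. The effective threshold is never allowed
#' below `cfg$exg_min`: vegetation has strictly positive excess green
#' while soil and straw sit at or below zero, so on scenes with little or
#' no vegetation Otsu would otherwise split the soil noise in half.
#' Because the index is computed on chromatic coordinates, the result is
#' invariant to global brightness scaling.
#'
#' @param img Rectified `H x W x 3` array.
#' @param cfg A [run_config()]; `morph_radius` sets the cleanup radius and
#'   `exg_min` the vegetation floor.
#' @return Logical seedling mask with attribute `"threshold"`.
#' @export
segment_seedlings <- function(img, cfg = run_config()) {
  exg <- excess_green(img)
  ot <- otsu_threshold(exg)
  thr <- max(ot$threshold, cfg$exg_min)
  mask <- morphological_cleanup(exg > thr, cfg$morph_radius)
  attr(mask, "threshold") <- thr
  mask
}
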