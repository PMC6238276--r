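#' Extract the white reference-frame mask from a field image
#'
#' A pixel belongs to the white frame when it is bright
#' (`r + g + b > 2.1` on `[0, 1]` channels) and colour-neutral
#' (`r - b < 0.05`); the second condition rejects pale straw, which is
#' red-shifted. Of all pixels passing both tests only the largest connected
#' component is kept, since specular highlights can also pass the
#' thresholds and the frame is assumed to be the largest white object in
#' the scene.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param cfg A [run_config()]; supplies the two thresholds.
#' @return Logical matrix: the frame-band mask.
#' @export
extract_white_quadrangle <- function(img, cfg = run_config()) {
  validate_rgb(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  raw <- (r + g + b > cfg$frame_sum_min) & (r - b < cfg$frame_rb_max)
  comp <- largest_component(raw, connectivity = 8)
  if (sum(comp) < 0.001 * length(comp)) {
    abort("no frame found: largest white component below 0.1% of image area")
  }
  comp
}

#' Locate the four frame corners from boundary curvature
#'
#' Corners are the four boundary points with the strongest direction
#' change, subject to a pairwise arc-length separation of at least 10% of
#' the perimeter so that several high-curvature points belonging to one
#' physical corner are not selected together. To be robust against the
#' staircase noise that single-step Freeman code differences exhibit on
#' tilted digital edges, the turn at each point is measured between the
#' chords to the boundary points `s` steps behind and ahead (`s` about 1%
#' of the perimeter); a genuine corner must turn by at least 45 degrees,
#' which uniform-curvature shapes such as circles never reach at this
#' chord scale. Each detected corner is then refined to the boundary point
#' of maximal distance from the chord spanning its neighbourhood. Corners
#' are returned in canonical top-left, top-right, bottom-right,
#' bottom-left order (sorted by angle about their centroid).
#'
#' @param profile A [curvature_profile()] of the same chain; its `e`
#'   response is consulted as a consistency check (a boundary whose raw
#'   curvature response is zero everywhere has no corners).
#' @param chain The [trace_boundary()] chain the profile was computed from.
#' @return 4 x 2 matrix of `(row, col)` corners, class `"quadrangle"`.
#' @export
detect_frame_corners <- function(profile, chain) {
  stopifnot(inherits(profile, "curvature_profile"),
            inherits(chain, "chain_code"))
  pts <- chain$pixels
  n <- nrow(pts)
  if (n < 12 || all(profile$e == 0)) {
    abort("corners not found: boundary too short or without curvature")
  }
  s <- max(3L, as.integer(round(0.01 * n)))
  if (4L * s > n) s <- max(1L, n %/% 8L)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  idx <- seq_len(n)
  ahead <- pts[wrap(idx + s), , drop = FALSE] - pts
  behind <- pts - pts[wrap(idx - s), , drop = FALSE]
  ## turn angle between incoming and outgoing chords, in [0, pi]
  dotp <- rowSums(ahead * behind)
  crossp <- ahead[, 1] * behind[, 2] - ahead[, 2] * behind[, 1]
  turn <- atan2(abs(crossp), dotp)
  min_sep <- max(1, ceiling(0.1 * n))
  ord <- order(turn, decreasing = TRUE)
  ord <- ord[turn[ord] >= pi / 4]
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) == 4L) break
    if (all(circ_dist(i, chosen, n) >= min_sep)) chosen <- c(chosen, i)
  }
  if (length(chosen) < 4L) {
    abort("corners not found: fewer than 4 separated curvature maxima")
  }
  refined <- t(vapply(chosen, function(i) refine_corner(pts, i, s),
                      numeric(2)))
  order_quadrangle(refined)
}

## snap a detected corner to the boundary point farthest from the chord
## spanning its +-s neighbourhood (exact for polygon vertices)
refine_corner <- function(pts, i, s) {
  n <- nrow(pts)
  wrap <- function(j) ((j - 1L) %% n) + 1L
  win <- wrap(seq(i - s, i + s))
  a <- pts[wrap(i - s), ]
  b <- pts[wrap(i + s), ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len < 1e-9) return(pts[i, ])
  d <- abs((pts[win, 1] - a[1]) * ab[2] - (pts[win, 2] - a[2]) * ab[1]) / len
  pts[win[which.max(d)], ]
}

circ_dist <- function(i, j, n) {
  if (!length(j)) return(Inf)
  d <- abs(i - j)
  pmin(d, n - d)
}

#' Put four points in canonical TL, TR, BR, BL order
#'
#' Sorts by angle about the centroid and rotates so the first corner is the
#' one closest to the top-left.
#'
#' @param pts 4 x 2 matrix of `(row, col)` points.
#' @return 4 x 2 matrix of class `"quadrangle"`.
#' @export
order_quadrangle <- function(pts) {
  stopifnot(is.matrix(pts), nrow(pts) == 4, ncol(pts) == 2)
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 1] - ctr[1], pts[, 2] - ctr[2])
  pts <- pts[order(ang), , drop = FALSE]
  first <- which.min(pts[, 1] + pts[, 2])
  if (first > 1) pts <- pts[c(first:4, seq_len(first - 1)), , drop = FALSE]
  if (anyDuplicated(pts)) abort("degenerate quadrangle: repeated corners")
  if (quad_area(pts) <= 0) abort("degenerate quadrangle: zero area")
  colnames(pts) <- c("row", "col")
  structure(pts, class = c("quadrangle", class(pts)))
}

quad_area <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Solve the perspective transform mapping one quadrangle onto another
#'
#' Sets up the 8-unknown linear system given by the four point
#' correspondences and solves it directly. The returned 3 x 3 matrix `H`
#' has `a33 = 1` and acts on row vectors: `[x', y', w'] = [x, y, 1] %*% H`,
#' with image coordinates `x = col`, `y = row` and the mapped point
#' `(x'/w', y'/w')`.
#'
#' @param src,dst 4 x 2 `(row, col)` matrices in matching corner order.
#' @return 3 x 3 homography matrix of class `"homography"`.
#' @examples
#' sq <- cbind(row = c(1, 1, 10, 10), col = c(1, 10, 10, 1))
#' solve_perspective(sq, sq)  # identity
#' @export
solve_perspective <- function(src, dst) {
  stopifnot(is.matrix(src), is.matrix(dst),
            nrow(src) == 4, nrow(dst) == 4)
  if (collinear_triple(src)) {
    abort("degenerate correspondence: 3 source corners are collinear")
  }
  u <- src[, 2]; v <- src[, 1]      # x = col, y = row
  xd <- dst[, 2]; yd <- dst[, 1]
  A <- matrix(0, 8, 8)
  rhs <- numeric(8)
  for (i in 1:4) {
    ## x' = u a11 + v a21 + a31 ; w' = u a13 + v a23 + 1
    A[2 * i - 1, ] <- c(u[i], v[i], 1, 0, 0, 0, -xd[i] * u[i], -xd[i] * v[i])
    A[2 * i, ]     <- c(0, 0, 0, u[i], v[i], 1, -yd[i] * u[i], -yd[i] * v[i])
    rhs[2 * i - 1] <- xd[i]
    rhs[2 * i]     <- yd[i]
  }
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) abort("degenerate correspondence"))
  H <- matrix(c(sol[1], sol[4], sol[7],
                sol[2], sol[5], sol[8],
                sol[3], sol[6], 1), 3, 3, byrow = TRUE)
  if (abs(det(H)) < 1e-12) abort("degenerate correspondence: singular matrix")
  structure(H, class = c("homography", class(H)))
}

collinear_triple <- function(pts) {
  combs <- utils::combn(4, 3)
  diam2 <- max(stats::dist(pts))^2
  for (j in seq_len(ncol(combs))) {
    p <- pts[combs[, j], , drop = FALSE]
    area2 <- abs((p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]) -
                 (p[3, 2] - p[1, 2]) * (p[2, 1] - p[1, 1]))
    if (area2 < 1e-9 * max(diam2, 1)) return(TRUE)
  }
  FALSE
}

#' Apply a homography to points
#'
#' @param H `homography` matrix.
#' @param pts n x 2 matrix of `(row, col)` points.
#' @return n x 2 matrix of mapped `(row, col)` points.
#' @export
apply_homography <- function(H, pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  P <- cbind(pts[, 2], pts[, 1], 1) %*% unclass(H)  # row-vector convention
  w <- P[, 3]
  if (any(abs(w) < 1e-300)) abort("point maps to infinity under homography")
  out <- cbind(row = P[, 2] / w, col = P[, 1] / w)
  out
}

#' Invert a homography
#' @param H `homography` matrix.
#' @return `homography` matrix with `a33` renormalised to 1.
#' @export
homography_inverse <- function(H) {
  Hi <- tryCatch(solve(unclass(H)),
                 error = function(e) abort("singular transform"))
  Hi <- Hi / Hi[3, 3]
  structure(Hi, class = c("homography", class(Hi)))
}

#' Warp an image under a homography and crop to a square
#'
#' Each output pixel is sampled from the input image at the location given
#' by the inverse transform, using bilinear interpolation; locations that
#' fall outside the input are filled with 0.
#'
#' @param img `H x W x 3` array (or a single-channel matrix).
#' @param H `homography` mapping input coordinates to output coordinates.
#' @param size Side length of the square output, in pixels.
#' @return `size x size x 3` array (or `size x size` matrix for matrix
#'   input).
#' @export
warp_and_crop <- function(img, H, size) {
  Hi <- homography_inverse(H)
  grid <- cbind(row = rep(seq_len(size), times = size),
                col = rep(seq_len(size), each = size))
  srcpts <- apply_homography(Hi, grid)
  is_mat <- is.matrix(img)
  if (is_mat) img <- array(img, c(nrow(img), ncol(img), 1))
  nr <- dim(img)[1]; nc <- dim(img)[2]; nch <- dim(img)[3]
  r <- srcpts[, 1]; c <- srcpts[, 2]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  out <- array(0, c(size, size, nch))
  ## validity of the four neighbours of each sample
  ok00 <- r0 >= 1 & r0 <= nr & c0 >= 1 & c0 <= nc
  ok01 <- r0 >= 1 & r0 <= nr & c0 + 1 >= 1 & c0 + 1 <= nc
  ok10 <- r0 + 1 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 <= nc
  ok11 <- r0 + 1 >= 1 & r0 + 1 <= nr & c0 + 1 >= 1 & c0 + 1 <= nc
  i00 <- ifelse(ok00, (pmin(pmax(c0, 1), nc) - 1) * nr +
                  pmin(pmax(r0, 1), nr), 1)
  i01 <- ifelse(ok01, (pmin(pmax(c0 + 1, 1), nc) - 1) * nr +
                  pmin(pmax(r0, 1), nr), 1)
  i10 <- ifelse(ok10, (pmin(pmax(c0, 1), nc) - 1) * nr +
                  pmin(pmax(r0 + 1, 1), nr), 1)
  i11 <- ifelse(ok11, (pmin(pmax(c0 + 1, 1), nc) - 1) * nr +
                  pmin(pmax(r0 + 1, 1), nr), 1)
  w00 <- (1 - fr) * (1 - fc) * ok00
  w01 <- (1 - fr) * fc * ok01
  w10 <- fr * (1 - fc) * ok10
  w11 <- fr * fc * ok11
  for (ch in seq_len(nch)) {
    plane <- img[, , ch]
    vals <- w00 * plane[i00] + w01 * plane[i01] +
            w10 * plane[i10] + w11 * plane[i11]
    out[, , ch] <- matrix(vals, size, size)
  }
  if (is_mat) out[, , 1] else out
}

#' Target-square corners for a given rectified size
#' @param size Side length in pixels.
#' @return 4 x 2 `(row, col)` quadrangle TL, TR, BR, BL.
#' @export
target_square <- function(size) {
  order_quadrangle(cbind(row = c(1, 1, size, size),
                         col = c(1, size, size, 1)))
}

#' Rectify the 1-m2 target area of a field image
#'
#' Composes the full target-area pipeline: find the white frame band,
#' isolate the enclosed interior region, trace its boundary, locate the
#' four corners by chain-code curvature, solve the perspective transform
#' to a square, and warp. The corners are taken on the *inner* contour of
#' the frame band because the counting area is the inside of the frame.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param cfg A [run_config()]; `target_size` sets the output size.
#' @return `target_size x target_size x 3` array with attributes
#'   `"corners"` (the detected source quadrangle) and `"homography"`.
#' @export
rectify_target_area <- function(img, cfg = run_config()) {
  band <- with_stage("extract_white_quadrangle",
                     extract_white_quadrangle(img, cfg))
  interior <- with_stage("frame_interior", frame_interior(band))
  chain <- with_stage("trace_boundary", trace_boundary(interior))
  prof <- with_stage("curvature_profile", curvature_profile(chain, k = 8))
  src <- with_stage("detect_frame_corners", detect_frame_corners(prof, chain))
  dst <- target_square(cfg$target_size)
  H <- with_stage("solve_perspective", solve_perspective(src, dst))
  out <- with_stage("warp_and_crop", warp_and_crop(img, H, cfg$target_size))
  attr(out, "corners") <- src
  attr(out, "homography") <- H
  out
}

## interior of the frame band: background holes of the band, i.e. the
## filled band minus the band itself; keep the largest such region
frame_interior <- function(band) {
  filled <- as.matrix(EBImage::fillHull(matrix(as.numeric(band),
                                               nrow(band), ncol(band)))) > 0.5
  hole <- filled & !band
  if (!any(hole)) abort("frame has no enclosed interior")
  largest_component(hole, connectivity = 4)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[", stage, "] ", conditionMessage(e)))
  })
}
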