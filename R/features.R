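#' Harris detector parameters
#'
#' @param k Response constant in `[0.04, 0.06]`.
#' @param window_sigma Gaussian window scale in pixels.
#' @param threshold_frac Fraction of the maximum response below which
#'   candidates are discarded, in (0, 1).
#' @param nms_radius Non-maximum-suppression radius in pixels (>= 1).
#' @return List of class `"harris_params"`.
#' @export
harris_params <- function(k = 0.04, window_sigma = 1.5,
                          threshold_frac = 0.01, nms_radius = 5) {
  if (k < 0.04 || k > 0.06) abort("`k` must lie in [0.04, 0.06]")
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    abort("`threshold_frac` must lie in (0, 1)")
  }
  if (nms_radius < 1) abort("`nms_radius` must be >= 1")
  structure(list(k = k, window_sigma = window_sigma,
                 threshold_frac = threshold_frac, nms_radius = nms_radius),
            class = "harris_params")
}

harris_params_from_config <- function(cfg) {
  harris_params(k = cfg$harris_k, window_sigma = cfg$window_sigma,
                threshold_frac = cfg$corner_threshold_frac,
                nms_radius = cfg$nms_radius)
}

#' Coverage degree of a seedling mask
#'
#' Fraction of the target area covered by seedling foreground: foreground
#' pixel count divided by total pixel count.
#'
#' @param mask Logical matrix.
#' @return Numeric in `[0, 1]`.
#' @export
coverage_degree <- function(mask) {
  stopifnot(is.matrix(mask))
  if (length(mask) == 0) abort("zero-size mask")
  mean(mask)
}

#' Harris corner response of a binary mask
#'
#' The mask is lifted to reals and smoothed with a Gaussian of scale
#' `window_sigma`; gradients are taken with 3 x 3 Sobel kernels; the
#' structure tensor entries are Gaussian-weighted with the same window; and
#' the response is `R = det(M) - k * trace(M)^2`. Computing the response on
#' the segmented mask rather than the colour image confines corners to
#' seedling geometry (leaf tips, leaf-leaf intersections, curl folds) and
#' suppresses soil texture.
#'
#' @param mask Logical matrix.
#' @param p A [harris_params()].
#' @return Numeric matrix of response values.
#' @export
harris_response <- function(mask, p = harris_params()) {
  stopifnot(is.matrix(mask))
  ## replicate-pad so image borders do not masquerade as gradients
  pad <- as.integer(ceiling(3 * p$window_sigma)) + 3L
  A <- pad_replicate(matrix(as.numeric(mask), nrow(mask), ncol(mask)), pad)
  A <- EBImage::gblur(A, sigma = p$window_sigma)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  Ix <- as.matrix(EBImage::filter2(A, sx))
  Iy <- as.matrix(EBImage::filter2(A, t(sx)))
  Ixx <- EBImage::gblur(Ix * Ix, sigma = p$window_sigma)
  Iyy <- EBImage::gblur(Iy * Iy, sigma = p$window_sigma)
  Ixy <- EBImage::gblur(Ix * Iy, sigma = p$window_sigma)
  detM <- Ixx * Iyy - Ixy * Ixy
  trM <- Ixx + Iyy
  R <- as.matrix(detM - p$k * trM * trM)
  R[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))]
}

pad_replicate <- function(m, pad) {
  ri <- c(rep(1L, pad), seq_len(nrow(m)), rep(nrow(m), pad))
  ci <- c(rep(1L, pad), seq_len(ncol(m)), rep(ncol(m), pad))
  m[ri, ci]
}

#' Count angular points in a Harris response map
#'
#' Candidate pixels are those with response above `threshold_frac` times
#' the maximum response (zero if the maximum is not positive); greedy
#' non-maximum suppression then keeps response maxima separated by at
#' least `nms_radius` pixels, and the number kept is the angular-point
#' count.
#'
#' @param resp Response matrix from [harris_response()].
#' @param p A [harris_params()].
#' @return Integer count; the `(row, col)` positions kept are attached as
#'   attribute `"points"`.
#' @export
count_angular_points <- function(resp, p = harris_params()) {
  stopifnot(is.matrix(resp))
  mx <- max(resp)
  if (mx <= 0) {
    return(structure(0L, points = matrix(numeric(0), 0, 2)))
  }
  cand <- which(resp > p$threshold_frac * mx)
  ord <- cand[order(resp[cand], decreasing = TRUE)]
  rr <- ((ord - 1) %% nrow(resp)) + 1
  cc <- ((ord - 1) %/% nrow(resp)) + 1
  keep_r <- numeric(0); keep_c <- numeric(0)
  r2 <- p$nms_radius^2
  for (i in seq_along(ord)) {
    if (length(keep_r) == 0 ||
        all((keep_r - rr[i])^2 + (keep_c - cc[i])^2 >= r2)) {
      keep_r <- c(keep_r, rr[i])
      keep_c <- c(keep_c, cc[i])
    }
  }
  structure(length(keep_r),
            points = cbind(row = keep_r, col = keep_c))
}

#' Extract the feature vector of a segmented target area
#'
#' Combines coverage degree `Co`, angular-point count `Ha`, the
#' user-supplied (possibly non-integer) leaf age `La` and the variety
#' coefficient `Va` looked up from the configuration's variety table.
#'
#' @param mask Logical seedling mask.
#' @param La Leaf age in `[1, 3]`.
#' @param variety Variety name present in `cfg$variety_table`.
#' @param cfg A [run_config()].
#' @return One-row tibble with columns `variety`, `La`, `Va`, `Co`, `Ha`.
#' @export
extract_features <- function(mask, La, variety, cfg = run_config()) {
  if (!is.numeric(La) || La < 1 || La > 3) {
    abort("`La` (leaf age) must lie in [1, 3]")
  }
  if (!variety %in% names(cfg$variety_table)) {
    abort(paste0("unknown variety '", variety, "'; known varieties: ",
                 paste(names(cfg$variety_table), collapse = ", ")))
  }
  p <- harris_params_from_config(cfg)
  co <- coverage_degree(mask)
  ha <- if (any(mask)) count_angular_points(harris_response(mask, p), p) else 0L
  tibble::tibble(variety = variety, La = La,
                 Va = unname(cfg$variety_table[variety]),
                 Co = co, Ha = as.integer(ha))
}
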