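## Freeman chain codes on (row, col) rasters. Codes follow the usual
## compass convention with row 1 at the top of the image:
##   0 = E, 1 = NE, 2 = N, 3 = NW, 4 = W, 5 = SW, 6 = S, 7 = SE
## so decreasing code order is clockwise as the image is displayed.
.chain_drow <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
.chain_dcol <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

#' Label connected components of a binary mask
#'
#' Thin wrapper over `EBImage::bwlabel()` (4-connectivity) that optionally
#' merges diagonally adjacent labels to yield 8-connected components, the
#' connectivity under which closed Freeman chains are traced.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(mask),
                                           nrow(mask), ncol(mask))))
  storage.mode(lab) <- "integer"
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  ## union-find over labels touching diagonally
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1), if (d[2] > 0) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (d[2] > 0) 2:nc else seq_len(nc - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    if (length(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (r in seq_len(nrow(pairs))) unite(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Keep only the largest connected component of a mask
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Logical matrix with a single component (or all-`FALSE`).
#' @export
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Trace the outer boundary of a mask as a Freeman chain code
#'
#' Moore-neighbour tracing of the single 8-connected foreground component,
#' clockwise (as displayed), starting from the topmost-then-leftmost
#' boundary pixel. The returned chain is closed: walking all codes from the
#' start pixel returns to it.
#'
#' @param mask Logical matrix with exactly one 8-connected foreground
#'   component.
#' @return A list of class `"chain_code"` with elements `start` (`c(row,
#'   col)`), `codes` (integer vector in 0..7), `closed` (`TRUE`) and
#'   `pixels` (n x 2 matrix of the boundary walk, first row = start).
#' @examples
#' m <- matrix(FALSE, 12, 12); m[3:8, 4:9] <- TRUE
#' ch <- trace_boundary(m)
#' length(ch$codes)
#' @export
trace_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) abort("empty mask: nothing to trace")
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) > 1) abort("ambiguous boundary: mask has multiple components")
  idx <- which(mask, arr.ind = TRUE)
  ## topmost row, then leftmost column within it
  top <- min(idx[, 1])
  start <- c(top, min(idx[idx[, 1] == top, 2]))
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]

  if (sum(mask) == 1L) {
    return(structure(list(start = start, codes = integer(0), closed = TRUE,
                          pixels = matrix(start, 1, 2,
                                          dimnames = list(NULL, c("row", "col")))),
                     class = "chain_code"))
  }

  ## we "came from" the pixel above the start (background by construction)
  pixels <- matrix(0L, sum(mask) * 4L + 8L, 2)
  codes <- integer(nrow(pixels))
  cur <- start
  back_dir <- 2L  # direction from current pixel towards previous (N)
  n <- 0L
  first_move <- NA_integer_
  repeat {
    ## scan clockwise (decreasing code) starting just after the backtrack
    found <- FALSE
    for (s in 1:8) {
      d <- (back_dir - s) %% 8L
      r2 <- cur[1] + .chain_drow[d + 1L]
      c2 <- cur[2] + .chain_dcol[d + 1L]
      if (fg(r2, c2)) {
        n <- n + 1L
        pixels[n, ] <- cur
        codes[n] <- d
        ## stopping rule: back at the start, about to repeat the first move
        if (n > 1L && cur[1] == start[1] && cur[2] == start[2] &&
            d == first_move) {
          n <- n - 1L
          found <- NA
          break
        }
        if (n == 1L) first_move <- d
        cur <- c(r2, c2)
        back_dir <- (d + 4L) %% 8L
        found <- TRUE
        break
      }
    }
    if (is.na(found) || !found) break
    if (n > nrow(pixels) - 2L) abort("boundary trace failed to close")
  }
  pixels <- pixels[seq_len(n), , drop = FALSE]
  colnames(pixels) <- c("row", "col")
  structure(list(start = start, codes = codes[seq_len(n)], closed = TRUE,
                 pixels = pixels),
            class = "chain_code")
}

#' @export
print.chain_code <- function(x, ...) {
  cat("<chain_code> start (", x$start[1], ",", x$start[2], "), length ",
      length(x$codes), if (x$closed) ", closed" else "", "\n", sep = "")
  invisible(x)
}

#' Chain-code curvature profile of a closed boundary
#'
#' For a closed Freeman chain with neighbourhood parameter `k`, the tangent
#' direction change at position i is `theta_i = |C(i + k/8) - C(i)|`
#' (circular indexing). The preliminary curvature folds the wrap-around:
#' `phi_i = theta_i` when `theta_i <= k/2`, else `k - theta_i`, so
#' `phi` lies in `[0, k/2]`. The corner response accumulates curvature over
#' the immediate neighbourhood: `e_i = phi_i * (phi_{i-1} + phi_i +
#' phi_{i+1})`. Straight runs give `e = 0`; isolated right-angle corners of
#' a digital square give `phi = 2`, `e = 4` at the corner.
#'
#' @param chain A `chain_code` from [trace_boundary()].
#' @param k Neighbourhood parameter; must be a positive multiple of 8
#'   (default 8, matching 8-direction Freeman codes, giving offset `k/8 = 1`).
#' @return List of class `"curvature_profile"` with numeric vectors `theta`,
#'   `phi`, `e` (one entry per chain code) and the offset used.
#' @export
curvature_profile <- function(chain, k = 8) {
  stopifnot(inherits(chain, "chain_code"))
  if (k < 8 || k %% 8 != 0) abort("`k` must be a positive multiple of 8")
  n <- length(chain$codes)
  if (n < k) abort("chain too short for curvature: need length >= k")
  off <- k %/% 8L
  codes <- as.numeric(chain$codes)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  theta <- abs(codes[wrap(seq_len(n) + off)] - codes)
  phi <- ifelse(theta <= k / 2, theta, k - theta)
  e <- phi * (phi[wrap(seq_len(n) - 1L)] + phi + phi[wrap(seq_len(n) + 1L)])
  structure(list(theta = theta, phi = phi, e = e, k = k, offset = off),
            class = "curvature_profile")
}

## The curvature entry at chain index i describes the code change between
## moves i and i+offset, which is localised at the pixel reached by move i,
## i.e. pixel i+1 of the boundary walk.
chain_point_of_index <- function(chain, i) {
  n <- length(chain$codes)
  chain$pixels[((i) %% n) + 1L, ]
}
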