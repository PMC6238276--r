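#' Run configuration for the counting pipeline
#'
#' Bundles every tunable knob of the pipeline in one place. Defaults follow
#' the method as published where a value is stated (rectified target size
#' 800 px, Harris constant `k = 0.04`) and sensible engineering choices where
#' it is not (corner response threshold, suppression radius, morphology
#' radius). The frame-extraction colour thresholds operate on channels
#' normalised to `[0, 1]`, where an ideal white pixel has `r + g + b = 3`.
#'
#' @param target_size Side length, in pixels, of the rectified square target
#'   area. Must be at least 64.
#' @param harris_k Harris corner response constant; the usual empirical range
#'   is 0.04-0.06 and the method uses 0.04.
#' @param corner_threshold_frac Fraction of the maximum Harris response below
#'   which candidate corners are discarded, in (0, 1).
#' @param nms_radius Minimum separation, in pixels, enforced between counted
#'   angular points (greedy non-maximum suppression radius).
#' @param morph_radius Disc radius, in pixels, of the structuring element
#'   used for morphological opening of the seedling mask.
#' @param window_sigma Scale, in pixels, of the Gaussian window used both to
#'   smooth the mask before differencing and to weight the Harris structure
#'   tensor.
#' @param frame_sum_min Minimum of `r + g + b` for a pixel to count as frame
#'   white.
#' @param frame_rb_max Maximum of `r - b` for a pixel to count as frame white
#'   (excludes pale straw, which is red-shifted).
#' @param exg_min Floor on the excess-green segmentation threshold;
#'   vegetation scores well above it, soil and straw below zero.
#' @param variety_table Named numeric vector mapping variety names to their
#'   multiplicative variety coefficients `Va`.
#' @param seed Integer seed used by stochastic helpers that take their
#'   randomness from the configuration.
#'
#' @return A list of class `"wheat_config"`.
#' @examples
#' cfg <- run_config(target_size = 400)
#' cfg$harris_k
#' @export
run_config <- function(target_size = 800,
                       harris_k = 0.04,
                       corner_threshold_frac = 0.01,
                       nms_radius = 5,
                       morph_radius = 1,
                       window_sigma = 1.5,
                       frame_sum_min = 2.1,
                       frame_rb_max = 0.05,
                       exg_min = 0.15,
                       variety_table = c(YM23 = 1.05, HM7 = 0.86, YF4 = 1.12),
                       seed = 1L) {
  if (!is.numeric(target_size) || target_size < 64) {
    abort("`target_size` must be a number >= 64")
  }
  if (!is.numeric(harris_k) || harris_k < 0.04 || harris_k > 0.06) {
    abort("`harris_k` must lie in [0.04, 0.06]")
  }
  if (!is.numeric(corner_threshold_frac) ||
      corner_threshold_frac <= 0 || corner_threshold_frac >= 1) {
    abort("`corner_threshold_frac` must lie in (0, 1)")
  }
  if (!is.numeric(nms_radius) || nms_radius < 1) {
    abort("`nms_radius` must be >= 1")
  }
  if (!is.numeric(morph_radius) || morph_radius < 1) {
    abort("`morph_radius` must be >= 1")
  }
  if (is.null(names(variety_table)) || !is.numeric(variety_table) ||
      any(variety_table <= 0)) {
    abort("`variety_table` must be a named numeric vector of positive Va values")
  }
  structure(
    list(
      target_size = as.integer(target_size),
      harris_k = harris_k,
      corner_threshold_frac = corner_threshold_frac,
      nms_radius = nms_radius,
      morph_radius = morph_radius,
      window_sigma = window_sigma,
      frame_sum_min = frame_sum_min,
      frame_rb_max = frame_rb_max,
      exg_min = exg_min,
      variety_table = variety_table,
      seed = as.integer(seed)
    ),
    class = "wheat_config"
  )
}

#' @export
print.wheat_config <- function(x, ...) {
  cat("<wheat_config>\n")
  cat("  target_size:", x$target_size, "px; harris_k:", x$harris_k, "\n")
  cat("  corner_threshold_frac:", x$corner_threshold_frac,
      "; nms_radius:", x$nms_radius, "px\n")
  cat("  morph_radius:", x$morph_radius, "px; window_sigma:",
      x$window_sigma, "px\n")
  cat("  frame thresholds: r+g+b >", x$frame_sum_min, ", r-b <",
      x$frame_rb_max, "\n")
  cat("  varieties:", paste(names(x$variety_table), x$variety_table,
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and lines starting with `#`
#' are ignored. Values that parse as numbers become numeric; the special key
#' `variety_table` takes `name:value` pairs separated by commas.
#'
#' @param path Path to the configuration file.
#' @param base Configuration to override; defaults to [run_config()].
#' @return A `wheat_config` with the file's overrides applied.
#' @export
read_config_file <- function(path, base = run_config()) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort(paste0("malformed config line: ", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (key == "variety_table") {
      pairs <- strsplit(strsplit(val, ",")[[1]], ":")
      overrides[[key]] <- setNames(
        vapply(pairs, function(p) as.numeric(trimws(p[2])), numeric(1)),
        vapply(pairs, function(p) trimws(p[1]), character(1))
      )
    } else {
      num <- suppressWarnings(as.numeric(val))
      overrides[[key]] <- if (is.na(num)) val else num
    }
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, modifyList(as.list(unclass(base))[known[known %in%
    names(unclass(base))]], overrides))
}
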