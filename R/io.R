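#' Read an RGB image into a normalised array
#'
#' Decodes a PNG or JPEG file into an `H x W x 3` numeric array with every
#' channel in `[0, 1]` (8- or 16-bit inputs are divided by their full-scale
#' value by the decoder). An alpha channel, if present, is discarded;
#' grayscale images are rejected because the frame and vegetation thresholds
#' are defined on colour.
#'
#' @param path Path to an image file.
#' @return Numeric array `H x W x 3`, values in `[0, 1]`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(runif(24 * 32 * 3), c(24, 32, 3)), f)
#' dim(read_image(f))
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(paste0("cannot read image: no such file: ", path))
  }
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) abort(paste0("cannot decode image '", path, "': ",
                                     conditionMessage(e)))
  )
  a <- as.array(img)
  if (length(dim(a)) == 2) abort(paste0("image is not RGB (grayscale): ", path))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(a)[3] != 3) {
    abort(paste0("image is not RGB (", dim(a)[3], " channel(s)): ", path))
  }
  ## EBImage stores (x, y, channel); convert to (row, col, channel)
  a <- aperm(a, c(2, 1, 3))
  a[a < 0] <- 0
  a[a > 1] <- 1
  validate_rgb(a)
  a
}

#' Write an RGB array or binary mask to a PNG file
#'
#' @param x `H x W x 3` numeric array in `[0, 1]`, or a logical matrix (a
#'   mask), written as 0/255 grayscale.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.numeric(x), nrow(x), ncol(x))
  ok <- tryCatch({
    png::writePNG(x, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write image: ", path))
  invisible(path)
}

#' Read a binary mask from a grayscale PNG
#'
#' Pixels above half scale are foreground.
#'
#' @param path Path to a PNG mask.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read mask: no such file: ", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}

validate_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    abort("expected an H x W x 3 array")
  }
  if (dim(img)[1] < 16 || dim(img)[2] < 16) {
    abort("image too small: need height and width >= 16")
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 1) {
    abort("channel values must be finite and in [0, 1]")
  }
  invisible(img)
}

#' Write a per-image count record as JSON
#'
#' A count record carries the extracted features (`Co`, `Ha`, `La`, `Va`),
#' the seedling-number estimate `SN` and the identifier of the model that
#' produced it. The JSON document round-trips losslessly through
#' [read_result()].
#'
#' @param record Named list with at least `Co`, `Ha`, `La`, `Va`, `SN`,
#'   `model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_result <- function(record, path) {
  required <- c("Co", "Ha", "La", "Va", "SN", "model")
  missing <- setdiff(required, names(record))
  if (length(missing)) {
    abort(paste0("missing fields in count record: ",
                 paste(missing, collapse = ", ")))
  }
  num <- record[c("Co", "Ha", "La", "Va", "SN")]
  if (!all(vapply(num, function(v) is.numeric(v) && all(is.finite(v)),
                  logical(1)))) {
    abort("non-finite feature in count record")
  }
  ok <- tryCatch({
    jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write result: ", path))
  invisible(path)
}

#' Read a count record written by [write_result()]
#' @param path Path to the JSON record.
#' @return Named list.
#' @export
read_result <- function(path) {
  if (!file.exists(path)) abort(paste0("no such result file: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a table of calibration observations
#'
#' Expects a CSV with header columns `image_id`, `variety`, `La`, `Co`,
#' `Ha` and optionally `SN_true` (plus any extras such as `site` or
#' `stage`), one row per analysed image.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_observation_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such table: ", path))
  tb <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  needed <- c("variety", "La", "Co", "Ha")
  missing <- setdiff(needed, names(tb))
  if (length(missing)) {
    abort(paste0("observation table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  tb
}

#' Write an observation table as CSV
#' @param table Data frame of observations.
#' @param path Output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_observation_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
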