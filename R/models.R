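#' Construct a per-stage linear counting model
#'
#' A stage model estimates the seedling number of one variety at one leaf
#' stage as `SN = coef_Ha * Ha + coef_Co * Co + intercept`.
#'
#' @param variety Variety name.
#' @param stage Integer leaf stage, 1-3.
#' @param coef_Ha,coef_Co,intercept Finite model coefficients.
#' @return List of class `"stage_model"`.
#' @export
stage_model <- function(variety, stage, coef_Ha, coef_Co, intercept) {
  if (!stage %in% 1:3) abort("`stage` must be 1, 2 or 3")
  coefs <- c(coef_Ha, coef_Co, intercept)
  if (!all(is.finite(coefs))) abort("stage model coefficients must be finite")
  structure(list(variety = variety, stage = as.integer(stage),
                 coef_Ha = coef_Ha, coef_Co = coef_Co, intercept = intercept),
            class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf("<stage_model> %s stage %d: SN = %.4g*Ha + %.4g*Co + %.4g\n",
              x$variety, x$stage, x$coef_Ha, x$coef_Co, x$intercept))
  invisible(x)
}

#' Construct the unified multi-factor counting model
#'
#' The unified model replaces the nine per-variety, per-stage equations by
#' `SN = Va * (a*Ha + b*Co + c) / (d*La)`, where `Va` is a per-variety
#' multiplicative coefficient and `La` the (non-integer) leaf age. Note the
#' parametrisation is scale-degenerate: multiplying `a`, `b`, `c` and `d`
#' by a common factor leaves every prediction unchanged, which is why
#' calibration requires either `d` or the `Va` values to be fixed.
#'
#' @param a,b,c,d Model coefficients; `d > 0`.
#' @param variety_table Named numeric vector of positive `Va` values.
#' @return List of class `"unified_model"`.
#' @export
unified_model <- function(a = 0.44, b = 110.43, c = 3.35, d = 1.11,
                          variety_table = c(YM23 = 1.05, HM7 = 0.86,
                                            YF4 = 1.12)) {
  if (!is.finite(d) || d <= 0) abort("`d` must be a positive number")
  if (!all(is.finite(c(a, b, c)))) abort("coefficients must be finite")
  if (any(variety_table <= 0)) abort("all `Va` values must be positive")
  structure(list(a = a, b = b, c = c, d = d, variety_table = variety_table),
            class = "unified_model")
}

#' @export
print.unified_model <- function(x, ...) {
  cat(sprintf("<unified_model> SN = Va*(%.4g*Ha + %.4g*Co + %.4g)/(%.4g*La)\n",
              x$a, x$b, x$c, x$d))
  cat("  Va:", paste(names(x$variety_table), x$variety_table,
                     sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Built-in model registry
#'
#' Loads the published coefficient sets shipped with the package: nine
#' stage models (three varieties x three leaf stages) and the default
#' unified model with its variety coefficients.
#'
#' @return List with `stagewise` (tibble of stage-model coefficients),
#'   `unified` (a [unified_model()]) and `version`.
#' @examples
#' reg <- builtin_models()
#' reg$unified$variety_table[["HM7"]]
#' @export
builtin_models <- function() {
  path <- system.file("extdata", "builtin-models.json", package = "wheatcount")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  u <- raw$unified
  list(
    version = raw$version,
    stagewise = tibble::as_tibble(raw$stagewise),
    unified = unified_model(a = u$a, b = u$b, c = u$c, d = u$d,
                            variety_table = unlist(u$variety_table))
  )
}

#' Fetch one built-in stage model
#' @param variety Variety name.
#' @param stage Leaf stage 1-3.
#' @param registry Registry from [builtin_models()].
#' @return A [stage_model()].
#' @export
get_stage_model <- function(variety, stage, registry = builtin_models()) {
  tb <- registry$stagewise
  row <- tb[tb$variety == variety & tb$stage == stage, ]
  if (nrow(row) != 1) {
    abort(paste0("no built-in stage model for ", variety, " stage ", stage))
  }
  stage_model(row$variety, row$stage, row$coef_Ha, row$coef_Co, row$intercept)
}

resolve_features <- function(data, needed) {
  if (inherits(data, "data.frame")) {
    missing <- setdiff(needed, names(data))
    if (length(missing)) {
      abort(paste0("features lack columns: ", paste(missing, collapse = ", ")))
    }
    data
  } else if (is.list(data)) {
    missing <- setdiff(needed, names(data))
    if (length(missing)) {
      abort(paste0("features lack fields: ", paste(missing, collapse = ", ")))
    }
    tibble::as_tibble(data[needed])
  } else {
    abort("features must be a data frame or named list")
  }
}

clamp_sn <- function(sn) {
  neg <- sn < 0
  if (any(neg)) {
    warn(paste0(sum(neg), " negative estimate(s) clamped to 0"))
    sn[neg] <- 0
  }
  structure(sn, clamped = any(neg))
}

#' Predict seedling number with a per-stage model
#'
#' @param features Data frame (or named list) with columns `Ha` and `Co`;
#'   if it carries `variety` or `stage` columns they are checked against
#'   the model.
#' @param model A [stage_model()] or a fitted `stage_fit`.
#' @return Numeric vector of estimates, clamped at 0 (with a warning and
#'   attribute `"clamped"` when clamping occurred).
#' @examples
#' m <- get_stage_model("YM23", 1)
#' predict_stagewise(data.frame(Ha = 100, Co = 0.5), m)
#' @export
predict_stagewise <- function(features, model) {
  if (inherits(model, "stage_fit")) model <- model$model
  stopifnot(inherits(model, "stage_model"))
  f <- resolve_features(features, c("Ha", "Co"))
  if (!all(is.finite(f$Ha)) || !all(is.finite(f$Co))) {
    abort("non-finite feature values")
  }
  if ("variety" %in% names(f) && !is.na(model$variety) &&
      any(f$variety != model$variety)) {
    abort(paste0("variety mismatch: features are not ", model$variety))
  }
  if ("stage" %in% names(f) && any(f$stage != model$stage)) {
    abort(paste0("stage mismatch: features are not stage ", model$stage))
  }
  clamp_sn(model$coef_Ha * f$Ha + model$coef_Co * f$Co + model$intercept)
}

#' Predict seedling number with the unified model
#'
#' Evaluates `SN = Va * (a*Ha + b*Co + c) / (d*La)`. `Va` is taken from a
#' `Va` column if present, otherwise looked up from the model's variety
#' table via the `variety` column.
#'
#' @param features Data frame (or named list) with `Ha`, `Co`, `La` and
#'   `Va` or `variety`.
#' @param model A [unified_model()] or fitted `unified_fit`.
#' @return Numeric vector of estimates, clamped at 0.
#' @examples
#' predict_unified(data.frame(Ha = 0, Co = 0, La = 1, Va = 1.05),
#'                 unified_model())
#' @export
predict_unified <- function(features, model = unified_model()) {
  if (inherits(model, "unified_fit")) model <- model$model
  stopifnot(inherits(model, "unified_model"))
  f <- resolve_features(features, c("Ha", "Co", "La"))
  if (any(!is.finite(f$La)) || any(f$La <= 0)) {
    abort("invalid leaf age: `La` must be positive")
  }
  if ("Va" %in% names(f)) {
    va <- f$Va
  } else if ("variety" %in% names(f)) {
    unknown <- setdiff(unique(f$variety), names(model$variety_table))
    if (length(unknown)) {
      abort(paste0("unknown variety '", paste(unknown, collapse = "', '"),
                   "'; known varieties: ",
                   paste(names(model$variety_table), collapse = ", ")))
    }
    va <- unname(model$variety_table[f$variety])
  } else {
    abort("features need a `Va` or `variety` column")
  }
  clamp_sn(va * (model$a * f$Ha + model$b * f$Co + model$c) /
             (model$d * f$La))
}
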