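#' Fit metrics for seedling-number predictions
#'
#' Computes the four headline metrics used to judge counting models:
#' `R2 = 1 - SSE/SST`, adjusted `R2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`,
#' `RMSE = sqrt(SSE/n)` (population denominator) and `REP = 100 *
#' RMSE / mean(obs)`, the RMSE as a percentage of the observed mean.
#'
#' @param pred Numeric vector of predicted seedling numbers.
#' @param obs Numeric vector of observed (true) seedling numbers.
#' @param n_predictors Number of predictors used by the model.
#' @return One-row tibble with `r2`, `adj_r2`, `rmse`, `rep`, `n`.
#' @examples
#' fit_metrics(c(110, 190, 310), c(100, 200, 300), n_predictors = 1)
#' @export
fit_metrics <- function(pred, obs, n_predictors) {
  if (length(pred) != length(obs)) abort("`pred` and `obs` lengths differ")
  n <- length(obs)
  if (n < n_predictors + 2) abort("too few observations for the metrics")
  if (!all(is.finite(pred)) || !all(is.finite(obs))) {
    abort("non-finite values in predictions or observations")
  }
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) abort("degenerate observations: zero variance")
  sse <- sum((obs - pred)^2)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
  rmse <- sqrt(sse / n)
  tibble::tibble(r2 = r2, adj_r2 = adj_r2, rmse = rmse,
                 rep = 100 * rmse / mean(obs), n = n)
}

check_observation_table <- function(table, need_sn = TRUE) {
  needed <- c("Co", "Ha", if (need_sn) "SN_true")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    abort(paste0("observation table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (need_sn && any(table$SN_true < 0)) abort("`SN_true` must be >= 0")
  if (any(table$Co < 0 | table$Co > 1)) abort("`Co` must lie in [0, 1]")
  if (any(table$Ha < 0)) abort("`Ha` must be >= 0")
  invisible(table)
}

#' Stepwise multiple linear regression for a stage model
#'
#' Classic forward-entry / backward-removal stepwise selection on the
#' candidate predictors (by default `Ha` and `Co`): at each cycle the
#' candidate with the smallest partial-F p-value enters if `p < alpha_in`,
#' then included predictors with `p > alpha_out` are removed, until the
#' selection is stable. Final coefficients are ordinary least squares on
#' the selected predictors. If nothing enters, an intercept-only model is
#' returned with a warning.
#'
#' @param table Data frame with columns `Ha`, `Co`, `SN_true` (and
#'   optionally `variety`/`stage`, recorded in the result).
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha_in Entry significance level (default 0.05). Setting
#'   `alpha_in = 1` forces every candidate in.
#' @param alpha_out Removal significance level (default 0.10).
#' @return Object of class `"stage_fit"`: a list with the selected
#'   `predictors`, the fitted [stage_model()] (`model`), the underlying
#'   `lm` fit, and `metrics` from [fit_metrics()]. Supports [tidy()],
#'   [glance()] and [predict_stagewise()].
#' @export
stepwise_mlr <- function(table, candidates = c("Ha", "Co"),
                         alpha_in = 0.05, alpha_out = 0.10) {
  check_observation_table(table)
  if (nrow(table) < 10) abort("need at least 10 rows for stepwise fitting")
  if (!all(candidates %in% names(table))) {
    abort("candidate predictors missing from table")
  }
  dat <- as.data.frame(table)
  selected <- character(0)
  repeat {
    changed <- FALSE
    ## forward entry
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      base_f <- stats::reformulate(c("1", selected), response = "SN_true")
      fit0 <- lm(base_f, data = dat)
      scope <- stats::reformulate(c("1", selected, pool),
                                  response = "SN_true")
      a1 <- suppressWarnings(add1(fit0, scope = scope, test = "F"))
      pvals <- a1[["Pr(>F)"]][-1]
      names(pvals) <- rownames(a1)[-1]
      pvals <- pvals[!is.na(pvals)]
      if (length(pvals) && min(pvals) < alpha_in) {
        selected <- c(selected, names(pvals)[which.min(pvals)])
        changed <- TRUE
      }
    }
    ## backward removal
    if (length(selected)) {
      fit1 <- lm(stats::reformulate(c("1", selected), response = "SN_true"),
                 data = dat)
      d1 <- suppressWarnings(drop1(fit1, test = "F"))
      pvals <- d1[["Pr(>F)"]][-1]
      names(pvals) <- rownames(d1)[-1]
      pvals <- pvals[!is.na(pvals)]
      if (length(pvals) && max(pvals) > alpha_out) {
        selected <- setdiff(selected, names(pvals)[which.max(pvals)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(selected)) {
    warn("no predictor entered the model; returning intercept-only fit")
  }
  fit <- lm(stats::reformulate(c("1", selected), response = "SN_true"),
            data = dat)
  cf <- coef(fit)
  variety <- if ("variety" %in% names(dat) &&
                 length(unique(dat$variety)) == 1) dat$variety[1] else NA
  stage <- if ("stage" %in% names(dat) &&
               length(unique(dat$stage)) == 1) dat$stage[1] else 1L
  model <- stage_model(
    variety = variety, stage = stage,
    coef_Ha = if ("Ha" %in% selected) unname(cf["Ha"]) else 0,
    coef_Co = if ("Co" %in% selected) unname(cf["Co"]) else 0,
    intercept = unname(cf["(Intercept)"])
  )
  metrics <- if (sd(dat$SN_true) > 0) {
    fit_metrics(stats::fitted(fit), dat$SN_true,
                n_predictors = length(selected))
  } else {
    tibble::tibble(r2 = NA_real_, adj_r2 = NA_real_, rmse = 0, rep = 0,
                   n = nrow(dat))
  }
  structure(list(model = model, predictors = selected, fit = fit,
                 metrics = metrics, data = tibble::as_tibble(dat)),
            class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat("<stage_fit> predictors:",
      if (length(x$predictors)) paste(x$predictors, collapse = ", ")
      else "(intercept only)", "\n")
  print(x$model)
  cat(sprintf("  R2 %.4f, adj R2 %.4f, RMSE %.2f, REP %.2f%% (n = %d)\n",
              x$metrics$r2, x$metrics$adj_r2, x$metrics$rmse,
              x$metrics$rep, x$metrics$n))
  invisible(x)
}

#' @export
tidy.stage_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.stage_fit <- function(x, ...) x$metrics

#' Fit the unified model by constrained least squares
#'
#' The unified parametrisation `SN = Va*(a*Ha + b*Co + c)/(d*La)` is not
#' identifiable jointly in `(a, b, c, d, Va)`: a common rescaling of
#' `(a, b, c)` and `d` (or of all `Va`) changes nothing. The caller must
#' therefore fix part of it:
#'
#' * fixing `d` (and the `Va` values, via `variety_table` or a `Va`
#'   column): the model is linear in `(a, b, c)` on the transformed
#'   predictors `Va*Ha/(d*La)`, `Va*Co/(d*La)`, `Va/(d*La)` and is solved
#'   by ordinary least squares;
#' * fixing `a, b, c, d`: each variety's `Va` has the closed-form
#'   one-parameter least-squares solution `sum(SN*u)/sum(u^2)` with
#'   `u = (a*Ha + b*Co + c)/(d*La)`.
#'
#' @param table Data frame with `Ha`, `Co`, `La`, `SN_true`, and `Va` or
#'   `variety`.
#' @param fixed Named list of fixed coefficients; must pin down the free
#'   scale (contain `d`, or all of `a`, `b`, `c`, `d`).
#' @param variety_table Named `Va` values used (with fixed `d`) when the
#'   table has no `Va` column.
#' @return Object of class `"unified_fit"` with elements `model` (a
#'   [unified_model()]), `fitted_terms` (which coefficients were
#'   estimated), `metrics` and `data`.
#' @export
fit_unified <- function(table, fixed = list(d = 1.11),
                        variety_table = NULL) {
  check_observation_table(table)
  if (!"La" %in% names(table)) abort("observation table lacks column: La")
  if (length(unique(table$La)) < 2) {
    abort("need at least 2 distinct La values to calibrate the unified model")
  }
  dat <- as.data.frame(table)
  has_abc <- all(c("a", "b", "c", "d") %in% names(fixed))
  has_d <- "d" %in% names(fixed)
  if (!has_d && !has_abc) {
    abort(paste0("model not identifiable: (a, b, c) and 1/d share a common ",
                 "scale; fix `d` (or all of a, b, c, d) in `fixed`"))
  }
  if (has_abc) {
    ## solve each variety's Va with everything else fixed
    if (!"variety" %in% names(dat)) {
      abort("fitting Va requires a `variety` column")
    }
    a <- fixed$a; b <- fixed$b; c <- fixed$c; d <- fixed$d
    u <- (a * dat$Ha + b * dat$Co + c) / (d * dat$La)
    vas <- vapply(split(seq_len(nrow(dat)), dat$variety), function(i) {
      sum(dat$SN_true[i] * u[i]) / sum(u[i]^2)
    }, numeric(1))
    model <- unified_model(a = a, b = b, c = c, d = d, variety_table = vas)
    fitted_terms <- "Va"
    pred <- predict_unified(dat, model)
    metrics <- fit_metrics(pred, dat$SN_true, n_predictors = length(vas))
  } else {
    d <- fixed$d
    if (!is.finite(d) || d <= 0) abort("fixed `d` must be positive")
    if ("Va" %in% names(dat)) {
      va <- dat$Va
      vat <- if (!is.null(variety_table)) variety_table
             else if ("variety" %in% names(dat)) {
               tapply(dat$Va, dat$variety, function(v) v[1])
             } else c(default = 1)
    } else {
      if (is.null(variety_table)) {
        abort("with fixed `d`, supply `Va` in the table or a `variety_table`")
      }
      unknown <- setdiff(unique(dat$variety), names(variety_table))
      if (length(unknown)) {
        abort(paste0("varieties missing from `variety_table`: ",
                     paste(unknown, collapse = ", ")))
      }
      va <- unname(variety_table[dat$variety])
      vat <- variety_table
    }
    z <- list(a = va * dat$Ha / (d * dat$La),
              b = va * dat$Co / (d * dat$La),
              c = va / (d * dat$La))
    free <- setdiff(c("a", "b", "c"), names(fixed))
    if (!length(free)) abort("nothing left to estimate: a, b, c all fixed")
    offset <- Reduce(`+`, lapply(setdiff(names(z), free),
                                 function(nm) fixed[[nm]] * z[[nm]]),
                     accumulate = FALSE, init = rep(0, nrow(dat)))
    df <- data.frame(y = dat$SN_true - offset, z[free])
    fit <- lm(stats::reformulate(c("0", free), response = "y"), data = df)
    cf <- setNames(rep(NA_real_, 3), c("a", "b", "c"))
    cf[free] <- coef(fit)[free]
    for (nm in setdiff(names(cf), free)) cf[nm] <- fixed[[nm]]
    model <- unified_model(a = cf[["a"]], b = cf[["b"]],
                           c = cf[["c"]], d = d,
                           variety_table = unlist(vat))
    fitted_terms <- setdiff(c("a", "b", "c"), names(fixed))
    pred <- va * (model$a * dat$Ha + model$b * dat$Co + model$c) /
      (model$d * dat$La)
    metrics <- fit_metrics(pred, dat$SN_true, n_predictors = length(free))
  }
  structure(list(model = model, fitted_terms = fitted_terms, fixed = fixed,
                 metrics = metrics, data = tibble::as_tibble(dat)),
            class = "unified_fit")
}

#' @export
print.unified_fit <- function(x, ...) {
  cat("<unified_fit> estimated:", paste(x$fitted_terms, collapse = ", "),
      "| fixed:", paste(names(x$fixed), unlist(x$fixed), sep = "=",
                        collapse = ", "), "\n")
  print(x$model)
  cat(sprintf("  R2 %.4f, adj R2 %.4f, RMSE %.2f, REP %.2f%% (n = %d)\n",
              x$metrics$r2, x$metrics$adj_r2, x$metrics$rmse,
              x$metrics$rep, x$metrics$n))
  invisible(x)
}

#' @export
tidy.unified_fit <- function(x, ...) {
  m <- x$model
  terms <- c(a = m$a, b = m$b, c = m$c, d = m$d,
             setNames(as.numeric(m$variety_table),
                      paste0("Va_", names(m$variety_table))))
  tibble::tibble(term = names(terms), estimate = unname(terms),
                 fitted = names(terms) %in% c(x$fitted_terms,
                   if ("Va" %in% x$fitted_terms)
                     paste0("Va_", names(m$variety_table))))
}

#' @export
glance.unified_fit <- function(x, ...) x$metrics

#' Split an observation table into training and validation sets
#'
#' Either a site-keyed split (the study design: one site trains, the other
#' validates) when `by` names a column, or a seeded random fraction.
#'
#' @param table Non-empty data frame.
#' @param by Either a column name (each level becomes one group; the first
#'   level in sort order trains) or a numeric fraction in (0, 1) giving
#'   the training share.
#' @param seed Integer seed for the random split.
#' @return List with tibbles `train` and `validation` (disjoint,
#'   exhaustive).
#' @export
train_validate_split <- function(table, by = 0.5, seed = 1L) {
  if (!nrow(table)) abort("empty table")
  tb <- tibble::as_tibble(table)
  if (is.character(by)) {
    if (!by %in% names(tb)) abort(paste0("unknown site key: ", by))
    lev <- sort(unique(tb[[by]]))
    if (length(lev) < 2) abort("site column has fewer than 2 levels")
    list(train = tb[tb[[by]] == lev[1], ],
         validation = tb[tb[[by]] != lev[1], ])
  } else {
    if (!is.numeric(by) || by <= 0 || by >= 1) {
      abort("`by` must be a column name or a fraction in (0, 1)")
    }
    n <- nrow(tb)
    idx <- local_seeded(seed, sample.int(n, size = round(by * n)))
    list(train = tb[idx, ], validation = tb[-idx, ])
  }
}

## evaluate expr under a temporary RNG state seeded with `seed`
local_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
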