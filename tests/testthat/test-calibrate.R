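grid_table <- function(model) {
  tb <- expand.grid(Ha = seq(0, 360, by = 40),
                    Co = seq(0.05, 0.95, length.out = 10))
  tb$SN_true <- model$coef_Ha * tb$Ha + model$coef_Co * tb$Co +
    model$intercept
  tb
}

test_that("fit metrics agree with hand arithmetic", {
  m <- fit_metrics(c(110, 190, 310), c(100, 200, 300), n_predictors = 1)
  expect_equal(m$rmse, 10)
  expect_equal(m$rep, 5)
  exact <- fit_metrics(c(1, 2, 3, 4), c(1, 2, 3, 4), n_predictors = 1)
  expect_equal(exact$r2, 1)
  expect_equal(exact$rmse, 0)
  expect_equal(exact$rep, 0)
  obs <- c(3, 5, 7, 9, 11)
  flat <- fit_metrics(rep(mean(obs), 5), obs, n_predictors = 1)
  expect_equal(flat$r2, 0)
  expect_error(fit_metrics(c(1, 2, 3), c(5, 5, 5), 1), "degenerate")
  expect_error(fit_metrics(1:3, 1:4, 1), "lengths differ")
})

test_that("adjusted R2 never exceeds R2", {
  set.seed(5)
  for (i in 1:10) {
    obs <- rnorm(30, 100, 20)
    pred <- obs + rnorm(30, 0, 10)
    m <- fit_metrics(pred, obs, n_predictors = 2)
    expect_lte(m$adj_r2, m$r2)
  }
})

test_that("stepwise regression recovers noiseless stage models exactly", {
  for (v in c("YM23", "YF4")) {
    for (st in c(1, 3)) {
      truth <- get_stage_model(v, st)
      fit <- stepwise_mlr(grid_table(truth))
      expect_setequal(fit$predictors, c("Ha", "Co"))
      expect_lte(abs(fit$model$coef_Ha - truth$coef_Ha), 1e-8)
      expect_lte(abs(fit$model$coef_Co - truth$coef_Co), 1e-8)
      expect_lte(abs(fit$model$intercept - truth$intercept), 1e-8)
    }
  }
})

test_that("forced stepwise equals the normal-equations solution", {
  set.seed(77)
  for (i in 1:20) {
    n <- 40
    tb <- data.frame(Ha = runif(n, 0, 300), Co = runif(n, 0, 1))
    tb$SN_true <- pmax(runif(1, 0, 1) * tb$Ha + runif(1, 0, 150) * tb$Co +
                         runif(1, 0, 20) + rnorm(n, 0, 5), 0)
    fit <- stepwise_mlr(tb, alpha_in = 1, alpha_out = 1)
    X <- cbind(1, tb$Ha, tb$Co)
    beta <- solve(t(X) %*% X, t(X) %*% tb$SN_true)
    expect_lte(abs(fit$model$intercept - beta[1]), 1e-10)
    expect_lte(abs(fit$model$coef_Ha - beta[2]), 1e-10)
    expect_lte(abs(fit$model$coef_Co - beta[3]), 1e-10)
  }
})

test_that("a pure-noise predictor is excluded almost always", {
  excluded <- vapply(1:100, function(i) {
    set.seed(i)
    n <- 200
    tb <- data.frame(Ha = abs(rnorm(n, 100, 30)), Co = runif(n, 0.05, 0.8))
    tb$SN_true <- 60 * tb$Co + 10 + rnorm(n, 0, 2)
    !"Ha" %in% stepwise_mlr(tb)$predictors
  }, logical(1))
  expect_gte(mean(excluded), 0.95)
})

test_that("constant responses fall back to an intercept-only model", {
  tb <- data.frame(Ha = runif(20, 0, 100), Co = runif(20, 0, 1),
                   SN_true = 50)
  expect_warning(fit <- stepwise_mlr(tb), "intercept-only")
  expect_length(fit$predictors, 0)
  expect_equal(fit$model$intercept, 50)
})

test_that("tidy and glance expose the fitted coefficients and metrics", {
  truth <- get_stage_model("YM23", 1)
  fit <- stepwise_mlr(grid_table(truth))
  ## the grid fit is exact, so lm's "perfect fit" caveat is expected
  td <- suppressWarnings(tidy(fit))
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$r2, 1, tolerance = 1e-12)
})

unified_design <- function(noise_sd = 0, seed = NULL, n_rep = 1) {
  um <- unified_model()
  des <- expand.grid(Ha = seq(0, 300, by = 60),
                     Co = seq(0.05, 0.9, length.out = 6),
                     La = 1:3, variety = c("YM23", "HM7", "YF4"),
                     rep = seq_len(n_rep),
                     stringsAsFactors = FALSE)
  des$Va <- unname(um$variety_table[des$variety])
  des$SN_true <- des$Va * (um$a * des$Ha + um$b * des$Co + um$c) /
    (um$d * des$La)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    des$SN_true <- pmax(des$SN_true + rnorm(nrow(des), 0, noise_sd), 0)
  }
  des
}

test_that("unified coefficients recover exactly with d and Va fixed", {
  des <- unified_design()
  fit <- fit_unified(des, fixed = list(d = 1.11))
  expect_lte(abs(fit$model$a - 0.44), 1e-8)
  expect_lte(abs(fit$model$b - 110.43), 1e-8)
  expect_lte(abs(fit$model$c - 3.35), 1e-8)
  expect_equal(glance(fit)$r2, 1, tolerance = 1e-12)
})

test_that("variety coefficients recover exactly with a, b, c, d fixed", {
  des <- unified_design()
  hm <- des[des$variety == "HM7", ]
  hm$Va <- NULL
  fit <- fit_unified(hm, fixed = list(a = 0.44, b = 110.43,
                                      c = 3.35, d = 1.11))
  expect_lte(abs(fit$model$variety_table[["HM7"]] - 0.86), 1e-8)
})

test_that("an unpinned unified fit is rejected as unidentifiable", {
  des <- unified_design()
  expect_error(fit_unified(des, fixed = list()), "not identifiable")
  one_la <- des[des$La == 2, ]
  expect_error(fit_unified(one_la, fixed = list(d = 1.11)),
               "distinct La")
})

test_that("unified coefficients recover within 5% under field-scale noise", {
  rel_err <- t(vapply(1:100, function(i) {
    des <- unified_design(noise_sd = 2, seed = 1000 + i, n_rep = 3)
    des <- des[sample.int(nrow(des), 720), ]
    fit <- fit_unified(des, fixed = list(d = 1.11))
    c(abs(fit$model$a - 0.44) / 0.44, abs(fit$model$b - 110.43) / 110.43)
  }, numeric(2)))
  expect_lte(max(rel_err[, 1]), 0.05)
  expect_lte(max(rel_err[, 2]), 0.05)
})

test_that("train/validation splits are disjoint, exhaustive, reproducible", {
  tb <- tibble::tibble(id = 1:10, site = rep(c("HA", "YZ"), each = 5),
                       Co = runif(10), Ha = 1:10, SN_true = 1:10)
  sp <- train_validate_split(tb, by = 0.5, seed = 7)
  expect_equal(nrow(sp$train), 5)
  expect_equal(nrow(sp$validation), 5)
  expect_length(intersect(sp$train$id, sp$validation$id), 0)
  sp2 <- train_validate_split(tb, by = 0.5, seed = 7)
  expect_equal(sp$train$id, sp2$train$id)
  site <- train_validate_split(tb, by = "site")
  expect_true(all(site$train$site == "HA"))
  expect_true(all(site$validation$site == "YZ"))
  expect_error(train_validate_split(tb, by = "plot"), "unknown site key")
  expect_error(train_validate_split(tb[0, ], by = 0.5), "empty")
})
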