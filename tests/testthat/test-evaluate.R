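test_that("diagnostics hit their closed-form limits", {
  # fitted == observed: perfect fit
  co <- revised_coefficients()
  df <- toy_entries(6, body_weight_kg = c(0.3, 0.5, 0.9, 1.4, 2.1, 3.0),
                    temperature_c = c(4, 7, 10, 13, 16, 18))
  df$mo2_mg_kg_h <- predict_fixed(co, df$body_weight_kg, df$temperature_c,
                                  df$rel_speed_bl_s)
  ds <- respirometry_dataset(df)
  d <- model_diagnostics(co, ds)
  expect_equal(d$r2, 1)
  expect_equal(d$rmse, 0)
  # fitted == mean(observed): r2 exactly 0
  flat <- coefficient_set(200, 0, 1, 1)   # predicts 200 everywhere
  df2 <- toy_entries(6, mo2_mg_kg_h = c(150, 250, 180, 220, 190, 210))  # mean 200
  d2 <- model_diagnostics(flat, respirometry_dataset(df2))
  expect_equal(d2$r2, 0, tolerance = 1e-12)
  expect_true(d2$adj_r2 <= d2$r2)   # n > p + 1
  # adjusted R2 undefined when n <= p + 1
  d3 <- model_diagnostics(co, toy_dataset(4))
  expect_false(d3$adj_r2_defined)
  expect_true(is.na(d3$adj_r2))
})

test_that("diagnostics are invariant under entry reordering", {
  ds <- refine(generate_dataset(default_synth_config(seed = 4))$dataset)
  fit <- fit_stage2_nlme(ds)
  d <- model_diagnostics(fit, ds)
  df <- as.data.frame(ds)
  withr::with_seed(7, perm <- sample(nrow(df)))
  d2 <- model_diagnostics(fit, respirometry_dataset(df[perm, ]))
  expect_equal(d2$r2, d$r2, tolerance = 1e-12)
  expect_equal(d2$rmse, d$rmse, tolerance = 1e-12)
  # Q-Q pairs follow the plotting-position definition
  n <- d$n
  expect_equal(d$qq_pairs$theoretical, qnorm((seq_len(n) - 0.5) / n))
  expect_equal(d$qq_pairs$sample, sort(d$residuals / fit$sigma_resid))
})

test_that("conditional diagnostics use the empirical-Bayes study deviations", {
  ds <- refine(generate_dataset(default_synth_config(seed = 4))$dataset)
  fit <- fit_stage2_nlme(ds)
  dp <- model_diagnostics(fit, ds, level = "population")
  dc <- model_diagnostics(fit, ds, level = "conditional")
  # conditional predictions absorb between-study spread: SSE cannot grow
  expect_lte(dc$rmse, dp$rmse + 1e-9)
  expect_error(model_diagnostics(revised_coefficients(), ds,
                                 level = "conditional"), "mo2_fit")
})

test_that("model comparison favors the generating coefficient set", {
  co <- revised_coefficients()
  leg <- legacy_coefficients()
  # identical sets give identical reports
  ds <- refine(generate_dataset(default_synth_config(seed = 9))$dataset)
  cmp_same <- compare_models(ds, leg, legacy = leg)
  expect_equal(cmp_same$candidate$rmse, cmp_same$legacy$rmse)
  expect_equal(cmp_same$candidate$r2, cmp_same$legacy$r2)
  # noise-free data from the legacy equation: legacy fits perfectly
  cfg <- default_synth_config(
    seed = 2, truth = synthetic_truth(a = 61.6, b = -0.33, c = 1.03, d = 1.79,
                                      sigma_study = 0, sigma_resid = 0),
    include_plateau_rows = FALSE)
  ds_leg <- generate_dataset(cfg)$dataset
  cmp <- compare_models(ds_leg, co, legacy = leg)
  expect_equal(cmp$legacy$rmse, 0, tolerance = 1e-9)
  expect_gt(cmp$candidate$rmse, cmp$legacy$rmse)
  # and symmetrically for candidate-generated data
  cfg2 <- default_synth_config(
    seed = 2, truth = synthetic_truth(sigma_study = 0, sigma_resid = 0),
    include_plateau_rows = FALSE)
  cmp2 <- compare_models(generate_dataset(cfg2)$dataset, co, legacy = leg)
  expect_equal(cmp2$candidate$rmse, 0, tolerance = 1e-9)
  expect_lt(cmp2$candidate$rmse, cmp2$legacy$rmse)
})

test_that("prediction bands follow the delta method on the log scale", {
  ds <- refine(generate_dataset(default_synth_config(seed = 4))$dataset)
  fit <- fit_stage2_nlme(ds)
  g <- prediction_grid(fit, axis = "T", range = c(3, 18), n = 25,
                       held = list(W = 0.6, U = 1.2))
  expect_true(attr(g, "bands_available"))
  expect_true(all(g$lower <= g$mo2 & g$mo2 <= g$upper))
  expect_true(all(g$lower > 0))
  # zero covariance collapses the band onto the prediction
  fit0 <- fit
  fit0$vcov_opt <- matrix(0, 4, 4)
  g0 <- prediction_grid(fit0, axis = "W", range = c(0.3, 3), n = 10,
                        held = list(T = 10, U = 1))
  expect_equal(g0$lower, g0$mo2)
  expect_equal(g0$upper, g0$mo2)
  # missing covariance: bands omitted with the flag down
  fitNA <- fit
  fitNA$vcov_opt <- matrix(NA_real_, 4, 4)
  gna <- prediction_grid(fitNA, axis = "U", range = c(0, 2), n = 5,
                         held = list(W = 1, T = 10))
  expect_false(attr(gna, "bands_available"))
  expect_true(all(is.na(gna$lower)))
  # at (W=1, T=0, U=0) with only var(a) nonzero the band is the closed form
  # a * exp(-+ z sqrt(var a) / a)
  fitA <- fit
  va <- 25
  fitA$vcov_opt <- diag(c(va, 0, 0, 0))
  g1 <- prediction_grid(fitA, axis = "W", range = c(1, 1), n = 1,
                        held = list(T = 0, U = 0))
  a <- unclass(fit$coefficients)[["a"]]
  z <- qnorm(0.975)
  expect_equal(g1$lower, a * exp(-z * sqrt(va) / a), tolerance = 1e-12)
  expect_equal(g1$upper, a * exp(z * sqrt(va) / a), tolerance = 1e-12)
})

test_that("the delta band matches a parametric-bootstrap oracle", {
  ds <- refine(generate_dataset(default_synth_config(seed = 4))$dataset)
  fit <- fit_stage2_nlme(ds)
  g <- prediction_grid(fit, axis = "T", range = c(10, 10), n = 1,
                       held = list(W = 0.6, U = 1.2))
  co <- unclass(fit$coefficients)
  est <- c(co[["a"]], co[["b"]], log(co[["c"]]), log(co[["d"]]))
  withr::with_seed(99, {
    draws <- matrix(rnorm(2000 * 4), 2000) %*% chol(fit$vcov_opt)
  })
  draws <- sweep(draws, 2, est, "+")
  mo2b <- draws[, 1] * 0.6^draws[, 2] * exp(10 * draws[, 3] + 1.2 * draws[, 4])
  qb <- unname(quantile(mo2b, c(0.025, 0.975)))
  expect_equal(g$upper - g$lower, diff(qb), tolerance = 0.05)
})
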