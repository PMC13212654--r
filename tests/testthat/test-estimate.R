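test_that("stage 1 recovers the truth exactly on noise-free data", {
  cfg <- default_synth_config(
    seed = 3, truth = synthetic_truth(sigma_study = 0, sigma_resid = 0),
    include_plateau_rows = FALSE)
  ds <- generate_dataset(cfg)$dataset
  est <- unclass(fit_stage1_loglinear(ds))
  expect_equal(max(abs(est / truth_vector() - 1)), 0, tolerance = 1e-10)
})

test_that("stage 1 equals the normal-equations solution", {
  df <- toy_entries(6,
                    body_weight_kg = c(0.3, 0.5, 0.9, 1.4, 2.1, 3.0),
                    temperature_c = c(4, 7, 10, 13, 16, 18),
                    rel_speed_bl_s = c(0.4, 1.9, 0.8, 2.3, 1.2, 1.6),
                    mo2_mg_kg_h = c(120, 310, 205, 480, 260, 350))
  ds <- respirometry_dataset(df)
  est <- unclass(fit_stage1_loglinear(ds))
  # oracle: explicit least-squares solve of the log-linear system
  X <- cbind(1, log(df$body_weight_kg), df$temperature_c, df$rel_speed_bl_s)
  beta <- solve(crossprod(X), crossprod(X, log(df$mo2_mg_kg_h)))
  expect_equal(unname(est),
               c(exp(beta[1]), beta[2], exp(beta[3]), exp(beta[4])),
               tolerance = 1e-10)
})

test_that("stage 1 names the collinear predictor", {
  ds <- toy_dataset(6, rel_speed_bl_s = 1.2,
                    treatment_id = paste0("g", 1:6),
                    temperature_c = c(4, 7, 10, 13, 16, 18),
                    body_weight_kg = c(0.3, 0.5, 0.9, 1.4, 2.1, 3.0))
  expect_error(fit_stage1_loglinear(ds), "collinear: rel_speed")
  ds2 <- toy_dataset(6, temperature_c = 10,
                     body_weight_kg = c(0.3, 0.5, 0.9, 1.4, 2.1, 3.0))
  expect_error(fit_stage1_loglinear(ds2), "collinear: temperature")
  expect_error(fit_stage1_loglinear(toy_dataset(4)), "at least 5")
})

test_that("stage 2 on noise-free single-study data recovers the truth", {
  grid <- expand.grid(body_weight_kg = c(0.3, 0.8, 2.0),
                      temperature_c = c(5, 12, 17),
                      rel_speed_bl_s = c(0.5, 1.5, 2.5))
  df <- toy_entries(nrow(grid), treatment_id = paste0("g", seq_len(nrow(grid))),
                    body_weight_kg = grid$body_weight_kg,
                    temperature_c = grid$temperature_c,
                    rel_speed_bl_s = grid$rel_speed_bl_s)
  df$mo2_mg_kg_h <- predict_fixed(revised_coefficients(), df$body_weight_kg,
                                  df$temperature_c, df$rel_speed_bl_s)
  one <- respirometry_dataset(df)
  expect_warning(fit <- fit_stage2_nlme(one), "single study")
  expect_equal(unname(unclass(fit$coefficients)), unname(truth_vector()),
               tolerance = 1e-6)
  expect_lt(fit$sigma_resid, 1e-6)   # residual SD driven to its floor
  expect_equal(fit$sigma_study, 0)
})

test_that("stage 2 equals nonlinear least squares when sigma_study = 0", {
  skip_if_not_installed("minpack.lm")
  cfg <- default_synth_config(seed = 5, truth = synthetic_truth(sigma_study = 0))
  ds <- refine(generate_dataset(cfg)$dataset)
  fit <- fit_stage2_nlme(ds)
  df <- as.data.frame(ds)
  # oracle: Levenberg-Marquardt nonlinear least squares on the same data
  nls_fit <- minpack.lm::nlsLM(
    mo2_mg_kg_h ~ a * body_weight_kg^b * cc^temperature_c * dd^rel_speed_bl_s,
    data = df, start = list(a = 80, b = -0.14, cc = 1.04, dd = 1.63),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  expect_equal(max(abs(unclass(fit$coefficients) / coef(nls_fit) - 1)), 0,
               tolerance = 1e-4)
  expect_equal(fit$sigma_study, 0)
  expect_true(fit$converged)
})

test_that("stage 2 is invariant to entry order and study relabeling", {
  ds <- refine(generate_dataset(default_synth_config(seed = 10))$dataset)
  fit <- fit_stage2_nlme(ds)
  df <- as.data.frame(ds)
  withr::with_seed(1, perm <- sample(nrow(df)))
  shuffled <- respirometry_dataset(df[perm, ])
  fit_p <- fit_stage2_nlme(shuffled)
  expect_equal(unclass(fit_p$coefficients), unclass(fit$coefficients),
               tolerance = 1e-6)
  relabeled <- df
  relabeled$study_id <- paste0("zz_", relabeled$study_id)
  fit_r <- fit_stage2_nlme(respirometry_dataset(relabeled))
  expect_equal(unclass(fit_r$coefficients), unclass(fit$coefficients),
               tolerance = 1e-6)
  expect_equal(fit_r$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("the fitted optimum is a local maximum of the marginal likelihood", {
  ds <- refine(generate_dataset(default_synth_config(seed = 12))$dataset)
  fit <- fit_stage2_nlme(ds)
  co <- unclass(fit$coefficients)
  ll0 <- marginal_loglik(ds, fit$coefficients, fit$sigma_study, fit$sigma_resid)
  withr::with_seed(2024, {
    for (k in 1:100) {
      which_par <- sample(4, 1)
      eps <- sample(c(-1, 1), 1) * runif(1, 0.001, 0.05)
      pert <- co
      pert[which_par] <- pert[which_par] * (1 + eps)
      ll <- marginal_loglik(ds, coefficient_set(pert[1], pert[2], pert[3],
                                                pert[4]),
                            fit$sigma_study, fit$sigma_resid)
      expect_lte(ll, ll0 + 1e-8)
    }
  })
})

test_that("Wald intervals behave as closed-form theory dictates", {
  ds <- refine(generate_dataset(default_synth_config(seed = 4))$dataset)
  fit <- fit_stage2_nlme(ds)
  ci95 <- wald_confint(fit, 0.95)
  ci99 <- wald_confint(fit, 0.99)
  expect_true(all(ci95$lower <= ci95$estimate & ci95$estimate <= ci95$upper))
  expect_true(all(ci95$lower[c(1, 3, 4)] > 0))  # a, c, d intervals positive
  # widths scale by the normal-quantile ratio on the optimization scale
  ratio <- qnorm(0.995) / qnorm(0.975)
  expect_equal((ci99$upper - ci99$lower)[1:2] / (ci95$upper - ci95$lower)[1:2],
               rep(ratio, 2), tolerance = 1e-9)
  expect_equal(log(ci99$upper / ci99$lower)[3:4] /
                 log(ci95$upper / ci95$lower)[3:4],
               rep(ratio, 2), tolerance = 1e-9)
  # zero standard errors collapse the intervals onto the estimates
  fit0 <- fit
  fit0$se_opt <- rep(0, 4)
  ci0 <- wald_confint(fit0)
  expect_equal(ci0$lower, ci0$estimate)
  expect_equal(ci0$upper, ci0$estimate)
  expect_error(wald_confint(fit, 1.2), "level")
  expect_error(wald_confint(fit, 0), "level")
})

test_that("interaction screening retains a strongly planted T:U term", {
  ds <- planted_tu_dataset(seed = 1)
  fit <- fit_stage2_nlme(ds)
  sc <- screen_interactions(ds, fit)
  expect_identical(sc$retained, "T:U")
  tu <- sc$candidates[sc$candidates$candidate == "T:U", ]
  expect_lt(tu$p_value, 0.001)
  expect_lt(tu$delta_aic, -2)
  # and the null screen on interaction-free data keeps nothing (single seed)
  ds0 <- refine(generate_dataset(default_synth_config(seed = 1))$dataset)
  fit0 <- fit_stage2_nlme(ds0)
  sc0 <- screen_interactions(ds0, fit0)
  expect_length(sc0$retained, 0)
  expect_true(all(sc0$candidates$p_value >= 0 & sc0$candidates$p_value <= 1,
                  na.rm = TRUE))
  fit_bad <- fit0
  fit_bad$converged <- FALSE
  expect_error(screen_interactions(ds0, fit_bad), "not converged")
})
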