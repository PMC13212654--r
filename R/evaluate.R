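#' Fit diagnostics
#'
#' Coefficient of determination, adjusted R-squared (for p = 3 predictors by
#' default), root-mean-square error, residuals, standardised residuals and
#' normal Q-Q pairs for a fitted or fixed coefficient set evaluated against a
#' dataset.
#'
#' Fitted values use the fixed effects only (`level = "population"`) unless
#' `level = "conditional"`, in which case the empirical-Bayes study
#' deviations (BLUPs) of an `mo2_fit` are added. RMSE uses 1/n
#' normalisation. Standardised residuals divide by the fit's residual SD
#' (or, for a bare coefficient set, by the RMSE).
#'
#' @param object An `mo2_fit` or an `mo2_coefs` coefficient set.
#' @param ds The `respirometry` dataset to evaluate against.
#' @param level `"population"` (default) or `"conditional"` (fit only).
#' @param p Number of predictors for the adjusted R-squared (default 3).
#' @return A list of class `mo2_diagnostics` with `r2`, `adj_r2`, `rmse`,
#'   `residuals`, `std_residuals`, `qq_pairs` (data frame `theoretical`,
#'   `sample`), `n`, `p`, and `adj_r2_defined`.
#' @export
model_diagnostics <- function(object, ds, level = c("population", "conditional"),
                              p = 3) {
  level <- match.arg(level)
  stopifnot(inherits(ds, "respirometry"))
  df <- as.data.frame(ds)
  if (inherits(object, "mo2_fit")) {
    coefs <- object$coefficients
    sigma <- object$sigma_resid
  } else {
    coefs <- as_mo2_coefs(object)
    sigma <- NULL
    if (level == "conditional") {
      stop("conditional predictions require an 'mo2_fit'", call. = FALSE)
    }
  }
  fitted <- predict_fixed(coefs, df$body_weight_kg, df$temperature_c,
                          df$rel_speed_bl_s)
  if (level == "conditional") {
    u <- study_blups(object, ds)
    x <- fitted / coefs[["a"]]
    fitted <- fitted + u[df$study_id] * x
  }
  y <- df$mo2_mg_kg_h
  n <- length(y)
  resid <- y - fitted
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  adj_ok <- n > p + 1
  adj_r2 <- if (adj_ok) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  rmse <- sqrt(sse / n)
  if (is.null(sigma)) sigma <- rmse
  std <- if (sigma > 0) resid / sigma else resid * 0
  qq <- data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
                   sample = sort(std))
  structure(list(r2 = r2, adj_r2 = adj_r2, adj_r2_defined = adj_ok,
                 rmse = rmse, residuals = resid, fitted = fitted,
                 std_residuals = std, qq_pairs = qq, n = n, p = p,
                 level = level),
            class = "mo2_diagnostics")
}

# Empirical-Bayes (BLUP) study-intercept deviations:
# E[u_i | y_i] = su2 x_i' r_i / (s2 + su2 |x_i|^2) with r_i the fixed-effect
# residuals.
study_blups <- function(fit, ds) {
  stopifnot(inherits(fit, "mo2_fit"))
  groups <- prepare_groups(ds)
  co <- unclass(fit$coefficients)
  su2 <- fit$sigma_study^2
  s2 <- fit$sigma_resid^2
  vapply(groups, function(grp) {
    x <- exp(co[["b"]] * grp$lnW + log(co[["c"]]) * grp$T +
               log(co[["d"]]) * grp$U)
    r <- grp$y - co[["a"]] * x
    su2 * sum(x * r) / (s2 + su2 * sum(x * x))
  }, 0)
}

#' @export
print.mo2_diagnostics <- function(x, ...) {
  cat(sprintf("R2 = %.4f, adjusted R2 = %s, RMSE = %.2f (n = %d, %s)\n",
              x$r2, if (x$adj_r2_defined) sprintf("%.4f", x$adj_r2) else "undefined",
              x$rmse, x$n, x$level))
  invisible(x)
}

#' Compare a candidate coefficient set against the legacy model
#'
#' Evaluates two fixed coefficient sets against the same dataset (population
#' predictions, no refitting -- the legacy equation is applied as published)
#' and returns both diagnostic reports.
#'
#' @param ds A `respirometry` dataset.
#' @param candidate Candidate `mo2_coefs` (or an `mo2_fit`).
#' @param legacy Legacy `mo2_coefs`; default [legacy_coefficients()].
#' @return A list of class `mo2_comparison` with elements `candidate` and
#'   `legacy`, each an `mo2_diagnostics`.
#' @export
compare_models <- function(ds, candidate, legacy = legacy_coefficients()) {
  if (inherits(candidate, "mo2_fit")) candidate <- candidate$coefficients
  structure(list(candidate = model_diagnostics(as_mo2_coefs(candidate), ds),
                 legacy = model_diagnostics(as_mo2_coefs(legacy), ds)),
            class = "mo2_comparison")
}

#' @export
print.mo2_comparison <- function(x, ...) {
  cat("candidate: "); print(x$candidate)
  cat("legacy:    "); print(x$legacy)
  invisible(x)
}

#' Prediction grid with delta-method confidence bands
#'
#' Varies one primary parameter over a range while holding the other two
#' fixed, and returns point predictions with a 95 % (by default) confidence
#' band. The band is computed by the delta method on `log(MO2)`, whose
#' gradient with respect to `(a, b, log c, log d)` is
#' `(1/a, log W, T, U)`; the band is exponentiated back, so it is positive
#' and contains the point prediction.
#'
#' @param fit An `mo2_fit` with an available `vcov_opt` (bands are omitted,
#'   with `bands_available = FALSE`, when the covariance is missing).
#' @param axis Which parameter to vary: `"W"`, `"T"` or `"U"`.
#' @param range Length-2 numeric `(lo, hi)` for the varied axis.
#' @param n Number of grid points (default 50).
#' @param held Named list giving the two held axes, e.g.
#'   `list(T = 11, U = 1.3)` when `axis = "W"`.
#' @param level Band level in (0, 1); default 0.95.
#' @return A data frame of class `mo2_grid` with columns `W`, `T`, `U`,
#'   `mo2`, `lower`, `upper`, and attribute `bands_available`.
#' @export
prediction_grid <- function(fit, axis = c("W", "T", "U"), range, n = 50,
                            held = list(), level = 0.95) {
  axis <- match.arg(axis)
  stopifnot(inherits(fit, "mo2_fit"), length(range) == 2, n >= 1)
  others <- setdiff(c("W", "T", "U"), axis)
  if (!all(others %in% names(held))) {
    stop("'held' must supply values for: ", paste(others, collapse = ", "),
         call. = FALSE)
  }
  vals <- if (n == 1) mean(range) else seq(range[1], range[2], length.out = n)
  ax <- list(W = NULL, T = NULL, U = NULL)
  ax[[axis]] <- vals
  for (o in others) ax[[o]] <- rep(held[[o]], length(vals))
  co <- unclass(fit$coefficients)
  mo2 <- predict_fixed(fit$coefficients, ax$W, ax$T, ax$U)
  V <- fit$vcov_opt
  bands <- !is.null(V) && !anyNA(V)
  lower <- upper <- rep(NA_real_, length(vals))
  if (bands) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    G <- cbind(1 / co[["a"]], log(ax$W), ax$T, ax$U)
    var_log <- rowSums((G %*% V) * G)
    var_log <- pmax(var_log, 0)
    lower <- mo2 * exp(-z * sqrt(var_log))
    upper <- mo2 * exp(z * sqrt(var_log))
  }
  structure(data.frame(W = ax$W, T = ax$T, U = ax$U, mo2 = mo2,
                       lower = lower, upper = upper),
            bands_available = bands, axis = axis, level = level,
            class = c("mo2_grid", "data.frame"))
}
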