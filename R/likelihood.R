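# Per-study data blocks used by the likelihood. `z` carries an optional
# interaction regressor (a product term added inside the exponential of the
# log-scale mean); zero when absent.
prepare_groups <- function(ds, interaction = NULL) {
  stopifnot(inherits(ds, "respirometry"))
  df <- as.data.frame(ds)
  z <- switch(
    if (is.null(interaction)) "none" else interaction,
    none    = rep(0, nrow(df)),
    `lnW:T` = log(df$body_weight_kg) * df$temperature_c,
    `lnW:U` = log(df$body_weight_kg) * df$rel_speed_bl_s,
    `T:U`   = df$temperature_c * df$rel_speed_bl_s,
    stop("unknown interaction term: ", interaction, call. = FALSE)
  )
  idx <- split(seq_len(nrow(df)), df$study_id)
  lapply(idx, function(i) list(
    lnW = log(df$body_weight_kg[i]),
    T = df$temperature_c[i],
    U = df$rel_speed_bl_s[i],
    z = z[i],
    y = df$mo2_mg_kg_h[i]
  ))
}

# Exact Gaussian marginal log-likelihood of the random-intercept model.
# Within study i, with x_ij = W^b c^T d^U (times exp(g z) when an interaction
# is screened), y_i ~ N(a x_i, sigma_study^2 x_i x_i' + sigma_resid^2 I).
# The rank-one covariance is handled in closed form via the matrix
# determinant lemma and the Sherman-Morrison identity:
#   log|Sigma| = (n-1) log s2 + log(s2 + su2 |x|^2)
#   r' Sigma^-1 r = r'r / s2 - su2 (x'r)^2 / (s2 (s2 + su2 |x|^2))
loglik_core <- function(groups, a, b, lc, ld, g, su2, s2) {
  ll <- 0
  for (grp in groups) {
    x <- exp(b * grp$lnW + lc * grp$T + ld * grp$U + g * grp$z)
    r <- grp$y - a * x
    n <- length(r)
    denom <- s2 + su2 * sum(x * x)
    ll <- ll - 0.5 * (n * log(2 * pi) + (n - 1) * log(s2) + log(denom) +
                        sum(r * r) / s2 - su2 * sum(x * r)^2 / (s2 * denom))
  }
  ll
}

#' Marginal log-likelihood of the random-intercept MO2 model
#'
#' Exact Gaussian marginal log-likelihood of
#' `mo2_ij = (a + u_i) W^b c^T d^U + eps_ij`, with
#' `u_i ~ N(0, sigma_study^2)` per study and iid residuals
#' `eps ~ N(0, sigma_resid^2)`, integrated analytically over the random
#' effect. Computed stably through the rank-one structure of the per-study
#' covariance (matrix determinant lemma / Sherman-Morrison), so no matrix
#' factorisation is required.
#'
#' @param ds A `respirometry` dataset (grouped by `study_id`).
#' @param coefs An `mo2_coefs` coefficient set.
#' @param sigma_study Between-study intercept SD; >= 0 (0 reduces to the iid
#'   Gaussian log-likelihood of the fixed-effect residuals).
#' @param sigma_resid Residual SD; must be > 0.
#' @return The scalar marginal log-likelihood.
#' @export
marginal_loglik <- function(ds, coefs, sigma_study, sigma_resid) {
  coefs <- as_mo2_coefs(coefs)
  if (!is.numeric(sigma_resid) || sigma_resid <= 0) {
    stop("'sigma_resid' must be > 0", call. = FALSE)
  }
  if (!is.numeric(sigma_study) || sigma_study < 0) {
    stop("'sigma_study' must be >= 0", call. = FALSE)
  }
  groups <- prepare_groups(ds)
  loglik_core(groups, coefs[["a"]], coefs[["b"]], log(coefs[["c"]]),
              log(coefs[["d"]]), 0, sigma_study^2, sigma_resid^2)
}

# Central-difference numerical Hessian with relative step 1e-5.
num_hessian <- function(f, x, rel_step = 1e-5) {
  k <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}
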