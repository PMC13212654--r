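#' Stage 1: log-linear starting values
#'
#' Ordinary least squares of `log(mo2)` on `{1, log(W), T, U}`. The
#' multiplicative model is exactly linear on the log scale, so the intercept
#' exponentiates to `a`, the `log(W)` slope is `b`, and the `T` and `U`
#' slopes exponentiate to `c` and `d`. These serve as biologically
#' interpretable starting values for the stage-2 mixed-effects fit.
#'
#' @param ds A `respirometry` dataset with at least 5 entries, all
#'   `mo2 > 0` and `body_weight > 0`.
#' @return An `mo2_coefs` coefficient set.
#' @export
fit_stage1_loglinear <- function(ds) {
  stopifnot(inherits(ds, "respirometry"))
  df <- as.data.frame(ds)
  if (nrow(df) < 5L) stop("need at least 5 entries", call. = FALSE)
  stopifnot(all(df$mo2_mg_kg_h > 0), all(df$body_weight_kg > 0))
  preds <- list(body_weight = log(df$body_weight_kg),
                temperature = df$temperature_c,
                rel_speed = df$rel_speed_bl_s)
  for (nm in names(preds)) {
    if (stats::sd(preds[[nm]]) == 0) {
      stop("collinear: ", nm, " is constant across entries", call. = FALSE)
    }
  }
  X <- cbind(1, preds$body_weight, preds$temperature, preds$rel_speed)
  if (qr(X)$rank < 4L) {
    stop("collinear: rank-deficient design (some predictors are linearly ",
         "dependent)", call. = FALSE)
  }
  fit <- stats::lm(log(df$mo2_mg_kg_h) ~ preds$body_weight +
                     preds$temperature + preds$rel_speed)
  cf <- unname(stats::coef(fit))
  coefficient_set(exp(cf[1]), cf[2], exp(cf[3]), exp(cf[4]))
}

# Maximum-likelihood engine shared by the stage-2 fit and the interaction
# refits. Parameters on the optimization scale:
#   (a, b, lc = log c, ld = log d, [g], [lsu = log sigma_study], lsr = log sigma_resid)
# Variance components are optimized on the log scale to enforce positivity;
# sigma_study has an effective floor of 1e-8 * a0. Quasi-Newton (L-BFGS-B)
# from the supplied start, then Newton polishing with Richardson gradients
# until the gradient infinity-norm over interior parameters drops below 1e-6.
fit_ml_engine <- function(groups, a0, b0, lc0, ld0, g0 = NULL,
                          su0, sr0, fix_su = FALSE,
                          max_iter = 500, grad_tol = 1e-6) {
  has_g <- !is.null(g0)
  nm <- c("a", "b", "lc", "ld", if (has_g) "g",
          if (!fix_su) "lsu", "lsr")
  lsu_floor <- log(1e-8 * a0)
  lsr_floor <- log(1e-10 * max(sr0, 1))
  par0 <- c(a0, b0, lc0, ld0,
            if (has_g) g0,
            if (!fix_su) max(log(max(su0, 0)), lsu_floor),
            max(log(sr0), lsr_floor + 1))
  names(par0) <- nm
  lower <- c(1e-8, -Inf, -Inf, -Inf, if (has_g) -Inf,
             if (!fix_su) lsu_floor, lsr_floor)

  negll <- function(p) {
    a <- p[[1]]; b <- p[[2]]; lc <- p[[3]]; ld <- p[[4]]
    i <- 5L
    g <- 0
    if (has_g) { g <- p[[i]]; i <- i + 1L }
    su2 <- 0
    if (!fix_su) { su2 <- exp(2 * p[[i]]); i <- i + 1L }
    s2 <- exp(2 * p[[i]])
    v <- loglik_core(groups, a, b, lc, ld, g, su2, s2)
    if (!is.finite(v)) return(1e10)
    -v
  }

  parscale <- pmax(abs(par0), c(1, 0.1, 0.02, 0.1, if (has_g) 0.02,
                                if (!fix_su) 1, 1))
  opt <- stats::optim(par0, negll, method = "L-BFGS-B", lower = lower,
                      control = list(maxit = max_iter, factr = 1e4,
                                     parscale = parscale))
  par <- opt$par
  n_iter <- opt$counts[["function"]]

  # Newton polish over interior (non-boundary) parameters.
  at_bound <- function(p) is.finite(lower) & (p <= lower + 1e-9)
  polish <- function(par) {
    grad_ok <- FALSE
    for (it in seq_len(50)) {
      free <- which(!at_bound(par))
      f_free <- function(pf) { p <- par; p[free] <- pf; negll(p) }
      gr <- pracma::grad(f_free, par[free])
      if (max(abs(gr)) < grad_tol) { grad_ok <- TRUE; break }
      H <- num_hessian(f_free, par[free])
      step <- tryCatch(-solve(H, gr), error = function(e)
        -solve(H + diag(1e-6 * max(abs(diag(H))), length(free)), gr))
      f_cur <- negll(par)
      try_step <- function(step) {
        lam <- 1
        for (ls in seq_len(25)) {
          cand <- par
          cand[free] <- par[free] + lam * step
          cand <- pmax(cand, lower)
          f_new <- negll(cand)
          if (is.finite(f_new) && f_new <= f_cur + 1e-9 * max(1, abs(f_cur))) {
            return(cand)
          }
          lam <- lam / 2
        }
        NULL
      }
      cand <- try_step(step)
      if (is.null(cand)) {
        # Newton direction unusable (indefinite Hessian far from the
        # optimum); fall back on scaled steepest descent.
        cand <- try_step(-gr * parscale[free]^2 / max(abs(gr * parscale[free])))
      }
      n_iter <<- n_iter + 1L
      if (is.null(cand)) break
      par <- cand
    }
    if (!grad_ok) {   # final check after the last step
      free <- which(!at_bound(par))
      f_free <- function(pf) { p <- par; p[free] <- pf; negll(p) }
      grad_ok <- max(abs(pracma::grad(f_free, par[free]))) < grad_tol
    }
    list(par = par, grad_ok = grad_ok)
  }
  pol <- polish(par)
  par <- pol$par
  # A between-study SD below 1e-3 * a is statistically indistinguishable
  # from zero but leaves the likelihood nearly flat (and the Hessian
  # singular) in that direction; snap it to the floor and re-polish the rest.
  if (!fix_su && !at_bound(par)[["lsu"]] &&
      exp(par[["lsu"]]) < 1e-3 * par[["a"]]) {
    par[["lsu"]] <- lsu_floor
    pol <- polish(par)
    par <- pol$par
  }
  grad_ok <- pol$grad_ok

  free <- which(!at_bound(par))
  f_free <- function(pf) { p <- par; p[free] <- pf; negll(p) }
  H_free <- num_hessian(f_free, par[free])
  vcov_free <- tryCatch(solve(H_free), error = function(e) NULL)

  list(par = par, names = nm, loglik = -negll(par),
       converged = grad_ok,
       n_iter = n_iter, free = free, vcov_free = vcov_free,
       at_boundary = nm[at_bound(par)])
}

#' Stage 2: maximum-likelihood nonlinear mixed-effects fit
#'
#' Fits `mo2 = (a + u_study) W^b c^T d^U + eps` by maximizing the exact
#' marginal likelihood (see [marginal_loglik()]) over
#' `(a, b, log c, log d, log sigma_study, log sigma_resid)` by quasi-Newton
#' iteration with Newton polishing, starting from the stage-1 log-linear
#' estimates, `sigma_study = 10 %` of the starting intercept and the stage-1
#' residual SD on the natural scale. Standard errors come from the inverse
#' numerical Hessian (central differences, relative step 1e-5) of the
#' negative marginal log-likelihood at the optimum, delta-method-transformed
#' to the natural `(a, b, c, d)` scale.
#'
#' With a single study the between-study SD is not identifiable and is fixed
#' at 0 with a warning. Non-convergence is reported in the result
#' (`converged = FALSE`), not raised as an error.
#'
#' @param ds A `respirometry` dataset.
#' @param start Starting `mo2_coefs`; default [fit_stage1_loglinear()]`(ds)`.
#' @param fix_sigma_study0 Fix the between-study SD at exactly 0 (plain
#'   maximum likelihood = nonlinear least squares for the fixed effects)?
#' @param multi_start Number of additional seeded random restarts (0 = the
#'   deterministic single start). Restarts jitter the starting values by
#'   10 % and keep the best optimum.
#' @param seed Seed for the multi-start jitter (ignored when
#'   `multi_start = 0`).
#' @return An object of class `mo2_fit`: a list with `coefficients`
#'   (`mo2_coefs`), `se` (natural scale), `vcov` (natural scale, 4 x 4),
#'   `vcov_opt` (on `(a, b, log c, log d)`), `sigma_study`, `sigma_resid`,
#'   `loglik`, `n_entries`, `n_studies`, `converged`, `n_iter`,
#'   `start_values`, and bookkeeping fields used by downstream operations.
#' @export
fit_stage2_nlme <- function(ds, start = NULL, fix_sigma_study0 = FALSE,
                            multi_start = 0, seed = 1) {
  stopifnot(inherits(ds, "respirometry"))
  if (is.null(start)) start <- fit_stage1_loglinear(ds)
  start <- as_mo2_coefs(start)
  stopifnot(all(is.finite(unclass(start))))
  df <- as.data.frame(ds)
  groups <- prepare_groups(ds)
  n_studies <- length(groups)
  notes <- character()
  if (n_studies < 2L && !fix_sigma_study0) {
    warning("single study: sigma_study is not identifiable and is fixed at 0")
    notes <- c(notes, "sigma_study fixed at 0 (single study)")
    fix_sigma_study0 <- TRUE
  }

  # Stage-1 residual SD on the natural (untransformed) scale.
  fitted1 <- predict_fixed(start, df$body_weight_kg, df$temperature_c,
                           df$rel_speed_bl_s)
  sr0 <- stats::sd(df$mo2_mg_kg_h - fitted1)
  if (!is.finite(sr0) || sr0 <= 0) sr0 <- 1e-6 * mean(df$mo2_mg_kg_h)

  run_once <- function(a0, b0, lc0, ld0) {
    fit_ml_engine(groups, a0, b0, lc0, ld0, g0 = NULL,
                  su0 = 0.1 * a0, sr0 = sr0, fix_su = fix_sigma_study0)
  }
  res <- run_once(start[["a"]], start[["b"]], log(start[["c"]]),
                  log(start[["d"]]))
  if (multi_start > 0) {
    with_local_seed(seed, {
      for (k in seq_len(multi_start)) {
        jit <- stats::rnorm(4, 1, 0.1)
        cand <- tryCatch(
          run_once(start[["a"]] * jit[1], start[["b"]] * jit[2],
                   log(start[["c"]]) * jit[3], log(start[["d"]]) * jit[4]),
          error = function(e) NULL)
        if (!is.null(cand) && cand$loglik > res$loglik) res <- cand
      }
    })
  }

  par <- res$par
  a <- par[["a"]]; b <- par[["b"]]
  cc <- exp(par[["lc"]]); d <- exp(par[["ld"]])
  sigma_study <- if (fix_sigma_study0) 0 else exp(par[["lsu"]])
  sigma_resid <- exp(par[["lsr"]])
  if ("lsu" %in% res$at_boundary) {
    sigma_study <- 0
    notes <- c(notes, "sigma_study at its lower floor (effectively 0)")
  }

  # vcov of the fixed-effect block (a, b, lc, ld) from the inverse Hessian
  # over the interior parameters.
  fixed_idx <- match(c("a", "b", "lc", "ld"), res$names[res$free])
  vcov_opt <- matrix(NA_real_, 4, 4,
                     dimnames = list(c("a", "b", "lc", "ld"),
                                     c("a", "b", "lc", "ld")))
  if (!is.null(res$vcov_free) && !anyNA(fixed_idx)) {
    vcov_opt[, ] <- res$vcov_free[fixed_idx, fixed_idx]
  }
  J <- diag(c(1, 1, cc, d))
  vcov_nat <- J %*% vcov_opt %*% J
  dimnames(vcov_nat) <- list(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  se <- sqrt(pmax(diag(vcov_nat), 0))
  names(se) <- c("a", "b", "c", "d")

  structure(list(
    coefficients = coefficient_set(a, b, cc, d),
    se = se, vcov = vcov_nat, vcov_opt = vcov_opt,
    se_opt = sqrt(pmax(diag(vcov_opt), 0)),
    sigma_study = sigma_study, sigma_resid = sigma_resid,
    loglik = res$loglik, n_entries = nrow(df), n_studies = n_studies,
    converged = res$converged, n_iter = res$n_iter,
    start_values = start, fix_sigma_study0 = fix_sigma_study0,
    notes = notes
  ), class = "mo2_fit")
}

#' @export
print.mo2_fit <- function(x, ...) {
  co <- unclass(x$coefficients)
  cat(sprintf("MO2 mixed-effects fit (%d entries, %d studies)%s\n",
              x$n_entries, x$n_studies,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (i in seq_along(co)) {
    cat(sprintf("  %s = %8.4f +/- %.4f\n", names(co)[i], co[i], x$se[i]))
  }
  cat(sprintf("  sigma_study = %.3f, sigma_resid = %.3f, logLik = %.3f\n",
              x$sigma_study, x$sigma_resid, x$loglik))
  invisible(x)
}

#' Wald confidence intervals for the model coefficients
#'
#' Intervals are formed as estimate +/- z(level) * SE on the optimization
#' scale -- plain for `a` and `b`, on the log scale (then exponentiated) for
#' `c` and `d` -- so intervals for the multipliers are positive by
#' construction and contain the point estimate.
#'
#' @param fit An `mo2_fit`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A data frame with columns `coefficient`, `estimate`, `lower`,
#'   `upper`.
#' @export
wald_confint <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mo2_fit"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("'level' must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  co <- unclass(fit$coefficients)
  se <- fit$se_opt
  est_opt <- c(co[["a"]], co[["b"]], log(co[["c"]]), log(co[["d"]]))
  lo <- est_opt - z * se
  hi <- est_opt + z * se
  lo[3:4] <- exp(lo[3:4]); hi[3:4] <- exp(hi[3:4])
  data.frame(coefficient = c("a", "b", "c", "d"),
             estimate = unname(co), lower = unname(lo), upper = unname(hi))
}
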