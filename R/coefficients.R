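#' Coefficient set for the multiplicative MO2 model
#'
#' Bundles the four coefficients of the fundamental oxygen-consumption model
#' \deqn{MO_2 = a \, W^b \, c^T \, d^U}
#' where `MO2` is mass-specific oxygen consumption (mg O2 kg^-1 h^-1),
#' `W` body weight (kg), `T` water temperature (deg C) and `U` relative
#' swimming speed (body lengths s^-1).
#'
#' @param a Intercept: MO2 at W = 1 kg, T = 0 deg C, U = 0 BL s^-1. Must be > 0.
#' @param b Body-weight exponent (dimensionless; negative for mass-specific
#'   rates, since smaller fish consume more oxygen per kg).
#' @param c Per-degree-Celsius multiplier (> 0).
#' @param d Per-BL-s^-1 multiplier (> 0).
#'
#' @return An object of class `mo2_coefs`: a named numeric vector
#'   `c(a =, b =, c =, d =)`.
#' @examples
#' coefficient_set(79.7, -0.14, 1.04, 1.63)
#' @export
coefficient_set <- function(a, b, c, d) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            length(a) == 1L, length(b) == 1L, length(c) == 1L, length(d) == 1L,
            is.finite(a), is.finite(b), is.finite(c), is.finite(d))
  if (a <= 0) stop("coefficient 'a' must be positive", call. = FALSE)
  if (c <= 0) stop("coefficient 'c' must be positive", call. = FALSE)
  if (d <= 0) stop("coefficient 'd' must be positive", call. = FALSE)
  structure(c(a = unname(a), b = unname(b), c = unname(c), d = unname(d)),
            class = "mo2_coefs")
}

#' @export
print.mo2_coefs <- function(x, digits = 4, ...) {
  cat("MO2 = a * W^b * c^T * d^U\n")
  print(round(unclass(x), digits))
  invisible(x)
}

as_mo2_coefs <- function(x) {
  if (inherits(x, "mo2_coefs")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    return(coefficient_set(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  if (is.list(x) && all(c("a", "b", "c", "d") %in% names(x))) {
    return(coefficient_set(x$a, x$b, x$c, x$d))
  }
  stop("cannot interpret 'x' as an MO2 coefficient set", call. = FALSE)
}

#' Revised and legacy coefficient sets
#'
#' `revised_coefficients()` returns the refined coefficient set estimated by
#' log-linear regression fitted via nonlinear mixed effects on compiled group
#' swim-tunnel respirometry data (a = 79.7, b = -0.14, c = 1.04, d = 1.63).
#' `legacy_coefficients()` returns the Grottum & Sigholt (1998) set
#' (a = 61.6, b = -0.33, c = 1.03, d = 1.79) that the refined fit supersedes.
#'
#' @return An `mo2_coefs` object.
#' @export
revised_coefficients <- function() coefficient_set(79.7, -0.14, 1.04, 1.63)

#' @rdname revised_coefficients
#' @export
legacy_coefficients <- function() coefficient_set(61.6, -0.33, 1.03, 1.79)

#' Fixed-effect MO2 prediction
#'
#' Evaluates the multiplicative model `a * W^b * c^T * d^U` at the population
#' level (no random study effect). Vectorised over `W`, `T`, `U`.
#'
#' @param coefs An `mo2_coefs` object (or coercible; see [coefficient_set()]).
#' @param W Body weight in kg; all values must be > 0.
#' @param T Water temperature in deg C.
#' @param U Relative swimming speed in body lengths s^-1.
#'
#' @return Numeric vector of MO2 predictions, mg O2 kg^-1 h^-1.
#' @examples
#' predict_fixed(revised_coefficients(), W = 1, T = 0, U = 0)   # the intercept
#' predict_fixed(revised_coefficients(), W = 0.5, T = 11, U = 1.6)
#' @export
predict_fixed <- function(coefs, W, T, U) {
  coefs <- as_mo2_coefs(coefs)
  stopifnot(is.numeric(W), is.numeric(T), is.numeric(U))
  if (any(!is.finite(W)) || any(W <= 0)) {
    stop("body weight 'W' must be positive and finite", call. = FALSE)
  }
  coefs[["a"]] * W^coefs[["b"]] * coefs[["c"]]^T * coefs[["d"]]^U
}

#' Q10 temperature coefficient
#'
#' The multiplicative change in metabolic rate for a 10 deg C temperature
#' increase implied by the per-degree multiplier `c`: `Q10 = c^10`.
#'
#' @param coefs An `mo2_coefs` object, or a single positive number taken as
#'   the per-degree multiplier `c` directly.
#' @return Dimensionless Q10.
#' @examples
#' q10(1.04)
#' q10(legacy_coefficients())
#' @export
q10 <- function(coefs) {
  cc <- if (is.numeric(coefs) && length(coefs) == 1L && !inherits(coefs, "mo2_coefs")) {
    coefs
  } else {
    as_mo2_coefs(coefs)[["c"]]
  }
  if (!is.finite(cc) || cc <= 0) stop("'c' must be positive", call. = FALSE)
  cc^10
}

#' Contrast two coefficient sets
#'
#' Summarises how a revised coefficient set reshapes the MO2 prediction curve
#' relative to an older one: the percentage rise of the whole curve (via the
#' intercept), the absolute change in the body-weight exponent, both Q10
#' values, the relative change in temperature sensitivity (the per-10-deg-C
#' percentage rise), and the percentage change in the swimming-speed
#' multiplier.
#'
#' The temperature-sensitivity contrast is
#' `100 * ((Q10_new - 1) - (Q10_old - 1)) / (Q10_old - 1)`,
#' i.e. the relative change of the percentage increase in MO2 over a 10 deg C
#' span. Explicit Q10 overrides may be supplied to contrast at printed
#' (rounded) Q10 values rather than ones recomputed from `c`.
#'
#' @param old,new `mo2_coefs` objects (or coercible).
#' @param q10_old,q10_new Optional Q10 overrides; default `q10(old)`, `q10(new)`.
#' @return A list of class `mo2_contrast` with elements
#'   `intercept_pct_change`, `b_abs_change`, `q10_old`, `q10_new`,
#'   `q10_sensitivity_pct`, `d_pct_change`.
#' @examples
#' coefficient_contrast(legacy_coefficients(), revised_coefficients())
#' @export
coefficient_contrast <- function(old, new, q10_old = NULL, q10_new = NULL) {
  old <- as_mo2_coefs(old)
  new <- as_mo2_coefs(new)
  qo <- if (is.null(q10_old)) q10(old) else q10_old
  qn <- if (is.null(q10_new)) q10(new) else q10_new
  out <- list(
    intercept_pct_change = 100 * (new[["a"]] / old[["a"]] - 1),
    b_abs_change         = new[["b"]] - old[["b"]],
    q10_old              = qo,
    q10_new              = qn,
    q10_sensitivity_pct  = 100 * ((qn - 1) - (qo - 1)) / (qo - 1),
    d_pct_change         = 100 * (new[["d"]] / old[["d"]] - 1)
  )
  stopifnot(all(vapply(out, is.finite, logical(1))))
  class(out) <- "mo2_contrast"
  out
}

#' @export
print.mo2_contrast <- function(x, ...) {
  cat(sprintf("Intercept: %+.1f%% | b: %+.3f | Q10: %.3f -> %.3f (%+.1f%% sensitivity) | d: %+.1f%%\n",
              x$intercept_pct_change, x$b_abs_change, x$q10_old, x$q10_new,
              x$q10_sensitivity_pct, x$d_pct_change))
  invisible(x)
}

#' Convert between absolute and relative swimming speed
#'
#' Relative speed is absolute speed normalised by fork length:
#' `U [BL s^-1] = speed [cm s^-1] / fork_length [cm]`.
#'
#' @param speed Swimming speed in cm s^-1.
#' @param fork_length Fork length in cm (> 0).
#' @return `convert_speed()`: relative speed in BL s^-1;
#'   `convert_speed_inverse()`: absolute speed in cm s^-1.
#' @examples
#' convert_speed(60, fork_length = 40)   # 1.5 BL/s
#' @export
convert_speed <- function(speed, fork_length) {
  stopifnot(is.numeric(speed), is.numeric(fork_length))
  if (any(!is.finite(fork_length)) || any(fork_length <= 0)) {
    stop("'fork_length' must be positive", call. = FALSE)
  }
  speed / fork_length
}

#' @rdname convert_speed
#' @param rel_speed Relative speed in BL s^-1.
#' @export
convert_speed_inverse <- function(rel_speed, fork_length) {
  stopifnot(is.numeric(rel_speed), is.numeric(fork_length))
  if (any(!is.finite(fork_length)) || any(fork_length <= 0)) {
    stop("'fork_length' must be positive", call. = FALSE)
  }
  rel_speed * fork_length
}
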