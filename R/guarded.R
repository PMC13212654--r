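# Extrapolation guardrails, per axis. "Core" is the coverage of the refined
# dataset; "ok" is the band where extrapolation is physiologically defensible;
# outside that, caution or refusal.
GUARD_CORE <- list(W = c(0.205, 3.38), T = c(3, 18), U = c(0.31, 2.84))
GUARD_OK_W <- c(0.1, 6)   # sea-transfer size to large-fish sites

#' Guardrailed MO2 prediction
#'
#' Computes the fixed-effect MO2 prediction and attaches per-axis
#' extrapolation flags encoding where the multiplicative model can be
#' trusted:
#' \itemize{
#'   \item `in_range`: within the refined dataset's coverage
#'     (W 0.205--3.38 kg, T 3--18 deg C, U 0.31--2.84 BL s^-1).
#'   \item `extrapolated_ok`: outside the core but physiologically
#'     defensible -- W in 0.1--6 kg (sea transfer to large-fish harvest),
#'     T in 0--3 deg C (MO2 scales smoothly to near-freezing), U in
#'     0--0.31 (exponential rise from rest is well supported).
#'   \item `extrapolated_caution`: W outside 0.1--6 kg; T in 18--23 deg C
#'     (predictions likely only minorly inflated as the thermal plateau is
#'     approached); U above 2.84 BL s^-1 (80--90 % of the critical swimming
#'     speed is the functional ceiling -- beyond it anaerobic recruitment
#'     plateaus MO2).
#' }
#' Requests are refused outright for T < 0 deg C (plasma freezing: salmon
#' cannot survive below 0) and T > 23 deg C (the recommended extrapolation
#' cap near the upper thermal tolerance). Supplying an oxygen saturation
#' below 100 % appends a qualitative `hypoxia_caution` flag (below the
#' limiting oxygen saturation the prediction is an overestimate; no LOS
#' arithmetic is attempted).
#'
#' @param W Body weight, kg (> 0).
#' @param T Water temperature, deg C (refused outside [0, 23]).
#' @param U Relative swimming speed, BL s^-1 (>= 0). Supply either `U` or
#'   both `speed_cm_s` and `fork_length_cm` (converted via
#'   [convert_speed()]), never both.
#' @param speed_cm_s Absolute swimming speed, cm s^-1.
#' @param fork_length_cm Fork length, cm.
#' @param do_saturation Optional dissolved-oxygen saturation, % of air
#'   saturation.
#' @param coefs Coefficient set; default [revised_coefficients()].
#' @return A list of class `mo2_prediction`: `mo2` (mg O2 kg^-1 h^-1),
#'   `mo2_absolute` (mg O2 h^-1, = `mo2 * W`), `flags` (named per-axis
#'   flags plus any `hypoxia_caution`), `messages` (per-flag explanations).
#' @export
predict_guarded <- function(W, T, U = NULL, speed_cm_s = NULL,
                            fork_length_cm = NULL, do_saturation = NULL,
                            coefs = revised_coefficients()) {
  if (is.null(U) == is.null(speed_cm_s)) {
    stop("supply exactly one of 'U' or ('speed_cm_s' + 'fork_length_cm')",
         call. = FALSE)
  }
  if (is.null(U)) {
    if (is.null(fork_length_cm)) {
      stop("'fork_length_cm' is required with 'speed_cm_s'", call. = FALSE)
    }
    U <- convert_speed(speed_cm_s, fork_length_cm)
  }
  stopifnot(length(W) == 1L, length(T) == 1L, length(U) == 1L)
  if (!is.finite(W) || W <= 0) stop("'W' must be positive", call. = FALSE)
  if (!is.finite(U) || U < 0) stop("'U' must be non-negative", call. = FALSE)
  if (!is.finite(T)) stop("'T' must be finite", call. = FALSE)
  if (T < 0) {
    stop("refusing to predict at T < 0 deg C: Atlantic salmon cannot ",
         "survive below 0 deg C (plasma freezing)", call. = FALSE)
  }
  if (T > 23) {
    stop("refusing to predict at T > 23 deg C: extrapolation is capped at ",
         "~23 deg C, near the upper thermal tolerance where metabolic rate ",
         "plateaus", call. = FALSE)
  }

  flags <- character()
  messages <- list()
  flag_axis <- function(axis, flag, msg = NULL) {
    flags[[axis]] <<- flag
    if (!is.null(msg)) messages[[paste0(axis, ":", flag)]] <<- msg
  }

  core <- GUARD_CORE
  if (W >= core$W[1] && W <= core$W[2]) flag_axis("W", "in_range")
  else if (W >= GUARD_OK_W[1] && W <= GUARD_OK_W[2]) {
    flag_axis("W", "extrapolated_ok",
              "outside the 0.205-3.38 kg core but within 0.1-6 kg, where allometric scaling extrapolates reliably")
  } else {
    flag_axis("W", "extrapolated_caution",
              "body weight outside 0.1-6 kg: beyond sea-transfer and large-harvest sizes")
  }

  if (T >= core$T[1] && T <= core$T[2]) flag_axis("T", "in_range")
  else if (T < core$T[1]) {
    flag_axis("T", "extrapolated_ok",
              "0-3 deg C: MO2 scales smoothly down to near-freezing in this cold-adapted species")
  } else {
    flag_axis("T", "extrapolated_caution",
              "18-23 deg C: predictions likely only minorly inflated as the thermal MO2 plateau is approached")
  }

  if (U >= core$U[1] && U <= core$U[2]) flag_axis("U", "in_range")
  else if (U < core$U[1]) {
    flag_axis("U", "extrapolated_ok",
              "below 0.31 BL/s: the exponential rise of MO2 from rest is well supported down to U = 0")
  } else {
    flag_axis("U", "extrapolated_caution",
              "above 2.84 BL/s: 80-90% of the critical swimming speed is the functional ceiling; anaerobic recruitment plateaus MO2 beyond it")
  }

  if (!is.null(do_saturation) && do_saturation < 100) {
    flags <- c(flags, hypoxia = "hypoxia_caution")
    messages[["hypoxia_caution"]] <-
      "oxygen saturation below 100%: below the limiting oxygen saturation the prediction overestimates MO2, and peak MO2 at high speeds is suppressed"
  }

  mo2 <- predict_fixed(coefs, W, T, U)
  structure(list(mo2 = mo2, mo2_absolute = mo2 * W, W = W, T = T, U = U,
                 flags = flags, messages = messages),
            class = "mo2_prediction")
}

#' @export
print.mo2_prediction <- function(x, ...) {
  cat(sprintf("MO2 = %.1f mg O2/kg/h (%.1f mg O2/h at W = %.3g kg)\n",
              x$mo2, x$mo2_absolute, x$W))
  cat("flags:", paste(sprintf("%s=%s", names(x$flags), x$flags),
                      collapse = ", "), "\n")
  for (m in x$messages) cat("  -", m, "\n")
  invisible(x)
}
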