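# Run code under a local, deterministic RNG state without disturbing the
# caller's stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fork length (cm) from body weight (kg) at Fulton condition factor K = 1.2
# (typical for farmed post-smolt Atlantic salmon): K = 100 * W_g / L_cm^3.
fork_length_from_weight <- function(weight_kg, K = 1.2) {
  (100 * weight_kg * 1000 / K)^(1 / 3)
}

#' Generating truth for the synthetic-data module
#'
#' The parameters of the data-generating process the estimation stage
#' assumes: the four mean-model coefficients, the between-study SD of the
#' additive random intercept deviation, the residual SD, and the residual
#' variance mode (`"constant"`, or `"proportional"` where the residual SD
#' scales with the conditional mean to mimic the mild heteroscedasticity seen
#' at high fitted values).
#'
#' Defaults are the refined coefficient set with `sigma_study = 8`
#' (about 10 % of the intercept) and `sigma_resid = 55` mg O2 kg^-1 h^-1,
#' which place a refit's residual scatter near that of the compiled dataset.
#'
#' @param a,b,c,d Generating coefficients (see [coefficient_set()]).
#' @param sigma_study SD of the between-study intercept deviation (same units
#'   as `a`); >= 0.
#' @param sigma_resid Residual SD, mg O2 kg^-1 h^-1; >= 0.
#' @param cv_mode `"constant"` or `"proportional"`.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(a = 79.7, b = -0.14, c = 1.04, d = 1.63,
                            sigma_study = 8, sigma_resid = 55,
                            cv_mode = c("constant", "proportional")) {
  cv_mode <- match.arg(cv_mode)
  coefs <- coefficient_set(a, b, c, d)
  stopifnot(sigma_study >= 0, sigma_resid >= 0)
  structure(list(coefficients = coefs, sigma_study = sigma_study,
                 sigma_resid = sigma_resid, cv_mode = cv_mode),
            class = "synthetic_truth")
}

# One block of a synthetic study: a set of (weight, temperature) treatment
# groups sharing a speed ladder. Repeated study_id values share one random
# study effect, which is how per-weight speed ladders within a study are
# expressed.
study_block <- function(study_id, weights, temperatures, speeds,
                        group_size, n_replicates,
                        ucrit_test = TRUE, plateau_only = FALSE) {
  stopifnot(all(weights > 0), length(speeds) >= 1,
            all(temperatures >= 0), all(temperatures <= 25))
  list(study_id = study_id, weights = weights, temperatures = temperatures,
       speeds = speeds, group_size = group_size, n_replicates = n_replicates,
       ucrit_test = ucrit_test, plateau_only = plateau_only)
}

#' Default synthetic configuration
#'
#' A seven-study layout emulating the structure of the compiled group
#' swim-tunnel respirometry dataset: coverage spanning 0.205--3.38 kg,
#' 3--18 deg C and 0.31--2.84 BL s^-1 across studies of unequal size, plus
#' (when `include_plateau_rows = TRUE`) the "raw" rows the model-assumption
#' filters exist to remove -- one whole treatment group held at 23 deg C and
#' one 100 %-of-U_crit top step per incremental swim-test group, 20 rows in
#' all, so the raw table has 96 entries and the refined one 76.
#'
#' Plateau-row MO2 is generated at 0.85 x the multiplicative-model
#' extrapolation, mimicking the metabolic plateau near the upper thermal
#' tolerance and near the critical swimming speed.
#'
#' @param seed Integer seed; fixed seed implies a fully reproducible dataset.
#' @param truth A [synthetic_truth()] object (the generating parameters).
#' @param include_plateau_rows Emit the 23-deg-C group and 100 %-U_crit rows?
#' @param n_planted_violations Number of extra entries appended with planted
#'   inclusion-criteria violations (cycling hypoxia, brackish water, short
#'   acclimation, poor health, unfed state).
#' @return A list of class `synthetic_config`.
#' @export
default_synth_config <- function(seed = 1, truth = synthetic_truth(),
                                 include_plateau_rows = TRUE,
                                 n_planted_violations = 0) {
  studies <- list(
    study_block("hvas_folkedal_2017", 0.45, c(3, 8, 13, 18),
                seq(0.40, 2.66, length.out = 5), 10, 3),
    study_block("hvas_folkedal_2017", 0.45, 23,
                seq(0.40, 2.60, length.out = 9), 10, 3,
                ucrit_test = FALSE, plateau_only = TRUE),
    study_block("oldham_2019", 0.205, 16, seq(0.60, 2.70, length.out = 6), 28, 2),
    study_block("oldham_2019", 0.949, 16, seq(0.45, 2.30, length.out = 6), 29, 2),
    study_block("oldham_2019", 3.38, 16, seq(0.31, 1.40, length.out = 6), 7, 2),
    study_block("hvas_2022", 0.477, 18, seq(0.89, 2.69, length.out = 11), 8, 2,
                ucrit_test = FALSE),
    study_block("hvas_karlsbakk_2017", 0.347, 13,
                seq(0.63, 2.84, length.out = 9), 15, 2),
    study_block("hvas_oppedal_2017", 0.821, 13,
                seq(0.46, 1.87, length.out = 6), 8, 3),
    study_block("hvas_2018", 0.403, 13, seq(0.44, 2.70, length.out = 7), 10, 2),
    study_block("hvas_2021", 0.667, 12, seq(0.78, 2.35, length.out = 5), 10, 3)
  )
  new_synth_config(studies, truth, include_plateau_rows,
                   n_planted_violations, seed)
}

new_synth_config <- function(studies, truth, include_plateau_rows,
                             n_planted_violations, seed) {
  stopifnot(length(studies) >= 1, inherits(truth, "synthetic_truth"),
            is.logical(include_plateau_rows), n_planted_violations >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(studies = studies, truth = truth,
                 include_plateau_rows = isTRUE(include_plateau_rows),
                 n_planted_violations = as.integer(n_planted_violations),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Draw one residual, redrawing until the observation is positive
# (truncation-by-redraw preserves positivity with negligible bias at the
# default noise levels).
draw_positive <- function(mean, sdev) {
  if (sdev == 0) return(mean)
  repeat {
    y <- mean + stats::rnorm(1, 0, sdev)
    if (y > 0) return(y)
  }
}

#' Generate a synthetic respirometry dataset
#'
#' Simulates the data-generating process the estimation stage assumes: per
#' study `i` a single intercept deviation `u_i ~ N(0, sigma_study^2)`, and
#' per entry
#' `mo2 = (a + u_i) * W^b * c^T * d^U + eps`,
#' `eps ~ N(0, s^2)` with `s = sigma_resid` (constant mode) or
#' `s = sigma_resid * mean / a` (proportional mode); negative draws are
#' redrawn. Plateau rows (the 23-deg-C group and the 100 %-U_crit steps) are
#' generated at 0.85 x the model extrapolation. All metadata fields are set
#' to inclusion-passing values except in planted-violation rows.
#'
#' @param config A `synthetic_config`, e.g. from [default_synth_config()].
#' @return A list with elements `dataset` (a `respirometry` dataset with
#'   provenance `"synthetic(seed=<seed>)"`) and `truth` (the generating
#'   [synthetic_truth()], augmented with the drawn per-study deviations `u`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- config$truth
  co <- truth$coefficients
  a <- co[["a"]]; b <- co[["b"]]; cc <- co[["c"]]; d <- co[["d"]]

  study_ids <- unique(vapply(config$studies, `[[`, "", "study_id"))
  rows <- list()
  with_local_seed(config$seed, {
    u <- stats::setNames(stats::rnorm(length(study_ids), 0, truth$sigma_study),
                         study_ids)
    for (blk in config$studies) {
      if (blk$plateau_only && !config$include_plateau_rows) next
      ui <- u[[blk$study_id]]
      for (w in blk$weights) {
        for (tt in blk$temperatures) {
          treatment <- sprintf("W%.3f_T%g", w, tt)
          speeds <- round(blk$speeds, 3)
          pct <- round(85 * speeds / max(speeds), 1)
          if (!blk$ucrit_test) pct <- rep(NA_real_, length(speeds))
          if (config$include_plateau_rows && blk$ucrit_test) {
            speeds <- c(speeds, round(max(blk$speeds) / 0.85, 3))
            pct <- c(pct, 100)
          }
          plateau <- blk$plateau_only | (!is.na(pct) & pct >= 100)
          for (k in seq_along(speeds)) {
            mu <- (a + ui) * w^b * cc^tt * d^speeds[k]
            if (plateau[k]) mu <- 0.85 * mu
            sdev <- if (truth$cv_mode == "proportional")
              truth$sigma_resid * mu / a else truth$sigma_resid
            rows[[length(rows) + 1L]] <- data.frame(
              study_id = blk$study_id, treatment_id = treatment,
              body_weight_kg = w,
              fork_length_cm = round(fork_length_from_weight(w), 1),
              temperature_c = tt, rel_speed_bl_s = speeds[k],
              pct_ucrit = pct[k], mo2_mg_kg_h = draw_positive(mu, sdev),
              group_size = blk$group_size, n_replicates = blk$n_replicates,
              salinity_regime = "seawater_full", oxygen_regime = "normoxia",
              acclimation_weeks = 6, health_status = "healthy",
              fed_state = "fed_then_overnight_fast", strain = "aquagen",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (config$n_planted_violations > 0) {
      viol <- list(
        list(oxygen_regime = "hypoxia"),
        list(salinity_regime = "brackish"),
        list(acclimation_weeks = 1),
        list(health_status = "other"),
        list(fed_state = "fasted_48h")
      )
      base <- config$studies[[1]]
      ui <- u[[base$study_id]]
      for (k in seq_len(config$n_planted_violations)) {
        w <- base$weights[1]; tt <- base$temperatures[1]
        sp <- 0.05 * k   # off-ladder speeds keep entry keys unique
        mu <- (a + ui) * w^b * cc^tt * d^sp
        row <- data.frame(
          study_id = base$study_id,
          treatment_id = sprintf("violation_%02d", k),
          body_weight_kg = w,
          fork_length_cm = round(fork_length_from_weight(w), 1),
          temperature_c = tt, rel_speed_bl_s = sp, pct_ucrit = NA_real_,
          mo2_mg_kg_h = draw_positive(mu, truth$sigma_resid),
          group_size = base$group_size, n_replicates = base$n_replicates,
          salinity_regime = "seawater_full", oxygen_regime = "normoxia",
          acclimation_weeks = 6, health_status = "healthy",
          fed_state = "fed_then_overnight_fast", strain = "aquagen",
          stringsAsFactors = FALSE)
        patch <- viol[[((k - 1L) %% length(viol)) + 1L]]
        row[names(patch)] <- patch
        rows[[length(rows) + 1L]] <- row
      }
    }
  })
  df <- do.call(rbind, rows)
  truth$u <- u
  ds <- respirometry_dataset(df, provenance = sprintf("synthetic(seed=%d)",
                                                      config$seed))
  list(dataset = ds, truth = truth)
}

#' Read or write a synthetic configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_synth_config()`: a `synthetic_config`;
#'   `write_synth_config()`: `path`, invisibly.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  truth <- do.call(synthetic_truth, y$truth)
  studies <- lapply(y$studies, function(s) do.call(study_block, s))
  new_synth_config(studies, truth, y$include_plateau_rows,
                   y$n_planted_violations, y$seed)
}

#' @rdname read_synth_config
#' @param config A `synthetic_config`.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  co <- config$truth$coefficients
  y <- list(
    seed = config$seed,
    include_plateau_rows = config$include_plateau_rows,
    n_planted_violations = config$n_planted_violations,
    truth = list(a = co[["a"]], b = co[["b"]], c = co[["c"]], d = co[["d"]],
                 sigma_study = config$truth$sigma_study,
                 sigma_resid = config$truth$sigma_resid,
                 cv_mode = config$truth$cv_mode),
    studies = lapply(config$studies, function(s) s[names(s)])
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write the generating-truth record as a JSON sidecar
#'
#' @param truth A `synthetic_truth` (possibly with drawn study deviations).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  co <- truth$coefficients
  obj <- list(a = co[["a"]], b = co[["b"]], c = co[["c"]], d = co[["d"]],
              sigma_study = truth$sigma_study, sigma_resid = truth$sigma_resid,
              cv_mode = truth$cv_mode)
  if (!is.null(truth$u)) obj$u <- as.list(truth$u)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
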