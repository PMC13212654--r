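# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except what a test itself writes to a tempdir.

# A canonical, inclusion-passing entry table. Any column can be overridden;
# scalar overrides are recycled.
toy_entries <- function(n = 3, ...) {
  df <- data.frame(
    study_id = "study_a",
    treatment_id = paste0("grp", seq_len(n)),
    body_weight_kg = 0.5,
    fork_length_cm = 35,
    temperature_c = 10,
    rel_speed_bl_s = seq(0.5, by = 0.3, length.out = n),
    pct_ucrit = NA_real_,
    mo2_mg_kg_h = 200 + 10 * seq_len(n),
    group_size = 8,
    n_replicates = 2,
    salinity_regime = "seawater_full",
    oxygen_regime = "normoxia",
    acclimation_weeks = 4,
    health_status = "healthy",
    fed_state = "fed_then_overnight_fast",
    strain = "aquagen",
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

toy_dataset <- function(n = 3, ...) {
  respirometry_dataset(toy_entries(n, ...), provenance = "fixture")
}

# Inclusion + model-assumption filters in sequence, returning the refined set.
refine <- function(ds) {
  apply_model_assumption_filters(apply_inclusion_criteria(ds)$dataset)$dataset
}

# Default-structure dataset with a multiplicative T*U interaction planted in
# the mean surface (constant residual noise added on top), for screening
# power checks. g = 0.06 puts the fitted interaction near 10 standard errors.
planted_tu_dataset <- function(seed, g = 0.06, sigma_resid = 55) {
  cfg <- default_synth_config(seed = seed,
                              truth = synthetic_truth(sigma_resid = 0))
  d <- refine(generate_dataset(cfg)$dataset)
  df <- as.data.frame(d)
  mu <- df$mo2_mg_kg_h * exp(g * df$temperature_c * df$rel_speed_bl_s)
  withr::with_seed(seed + 10000L, {
    df$mo2_mg_kg_h <- pmax(mu + stats::rnorm(nrow(df), 0, sigma_resid), 1)
  })
  respirometry_dataset(df, provenance = sprintf("planted_tu(seed=%d)", seed))
}

truth_vector <- function() c(a = 79.7, b = -0.14, c = 1.04, d = 1.63)
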