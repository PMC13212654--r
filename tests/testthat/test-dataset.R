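test_that("CSV round trip preserves entries and validates on read", {
  ds <- toy_dataset(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_s3_class(back, "respirometry")
  expect_equal(nrow(back), 3)
  expect_identical(attr(back, "provenance"), path)
  expect_equal(as.data.frame(back), as.data.frame(ds), ignore_attr = TRUE)
  # missing pct_ucrit survives as NA through the round trip
  expect_true(all(is.na(back$pct_ucrit)))
})

test_that("malformed CSVs fail with informative errors", {
  df <- toy_entries(3)
  path <- withr::local_tempfile(fileext = ".csv")

  write.csv(df[setdiff(names(df), "mo2_mg_kg_h")], path, row.names = FALSE)
  expect_error(read_dataset(path), "missing required column.*mo2_mg_kg_h")

  df_bad <- df
  df_bad$mo2_mg_kg_h <- as.character(df_bad$mo2_mg_kg_h)
  df_bad$mo2_mg_kg_h[2] <- "NA"
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_dataset(path), "mo2_mg_kg_h.*row\\(s\\): 2")

  expect_error(read_dataset(file.path(tempdir(), "no-such.csv")), "not found")
})

test_that("entry invariants are enforced on construction", {
  expect_error(respirometry_dataset(toy_entries(2, body_weight_kg = -1)),
               "invariants")
  expect_error(respirometry_dataset(toy_entries(2, temperature_c = 45)),
               "invariants")
  expect_error(respirometry_dataset(toy_entries(2, pct_ucrit = 120)),
               "invariants")
  df <- toy_entries(2)
  df$rel_speed_bl_s <- c(1, 1)  # duplicate key
  df$treatment_id <- "same"
  expect_error(respirometry_dataset(df), "duplicate")
})

test_that("replicate aggregation averages trials per unique key", {
  trials <- rbind(toy_entries(1, mo2_mg_kg_h = 200),
                  toy_entries(1, mo2_mg_kg_h = 220))
  trials$n_replicates <- NULL
  agg <- aggregate_replicates(trials)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$mo2_mg_kg_h, 210)
  expect_equal(agg$n_replicates, 2)

  single <- toy_entries(1, mo2_mg_kg_h = 187.5)
  single$n_replicates <- NULL
  agg1 <- aggregate_replicates(single)
  expect_equal(agg1$mo2_mg_kg_h, 187.5)
  expect_equal(agg1$n_replicates, 1)
})

test_that("aggregation matches a brute-force group-and-average oracle", {
  reps <- c(2, 3, 2)
  withr::with_seed(42, {
    rows <- lapply(seq_along(reps), function(k) {
      tr <- toy_entries(1, treatment_id = paste0("key", k),
                        rel_speed_bl_s = 0.5 + 0.4 * k)
      tr <- tr[rep(1, reps[k]), ]
      tr$mo2_mg_kg_h <- stats::runif(reps[k], 150, 400)
      tr$body_weight_kg <- stats::runif(reps[k], 0.4, 0.6)
      tr$fork_length_cm <- stats::runif(reps[k], 32, 38)
      tr
    })
  })
  trials <- do.call(rbind, rows)
  trials$n_replicates <- NULL
  agg <- aggregate_replicates(trials)
  # oracle: independent split + colMeans
  key <- paste(trials$treatment_id)
  for (k in unique(key)) {
    g <- trials[key == k, ]
    i <- which(agg$treatment_id == k)
    expect_equal(agg$mo2_mg_kg_h[i], mean(g$mo2_mg_kg_h))
    expect_equal(agg$body_weight_kg[i], mean(g$body_weight_kg))
    expect_equal(agg$fork_length_cm[i], mean(g$fork_length_cm))
  }
  # total replicate count is preserved
  expect_equal(sum(agg$n_replicates), nrow(trials))
  # inconsistent categorical metadata within a key is an error
  bad <- trials
  bad$health_status[1] <- "other"
  expect_error(aggregate_replicates(bad), "inconsistent 'health_status'")
})

test_that("inclusion criteria remove exactly the planted violations", {
  ok <- toy_entries(6)
  v1 <- toy_entries(1, treatment_id = "v1", oxygen_regime = "hypoxia",
                    rel_speed_bl_s = 3)
  v2 <- toy_entries(1, treatment_id = "v2", salinity_regime = "brackish",
                    rel_speed_bl_s = 3.1)
  v3 <- toy_entries(1, treatment_id = "v3", acclimation_weeks = 1,
                    rel_speed_bl_s = 3.2)
  v4 <- toy_entries(1, treatment_id = "v4", health_status = "other",
                    rel_speed_bl_s = 3.3)
  ds <- respirometry_dataset(rbind(ok, v1, v2, v3, v4))
  res <- apply_inclusion_criteria(ds)
  expect_equal(res$report$n_in, 10)
  expect_equal(res$report$n_out, 6)
  expect_equal(nrow(res$dataset), 6)
  expect_setequal(res$report$removed$rule,
                  c("normoxia", "seawater_full", "acclimation", "healthy"))
  expect_equal(res$report$n_out,
               res$report$n_in - nrow(res$report$removed))
  # a compliant dataset passes through untouched
  res0 <- apply_inclusion_criteria(toy_dataset(5))
  expect_equal(nrow(res0$report$removed), 0)
  expect_equal(as.data.frame(res0$dataset), as.data.frame(toy_dataset(5)))
})

test_that("model-assumption filters cut the thermal and U_crit plateaus", {
  hot <- toy_entries(1, treatment_id = "hot", temperature_c = 23)
  top <- toy_entries(1, treatment_id = "top", pct_ucrit = 100,
                     rel_speed_bl_s = 3)
  keep <- toy_entries(3, pct_ucrit = c(40, 65, 88))
  ds <- respirometry_dataset(rbind(keep, hot, top))
  res <- apply_model_assumption_filters(ds)
  expect_equal(nrow(res$dataset), 3)
  removed <- res$report$removed
  expect_equal(removed$rule[grepl("hot", removed$entry)], "temp_cutoff")
  expect_equal(removed$rule[grepl("top", removed$entry)], "ucrit_cutoff")
  expect_true(max(res$dataset$pct_ucrit, na.rm = TRUE) <= 90)
  # entries with missing pct_ucrit are retained by the U_crit rule
  expect_true(all(!is.na(res$dataset$pct_ucrit)))
  ds_na <- toy_dataset(3)  # all pct_ucrit NA
  expect_equal(nrow(apply_model_assumption_filters(ds_na)$dataset), 3)
  # no-op on a clean set
  res0 <- apply_model_assumption_filters(toy_dataset(4, temperature_c = 18))
  expect_equal(nrow(res0$report$removed), 0)
})

test_that("filters are idempotent and order-independent", {
  gen <- generate_dataset(default_synth_config(seed = 11,
                                               n_planted_violations = 3))
  ds <- gen$dataset
  a1 <- apply_model_assumption_filters(ds)$dataset
  a2 <- apply_model_assumption_filters(a1)$dataset
  expect_equal(as.data.frame(a1), as.data.frame(a2))
  i1 <- apply_inclusion_criteria(ds)$dataset
  i2 <- apply_inclusion_criteria(i1)$dataset
  expect_equal(as.data.frame(i1), as.data.frame(i2))
  # composition order does not change the surviving set
  ab <- apply_model_assumption_filters(apply_inclusion_criteria(ds)$dataset)$dataset
  ba <- apply_inclusion_criteria(apply_model_assumption_filters(ds)$dataset)$dataset
  expect_equal(as.data.frame(ab), as.data.frame(ba))
})

test_that("summaries match a brute-force scan", {
  ds <- refine(generate_dataset(default_synth_config(seed = 7))$dataset)
  s <- summarize_dataset(ds)
  df <- as.data.frame(ds)
  for (v in c("body_weight_kg", "temperature_c", "rel_speed_bl_s",
              "mo2_mg_kg_h")) {
    expect_equal(s$ranges$min[s$ranges$variable == v], min(df[[v]]))
    expect_equal(s$ranges$max[s$ranges$variable == v], max(df[[v]]))
  }
  expect_equal(sum(s$studies$pct), 100, tolerance = 1e-9)
  expect_equal(sum(s$studies$n_entries), nrow(df))
  # degenerate single-entry dataset
  s1 <- summarize_dataset(toy_dataset(1))
  expect_equal(s1$ranges$min, s1$ranges$max)
  expect_error(summarize_dataset(respirometry_dataset(toy_entries(1)[0, ])),
               "empty")
})

test_that("filter reports serialise to JSON", {
  res <- apply_inclusion_criteria(toy_dataset(4, oxygen_regime =
                                                c("normoxia", "hypoxia",
                                                  "normoxia", "normoxia")))
  js <- jsonlite::fromJSON(filter_report_json(res$report))
  expect_equal(js$n_in, 4)
  expect_equal(js$n_out, 3)
  expect_equal(js$removed$rule, "normoxia")
})
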