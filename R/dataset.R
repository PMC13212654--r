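#' @importFrom stats aggregate complete.cases lm coef pchisq qnorm quantile
#'   rnorm sd setNames vcov median optim
#' @importFrom utils read.csv write.csv head
NULL

# Canonical column order of the respirometry table. One row = one
# replicate-aggregated entry: a unique (study, treatment, body weight,
# temperature, relative speed) combination.
RESPIRO_COLUMNS <- c(
  "study_id", "treatment_id", "body_weight_kg", "fork_length_cm",
  "temperature_c", "rel_speed_bl_s", "pct_ucrit", "mo2_mg_kg_h",
  "group_size", "n_replicates", "salinity_regime", "oxygen_regime",
  "acclimation_weeks", "health_status", "fed_state", "strain"
)

RESPIRO_NUMERIC <- c(
  "body_weight_kg", "fork_length_cm", "temperature_c", "rel_speed_bl_s",
  "pct_ucrit", "mo2_mg_kg_h", "group_size", "n_replicates",
  "acclimation_weeks"
)

# pct_ucrit is the only numeric column where a missing value is meaningful
# (sustained-speed tests have no critical-speed fraction).
RESPIRO_OPTIONAL <- "pct_ucrit"

entry_key <- function(df) {
  paste(df$study_id, df$treatment_id, df$body_weight_kg,
        df$temperature_c, df$rel_speed_bl_s, sep = "/")
}

#' Construct a respirometry dataset
#'
#' Validates a data frame of replicate-aggregated group swim-tunnel
#' respirometry entries against the package's schema and entry invariants:
#' positive weights, lengths and MO2; temperatures within a sanity band of
#' [-2, 40] deg C; non-negative relative speed; `pct_ucrit` (when present) in
#' (0, 100]; counts at least 1; unique
#' (study, treatment, weight, temperature, speed) combinations.
#'
#' @param df Data frame with the canonical columns (see Details).
#' @param provenance Character tag recording where the data came from
#'   (a file path, or e.g. `"synthetic(seed=1)"`).
#'
#' @details Canonical columns: `study_id`, `treatment_id`, `body_weight_kg`,
#' `fork_length_cm`, `temperature_c`, `rel_speed_bl_s`, `pct_ucrit`,
#' `mo2_mg_kg_h`, `group_size`, `n_replicates`, `salinity_regime`,
#' `oxygen_regime`, `acclimation_weeks`, `health_status`, `fed_state`,
#' `strain`. Missing `pct_ucrit` is allowed; all other numeric fields are
#' required.
#'
#' @return A data frame of class `respirometry` with attribute `provenance`.
#' @export
respirometry_dataset <- function(df, provenance = "in-memory") {
  missing_cols <- setdiff(RESPIRO_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[RESPIRO_COLUMNS]
  for (col in RESPIRO_NUMERIC) df[[col]] <- as.numeric(df[[col]])
  bad <- validate_entries(df)
  if (length(bad)) {
    stop("entries violate invariants at row(s): ",
         paste(names(bad), vapply(bad, `[`, "", 1L), sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  dup <- duplicated(entry_key(df))
  if (any(dup)) {
    stop("duplicate (study, treatment, weight, temperature, speed) ",
         "combination(s) at row(s): ", paste(which(dup), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("respirometry", "data.frame"))
}

# Returns a named list: row number -> character vector of violated invariants.
validate_entries <- function(df) {
  out <- list()
  for (i in seq_len(nrow(df))) {
    v <- character()
    row <- df[i, ]
    req <- setdiff(RESPIRO_NUMERIC, RESPIRO_OPTIONAL)
    if (anyNA(row[req])) v <- c(v, "missing required numeric value")
    else {
      if (row$body_weight_kg <= 0) v <- c(v, "body_weight_kg <= 0")
      if (row$fork_length_cm <= 0) v <- c(v, "fork_length_cm <= 0")
      if (row$temperature_c < -2 || row$temperature_c > 40)
        v <- c(v, "temperature_c outside [-2, 40]")
      if (row$rel_speed_bl_s < 0) v <- c(v, "rel_speed_bl_s < 0")
      if (row$mo2_mg_kg_h <= 0) v <- c(v, "mo2_mg_kg_h <= 0")
      if (row$group_size < 1) v <- c(v, "group_size < 1")
      if (row$n_replicates < 1) v <- c(v, "n_replicates < 1")
    }
    if (!is.na(row$pct_ucrit) && (row$pct_ucrit <= 0 || row$pct_ucrit > 100))
      v <- c(v, "pct_ucrit outside (0, 100]")
    if (length(v)) out[[as.character(i)]] <- v
  }
  out
}

#' Read a respirometry dataset from CSV
#'
#' Reads the canonical comma-separated table (UTF-8, period decimals, one
#' header row, missing values as empty fields) and validates it. Non-numeric
#' text (including the literal string `"NA"`) in a required numeric column is
#' a parse error naming the offending row; only `pct_ucrit` may be empty.
#'
#' @param path Path to a CSV file with the canonical columns.
#' @param format File format; only `"csv"` is supported.
#' @return A `respirometry` dataset with `provenance = path`.
#' @seealso [write_dataset()], [respirometry_dataset()]
#' @export
read_dataset <- function(path, format = "csv") {
  format <- match.arg(format, "csv")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         na.strings = character(0), fileEncoding = "UTF-8")
  missing_cols <- setdiff(RESPIRO_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[RESPIRO_COLUMNS]
  for (col in RESPIRO_NUMERIC) {
    txt <- trimws(raw[[col]])
    # the optional column accepts an explicit NA marker as missing;
    # required numerics do not
    empty <- txt == "" | (col %in% RESPIRO_OPTIONAL & txt == "NA")
    num <- suppressWarnings(as.numeric(txt))
    bad <- !empty & is.na(num)
    if (any(bad)) {
      stop("parse error: non-numeric value in column '", col,
           "' at row(s): ", paste(which(bad), collapse = ", "), call. = FALSE)
    }
    if (col %in% RESPIRO_OPTIONAL) {
      num[empty] <- NA_real_
    } else if (any(empty)) {
      stop("parse error: missing value in required column '", col,
           "' at row(s): ", paste(which(empty), collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- num
  }
  respirometry_dataset(raw, provenance = path)
}

#' Write a respirometry dataset to CSV
#'
#' Writes the canonical CSV representation (missing values as empty fields),
#' so that `read_dataset(write_dataset(ds, path))` round-trips the entries.
#'
#' @param ds A `respirometry` dataset.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "respirometry"))
  utils::write.csv(as.data.frame(ds)[RESPIRO_COLUMNS], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate replicate trials into dataset entries
#'
#' Collapses per-trial records to one entry per unique
#' (study, treatment, temperature, relative speed) combination. MO2, body
#' weight and fork length are unweighted means over the affiliated replicate
#' trials; `n_replicates` records how many trials were aggregated. Categorical
#' metadata must be constant within a combination.
#'
#' @param trials Data frame of per-trial records carrying the canonical
#'   columns except `n_replicates` (each row is one trial).
#' @param provenance Provenance tag for the resulting dataset.
#' @return A `respirometry` dataset.
#' @export
aggregate_replicates <- function(trials, provenance = "aggregated") {
  need <- setdiff(RESPIRO_COLUMNS, "n_replicates")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0L) {
    empty <- trials[0, need]
    empty$n_replicates <- numeric(0)
    return(respirometry_dataset(empty[RESPIRO_COLUMNS], provenance))
  }
  key <- paste(trials$study_id, trials$treatment_id, trials$temperature_c,
               trials$rel_speed_bl_s, sep = "/")
  const_cols <- c("group_size", "salinity_regime", "oxygen_regime",
                  "acclimation_weeks", "health_status", "fed_state", "strain")
  pieces <- lapply(split(trials, factor(key, levels = unique(key))), function(g) {
    for (col in const_cols) {
      if (length(unique(g[[col]])) > 1L) {
        stop("inconsistent '", col, "' within aggregation key ",
             paste(g$study_id[1], g$treatment_id[1], g$temperature_c[1],
                   g$rel_speed_bl_s[1], sep = "/"), call. = FALSE)
      }
    }
    out <- g[1, need]
    out$body_weight_kg <- mean(g$body_weight_kg)
    out$fork_length_cm <- mean(g$fork_length_cm)
    out$mo2_mg_kg_h <- mean(g$mo2_mg_kg_h)
    out$pct_ucrit <- if (anyNA(g$pct_ucrit)) NA_real_ else mean(g$pct_ucrit)
    out$n_replicates <- nrow(g)
    out
  })
  agg <- do.call(rbind, pieces)
  respirometry_dataset(agg[RESPIRO_COLUMNS], provenance)
}

new_filter_report <- function(n_in, removed_df, rules) {
  structure(
    list(n_in = n_in, n_out = n_in - nrow(removed_df),
         removed = removed_df, rules_applied = rules),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d in, %d out (%d removed)\n",
              x$n_in, x$n_out, nrow(x$removed)))
  if (nrow(x$removed)) print(table(x$removed$rule))
  invisible(x)
}

#' Serialise a filter report to JSON
#'
#' @param report A `filter_report`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when `path` is given).
#' @export
filter_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  obj <- list(n_in = report$n_in, n_out = report$n_out,
              rules_applied = report$rules_applied,
              removed = report$removed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

run_filter <- function(ds, rules) {
  # rules: named list of predicate functions returning TRUE when the entry
  # VIOLATES the rule; the first violated rule names the removal.
  stopifnot(inherits(ds, "respirometry"))
  df <- as.data.frame(ds)
  hit <- rep(NA_character_, nrow(df))
  for (rule in names(rules)) {
    viol <- rules[[rule]](df)
    viol[is.na(viol)] <- FALSE
    hit[is.na(hit) & viol] <- rule
  }
  keep <- is.na(hit)
  removed <- data.frame(entry = entry_key(df)[!keep], rule = hit[!keep],
                        stringsAsFactors = FALSE)
  kept <- respirometry_dataset(df[keep, , drop = FALSE],
                               provenance = attr(ds, "provenance"))
  list(dataset = kept, report = new_filter_report(nrow(df), removed, names(rules)))
}

#' Apply the environmental/husbandry inclusion criteria
#'
#' Retains only entries measured under conditions comparable across the
#' compiled experiments: full-strength seawater, normoxia, at least
#' `min_acclimation_weeks` weeks at the target temperature, healthy fish, and
#' a fed state with only an overnight fast before the swim trial. Each removed
#' entry is attributed to the first rule it violates.
#'
#' @param ds A `respirometry` dataset.
#' @param min_acclimation_weeks Minimum thermal acclimation, weeks (default 3).
#' @return A list with elements `dataset` (the retained entries) and
#'   `report` (a `filter_report`).
#' @export
apply_inclusion_criteria <- function(ds, min_acclimation_weeks = 3) {
  rules <- list(
    seawater_full = function(df) df$salinity_regime != "seawater_full",
    normoxia      = function(df) df$oxygen_regime != "normoxia",
    acclimation   = function(df) df$acclimation_weeks < min_acclimation_weeks,
    healthy       = function(df) df$health_status != "healthy",
    fed_state     = function(df) df$fed_state != "fed_then_overnight_fast"
  )
  run_filter(ds, rules)
}

#' Apply the model-assumption filters
#'
#' Removes entries that violate the exponential-mean assumptions of the
#' multiplicative model: groups at or above the high-temperature cutoff
#' (default 23 deg C, where metabolic rate plateaus near the upper thermal
#' tolerance) and speeds at or above the critical-swimming-speed cutoff
#' (default 100 % U_crit, where anaerobic recruitment plateaus MO2). Entries
#' with no recorded `pct_ucrit` (sustained-speed tests) are never removed by
#' the speed rule.
#'
#' @param ds A `respirometry` dataset.
#' @param temp_cutoff Temperature cutoff in deg C; entries with
#'   `temperature_c >= temp_cutoff` are removed (default 23).
#' @param ucrit_cutoff Percent of critical swimming speed; entries with
#'   `pct_ucrit >= ucrit_cutoff` are removed (default 100).
#' @return A list with elements `dataset` and `report` (see
#'   [apply_inclusion_criteria()]).
#' @export
apply_model_assumption_filters <- function(ds, temp_cutoff = 23,
                                           ucrit_cutoff = 100) {
  rules <- list(
    temp_cutoff  = function(df) df$temperature_c >= temp_cutoff,
    ucrit_cutoff = function(df) !is.na(df$pct_ucrit) & df$pct_ucrit >= ucrit_cutoff
  )
  run_filter(ds, rules)
}

#' Summarise a respirometry dataset
#'
#' Ranges of the primary parameters and MO2, per-study entry counts and
#' percentage contributions, and the total number of fish analysed (summed
#' over unique treatment groups as `group_size * n_replicates`).
#'
#' @param ds A non-empty `respirometry` dataset.
#' @return A list of class `mo2_summary` with elements `ranges` (data frame
#'   with min/max for `body_weight_kg`, `temperature_c`, `rel_speed_bl_s`,
#'   `mo2_mg_kg_h`), `studies` (data frame of per-study `n_entries` and
#'   `pct`), `n_entries`, and `total_fish`.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "respirometry"))
  if (nrow(ds) == 0L) stop("cannot summarise an empty dataset", call. = FALSE)
  df <- as.data.frame(ds)
  vars <- c("body_weight_kg", "temperature_c", "rel_speed_bl_s", "mo2_mg_kg_h")
  ranges <- data.frame(
    variable = vars,
    min = vapply(df[vars], min, 0),
    max = vapply(df[vars], max, 0),
    row.names = NULL
  )
  tab <- table(df$study_id)
  studies <- data.frame(study_id = names(tab),
                        n_entries = as.integer(tab),
                        pct = 100 * as.integer(tab) / nrow(df),
                        row.names = NULL)
  studies <- studies[order(-studies$n_entries), ]
  grp <- df[!duplicated(paste(df$study_id, df$treatment_id, sep = "/")), ]
  structure(list(ranges = ranges, studies = studies, n_entries = nrow(df),
                 total_fish = sum(grp$group_size * grp$n_replicates)),
            class = "mo2_summary")
}

#' @export
print.mo2_summary <- function(x, ...) {
  cat(sprintf("%d entries, %d studies, %d fish\n",
              x$n_entries, nrow(x$studies), x$total_fish))
  print(x$ranges, row.names = FALSE)
  print(x$studies, row.names = FALSE)
  invisible(x)
}
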