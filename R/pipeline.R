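#' Serialise a fit to JSON
#'
#' @param fit An `mo2_fit`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when `path` is given).
#' @export
fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mo2_fit"))
  co <- unclass(fit$coefficients)
  obj <- list(
    coefficients = as.list(co),
    se = as.list(fit$se),
    vcov = unname(apply(fit$vcov, 1, as.list)),
    sigma_study = fit$sigma_study, sigma_resid = fit$sigma_resid,
    loglik = fit$loglik, n_entries = fit$n_entries,
    n_studies = fit$n_studies, converged = fit$converged,
    n_iter = fit$n_iter, start_values = as.list(unclass(fit$start_values)),
    notes = fit$notes
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# Plain-text coefficient table: refined fit (+/- SE, adjusted R2, RMSE) over
# the legacy row evaluated on the same data.
report_table <- function(fit, diag_fit, diag_legacy,
                         legacy = legacy_coefficients()) {
  co <- unclass(fit$coefficients)
  lg <- unclass(legacy)
  fmt_row <- function(label, a, b, cc, d, adj, rmse, se = NULL) {
    cf <- if (is.null(se)) {
      sprintf("%7.2f      %7.2f      %7.3f      %7.3f     ", a, b, cc, d)
    } else {
      sprintf("%7.2f+/-%-5.2f %6.2f+/-%-5.2f %6.3f+/-%-6.3f %6.3f+/-%-5.3f",
              a, se[1], b, se[2], cc, se[3], d, se[4])
    }
    sprintf("%-28s %s %6.2f %8.2f", label, cf, adj, rmse)
  }
  c(sprintf("%-28s %-15s %-15s %-17s %-15s %6s %8s",
            "model", "a", "b", "c", "d", "adjR2", "RMSE"),
    fmt_row("refined (mixed-effects ML)", co[["a"]], co[["b"]], co[["c"]],
            co[["d"]], diag_fit$adj_r2, diag_fit$rmse, se = fit$se),
    fmt_row("legacy (as published)", lg[["a"]], lg[["b"]], lg[["c"]],
            lg[["d"]], diag_legacy$adj_r2, diag_legacy$rmse))
}

#' Run the full estimation pipeline
#'
#' Composes the package end to end: read (or synthesise) the raw
#' respirometry table, apply the inclusion criteria and the model-assumption
#' filters, obtain log-linear starting values, fit the nonlinear
#' mixed-effects model, screen two-way interactions, compute diagnostics and
#' the legacy-model comparison, and write a machine-readable run directory.
#' Deterministic given the input (or seed).
#'
#' Outputs under `out_dir`: `raw.csv`, `refined.csv`, `filter_inclusion.json`,
#' `filter_assumptions.json`, `fit.json`, `interactions.json`,
#' `diagnostics.json`, `comparison.csv`, `table_coefficients.txt`,
#' `truth.json` (synthetic runs), and `log.txt`. A stage error is recorded in
#' the log and the returned object; downstream stages are skipped.
#'
#' @param input Either a path to a canonical CSV, or a `synthetic_config`
#'   (e.g. [default_synth_config()]), or `NULL` to use
#'   `default_synth_config(seed)`.
#' @param out_dir Output directory (created if needed); `NULL` for no file
#'   output.
#' @param seed Seed used when `input` is `NULL`.
#' @return A list of class `mo2_pipeline` with the stage results
#'   (`dataset_raw`, `filter_inclusion`, `filter_assumptions`, `dataset`,
#'   `start`, `fit`, `interactions`, `diagnostics`, `comparison`), `errors`
#'   (named by stage), and `log` (character lines).
#' @export
run_pipeline <- function(input = NULL, out_dir = NULL, seed = 1) {
  res <- list(errors = list(), log = character())
  note <- function(stage, msg) {
    res$log <<- c(res$log, sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    if (length(res$errors)) { note(name, "skipped"); return(NULL) }
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      res$errors[[name]] <<- conditionMessage(out)
      note(name, paste("ERROR:", conditionMessage(out)))
      NULL
    } else {
      note(name, "ok")
      out
    }
  }

  truth <- NULL
  res$dataset_raw <- stage("read", {
    if (is.null(input)) input <- default_synth_config(seed = seed)
    if (inherits(input, "synthetic_config")) {
      gen <- generate_dataset(input)
      truth <- gen$truth
      gen$dataset
    } else {
      read_dataset(input)
    }
  })
  res$truth <- truth
  res$filter_inclusion <- stage("inclusion_filter",
                                apply_inclusion_criteria(res$dataset_raw))
  res$filter_assumptions <- stage("assumption_filter",
    apply_model_assumption_filters(res$filter_inclusion$dataset))
  res$dataset <- res$filter_assumptions$dataset
  res$start <- stage("stage1", fit_stage1_loglinear(res$dataset))
  res$fit <- stage("stage2", fit_stage2_nlme(res$dataset, start = res$start))
  res$interactions <- stage("interactions",
                            screen_interactions(res$dataset, res$fit))
  res$diagnostics <- stage("diagnostics", model_diagnostics(res$fit, res$dataset))
  res$comparison <- stage("comparison", compare_models(res$dataset, res$fit))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    if (!is.null(res$dataset_raw)) write_dataset(res$dataset_raw, p("raw.csv"))
    if (!is.null(res$truth)) write_truth_json(res$truth, p("truth.json"))
    if (!is.null(res$filter_inclusion))
      filter_report_json(res$filter_inclusion$report, p("filter_inclusion.json"))
    if (!is.null(res$filter_assumptions))
      filter_report_json(res$filter_assumptions$report, p("filter_assumptions.json"))
    if (!is.null(res$dataset)) write_dataset(res$dataset, p("refined.csv"))
    if (!is.null(res$fit)) fit_json(res$fit, p("fit.json"))
    if (!is.null(res$interactions)) {
      writeLines(jsonlite::toJSON(list(candidates = res$interactions$candidates,
                                       retained = res$interactions$retained),
                                  auto_unbox = TRUE, digits = NA, pretty = TRUE),
                 p("interactions.json"))
    }
    if (!is.null(res$diagnostics)) {
      d <- res$diagnostics
      writeLines(jsonlite::toJSON(list(r2 = d$r2, adj_r2 = d$adj_r2,
                                       rmse = d$rmse, n = d$n),
                                  auto_unbox = TRUE, digits = NA, pretty = TRUE),
                 p("diagnostics.json"))
    }
    if (!is.null(res$comparison)) {
      cmp <- res$comparison
      utils::write.csv(data.frame(
        model = c("candidate", "legacy"),
        adj_r2 = c(cmp$candidate$adj_r2, cmp$legacy$adj_r2),
        rmse = c(cmp$candidate$rmse, cmp$legacy$rmse)),
        p("comparison.csv"), row.names = FALSE)
      if (!is.null(res$fit)) {
        writeLines(report_table(res$fit, cmp$candidate, cmp$legacy),
                   p("table_coefficients.txt"))
      }
    }
    writeLines(res$log, p("log.txt"))
  }
  class(res) <- "mo2_pipeline"
  res
}

#' @export
print.mo2_pipeline <- function(x, ...) {
  writeLines(x$log)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
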