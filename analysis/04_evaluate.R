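#!/usr/bin/env Rscript
# Step 4: diagnostics, legacy comparison and derived quantities.
#
# Evaluates the refit against the refined table (population-level
# predictions), compares it with the legacy coefficient set applied as
# published, and derives the Q10 temperature coefficients and the
# coefficient contrasts between the two models.

suppressPackageStartupMessages(library(salmonMO2))

data_dir <- "results/data"
fit_dir <- "results/fit"
out <- "results/evaluation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- read_dataset(file.path(data_dir, "refined.csv"))
fj <- jsonlite::fromJSON(file.path(fit_dir, "fit.json"))
fit_coefs <- coefficient_set(fj$coefficients$a, fj$coefficients$b,
                             fj$coefficients$c, fj$coefficients$d)

diag_fit <- model_diagnostics(fit_coefs, ds)
cat("Refit diagnostics:     "); print(diag_fit)
cmp <- compare_models(ds, fit_coefs)
cat("Legacy (as published): "); print(cmp$legacy)
write.csv(data.frame(model = c("refined", "legacy"),
                     r2 = c(cmp$candidate$r2, cmp$legacy$r2),
                     adj_r2 = c(cmp$candidate$adj_r2, cmp$legacy$adj_r2),
                     rmse = c(cmp$candidate$rmse, cmp$legacy$rmse)),
          file.path(out, "comparison.csv"), row.names = FALSE)
write.csv(data.frame(fitted = diag_fit$fitted, residual = diag_fit$residuals,
                     std_residual = diag_fit$std_residuals),
          file.path(out, "residuals.csv"), row.names = FALSE)
write.csv(diag_fit$qq_pairs, file.path(out, "qq_pairs.csv"), row.names = FALSE)

ct <- coefficient_contrast(legacy_coefficients(), fit_coefs)
cat("\nContrast against the legacy model:\n"); print(ct)
cat(sprintf("Q10: legacy %.3f -> refit %.3f\n", ct$q10_old, ct$q10_new))
writeLines(jsonlite::toJSON(unclass(ct), auto_unbox = TRUE, digits = NA,
                            pretty = TRUE),
           file.path(out, "contrast.json"))

cat("\nWrote comparison.csv, residuals.csv, qq_pairs.csv, contrast.json under",
    out, "\n")
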