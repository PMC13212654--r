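#!/usr/bin/env Rscript
# Step 2: apply the inclusion criteria and the model-assumption filters.
#
# Inclusion: full-strength seawater, normoxia, >= 3 weeks thermal
# acclimation, healthy fish, fed state with overnight fast. Assumptions:
# drop the >= 23 degC treatment group (thermal MO2 plateau) and the
# >= 100%-U_crit steps (anaerobic plateau). On the emulated compilation this
# takes 96 entries to 76.

suppressPackageStartupMessages(library(salmonMO2))

out <- "results/data"
raw <- read_dataset(file.path(out, "raw.csv"))

inc <- apply_inclusion_criteria(raw)
asm <- apply_model_assumption_filters(inc$dataset)

filter_report_json(inc$report, file.path(out, "filter_inclusion.json"))
filter_report_json(asm$report, file.path(out, "filter_assumptions.json"))
write_dataset(asm$dataset, file.path(out, "refined.csv"))

cat("Inclusion criteria:", inc$report$n_in, "->", inc$report$n_out, "entries\n")
cat("Model assumptions: ", asm$report$n_in, "->", asm$report$n_out, "entries\n")
if (nrow(asm$report$removed)) print(table(asm$report$removed$rule))
s <- summarize_dataset(asm$dataset)
cat("Refined coverage:\n"); print(s$ranges, row.names = FALSE)
cat("Wrote", file.path(out, "refined.csv"), "\n")
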