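#!/usr/bin/env Rscript
# Step 4 — dynamic profiling: shifts in dependency after 20 h pre-treatment.
#
# Two scenarios: JEKO1 (mantle-cell lymphoma) pre-treated with ironomycin,
# read at 1 uM of the MCL-1 inhibitor (expected shift +9.9 points), and an
# AML sample pre-treated with azacytidine, read across the venetoclax dose
# range (expected +17.6 / +32.83 / +25.9 points at 10 / 100 / 1000 nM).

suppressMessages(library(bh3toolkit))

out_tables <- "results/tables"
dir.create(out_tables, recursive = TRUE, showWarnings = FALSE)

rows <- list()

jeko <- recover_dynamic_shift("jeko1_ironomycin", dose_nM = 1000,
                              n_pairs = 3, n_events = 20000, seed = 6100)
rows[[1]] <- jeko$shift
message(sprintf("JEKO1 + ironomycin, AZD-5991 1 uM: shift %.2f points (truth %.1f)",
                jeko$shift$shift_pct, jeko$truth_shift_pct))

for (dose in c(10, 100, 1000)) {
  aml <- recover_dynamic_shift("aml_azacytidine", dose_nM = dose,
                               n_pairs = 3, n_events = 20000,
                               seed = 6200 + dose)
  rows[[length(rows) + 1]] <- aml$shift
  message(sprintf("AML + azacytidine, venetoclax %4d nM: shift %.2f points (truth %.2f)",
                  dose, aml$shift$shift_pct, aml$truth_shift_pct))
}

shifts <- dplyr::bind_rows(rows)
write_report(shifts, file.path(out_tables, "dynamic_shifts.csv"))
message("pre-treatment-induced dependency changes recovered with preserved sign")
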