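#!/usr/bin/env Rscript
# Step 5 — internal-control QC, counting-bead checks, and statistics.
#
# (a) Thaw-to-thaw reproducibility of each control line at 1 uM, with the
#     published SDs injected, and the k-SD batch acceptance rule.
# (b) Bead-normalized absolute counting of a CLL-like well (17,153 live
#     cells) and the 4 h / 24 h-later toxicity ratio of a control well.
# (c) Two-way ANOVA of the baseline dose response vs vehicle, and the
#     correlation between delta Annexin V and CTG cytotoxicity.

suppressMessages(library(bh3toolkit))

out_tables <- "results/tables"
dir.create(out_tables, recursive = TRUE, showWarnings = FALSE)

# --- (a) control reproducibility and QC ------------------------------------
refs <- default_control_references()
qc_rows <- list()
for (i in seq_len(nrow(refs))) {
  key <- paste0(refs$cell_line[i], ":", refs$drug[i])
  deltas <- simulate_thaw_deltas(control_line_truths()[[key]], n_thaws = 12,
                                 replicate_sd = refs$reference_sd[i],
                                 n_events = 10000, seed = 7000 + i)
  batches <- rep(1:4, each = 3)  # 4 batches x 3 vials
  qc <- qc_check(deltas, refs[i, ], batch_ids = batches)
  qc_rows[[i]] <- tibble::tibble(
    cell_line = refs$cell_line[i], drug = refs$drug[i],
    mean_delta = qc$mean, sd_delta = sd(deltas),
    reference_sd = refs$reference_sd[i], pass = qc$pass,
    inter_batch_sd = qc$inter_batch_sd, intra_batch_sd = qc$intra_batch_sd)
  message(sprintf("%s: thaw SD %.1f (injected %.1f), QC %s",
                  refs$cell_line[i], sd(deltas), refs$reference_sd[i],
                  if (qc$pass) "PASS" else "FAIL"))
}
write_report(dplyr::bind_rows(qc_rows), file.path(out_tables, "control_qc.csv"))

# --- (b) absolute counting and toxicity monitoring --------------------------
tr <- dose_response_truth("CLL-1", "venetoclax",
                          induced = c("0" = 0, "10" = 0.517),
                          baseline = c(alive = 0.96, early = 0.02, dead = 0.02))
w4 <- simulate_well(list(well_id = "A1", dose_nM = 10, beads_added = 10000),
                    tr, variability = variability_model(replicate_sd = 0, rng_seed = 71),
                    true_cell_count = 17503, acquisition_fraction = 0.6)
ac4 <- absolute_count(classify_events(w4, gate_config()), 10000, well_id = "A1")
message(sprintf("bead-normalized live count: %0.f (truth 17,153)",
                ac4$cells_alive + ac4$cells_early))

ctrl <- dose_response_truth("CLL-1", "venetoclax", attrition_24h = 0.16)
c4 <- simulate_well(list(well_id = "C1", dose_nM = 0, timepoint_h = 4, beads_added = 10000),
                    ctrl, variability = variability_model(replicate_sd = 0, rng_seed = 72),
                    true_cell_count = 17000, acquisition_fraction = 0.6)
c24 <- simulate_well(list(well_id = "C2", dose_nM = 0, timepoint_h = 28, beads_added = 10000),
                     ctrl, variability = variability_model(replicate_sd = 0, rng_seed = 73),
                     true_cell_count = 17000, acquisition_fraction = 0.6)
ratio <- toxicity_ratio(absolute_count(classify_events(c4, gate_config()), 10000),
                        absolute_count(classify_events(c24, gate_config()), 10000))
message(sprintf("control 24h/4h live-count ratio: %.2f (thawing decline, truth 0.84)", ratio))
write_report(dplyr::bind_rows(ac4), file.path(out_tables, "absolute_counts.csv"))

# --- (c) statistics ---------------------------------------------------------
quant <- read_report(file.path(out_tables, "well_quant.csv"))
oci <- quant[quant$sample_id == "OCI-Ly1", ]
m <- tibble::tibble(condition = "venetoclax", dose_nM = oci$dose_nM,
                    value = oci$annexin_pct)
cmp <- compare_to_control(m)
write_report(cmp$contrasts, file.path(out_tables, "anova_contrasts.csv"))
message("two-way ANOVA dose contrasts vs vehicle (OCI-Ly1):")
print(as.data.frame(cmp$contrasts[, c("dose_nM", "estimate", "adjusted_p", "stars")]))

# CTG luminescence emulated from the true kill of each baseline condition,
# then correlated with the recovered delta Annexin V
deltas <- read_report(file.path(out_tables, "delta_annexin_baseline.csv"))
set.seed(99)
lum <- dplyr::bind_rows(lapply(seq_len(nrow(deltas)), function(i) {
  kill <- min(deltas$delta_pct[i] * 1.25, 99.5)  # early apoptosis progresses
  tibble::tibble(well_id = paste0("L", i), sample_id = deltas$sample_id[i],
                 drug = deltas$drug[i], dose_nM = deltas$dose_nM[i],
                 luminescence = max(1000 * (1 - kill / 100), 1) * exp(rnorm(1, 0, 0.05)))
}))
lum_ctrl <- dplyr::distinct(lum[, "sample_id"]) |>
  dplyr::mutate(well_id = paste0("C", dplyr::row_number()), drug = "vehicle",
                dose_nM = 0, luminescence = 1000)
viab <- viability_from_ctg(dplyr::bind_rows(lum, lum_ctrl))
joined <- dplyr::inner_join(deltas, viab, by = c("sample_id", "drug", "dose_nM"))
cr <- correlate(joined$delta_pct, -joined$cytotoxicity_pct)
write_report(cr, file.path(out_tables, "delta_vs_ctg_correlation.csv"))
message(sprintf("delta Annexin V vs CTG kill: r = %.3f (R^2 = %.3f, p = %.2g)",
                cr$r, cr$r_squared, cr$p_value))
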