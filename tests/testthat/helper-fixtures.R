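# Shared fixtures for the suite. Everything is generated in code; seeds are
# fixed so every run sees the same data.

# A small truth with a strong 1 uM response, for quick wells.
toy_truth <- function(induced_1uM = 0.6) {
  dose_response_truth("TOY", "venetoclax",
                      induced = c("0" = 0, "10" = 0.05, "100" = 0.3,
                                  "1000" = induced_1uM))
}

# One quick synthetic well (cells + beads) with hidden labels.
toy_well <- function(dose_nM = 1000, n_events = 2000, seed = 1,
                     truth = toy_truth(), ...) {
  simulate_well(list(well_id = "A1", dose_nM = dose_nM, timepoint_h = 4),
                truth, variability = variability_model(rng_seed = seed), ...,
                n_events = n_events)
}

# A layout with one control line across the full drug x dose grid plus a
# vehicle well.
toy_layout <- function(sample_id = "OCI-Ly1", target = "BCL-2") {
  rows <- list(well_spec("A1", sample_id, "vehicle", 0,
                         sample_kind = "control_line", control_target = target))
  i <- 2
  for (dose in c(10, 100, 1000)) {
    rows[[i]] <- well_spec(paste0("A", i), sample_id, "venetoclax", dose,
                           sample_kind = "control_line", control_target = target)
    i <- i + 1
  }
  plate_layout(dplyr::bind_rows(rows))
}

expect_channels <- function(events) {
  expect_true(all(c("fsc", "ssc", "annexin", "viability_dye", "bead") %in%
                    names(events)))
}
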