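# End-to-end experiment wrappers: simulate wells with known truth, gate with
# thresholds fitted from the vehicle wells, quantify, and return both the
# pipeline estimate and the generator truth. These are the building blocks of
# the analysis scripts and of every recovery check.

#' Simulate paired treated/vehicle wells and recover delta Annexin V
#'
#' For each replicate pair one vehicle and one treated well are simulated,
#' Annexin V / 7AAD thresholds are fitted from the pooled vehicle wells
#' (robust vehicle-quantile rule by default), every well is classified, and
#' the delta Annexin V statistic is computed over the replicate pairs.
#'
#' @param truth A [dose_response_truth()] for the sample/drug under test.
#' @param dose_nM Treated dose (nM).
#' @param n_pairs Number of replicate pairs.
#' @param n_events Acquired cell events per well.
#' @param variability A [variability_model()]; its `rng_seed` (plus the
#'   replicate index) fixes every well.
#' @param gate Base [gate_config()] (thresholds re-fitted from vehicle wells
#'   unless `auto_threshold = FALSE`).
#' @param auto_threshold Fit thresholds from the vehicle wells (default) or
#'   use the gate as given.
#' @param paired Compute per-pair deltas instead of arm-mean deltas.
#' @param frozen Passed to [simulate_well()].
#' @return List: `delta` (the [delta_annexin()] row), `treated_pct`,
#'   `vehicle_pct` (per-replicate percentages), `truth_delta_pct` (mean true
#'   delta over the simulated pairs, percentage points), `gate` (the fitted
#'   gate).
#' @export
recover_delta <- function(truth, dose_nM = 1000, n_pairs = 3, n_events = 20000,
                          variability = variability_model(rng_seed = 1),
                          gate = gate_config(threshold_source = "robust_from_vehicle"),
                          auto_threshold = TRUE, paired = FALSE, frozen = FALSE) {
  base_seed <- variability$rng_seed %||% 1L
  veh_wells <- trt_wells <- vector("list", n_pairs)
  truth_deltas <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    vi <- variability
    vi$rng_seed <- base_seed + 2L * i
    veh_wells[[i]] <- simulate_well(
      list(well_id = sprintf("V%d", i), dose_nM = 0, timepoint_h = 4),
      truth, variability = vi, n_events = n_events, frozen = frozen)
    vi$rng_seed <- base_seed + 2L * i + 1L
    trt_wells[[i]] <- simulate_well(
      list(well_id = sprintf("T%d", i), dose_nM = dose_nM, timepoint_h = 4),
      truth, variability = vi, n_events = n_events, frozen = frozen)
    truth_deltas[i] <- 100 * (attr(trt_wells[[i]], "truth")$true_fraction_early -
                                attr(veh_wells[[i]], "truth")$true_fraction_early)
  }
  if (auto_threshold) gate <- fit_thresholds(veh_wells, gate)
  pct <- function(w) annexin_fraction(classify_events(w, gate))
  vehicle_pct <- vapply(veh_wells, pct, 0)
  treated_pct <- vapply(trt_wells, pct, 0)
  d <- delta_annexin(treated_pct, vehicle_pct, paired = paired,
                     sample_id = truth$sample_id, drug = truth$drug,
                     dose_nM = dose_nM)
  list(delta = d, treated_pct = treated_pct, vehicle_pct = vehicle_pct,
       truth_delta_pct = mean(truth_deltas), gate = gate)
}

#' Simulate independent thaw replicates of a control line
#'
#' Each thaw is one treated/vehicle well pair sharing a thaw-level
#' perturbation of the induced response drawn from `replicate_sd` (the
#' biological thaw-to-thaw variability), with fresh within-pair sampling
#' noise. Returns the per-thaw pipeline-estimated deltas, from which the
#' reproducibility SD of the control response is computed.
#'
#' @param truth Control-line [dose_response_truth()].
#' @param n_thaws Number of thaw replicates.
#' @param replicate_sd Thaw-to-thaw SD of the induced response (percentage
#'   points).
#' @param dose_nM Dose (default 1000 nM, the control dose).
#' @param n_events Events per well.
#' @param seed Base seed.
#' @param gate Gate configuration; fitted once from all vehicle wells.
#' @return Numeric vector of `n_thaws` estimated deltas (percentage points).
#' @export
simulate_thaw_deltas <- function(truth, n_thaws = 12, replicate_sd = 5.0,
                                 dose_nM = 1000, n_events = 20000, seed = 1,
                                 gate = gate_config(threshold_source = "robust_from_vehicle")) {
  veh_wells <- trt_wells <- vector("list", n_thaws)
  for (i in seq_len(n_thaws)) {
    set.seed(seed + 1000L * i)
    thaw_effect <- rnorm(1, 0, replicate_sd / 100)
    vb <- variability_model(replicate_sd = 0, rng_seed = NULL)
    veh_wells[[i]] <- simulate_well(
      list(well_id = sprintf("V%d", i), dose_nM = 0, timepoint_h = 4),
      truth, variability = vb, n_events = n_events, replicate_effect = 0)
    trt_wells[[i]] <- simulate_well(
      list(well_id = sprintf("T%d", i), dose_nM = dose_nM, timepoint_h = 4),
      truth, variability = vb, n_events = n_events,
      replicate_effect = thaw_effect)
  }
  gate <- fit_thresholds(veh_wells, gate)
  vapply(seq_len(n_thaws), function(i) {
    annexin_fraction(classify_events(trt_wells[[i]], gate)) -
      annexin_fraction(classify_events(veh_wells[[i]], gate))
  }, 0)
}

#' Ground truths of the dynamic-profiling scenarios
#'
#' Two pre-treatment scenarios used throughout the package. The pre-treatment
#' shifts are the assay's printed values; the vehicle-arm baselines are not
#' printed and are set once to plausible mid-range responses.
#' \describe{
#'   \item{`"jeko1_ironomycin"`}{MCL cell line JEKO1, 20 h ironomycin
#'     pre-treatment: AZD-5991 1 uM response shifts by +9.9 points (vehicle
#'     arm 10.0 -> treated arm 19.9).}
#'   \item{`"aml_azacytidine"`}{AML sample, 20 h azacytidine pre-treatment:
#'     venetoclax response shifts by +17.6 / +32.83 / +25.9 points at
#'     10 / 100 / 1000 nM, with no detectable 10 nM response in the vehicle
#'     arm.}
#' }
#'
#' @param scenario Scenario name.
#' @return List with `vehicle_arm` and `treated_arm`
#'   [dose_response_truth()]s, and `drug`.
#' @export
dynamic_scenario_truths <- function(scenario = c("jeko1_ironomycin", "aml_azacytidine")) {
  scenario <- match.arg(scenario)
  if (scenario == "jeko1_ironomycin") {
    list(
      vehicle_arm = dose_response_truth(
        "JEKO1", "AZD-5991",
        induced = c("0" = 0, "10" = 0.02, "100" = 0.05, "1000" = 0.100)),
      treated_arm = dose_response_truth(
        "JEKO1", "AZD-5991",
        induced = c("0" = 0, "10" = 0.03, "100" = 0.09, "1000" = 0.199)),
      drug = "AZD-5991", pretreatment_name = "ironomycin")
  } else {
    list(
      vehicle_arm = dose_response_truth(
        "AML-1", "venetoclax",
        induced = c("0" = 0, "10" = 0.000, "100" = 0.100, "1000" = 0.300)),
      treated_arm = dose_response_truth(
        "AML-1", "venetoclax",
        induced = c("0" = 0, "10" = 0.176, "100" = 0.4283, "1000" = 0.559)),
      drug = "venetoclax", pretreatment_name = "azacytidine")
  }
}

#' Recover a dynamic-profiling shift end-to-end
#'
#' Runs [recover_delta()] independently on the vehicle-pre-treated and
#' drug-pre-treated arms and differences the two delta Annexin V estimates
#' with [dynamic_shift()].
#'
#' @param scenario A [dynamic_scenario_truths()] list (or scenario name).
#' @param dose_nM Toolkit dose at which to report the shift.
#' @param n_pairs,n_events,seed Simulation size and seed.
#' @param variability Well-to-well [variability_model()] (the `rng_seed` field
#'   is overridden per arm from `seed`).
#' @return List: `shift` (the [dynamic_shift()] row at `dose_nM`),
#'   `truth_shift_pct`, and the two arm results.
#' @export
recover_dynamic_shift <- function(scenario = "jeko1_ironomycin", dose_nM = 1000,
                                  n_pairs = 3, n_events = 20000, seed = 1,
                                  variability = variability_model()) {
  if (is.character(scenario)) scenario <- dynamic_scenario_truths(scenario)
  run_arm <- function(truth, offset) {
    v <- variability
    v$rng_seed <- seed + offset
    recover_delta(truth, dose_nM = dose_nM, n_pairs = n_pairs,
                  n_events = n_events, variability = v)
  }
  veh <- run_arm(scenario$vehicle_arm, 0L)
  trt <- run_arm(scenario$treated_arm, 10000L)
  shift <- dynamic_shift(veh$delta, trt$delta,
                         pretreatment_name = scenario$pretreatment_name)
  truth_shift <- 100 * (induced_fraction(scenario$treated_arm, dose_nM) -
                          induced_fraction(scenario$vehicle_arm, dose_nM))
  list(shift = shift[shift$dose_nM == dose_nM, ],
       truth_shift_pct = truth_shift, vehicle_arm = veh, treated_arm = trt)
}
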