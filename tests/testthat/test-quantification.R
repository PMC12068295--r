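# Minimal hand-built WellQuant for arithmetic checks.
mk_quant <- function(n_alive, n_early, n_dead, n_beads = 100, n_debris = 0) {
  structure(list(counts = c(n_beads = n_beads, n_debris = n_debris,
                            n_alive = n_alive, n_early = n_early, n_dead = n_dead),
                 total_events = n_alive + n_early + n_dead + n_beads + n_debris,
                 frac_alive = n_alive / (n_alive + n_early + n_dead),
                 frac_early = n_early / (n_alive + n_early + n_dead),
                 frac_dead = n_dead / (n_alive + n_early + n_dead),
                 denominator = n_alive + n_early + n_dead,
                 denominator_kind = "intact_cells", all_beads = FALSE),
            class = "bh3_wellquant")
}

test_that("the Annexin V fraction is early / intact cells, in percent", {
  expect_identical(annexin_fraction(mk_quant(1000, 0, 0)), 0)
  expect_equal(annexin_fraction(mk_quant(18000, 1200, 800)), 6.0)
  expect_error(annexin_fraction(mk_quant(0, 0, 0)), "no cell events")
})

test_that("a well's estimated fraction sits within the binomial bound of truth", {
  tr <- toy_truth(induced_1uM = 0.554 - 0.046)  # true early frac 0.554 at 1 uM
  w <- simulate_well(list(well_id = "A1", dose_nM = 1000), tr,
                     variability = variability_model(replicate_sd = 0, rng_seed = 41),
                     n_events = 20000)
  est <- annexin_fraction(classify_events(w, gate_config()))
  expect_lt(abs(est - 55.4), 1.0)
})

test_that("delta Annexin V is the treated-minus-vehicle difference", {
  d <- delta_annexin(60.0, 4.6)
  expect_equal(d$delta_pct, 55.4)
  expect_identical(delta_annexin(c(10, 12), c(10, 12))$delta_pct, 0)
  p <- delta_annexin(c(60, 62, 58), c(5, 6, 4), paired = TRUE)
  expect_equal(p$delta_pct, 55)
  expect_equal(p$replicates[[1]], c(55, 56, 54))
  expect_equal(p$sem, sd(c(55, 56, 54)) / sqrt(3))
  expect_error(delta_annexin(c(1, 2), 1, paired = TRUE), "equal replicate")
  expect_error(delta_annexin(numeric(0), 1), "at least one replicate")
})

test_that("delta Annexin V estimates recover generator truth over replicates", {
  tr <- control_line_truths()[["OCI-Ly1:venetoclax"]]
  r <- recover_delta(tr, 1000, n_pairs = 3, n_events = 20000,
                     variability = variability_model(rng_seed = 77))
  expect_lt(abs(r$delta$delta_pct - r$truth_delta_pct), 2.0)
})

test_that("delta Annexin V is asymptotically unbiased for the true difference", {
  tr <- toy_truth(induced_1uM = 0.5)
  g <- gate_config()
  errs <- vapply(1:100, function(i) {
    vb <- variability_model(replicate_sd = 0, rng_seed = 5000 + 2 * i)
    wt <- simulate_well(list(well_id = "T", dose_nM = 1000), tr,
                        variability = vb, n_events = 20000)
    vb$rng_seed <- 5001 + 2 * i
    wv <- simulate_well(list(well_id = "V", dose_nM = 0), tr,
                        variability = vb, n_events = 20000)
    est <- annexin_fraction(classify_events(wt, g)) -
      annexin_fraction(classify_events(wv, g))
    est - 50
  }, 0)
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("bead normalization turns event counts into absolute counts", {
  q <- mk_quant(n_alive = 1000, n_early = 0, n_dead = 0, n_beads = 1000)
  expect_equal(absolute_count(q, 12345)$cells_alive, 12345)  # ratio identity
  q2 <- mk_quant(n_alive = 2000, n_early = 0, n_dead = 0, n_beads = 1000)
  expect_equal(absolute_count(q2, 10000)$cells_alive, 20000)
  # scale-free: doubling all counts leaves the estimate unchanged
  q3 <- mk_quant(n_alive = 4000, n_early = 0, n_dead = 0, n_beads = 2000)
  expect_equal(absolute_count(q3, 10000)$cells_alive,
               absolute_count(q2, 10000)$cells_alive)
  expect_error(absolute_count(mk_quant(10, 0, 0, n_beads = 0), 1000),
               "acquisition failure")
})

test_that("bead-normalized counts recover a known live-cell number within 5%", {
  # a CLL-like well: 17,503 intact cells of which 98% (17,153) are alive or
  # early-apoptotic, Poisson bead sampling, partial acquisition
  tr <- dose_response_truth("CLL-1", "venetoclax",
                            induced = c("0" = 0, "10" = 0.517),
                            baseline = c(alive = 0.96, early = 0.02, dead = 0.02))
  w <- simulate_well(list(well_id = "A1", dose_nM = 10, beads_added = 10000),
                     tr, variability = variability_model(replicate_sd = 0, rng_seed = 61),
                     true_cell_count = 17503, acquisition_fraction = 0.6)
  q <- classify_events(w, gate_config())
  ac <- absolute_count(q, 10000)
  live_est <- ac$cells_alive + ac$cells_early
  expect_lt(abs(live_est - 17153) / 17153, 0.05)
})

test_that("delta cell death is the viable-percentage difference, timepoint-guarded", {
  a <- mk_quant(900, 50, 50)
  expect_identical(delta_cell_death(a, a), 0)
  ctrl <- mk_quant(900, 50, 50)    # 90% viable
  trt <- mk_quant(200, 300, 500)   # 20% viable
  expect_equal(delta_cell_death(ctrl, trt), 70)
  expect_error(delta_cell_death(ctrl, trt, control_timepoint_h = 4,
                                treated_timepoint_h = 28),
               "timepoint mismatch")
  # also defined on absolute counts
  expect_equal(delta_cell_death(absolute_count(ctrl, 1000),
                                absolute_count(trt, 1000)), 70)
})

test_that("4 h delta Annexin V predicts 24 h delta cell death when progression is high", {
  doses <- c(10, 100, 1000)
  tr <- dose_response_truth("S", "venetoclax",
                            induced = c("0" = 0, "10" = 0.10, "100" = 0.35,
                                        "1000" = 0.70),
                            progression_rate = 0.9)
  g <- gate_config()
  da4 <- dcd24 <- numeric(length(doses))
  vb <- variability_model(replicate_sd = 0, rng_seed = 90)
  v4 <- simulate_well(list(well_id = "V4", dose_nM = 0, timepoint_h = 4), tr,
                      variability = vb, n_events = 10000)
  vb$rng_seed <- 91
  v24 <- simulate_well(list(well_id = "V24", dose_nM = 0, timepoint_h = 28), tr,
                       variability = vb, n_events = 10000)
  for (k in seq_along(doses)) {
    vb$rng_seed <- 92 + 2 * k
    t4 <- simulate_well(list(well_id = "T4", dose_nM = doses[k], timepoint_h = 4),
                        tr, variability = vb, n_events = 10000)
    vb$rng_seed <- 93 + 2 * k
    t24 <- simulate_well(list(well_id = "T24", dose_nM = doses[k], timepoint_h = 28),
                         tr, variability = vb, n_events = 10000)
    da4[k] <- annexin_fraction(classify_events(t4, g)) -
      annexin_fraction(classify_events(v4, g))
    dcd24[k] <- delta_cell_death(classify_events(v24, g), classify_events(t24, g))
  }
  cr <- correlate(da4, dcd24)
  expect_gte(cr$r, 0.8)
})

test_that("CTG viability normalizes to the dose-0 control with signed cytotoxicity", {
  lum <- tibble::tibble(
    well_id = paste0("A", 1:6), sample_id = "S",
    drug = c("vehicle", "venetoclax", "venetoclax", "vehicle", "A-1155463", "A-1155463"),
    dose_nM = c(0, 100, 1000, 0, 100, 1000),
    luminescence = c(1000, 500, 7, 1000, 600, 181))
  v <- viability_from_ctg(lum)
  expect_equal(v$viability_pct[v$drug == "venetoclax" & v$dose_nM == 1000], 0.7)
  expect_equal(v$cytotoxicity_pct[v$drug == "venetoclax" & v$dose_nM == 1000], -99.3)
  expect_equal(v$cytotoxicity_pct[v$drug == "A-1155463" & v$dose_nM == 1000], -81.9)
  expect_equal(v$cytotoxicity_pct[v$drug == "venetoclax" & v$dose_nM == 100], -50)
  same <- tibble::tibble(well_id = c("A1", "A2"), sample_id = "S",
                         drug = c("vehicle", "venetoclax"), dose_nM = c(0, 10),
                         luminescence = c(400, 400))
  v2 <- viability_from_ctg(same)
  expect_equal(v2$viability_pct, 100)
  expect_equal(v2$cytotoxicity_pct, 0)
  same$luminescence[1] <- 0
  expect_error(viability_from_ctg(same), "zero control")
  expect_error(viability_from_ctg(same[2, ]), "no dose-0 control")
})

test_that("toxicity monitoring reports the live-count ratio between plates", {
  early <- absolute_count(mk_quant(1700, 0, 0, n_beads = 1000), 10000)
  late <- absolute_count(mk_quant(1428, 0, 0, n_beads = 1000), 10000)
  expect_equal(toxicity_ratio(early, late), 1428 / 1700)
})
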