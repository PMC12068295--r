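test_that("dependency scores normalize to the matched control response", {
  expect_equal(dependency_score(49.06, 49.06, "BCL-2"), 100)  # self = 100
  expect_equal(dependency_score(68.0, 49.06, "BCL-2"), 100 * 68.0 / 49.06)
  expect_equal(round(dependency_score(68.0, 49.06, "BCL-2"), 1), 138.6)
  # MCL-1 weighted variant replaces the control denominator by 30
  expect_equal(dependency_score(18.47, 55.4, "MCL-1"), 100 * 18.47 / 30)
  expect_equal(round(dependency_score(18.47, 55.4, "MCL-1"), 1), 61.6)
  # ratio variant uses the JJN3 delta like the other axes
  expect_equal(dependency_score(18.47, 55.4, "MCL-1", formula_variant = "ratio"),
               100 * 18.47 / 55.4)
  expect_message(s <- dependency_score(-5, 50, "BCL-2"), "clipped")
  expect_identical(s, 0)
  expect_error(dependency_score(10, 0, "BCL-2"), "QC")
  expect_error(dependency_score(10, 50, "MCL-1", mcl1_weight = 0), "mcl1_weight")
})

test_that("ratio scores are invariant to common scaling of sample and control", {
  for (f in c(0.5, 2, 10)) {
    expect_equal(dependency_score(30 * f, 60 * f, "BCL-2"),
                 dependency_score(30, 60, "BCL-2"))
    expect_equal(dependency_score(30 * f, 60 * f, "BCL-XL"),
                 dependency_score(30, 60, "BCL-XL"))
  }
})

test_that("profile_sample scores three axes and annotates navitoclax", {
  controls <- tibble::tibble(
    sample_id = c("OCI-Ly1", "JJN3", "HEL"),
    drug = c("venetoclax", "AZD-5991", "A-1155463"),
    dose_nM = 1000, delta_pct = c(75.4, 55.4, 69.1))
  # a CLL-like sample: strong venetoclax, weak A-1155463 response
  sample <- tibble::tibble(
    sample_id = "CLL-1",
    drug = c("venetoclax", "AZD-5991", "A-1155463", "navitoclax"),
    dose_nM = 1000, delta_pct = c(70.0, 10.4, 7.6, 40.0))
  pr <- profile_sample(sample, controls)
  expect_equal(unname(pr$scores["BCL2_score"]), 100 * 70 / 75.4)
  expect_equal(unname(pr$scores["MCL1_score"]), 100 * 10.4 / 30)
  expect_gt(pr$scores[["BCL2_score"]], pr$scores[["BCLXL_score"]])
  expect_equal(pr$navitoclax_delta, 40.0)
  expect_identical(pr$formula_variant, "weighted")
  # the matched control against itself scores exactly 100 on ratio axes
  self <- tibble::tibble(sample_id = "OCI-Ly1",
                         drug = c("venetoclax", "AZD-5991", "A-1155463"),
                         dose_nM = 1000, delta_pct = c(75.4, 15.0, 2.0))
  expect_equal(unname(profile_sample(self, controls)$scores["BCL2_score"]), 100)
  # a missing control axis is an error naming the axis
  expect_error(profile_sample(sample, controls[controls$sample_id != "HEL", ]),
               "BCL-XL control \\(HEL\\)")
  expect_error(profile_sample(sample, controls[controls$sample_id != "JJN3", ],
                              formula_variant = "ratio"),
               "MCL-1 control \\(JJN3\\)")
  expect_error(profile_sample(sample[sample$drug != "venetoclax", ], controls),
               "no 1 uM measurement")
})

test_that("dynamic shifts difference the arms per (drug, dose), sign preserved", {
  veh <- tibble::tibble(sample_id = "S", drug = "AZD-5991", dose_nM = 1000,
                        delta_pct = 10.0)
  trt <- veh
  trt$delta_pct <- 19.9
  s <- dynamic_shift(veh, trt, pretreatment_name = "ironomycin")
  expect_equal(s$shift_pct, 9.9)
  expect_identical(dynamic_shift(veh, veh)$shift_pct, 0)
  down <- trt
  down$delta_pct <- -1.9  # a pre-treatment can reduce a dependency
  expect_equal(dynamic_shift(veh, down)$shift_pct, -11.9)
  extra <- dplyr::bind_rows(trt, tibble::tibble(sample_id = "S", drug = "venetoclax",
                                                dose_nM = 100, delta_pct = 5))
  expect_warning(s2 <- dynamic_shift(veh, extra), "only one arm")
  expect_identical(nrow(s2), 1L)
})

test_that("a simulated pre-treatment shift is recovered end-to-end", {
  r <- recover_dynamic_shift("jeko1_ironomycin", dose_nM = 1000,
                             n_pairs = 3, n_events = 8000, seed = 17)
  expect_lt(abs(r$shift$shift_pct - r$truth_shift_pct), 2.0)
})

test_that("batch QC applies the closed k-SD acceptance interval", {
  ref <- default_control_references()[1, ]  # OCI-Ly1: 75.4 +/- 5.0, k = 2
  expect_true(qc_check(c(75.4, 75.4), ref)$pass)
  # boundary values pass (closed interval)
  expect_true(qc_check(c(85.4, 85.4), ref)$pass)
  expect_true(qc_check(c(65.4, 65.4), ref)$pass)
  expect_false(qc_check(c(85.5, 85.5), ref)$pass)
  one <- qc_check(75.4, ref)
  expect_false(one$pass)
  expect_match(one$reason, "n_vials < 2")
  wide <- qc_check(c(60, 91), ref)  # mean inside even if vials straddle
  expect_true(wide$pass)
})

test_that("variance components separate inter- from intra-batch variability", {
  set.seed(123)
  n_batches <- 6; vials <- 4
  batch_means <- rnorm(n_batches, 75, 8)
  vals <- as.vector(vapply(batch_means, function(m) rnorm(vials, m, 2),
                           numeric(vials)))
  batches <- rep(seq_len(n_batches), each = vials)
  vc <- batch_variance_components(vals, batches)
  expect_gt(vc[["inter_batch_sd"]], vc[["intra_batch_sd"]])
  q <- qc_check(vals, default_control_references()[1, ], batch_ids = batches)
  expect_equal(q$inter_batch_sd, vc[["inter_batch_sd"]])
  # recovery over repeated simulation: median estimate within 20% of truth
  set.seed(321)
  est <- replicate(200, {
    bm <- rnorm(4, 75, 8)
    v <- as.vector(vapply(bm, function(m) rnorm(3, m, 2), numeric(3)))
    batch_variance_components(v, rep(1:4, each = 3))[["inter_batch_sd"]]
  })
  expect_lt(abs(median(est) - 8) / 8, 0.20)
})

test_that("thaw-replicate simulation reproduces the injected reproducibility SD", {
  tr <- control_line_truths()[["JJN3:AZD-5991"]]
  d <- simulate_thaw_deltas(tr, n_thaws = 12, replicate_sd = 7.7, seed = 2)
  expect_lt(abs(sd(d) - 7.7), 2.5)
  expect_lt(abs(mean(d) - 55.4), 5)
})
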