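test_that("the arcsinh transform is exact at zero, invertible, and guarded", {
  ev <- tibble::tibble(fsc = c(1e4, 5e4), ssc = c(1e4, 3e4),
                       annexin = c(0, 1234.5), viability_dye = c(10, -3),
                       bead = c(0.5, 8e4))
  tr <- apply_transform(ev, "arcsinh", 150)
  expect_identical(tr$annexin[1], 0)           # asinh(0) = 0
  expect_identical(tr$fsc, ev$fsc)             # scatter untransformed
  back <- invert_transform(tr, "arcsinh", 150)
  expect_equal(back$annexin, ev$annexin, tolerance = 1e-9)
  expect_equal(back$viability_dye, ev$viability_dye, tolerance = 1e-9)
  expect_identical(apply_transform(ev, "none")$annexin, ev$annexin)
  expect_error(apply_transform(ev, "arcsinh", cofactor = 0), "cofactor")
})

test_that("quantile thresholds honour their definition on degenerate inputs", {
  mk <- function(x) tibble::tibble(fsc = 50000, ssc = 30000, annexin = x,
                                   viability_dye = x, bead = 0)
  cfg <- gate_config(transform = "none",
                     threshold_source = "quantile_from_vehicle")
  # constant input: any quantile equals the constant
  fit <- suppressWarnings(fit_thresholds(mk(rep(1.0, 100)), cfg))
  expect_equal(fit$annexin_threshold, 1.0)
  # q = 0.5 on a symmetric sample equals its median
  cfg$quantile_q <- 0.5
  x <- c(-3, -1, 0, 1, 3)
  fit <- suppressWarnings(fit_thresholds(mk(x), cfg))
  expect_equal(fit$annexin_threshold, median(x))
  expect_error(fit_thresholds(list(), cfg), "vehicle well")
  expect_warning(fit_thresholds(mk(rep(1, 10)), gate_config(transform = "none")),
                 "usable vehicle events")
})

test_that("fitted thresholds match the exhaustive misclassification-minimizing cutoff", {
  # two well-separated populations; the exhaustive scan over all cutoffs is
  # the oracle. With positives just above the 1-q tail mass, the plain
  # quantile interpolates into the gap between the supports; the robust rule
  # must reach the same (zero) misclassification as the oracle.
  set.seed(71)
  neg <- 150 * sinh(rnorm(995, 0.3, 0.35))
  pos <- 150 * sinh(rnorm(5, 4.2, 0.35))
  ev <- tibble::tibble(fsc = 50000, ssc = 30000,
                       annexin = c(neg, pos), viability_dye = 40, bead = 0)
  labels <- rep(c(0, 1), c(995, 5))
  tx <- asinh(ev$annexin / 150)
  oracle_errors <- min(vapply(sort(tx), function(t) sum((tx > t) != labels), 0))
  expect_identical(oracle_errors, 0)
  fit_q <- fit_thresholds(ev, gate_config(threshold_source = "quantile_from_vehicle"))
  expect_gt(fit_q$annexin_threshold, max(asinh(neg / 150)))  # strictly between
  expect_lt(fit_q$annexin_threshold, min(asinh(pos / 150)))  # the supports
  # the robust rule targets the q-tail of the negatives, so it concedes at
  # most ~(1-q) errors over the oracle while staying below the positives
  fit_r <- fit_thresholds(ev, gate_config(threshold_source = "robust_from_vehicle"))
  expect_lte(sum((tx > fit_r$annexin_threshold) != labels),
             oracle_errors + ceiling(0.01 * length(tx)))
  expect_lt(fit_r$annexin_threshold, min(asinh(pos / 150)))
  expect_gt(fit_r$annexin_threshold, median(asinh(neg / 150)))
})

test_that("classification partitions every event into exactly one class", {
  w <- toy_well(seed = 31, n_events = 5000)
  q <- classify_events(w, gate_config())
  expect_identical(sum(q$counts), q$total_events)
  expect_identical(q$total_events, nrow(w))
  expect_equal(q$frac_alive + q$frac_early + q$frac_dead, 1, tolerance = 1e-12)
  expect_error(classify_events(w[0, ], gate_config()), "empty")
})

test_that("events exactly at a threshold are negative, deterministically", {
  g <- gate_config(transform = "none", annexin_threshold = 10,
                   viability_threshold = 20, bead_gate = 1000,
                   scatter_gate = c(fsc_lo = 0, fsc_hi = 1e6,
                                    ssc_lo = 0, ssc_hi = 1e6))
  ev <- tibble::tibble(fsc = 5e4, ssc = 3e4,
                       annexin = c(10, 10.0001, 5, 50),
                       viability_dye = c(20, 20, 20.0001, 20),
                       bead = c(0, 0, 0, 1000))
  q1 <- classify_events(ev, g)
  expect_identical(q1$classes,
                   c("alive", "early_apoptotic", "dead", "early_apoptotic"))
  expect_identical(classify_events(ev, g)$classes, q1$classes)
})

test_that("raising the Annexin V threshold never increases the early count", {
  w <- toy_well(seed = 32, n_events = 4000)
  thresholds <- seq(0.5, 4.5, by = 0.5)
  n_early <- vapply(thresholds, function(t) {
    g <- gate_config(annexin_threshold = t)
    classify_events(w, g)$counts[["n_early"]]
  }, 0)
  expect_true(all(diff(n_early) <= 0))
})

test_that("a well of pure double negatives inside the scatter gate is all alive", {
  ev <- tibble::tibble(fsc = rnorm(500, 5e4, 5e3), ssc = rnorm(500, 3e4, 3e3),
                       annexin = abs(rnorm(500, 40, 10)),
                       viability_dye = abs(rnorm(500, 40, 10)),
                       bead = abs(rnorm(500, 30, 10)))
  q <- classify_events(ev, gate_config())
  expect_identical(q$frac_alive, 1)
  # an all-bead acquisition is flagged
  beads <- tibble::tibble(fsc = 28000, ssc = 52000, annexin = 2e4,
                          viability_dye = 2e4, bead = rep(6e4, 100))
  expect_warning(q2 <- classify_events(beads, gate_config()), "beads")
  expect_true(q2$all_beads)
})

test_that("gating agrees with generator labels on >= 99% of events over 100 wells", {
  truths <- control_line_truths()
  agree <- total <- 0
  for (i in 1:100) {
    tr <- truths[[(i - 1) %% 3 + 1]]
    dose <- c(0, 10, 100, 1000)[(i - 1) %% 4 + 1]
    w <- simulate_well(list(well_id = "X", dose_nM = dose),
                       tr, variability = variability_model(rng_seed = 300 + i),
                       n_events = 1500)
    cls <- classify_events(w, gate_config())$classes
    agree <- agree + sum(cls == w$.truth_class)
    total <- total + nrow(w)
  }
  expect_gte(agree / total, 0.99)
})

test_that("gate configurations survive a YAML round-trip", {
  g <- gate_config(annexin_threshold = 1.75, quantile_q = 0.99,
                   denominator = "live_plus_early")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_gate(g, f)
  expect_equal(read_gate(f), g)
})
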