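#' Population model for one event class
#'
#' Describes the intensity distribution of a single event class (alive,
#' early-apoptotic, dead, debris or counting bead). Fluorescence channels are
#' Gaussian in arcsinh-transformed space (equivalently, approximately
#' log-normal on the raw scale), which is standard practice for conventional
#' flow data; scatter channels are Gaussian on the raw scale.
#'
#' @param class One of `"alive"`, `"early_apoptotic"`, `"dead"`, `"debris"`,
#'   `"bead"`.
#' @param fluor_mean,fluor_sd Named numeric vectors over
#'   `c("annexin", "viability_dye", "bead")`: location and spread in
#'   arcsinh-transformed intensity units.
#' @param scatter_mean,scatter_sd Named numeric vectors over
#'   `c("fsc", "ssc")`: location and spread in raw scatter units.
#' @return A `bh3_population` object.
#' @export
population_model <- function(class, fluor_mean, fluor_sd, scatter_mean, scatter_sd) {
  class <- match.arg(class, BH3_CLASSES)
  fl <- c("annexin", "viability_dye", "bead")
  sc <- c("fsc", "ssc")
  stopifnot(all(fl %in% names(fluor_mean)), all(fl %in% names(fluor_sd)),
            all(sc %in% names(scatter_mean)), all(sc %in% names(scatter_sd)))
  if (any(fluor_sd[fl] <= 0) || any(scatter_sd[sc] <= 0)) {
    stop("population dispersions must be strictly positive", call. = FALSE)
  }
  structure(list(class = class,
                 fluor_mean = fluor_mean[fl], fluor_sd = fluor_sd[fl],
                 scatter_mean = scatter_mean[sc], scatter_sd = scatter_sd[sc]),
            class = "bh3_population")
}

#' Default population models
#'
#' Locations are chosen so the five classes are pairwise separable under the
#' default gates: alive cells are double negative, early-apoptotic cells are
#' Annexin V single positive, dead cells are 7AAD positive (single or double
#' positive), debris sits at low forward scatter, and counting beads are
#' extremely bright in the dedicated bead channel and bright in all
#' fluorescence channels.
#'
#' @param cofactor arcsinh cofactor used to place raw-scale medians (default
#'   150, matching the default gating transform).
#' @return Named list of [population_model()] objects.
#' @export
default_population_models <- function(cofactor = 150) {
  tr <- function(x) asinh(x / cofactor)  # raw-scale median -> transformed mean
  fl <- function(annexin, aad, bead, sd = c(0.35, 0.35, 0.35)) {
    list(mean = c(annexin = annexin, viability_dye = aad, bead = bead),
         sd = c(annexin = sd[1], viability_dye = sd[2], bead = sd[3]))
  }
  sc <- function(fsc, ssc, fsc_sd, ssc_sd) {
    list(mean = c(fsc = fsc, ssc = ssc), sd = c(fsc = fsc_sd, ssc = ssc_sd))
  }
  mk <- function(class, f, s) {
    population_model(class, f$mean, f$sd, s$mean, s$sd)
  }
  neg <- tr(45)      # autofluorescence-level background
  pos_annexin <- tr(5000)
  pos_aad <- tr(6000)
  list(
    alive = mk("alive", fl(neg, neg, neg), sc(50000, 30000, 7000, 6000)),
    early_apoptotic = mk("early_apoptotic",
                         fl(pos_annexin, neg, neg),
                         sc(46000, 32000, 7000, 6000)),
    dead = mk("dead",
              fl(tr(3500), pos_aad, neg, sd = c(0.9, 0.40, 0.35)),
              sc(36000, 34000, 7000, 7000)),
    debris = mk("debris",
                fl(tr(30), tr(30), tr(30), sd = c(0.5, 0.5, 0.5)),
                sc(6000, 5000, 1800, 1500)),
    bead = mk("bead",
              fl(tr(20000), tr(20000), tr(60000), sd = c(0.2, 0.2, 0.15)),
              sc(28000, 52000, 2500, 4000))
  )
}

#' Ground-truth dose response for one sample
#'
#' Encodes the true early-apoptosis induction of one sample for one BH3
#' mimetic, either as explicit per-dose induced fractions on the assay's dose
#' grid (0, 10, 100, 1000 nM) or as a Hill curve. Explicit per-dose values are
#' the default mode because the assay reports per-dose responses, not fitted
#' curves.
#'
#' @param sample_id Sample identifier.
#' @param drug One of the toolkit drugs (see `BH3_DRUGS`).
#' @param induced Named numeric vector of true induced early-apoptotic
#'   fractions (0-1) by dose in nM, e.g. `c("0" = 0, "10" = 0.06,
#'   "100" = 0.49, "1000" = 0.754)`. Ignored when `hill` is given.
#' @param baseline Named fractions `c(alive=, early=, dead=)` of the vehicle
#'   well; must sum to 1.
#' @param hill Optional list `list(delta_max=, ec50_nM=, slope=)` for Hill-mode
#'   induction `delta_max * d^h / (ec50^h + d^h)`.
#' @param progression_rate Fraction of early-apoptotic cells that convert to
#'   dead between the 4 h read and the 24 h-later read.
#' @param attrition_24h Global fraction of cells lost between the two reads
#'   (thawing decline), applied to absolute counts only.
#' @return A `bh3_truth` object.
#' @export
dose_response_truth <- function(sample_id, drug,
                                induced = c("0" = 0),
                                baseline = c(alive = 0.90, early = 0.046, dead = 0.054),
                                hill = NULL,
                                progression_rate = 0.8,
                                attrition_24h = 0.16) {
  drug <- match.arg(drug, BH3_DRUGS)
  stopifnot(all(c("alive", "early", "dead") %in% names(baseline)))
  baseline <- baseline[c("alive", "early", "dead")]
  if (abs(sum(baseline) - 1) > 1e-8) {
    stop("baseline class fractions must sum to 1", call. = FALSE)
  }
  if (any(baseline < 0 | baseline > 1)) {
    stop("baseline fractions must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(hill)) {
    if (is.null(names(induced))) stop("`induced` must be named by dose in nM", call. = FALSE)
    if (any(induced < -1 | induced > 1)) {
      stop("induced fractions must lie in [-1, 1]", call. = FALSE)
    }
  } else {
    stopifnot(all(c("delta_max", "ec50_nM", "slope") %in% names(hill)))
  }
  structure(list(sample_id = sample_id, drug = drug, induced = induced,
                 baseline = baseline, hill = hill,
                 progression_rate = progression_rate,
                 attrition_24h = attrition_24h),
            class = "bh3_truth")
}

#' True induced early-apoptotic fraction at a dose
#' @param truth A [dose_response_truth()].
#' @param dose_nM Dose in nM.
#' @return Induced fraction (0-1).
#' @export
induced_fraction <- function(truth, dose_nM) {
  stopifnot(inherits(truth, "bh3_truth"))
  if (dose_nM == 0) return(0)
  if (!is.null(truth$hill)) {
    h <- truth$hill
    return(h$delta_max * dose_nM^h$slope / (h$ec50_nM^h$slope + dose_nM^h$slope))
  }
  key <- as.character(dose_nM)
  if (!key %in% names(truth$induced)) {
    stop("dose ", dose_nM, " nM not defined for sample '", truth$sample_id,
         "' / ", truth$drug, call. = FALSE)
  }
  unname(truth$induced[key])
}

#' True class fractions of a well
#'
#' Combines baseline fractions with dose-dependent induction and, for the
#' 24 h-later read, with early-to-dead progression. Induction converts alive
#' cells to early-apoptotic; progression converts early-apoptotic to dead.
#'
#' @inheritParams induced_fraction
#' @param timepoint_h 4 (profiling read) or 28 (the plate processed 24 h
#'   later).
#' @param extra_induced Additional induced fraction (replicate / batch /
#'   fresh-frozen perturbation), in fraction units; clipped into valid range
#'   with a warning when needed.
#' @return Named fractions `c(alive=, early=, dead=)` summing to 1.
#' @export
true_fractions <- function(truth, dose_nM, timepoint_h = 4, extra_induced = 0) {
  base <- truth$baseline
  ind <- induced_fraction(truth, dose_nM) + extra_induced
  if (ind < 0 || ind > base[["alive"]]) {
    warning("induced fraction ", signif(ind, 4), " outside [0, alive]; clipped",
            call. = FALSE)
    ind <- min(max(ind, 0), base[["alive"]])
  }
  early <- base[["early"]] + ind
  alive <- base[["alive"]] - ind
  dead <- base[["dead"]]
  if (timepoint_h > 4) {
    conv <- early * truth$progression_rate
    early <- early - conv
    dead <- dead + conv
  }
  c(alive = alive, early = early, dead = dead)
}

#' Variability model for the generator
#'
#' @param replicate_sd Between-replicate SD of the true induced fraction, in
#'   percentage points. The default (1.0) models technical well-to-well
#'   variation of replicate wells plated from one cell suspension;
#'   thaw-to-thaw biological variability of the control lines is larger (the
#'   assay's reported level is ~5 points for the BCL-2 control).
#' @param batch_shift_sd Between-batch shift SD (percentage points).
#' @param fresh_frozen_offset Additive offset applied to frozen-sample induced
#'   response (percentage points; negative lowers the frozen response).
#' @param rng_seed Integer seed; identical seeds reproduce identical event
#'   tables bit-for-bit.
#' @return A `bh3_variability` object.
#' @export
variability_model <- function(replicate_sd = 1.0, batch_shift_sd = 0,
                              fresh_frozen_offset = 0, rng_seed = NULL) {
  if (replicate_sd < 0 || batch_shift_sd < 0) {
    stop("variability SDs must be non-negative", call. = FALSE)
  }
  structure(list(replicate_sd = replicate_sd, batch_shift_sd = batch_shift_sd,
                 fresh_frozen_offset = fresh_frozen_offset, rng_seed = rng_seed),
            class = "bh3_variability")
}

# Draw n events from one population model; returns a tibble of raw-scale
# intensities. Fluorescence is Gaussian in arcsinh space, mapped back with
# cofactor * sinh(); scatter is Gaussian raw, floored at 1.
draw_population <- function(pop, n, cofactor = 150) {
  if (n == 0) {
    return(tibble::tibble(fsc = numeric(0), ssc = numeric(0),
                          annexin = numeric(0), viability_dye = numeric(0),
                          bead = numeric(0)))
  }
  fl <- lapply(c("annexin", "viability_dye", "bead"), function(ch) {
    cofactor * sinh(rnorm(n, pop$fluor_mean[[ch]], pop$fluor_sd[[ch]]))
  })
  sc <- lapply(c("fsc", "ssc"), function(ch) {
    pmax(rnorm(n, pop$scatter_mean[[ch]], pop$scatter_sd[[ch]]), 1)
  })
  tibble::tibble(fsc = sc[[1]], ssc = sc[[2]], annexin = fl[[1]],
                 viability_dye = fl[[2]], bead = fl[[3]])
}

#' Simulate one assay well
#'
#' Draws a per-well event table from the class mixture implied by the ground
#' truth at the well's dose and timepoint, plus a Poisson-sampled number of
#' counting-bead events. Every event carries its generating class in the
#' hidden `.truth_class` column; the true mixture weights and counts used are
#' attached as the `"truth"` attribute for recovery tests.
#'
#' @param spec A single-well spec (one row of a plate layout, or
#'   [well_spec()]); fields used: `well_id`, `dose_nM`, `timepoint_h`,
#'   `beads_added`.
#' @param truth A [dose_response_truth()] whose drug matches the well (vehicle
#'   wells may use any truth; their dose is 0).
#' @param populations Named list of [population_model()]s (default
#'   [default_population_models()]).
#' @param variability A [variability_model()]. When its `rng_seed` is set the
#'   RNG is seeded here, making the well fully reproducible.
#' @param n_events Number of cell + debris events acquired. Ignored when
#'   `true_cell_count` is given.
#' @param true_cell_count Optional true number of cells in the well; when
#'   given, the number of acquired cell events is Binomial(`true_cell_count`,
#'   `acquisition_fraction`) and bead events are Poisson with mean
#'   `beads_added * acquisition_fraction`, so bead-normalized estimates
#'   recover `true_cell_count`.
#' @param acquisition_fraction Fraction of well volume acquired.
#' @param debris_fraction Fraction of non-bead events that are debris.
#' @param replicate_effect Optional pre-drawn replicate perturbation of the
#'   induced fraction (fraction units); drawn from `replicate_sd` when `NULL`.
#' @param frozen Apply the fresh-frozen offset to the induced response.
#' @param cofactor arcsinh cofactor used when mapping transformed-space draws
#'   back to raw intensities.
#' @return An `EventTable`: tibble with columns `fsc, ssc, annexin,
#'   viability_dye, bead, .truth_class` and attributes `well_id` and `truth`
#'   (one-row tibble of the true fractions and counts used).
#' @export
simulate_well <- function(spec, truth,
                          populations = default_population_models(),
                          variability = variability_model(),
                          n_events = 20000,
                          true_cell_count = NULL,
                          acquisition_fraction = 0.6,
                          debris_fraction = 0.03,
                          replicate_effect = NULL,
                          frozen = FALSE,
                          cofactor = 150) {
  spec <- as.list(spec)
  if (!is.null(variability$rng_seed)) set.seed(variability$rng_seed)
  dose <- spec$dose_nM %||% 0
  tp <- spec$timepoint_h %||% 4
  beads_added <- spec$beads_added %||% 10000
  if (is.null(replicate_effect)) {
    replicate_effect <- rnorm(1, 0, variability$replicate_sd / 100)
  }
  extra <- replicate_effect + if (frozen) variability$fresh_frozen_offset / 100 else 0
  # replicate/frozen perturbations act on the induced response, so vehicle
  # wells (dose 0, no induction) are left at baseline
  if (dose == 0) extra <- 0
  fr <- true_fractions(truth, dose, tp, extra_induced = extra)

  if (!is.null(true_cell_count)) {
    if (tp > 4) true_cell_count <- round(true_cell_count * (1 - truth$attrition_24h))
    n_cells <- rbinom(1, round(true_cell_count), acquisition_fraction)
    n_debris <- rbinom(1, n_cells, debris_fraction / (1 - debris_fraction))
    n_events <- n_cells + n_debris
    bead_mean <- beads_added * acquisition_fraction
  } else {
    if (n_events <= 0) stop("n_events must be positive", call. = FALSE)
    n_cells <- round(n_events * (1 - debris_fraction))
    n_debris <- n_events - n_cells
    bead_mean <- beads_added * acquisition_fraction
  }
  n_beads <- rpois(1, bead_mean)
  n_class <- as.vector(rmultinom(1, n_cells, fr))
  names(n_class) <- names(fr)

  counts <- c(alive = n_class[["alive"]],
              early_apoptotic = n_class[["early"]],
              dead = n_class[["dead"]],
              debris = n_debris, bead = n_beads)
  parts <- lapply(names(counts), function(cl) {
    ev <- draw_population(populations[[cl]], counts[[cl]], cofactor = cofactor)
    ev$.truth_class <- rep(cl, counts[[cl]])
    ev
  })
  events <- dplyr::bind_rows(parts)
  events <- events[sample.int(nrow(events)), , drop = FALSE]

  truth_row <- tibble::tibble(
    well_id = spec$well_id %||% NA_character_,
    sample_id = truth$sample_id,
    drug = if (dose == 0) "vehicle" else truth$drug,
    dose_nM = dose, timepoint_h = tp,
    true_fraction_alive = fr[["alive"]],
    true_fraction_early = fr[["early"]],
    true_fraction_dead = fr[["dead"]],
    true_cell_count = if (!is.null(true_cell_count)) true_cell_count else n_cells,
    true_bead_count = n_beads)
  attr(events, "well_id") <- truth_row$well_id
  attr(events, "truth") <- truth_row
  events
}

#' Simulate a full plate
#'
#' One event table per well of the layout, each drawn under a deterministic
#' per-well seed derived from the variability model's `rng_seed`, plus a truth
#' table recording every true fraction and count used.
#'
#' @param layout A plate layout ([read_layout()] or [plate_layout()]).
#' @param truths Named list of [dose_response_truth()] keyed by
#'   `"sample_id"` or `"sample_id:drug"`; every treated well must resolve to a
#'   truth whose drug matches.
#' @param variability A [variability_model()]; its `rng_seed` (default 1)
#'   fixes the whole plate.
#' @param ... Passed to [simulate_well()] (e.g. `n_events`).
#' @return List with `events` (named list of event tables, one per well) and
#'   `truth` (tibble, one row per well).
#' @export
simulate_plate <- function(layout, truths, variability = variability_model(), ...) {
  wells <- if (inherits(layout, "bh3_layout")) layout$wells else layout
  if (anyDuplicated(wells$well_id)) {
    stop("duplicate well ids in layout: ",
         paste(unique(wells$well_id[duplicated(wells$well_id)]), collapse = ", "),
         call. = FALSE)
  }
  base_seed <- variability$rng_seed %||% 1L
  out <- vector("list", nrow(wells))
  names(out) <- wells$well_id
  truth_rows <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    tr <- resolve_truth(truths, w$sample_id, w$drug)
    vi <- variability
    vi$rng_seed <- base_seed + i
    out[[i]] <- simulate_well(w, tr, variability = vi, ...)
    truth_rows[[i]] <- attr(out[[i]], "truth")
  }
  list(events = out, truth = dplyr::bind_rows(truth_rows))
}

# Look up the truth for a sample/drug pair; vehicle wells may use any of the
# sample's truths (their dose is 0 so the drug never matters).
resolve_truth <- function(truths, sample_id, drug) {
  key <- paste0(sample_id, ":", drug)
  if (key %in% names(truths)) return(truths[[key]])
  if (sample_id %in% names(truths)) {
    tr <- truths[[sample_id]]
    if (drug != "vehicle" && tr$drug != drug) {
      stop("no dose-response truth for sample '", sample_id, "' and drug '",
           drug, "'", call. = FALSE)
    }
    return(tr)
  }
  if (drug == "vehicle") {
    hit <- grep(paste0("^", sample_id, ":"), names(truths), value = TRUE)
    if (length(hit) > 0) return(truths[[hit[1]]])
  }
  stop("no dose-response truth for sample '", sample_id, "' (drug '", drug,
       "')", call. = FALSE)
}

#' Ground truths of the internal control lines
#'
#' Per-dose induced early-apoptotic fractions of the three control lines for
#' their specific mimetic, set from the assay's printed 1 uM (and, where
#' printed, 10/100 nM) responses: OCI-Ly1 + venetoclax 75.4 points, JJN3 +
#' AZD-5991 55.4 points, HEL + A-1155463 69.1 points. Intermediate doses not
#' printed are filled with monotone plausible values.
#'
#' @return Named list of [dose_response_truth()] keyed `"sample:drug"`.
#' @export
control_line_truths <- function() {
  list(
    "OCI-Ly1:venetoclax" = dose_response_truth(
      "OCI-Ly1", "venetoclax",
      induced = c("0" = 0, "10" = 0.060, "100" = 0.490, "1000" = 0.754)),
    "JJN3:AZD-5991" = dose_response_truth(
      "JJN3", "AZD-5991",
      induced = c("0" = 0, "10" = 0.020, "100" = 0.180, "1000" = 0.554)),
    "HEL:A-1155463" = dose_response_truth(
      "HEL", "A-1155463",
      induced = c("0" = 0, "10" = 0.076, "100" = 0.350, "1000" = 0.691))
  )
}
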