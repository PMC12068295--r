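#' Annexin V single-positive percentage of a well
#'
#' The early-apoptotic (Annexin V-only positive) events as a percentage of the
#' well's cell denominator.
#'
#' @param q A `bh3_wellquant` from [classify_events()].
#' @return Percentage (0-100).
#' @export
annexin_fraction <- function(q) {
  stopifnot(inherits(q, "bh3_wellquant"))
  if (q$denominator <= 0) stop("no cell events in well", call. = FALSE)
  100 * q$counts[["n_early"]] / q$denominator
}

#' Delta Annexin V between treated and vehicle arms
#'
#' The assay's primary statistic: the difference in Annexin V single-positive
#' percentage between a mimetic-treated condition and its vehicle control.
#' With `paired = TRUE` (equal replicate counts, wells paired by position in
#' the vectors) per-replicate deltas are retained and summarized; the default
#' uses arm means.
#'
#' @param treated,vehicle Numeric vectors of per-replicate Annexin V
#'   percentages ([annexin_fraction()] outputs).
#' @param paired Pair replicates one-to-one instead of differencing arm means.
#' @param sample_id,drug,dose_nM,pretreatment Optional annotations carried to
#'   the output row.
#' @return One-row tibble: `delta_pct` (mean delta, percentage points), `sem`
#'   (over paired deltas when paired, else by error propagation across arms;
#'   `NA` when n < 2), `n_replicates`, and the per-replicate deltas in a list
#'   column `replicates` (paired mode).
#' @export
delta_annexin <- function(treated, vehicle, paired = FALSE,
                          sample_id = NA_character_, drug = NA_character_,
                          dose_nM = NA_real_, pretreatment = "none") {
  if (length(treated) < 1 || length(vehicle) < 1) {
    stop("each arm needs at least one replicate", call. = FALSE)
  }
  if (paired) {
    if (length(treated) != length(vehicle)) {
      stop("paired deltas need equal replicate counts (",
           length(treated), " vs ", length(vehicle), ")", call. = FALSE)
    }
    reps <- treated - vehicle
    n <- length(reps)
    delta <- mean(reps)
    sem <- if (n >= 2) sd(reps) / sqrt(n) else NA_real_
  } else {
    reps <- numeric(0)
    n <- min(length(treated), length(vehicle))
    delta <- mean(treated) - mean(vehicle)
    vt <- if (length(treated) >= 2) stats::var(treated) / length(treated) else NA_real_
    vv <- if (length(vehicle) >= 2) stats::var(vehicle) / length(vehicle) else NA_real_
    sem <- sqrt(vt + vv)
  }
  if (delta < -100 || delta > 100) stop("delta outside [-100, 100]", call. = FALSE)
  tibble::tibble(sample_id = sample_id, drug = drug, dose_nM = dose_nM,
                 pretreatment = pretreatment, delta_pct = delta, sem = sem,
                 n_replicates = n, replicates = list(reps))
}

#' Bead-normalized absolute cell counts
#'
#' Counting beads are spiked at a known number per well; the absolute number
#' of cells of each class is the observed class count scaled by
#' `beads_added / beads_observed`.
#'
#' @param q A `bh3_wellquant`.
#' @param beads_added Beads spiked into the well.
#' @param well_id Optional annotation.
#' @return One-row tibble with `cells_alive`, `cells_early`, `cells_dead`,
#'   `cells_total`, `beads_observed`, `beads_added`.
#' @export
absolute_count <- function(q, beads_added, well_id = NA_character_) {
  stopifnot(inherits(q, "bh3_wellquant"))
  nb <- q$counts[["n_beads"]]
  if (nb <= 0) {
    stop("no bead events observed: acquisition failure, cannot normalize",
         call. = FALSE)
  }
  f <- beads_added / nb
  tibble::tibble(well_id = well_id,
                 cells_alive = q$counts[["n_alive"]] * f,
                 cells_early = q$counts[["n_early"]] * f,
                 cells_dead = q$counts[["n_dead"]] * f,
                 cells_total = (q$counts[["n_alive"]] + q$counts[["n_early"]] +
                                  q$counts[["n_dead"]]) * f,
                 beads_observed = nb, beads_added = beads_added)
}

# Percentage of viable (alive) cells among intact cells, from either a
# bh3_wellquant or an absolute_count row.
viable_pct <- function(x) {
  if (inherits(x, "bh3_wellquant")) {
    if (x$denominator_kind != "intact_cells") {
      cnt <- x$counts
      denom <- cnt[["n_alive"]] + cnt[["n_early"]] + cnt[["n_dead"]]
      return(100 * cnt[["n_alive"]] / denom)
    }
    return(100 * x$frac_alive)
  }
  if (is.data.frame(x) && all(c("cells_alive", "cells_total") %in% names(x))) {
    return(100 * x$cells_alive / x$cells_total)
  }
  stop("expected a bh3_wellquant or an absolute_count row", call. = FALSE)
}

#' Delta cell death between control and treated condition
#'
#' Difference between the percentage of viable cells in the control and the
#' treated condition, in percentage points (positive = the treatment killed
#' cells).
#'
#' @param control,treated `bh3_wellquant` or [absolute_count()] rows of
#'   matched wells (same sample and timepoint).
#' @param control_timepoint_h,treated_timepoint_h Optional timepoints; when
#'   both given they must match.
#' @return Percentage points.
#' @export
delta_cell_death <- function(control, treated,
                             control_timepoint_h = NULL,
                             treated_timepoint_h = NULL) {
  if (!is.null(control_timepoint_h) && !is.null(treated_timepoint_h) &&
      control_timepoint_h != treated_timepoint_h) {
    stop("timepoint mismatch: control at ", control_timepoint_h,
         " h, treated at ", treated_timepoint_h, " h", call. = FALSE)
  }
  viable_pct(control) - viable_pct(treated)
}

#' Between-plate toxicity monitoring ratio
#'
#' Ratio of bead-normalized live counts between the later and the earlier
#' plate of the same condition; values well below 1 flag toxicity (or thawing
#' decline) between the reads.
#'
#' @param early_count,late_count [absolute_count()] rows of the same well
#'   condition on the two plates.
#' @return Dimensionless ratio `late / early` of live cells.
#' @export
toxicity_ratio <- function(early_count, late_count) {
  if (early_count$cells_alive <= 0) stop("no live cells in the early plate", call. = FALSE)
  late_count$cells_alive / early_count$cells_alive
}

#' Viability and cytotoxicity from CellTiter-Glo luminescence
#'
#' Normalizes treated luminescence to the matched dose-0 (vehicle) control of
#' the same sample (and pretreatment arm): viability = 100 x treated/control;
#' cytotoxicity = viability - 100 (signed, so near-complete kill reads
#' about -99).
#'
#' @param lum A luminescence table ([read_luminescence()]): columns
#'   `sample_id, drug, dose_nM, luminescence`, optional `pretreatment`.
#' @return Tibble with one row per treated (sample, pretreatment, drug, dose):
#'   `viability_pct`, `cytotoxicity_pct`.
#' @export
viability_from_ctg <- function(lum) {
  lum <- tibble::as_tibble(lum)
  if (!"pretreatment" %in% names(lum)) lum$pretreatment <- "none"
  ctrl <- lum |>
    dplyr::filter(.data$dose_nM == 0) |>
    dplyr::group_by(.data$sample_id, .data$pretreatment) |>
    dplyr::summarise(control_lum = mean(.data$luminescence), .groups = "drop")
  treated <- dplyr::filter(lum, .data$dose_nM > 0)
  out <- dplyr::left_join(treated, ctrl, by = c("sample_id", "pretreatment"))
  if (any(is.na(out$control_lum))) {
    miss <- unique(out$sample_id[is.na(out$control_lum)])
    stop("no dose-0 control luminescence for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(out$control_lum == 0)) {
    stop("zero control luminescence; cannot normalize", call. = FALSE)
  }
  out |>
    dplyr::group_by(.data$sample_id, .data$pretreatment, .data$drug, .data$dose_nM) |>
    dplyr::summarise(viability_pct = 100 * mean(.data$luminescence) /
                       .data$control_lum[1], .groups = "drop") |>
    dplyr::mutate(cytotoxicity_pct = .data$viability_pct - 100)
}

#' Quantify every well of a simulated or acquired plate
#'
#' Convenience wrapper: classifies each well under one gate and returns a
#' tidy per-well table joined to the layout metadata.
#'
#' @param events Named list of EventTables keyed by well id.
#' @param layout A `bh3_layout`.
#' @param gate A [gate_config()].
#' @return Tibble with one row per well: layout columns plus `annexin_pct`,
#'   class counts, and bead-normalized absolute counts.
#' @export
quantify_plate <- function(events, layout, gate = gate_config()) {
  wells <- layout$wells
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    w <- wells[i, ]
    ev <- events[[w$well_id]]
    if (is.null(ev)) stop("no events for well ", w$well_id, call. = FALSE)
    q <- classify_events(ev, gate)
    ac <- absolute_count(q, w$beads_added, well_id = w$well_id)
    dplyr::bind_cols(
      w,
      tibble::tibble(annexin_pct = annexin_fraction(q),
                     frac_alive = q$frac_alive, frac_dead = q$frac_dead,
                     n_alive = q$counts[["n_alive"]],
                     n_early = q$counts[["n_early"]],
                     n_dead = q$counts[["n_dead"]],
                     n_debris = q$counts[["n_debris"]],
                     n_beads = q$counts[["n_beads"]]),
      ac[, c("cells_alive", "cells_early", "cells_dead", "cells_total")])
  })
  dplyr::bind_rows(rows)
}
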