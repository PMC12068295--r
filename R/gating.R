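#' Gating configuration
#'
#' Holds the transform and the gate geometry used to classify events. The
#' default thresholds sit in the gap between the default synthetic negative
#' and positive populations; for real or re-parameterised data, fit them from
#' vehicle wells with [fit_thresholds()].
#'
#' @param transform `"arcsinh"` (default), `"log10"` or `"none"`, applied to
#'   fluorescence channels only; scatter stays raw.
#' @param cofactor arcsinh cofactor (default 150, conventional for
#'   conventional-flow fluorescence).
#' @param scatter_gate Named raw-scale bounds `c(fsc_lo=, fsc_hi=, ssc_lo=,
#'   ssc_hi=)`; events outside are debris.
#' @param bead_gate Bead-channel threshold in transformed units; events above
#'   are counting beads.
#' @param annexin_threshold,viability_threshold Transformed-intensity cutoffs;
#'   values at or below a cutoff are negative (tie rule).
#' @param threshold_source `"manual"`, `"robust_from_vehicle"` (default for
#'   fitting: median + z_q x MAD of pooled vehicle events, robust to the
#'   baseline apoptosis always present in vehicle wells) or
#'   `"quantile_from_vehicle"` (plain q-quantile; appropriate only when
#'   vehicle wells contain virtually no positives).
#' @param quantile_q Tail probability for fitted thresholds (default 0.995).
#' @param denominator `"intact_cells"` (alive + early + dead; default) or
#'   `"live_plus_early"` — the denominator used for class fractions.
#' @return A `bh3_gate` object.
#' @export
gate_config <- function(transform = c("arcsinh", "log10", "none"),
                        cofactor = 150,
                        scatter_gate = c(fsc_lo = 15000, fsc_hi = 2.5e5,
                                         ssc_lo = 0, ssc_hi = 2.5e5),
                        bead_gate = 3.0,
                        annexin_threshold = 2.0,
                        viability_threshold = 2.0,
                        threshold_source = c("manual", "robust_from_vehicle",
                                             "quantile_from_vehicle"),
                        quantile_q = 0.995,
                        denominator = c("intact_cells", "live_plus_early")) {
  transform <- match.arg(transform)
  threshold_source <- match.arg(threshold_source)
  denominator <- match.arg(denominator)
  if (cofactor <= 0) stop("cofactor must be positive", call. = FALSE)
  if (quantile_q <= 0 || quantile_q >= 1) {
    stop("quantile_q must lie strictly between 0 and 1", call. = FALSE)
  }
  thr <- c(bead_gate, annexin_threshold, viability_threshold, scatter_gate)
  if (any(!is.finite(thr))) stop("gate thresholds must be finite", call. = FALSE)
  structure(list(transform = transform, cofactor = cofactor,
                 scatter_gate = scatter_gate, bead_gate = bead_gate,
                 annexin_threshold = annexin_threshold,
                 viability_threshold = viability_threshold,
                 threshold_source = threshold_source, quantile_q = quantile_q,
                 denominator = denominator),
            class = "bh3_gate")
}

#' Transform fluorescence intensities
#'
#' Applies the configured transform to the fluorescence channels (`annexin`,
#' `viability_dye`, `bead`); scatter channels are left untransformed. The
#' arcsinh transform is `asinh(x / cofactor)` and is exactly invertible.
#'
#' @param events EventTable (raw intensities).
#' @param transform `"arcsinh"`, `"log10"` or `"none"`.
#' @param cofactor Positive arcsinh cofactor.
#' @return EventTable in transformed space.
#' @export
apply_transform <- function(events, transform = "arcsinh", cofactor = 150) {
  if (cofactor <= 0) stop("cofactor must be positive", call. = FALSE)
  fl <- intersect(c("annexin", "viability_dye", "bead"), names(events))
  for (ch in fl) {
    x <- events[[ch]]
    if (any(!is.finite(x))) stop("non-finite intensities in channel ", ch, call. = FALSE)
    events[[ch]] <- switch(transform,
                           arcsinh = asinh(x / cofactor),
                           log10 = log10(pmax(x, 1)),
                           none = x,
                           stop("unknown transform '", transform, "'", call. = FALSE))
  }
  events
}

#' Invert [apply_transform()]
#' @inheritParams apply_transform
#' @return EventTable on the raw intensity scale.
#' @export
invert_transform <- function(events, transform = "arcsinh", cofactor = 150) {
  fl <- intersect(c("annexin", "viability_dye", "bead"), names(events))
  for (ch in fl) {
    events[[ch]] <- switch(transform,
                           arcsinh = cofactor * sinh(events[[ch]]),
                           log10 = 10^events[[ch]],
                           none = events[[ch]])
  }
  events
}

# Masks on a transformed event table (internal). Tie rule everywhere:
# "> threshold" is positive, "<= threshold" is negative; scatter bounds are
# closed (inside includes the boundary).
gate_masks <- function(tev, gate) {
  sg <- gate$scatter_gate
  list(bead = tev$bead > gate$bead_gate,
       in_scatter = tev$fsc >= sg[["fsc_lo"]] & tev$fsc <= sg[["fsc_hi"]] &
         tev$ssc >= sg[["ssc_lo"]] & tev$ssc <= sg[["ssc_hi"]])
}

#' Fit Annexin V / 7AAD thresholds from vehicle wells
#'
#' Pools the scatter-gated, bead-excluded events of the vehicle wells and
#' places each fluorescence cutoff in the upper tail of the (negative-
#' dominated) vehicle distribution. `robust_from_vehicle` uses
#' median + z_q x MAD, which tolerates the baseline early-apoptotic and dead
#' events every vehicle well contains; `quantile_from_vehicle` uses the plain
#' q-quantile, which is only safe when fewer than `1 - q` of vehicle events
#' are genuinely positive.
#'
#' @param vehicle_wells A list of EventTables from vehicle wells (a single
#'   EventTable is accepted).
#' @param config A [gate_config()]; its `threshold_source` selects the rule
#'   (`"manual"` inputs default to `"robust_from_vehicle"` here).
#' @return The completed [gate_config()] with fitted `annexin_threshold` and
#'   `viability_threshold` (all manual fields preserved).
#' @export
fit_thresholds <- function(vehicle_wells, config = gate_config()) {
  if (is.data.frame(vehicle_wells)) vehicle_wells <- list(vehicle_wells)
  if (length(vehicle_wells) == 0) {
    stop("at least one vehicle well is required to fit thresholds", call. = FALSE)
  }
  pooled <- dplyr::bind_rows(lapply(vehicle_wells, function(e) {
    e[, intersect(BH3_CHANNELS, names(e)), drop = FALSE]
  }))
  tev <- apply_transform(pooled, config$transform, config$cofactor)
  m <- gate_masks(tev, config)
  usable <- tev[!m$bead & m$in_scatter, , drop = FALSE]
  if (nrow(usable) == 0) stop("no usable vehicle events after gating", call. = FALSE)
  if (nrow(usable) < 500) {
    warning("only ", nrow(usable), " usable vehicle events; thresholds may be unstable",
            call. = FALSE)
  }
  src <- config$threshold_source
  if (src == "manual") src <- "robust_from_vehicle"
  cut <- function(x) {
    if (src == "quantile_from_vehicle") {
      unname(quantile(x, config$quantile_q, names = FALSE))
    } else {
      median(x) + qnorm(config$quantile_q) * mad(x)
    }
  }
  config$annexin_threshold <- cut(usable$annexin)
  config$viability_threshold <- cut(usable$viability_dye)
  config$threshold_source <- src
  config
}

#' Classify events and quantify a well
#'
#' Classification order (each event gets exactly one class):
#' \enumerate{
#'   \item bead, if the bead channel exceeds the bead gate;
#'   \item debris, if outside the scatter gate;
#'   \item dead, if 7AAD-positive (regardless of Annexin V);
#'   \item early-apoptotic, if Annexin V-positive and 7AAD-negative;
#'   \item alive otherwise (double negative).
#' }
#' Values exactly at a threshold are negative. Fractions use the configured
#' cell denominator (default: intact cells = alive + early + dead).
#'
#' @param events EventTable (raw intensities; a `.truth_class` column is
#'   carried through untouched).
#' @param gate A complete [gate_config()].
#' @return A `bh3_wellquant`: list with `counts` (n_beads, n_debris, n_alive,
#'   n_early, n_dead), `total_events`, `frac_alive`, `frac_early`,
#'   `frac_dead`, `denominator`, `all_beads` flag and the per-event `classes`
#'   vector.
#' @export
classify_events <- function(events, gate = gate_config()) {
  if (nrow(events) == 0) stop("empty event table", call. = FALSE)
  tev <- apply_transform(events[, intersect(BH3_CHANNELS, names(events)), drop = FALSE],
                         gate$transform, gate$cofactor)
  m <- gate_masks(tev, gate)
  cls <- rep("alive", nrow(tev))
  dead <- tev$viability_dye > gate$viability_threshold
  early <- tev$annexin > gate$annexin_threshold & !dead
  cls[early] <- "early_apoptotic"
  cls[dead] <- "dead"
  cls[!m$in_scatter] <- "debris"
  cls[m$bead] <- "bead"

  counts <- c(n_beads = sum(m$bead),
              n_debris = sum(cls == "debris"),
              n_alive = sum(cls == "alive"),
              n_early = sum(cls == "early_apoptotic"),
              n_dead = sum(cls == "dead"))
  all_beads <- counts[["n_beads"]] == nrow(tev)
  if (all_beads) warning("all events classified as beads", call. = FALSE)
  denom <- switch(gate$denominator,
                  intact_cells = counts[["n_alive"]] + counts[["n_early"]] + counts[["n_dead"]],
                  live_plus_early = counts[["n_alive"]] + counts[["n_early"]])
  frac <- function(n) if (denom > 0) n / denom else NA_real_
  structure(list(counts = counts, total_events = nrow(tev),
                 frac_alive = frac(counts[["n_alive"]]),
                 frac_early = frac(counts[["n_early"]]),
                 frac_dead = if (gate$denominator == "intact_cells")
                   frac(counts[["n_dead"]]) else NA_real_,
                 denominator = denom, denominator_kind = gate$denominator,
                 all_beads = all_beads, classes = cls),
            class = "bh3_wellquant")
}

#' @export
print.bh3_wellquant <- function(x, ...) {
  cat("Well quantification (", x$total_events, " events)\n", sep = "")
  print(x$counts)
  cat(sprintf("fractions over %s (n=%d): alive %.3f, early %.3f, dead %s\n",
              x$denominator_kind, x$denominator, x$frac_alive, x$frac_early,
              ifelse(is.na(x$frac_dead), "-", sprintf("%.3f", x$frac_dead))))
  invisible(x)
}

#' Serialize / restore a gate configuration
#' @param gate A [gate_config()].
#' @param path YAML path.
#' @return `path` invisibly; `read_gate()` returns the `bh3_gate`.
#' @export
write_gate <- function(gate, path) {
  obj <- unclass(gate)
  obj$scatter_gate <- as.list(obj$scatter_gate)  # keep bound names in YAML
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_gate
#' @export
read_gate <- function(path) {
  y <- yaml::read_yaml(path)
  gate_config(transform = y$transform, cofactor = y$cofactor,
              scatter_gate = unlist(y$scatter_gate), bead_gate = y$bead_gate,
              annexin_threshold = y$annexin_threshold,
              viability_threshold = y$viability_threshold,
              threshold_source = y$threshold_source, quantile_q = y$quantile_q,
              denominator = y$denominator)
}
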