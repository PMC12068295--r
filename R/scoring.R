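#' Reference responses of the internal control lines
#'
#' Expected 1 uM delta Annexin V responses and thaw-to-thaw standard
#' deviations of the three internal-control cell lines, each paired with the
#' mimetic specific for its anti-apoptotic target: OCI-Ly1 (BCL-2,
#' venetoclax) 75.4 +/- 5.0; JJN3 (MCL-1, AZD-5991) 55.4 +/- 7.7; HEL
#' (BCL-XL, A-1155463) 69.1 +/- 5.9 percentage points.
#'
#' @param acceptance_k Half-width multiplier of the QC acceptance interval
#'   `mean +/- k x SD` (default 2).
#' @return Tibble with columns `cell_line, target, drug,
#'   reference_mean_delta, reference_sd, acceptance_k`.
#' @export
default_control_references <- function(acceptance_k = 2) {
  tibble::tibble(
    cell_line = c("OCI-Ly1", "JJN3", "HEL"),
    target = c("BCL-2", "MCL-1", "BCL-XL"),
    drug = c("venetoclax", "AZD-5991", "A-1155463"),
    reference_mean_delta = c(75.4, 55.4, 69.1),
    reference_sd = c(5.0, 7.7, 5.9),
    acceptance_k = acceptance_k)
}

#' Anti-apoptotic dependency score
#'
#' Normalizes a sample's 1 uM delta Annexin V to the matched internal
#' control so that the control response defines 100. Two published-compatible
#' variants of the MCL-1 axis are provided because the MCL-1 control (JJN3)
#' has the weakest response of the three lines:
#' \describe{
#'   \item{`"weighted"` (default)}{MCL-1 score = 100 x sample_delta / 30,
#'     i.e. the control denominator is replaced by a fixed weight of 30.}
#'   \item{`"ratio"`}{MCL-1 score = 100 x sample_delta / control_delta, like
#'     the other two axes.}
#' }
#' BCL-2 and BCL-XL scores are always 100 x sample_delta / control_delta.
#' Negative sample deltas clip to 0 (a radar axis cannot be negative); the
#' signed value belongs in the delta tables, not in scores.
#'
#' @param sample_delta_1uM Sample delta Annexin V at 1 uM (percentage points).
#' @param control_delta_1uM Matched control line's delta at 1 uM.
#' @param target `"BCL-2"`, `"MCL-1"` or `"BCL-XL"`.
#' @param mcl1_weight Fixed MCL-1 denominator (default 30).
#' @param formula_variant `"weighted"` or `"ratio"`.
#' @return Dimensionless score (>= 0; matched control scores 100 on ratio
#'   axes).
#' @export
dependency_score <- function(sample_delta_1uM, control_delta_1uM, target,
                             mcl1_weight = 30,
                             formula_variant = c("weighted", "ratio")) {
  target <- match.arg(target, BH3_TARGETS)
  formula_variant <- match.arg(formula_variant)
  denom <- if (target == "MCL-1" && formula_variant == "weighted") {
    if (mcl1_weight <= 0) stop("mcl1_weight must be positive", call. = FALSE)
    mcl1_weight
  } else {
    if (is.na(control_delta_1uM) || control_delta_1uM <= 0) {
      stop("non-positive control delta for ", target,
           "; review control-line QC before scoring", call. = FALSE)
    }
    control_delta_1uM
  }
  if (sample_delta_1uM < 0) {
    message("negative sample delta (", signif(sample_delta_1uM, 4),
            ") clipped to score 0 for ", target)
    return(0)
  }
  100 * sample_delta_1uM / denom
}

#' Dependency profile of one sample
#'
#' Computes the three dependency scores (BCL-2, MCL-1, BCL-XL) of a sample
#' from its 1 uM delta Annexin V values and the control lines measured in the
#' same run. The navitoclax delta, when present, is carried as an
#' overall-priming annotation (BCL-2/BCL-XL/BCL-W pan-inhibition) and never
#' scored.
#'
#' @param deltas Delta Annexin V table of the sample (columns `drug`,
#'   `dose_nM`, `delta_pct`); scores use the 1 uM rows.
#' @param control_deltas Delta table of the control lines at 1 uM (columns
#'   `sample_id`, `drug`, `delta_pct`).
#' @param refs Control reference table ([default_control_references()]) —
#'   defines which cell line controls which axis.
#' @param mcl1_weight,formula_variant Passed to [dependency_score()].
#' @param sample_id Annotation.
#' @return A `bh3_profile`: list with `sample_id`, `scores` (named numeric:
#'   `BCL2_score`, `MCL1_score`, `BCLXL_score`), `navitoclax_delta`,
#'   `control_deltas`, `mcl1_weight`, `formula_variant`.
#' @export
profile_sample <- function(deltas, control_deltas,
                           refs = default_control_references(),
                           mcl1_weight = 30,
                           formula_variant = c("weighted", "ratio"),
                           sample_id = deltas$sample_id[1]) {
  formula_variant <- match.arg(formula_variant)
  get_delta <- function(tab, drug, dose = 1000, who = "sample") {
    rows <- tab[tab$drug == drug & tab$dose_nM == dose, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_real_)
    mean(rows$delta_pct)
  }
  scores <- numeric(0)
  ctrl_used <- numeric(0)
  for (i in seq_len(nrow(refs))) {
    target <- refs$target[i]
    drug <- refs$drug[i]
    line <- refs$cell_line[i]
    sdelta <- get_delta(deltas, drug)
    if (is.na(sdelta)) {
      stop("sample has no 1 uM measurement for ", drug, " (", target, " axis)",
           call. = FALSE)
    }
    crows <- control_deltas[control_deltas$sample_id == line &
                              control_deltas$drug == drug &
                              control_deltas$dose_nM == 1000, , drop = FALSE]
    if (nrow(crows) == 0 && !(target == "MCL-1" && formula_variant == "weighted")) {
      stop("no ", target, " control (", line, ") on plate", call. = FALSE)
    }
    cdelta <- if (nrow(crows) > 0) mean(crows$delta_pct) else NA_real_
    key <- paste0(gsub("-", "", target), "_score")
    scores[key] <- dependency_score(sdelta, cdelta, target,
                                    mcl1_weight = mcl1_weight,
                                    formula_variant = formula_variant)
    ctrl_used[target] <- cdelta
  }
  structure(list(sample_id = sample_id, scores = scores,
                 navitoclax_delta = get_delta(deltas, "navitoclax"),
                 control_deltas = ctrl_used,
                 mcl1_weight = mcl1_weight, formula_variant = formula_variant),
            class = "bh3_profile")
}

#' @export
print.bh3_profile <- function(x, ...) {
  cat("Dependency profile for", x$sample_id, "\n")
  print(round(x$scores, 1))
  cat("MCL-1 formula:", x$formula_variant, "(weight", x$mcl1_weight, ")\n")
  if (!is.na(x$navitoclax_delta)) {
    cat("overall priming (navitoclax delta, not scored):",
        round(x$navitoclax_delta, 1), "points\n")
  }
  invisible(x)
}

#' Dynamic profiling shifts
#'
#' For each (drug, dose) measured in both arms, the change in delta Annexin V
#' caused by the 20 h pre-treatment: shift = delta(pre-treated) -
#' delta(vehicle-pre-treated), sign preserved (a pre-treatment can also lower
#' a dependency). Pairs present in only one arm are skipped with a warning.
#'
#' @param vehicle_arm,treated_arm Delta Annexin V tables (columns `drug`,
#'   `dose_nM`, `delta_pct`, optionally `sample_id`).
#' @param pretreatment_name Annotation for the output.
#' @return Tibble: `sample_id, pretreatment_name, drug, dose_nM, shift_pct`.
#' @export
dynamic_shift <- function(vehicle_arm, treated_arm, pretreatment_name = NA_character_) {
  key <- function(t) paste(t$drug, t$dose_nM)
  veh <- tibble::as_tibble(vehicle_arm)
  trt <- tibble::as_tibble(treated_arm)
  unmatched <- union(setdiff(key(veh), key(trt)), setdiff(key(trt), key(veh)))
  if (length(unmatched) > 0) {
    warning("skipping conditions measured in only one arm: ",
            paste(unmatched, collapse = "; "), call. = FALSE)
  }
  agg <- function(t) {
    dplyr::summarise(dplyr::group_by(t, .data$drug, .data$dose_nM),
                     delta_pct = mean(.data$delta_pct), .groups = "drop")
  }
  j <- dplyr::inner_join(agg(veh), agg(trt), by = c("drug", "dose_nM"),
                         suffix = c("_vehicle", "_treated"))
  tibble::tibble(
    sample_id = veh$sample_id[1] %||% NA_character_,
    pretreatment_name = pretreatment_name,
    drug = j$drug, dose_nM = j$dose_nM,
    shift_pct = j$delta_pct_treated - j$delta_pct_vehicle)
}

#' Internal-control batch QC
#'
#' A control-line batch passes when at least two vials were tested and the
#' mean 1 uM delta Annexin V falls inside the closed acceptance interval
#' `reference_mean +/- k x reference_sd` (boundary values pass). When vials
#' from two or more batches are supplied, the between- and within-batch
#' standard deviations are estimated by one-way random-effects
#' method-of-moments (expected mean squares of `aov`).
#'
#' @param vial_deltas Numeric vector of per-vial delta Annexin V values at
#'   1 uM.
#' @param ref One row of [default_control_references()] for the line under
#'   test.
#' @param batch_ids Optional vector (same length) assigning vials to batches.
#' @param acceptance_k Override of the reference's `k`.
#' @return A `bh3_qc`: list with `cell_line`, `mean`, `n_vials`, `pass`,
#'   `reason`, `lower`, `upper`, `inter_batch_sd`, `intra_batch_sd`.
#' @export
qc_check <- function(vial_deltas, ref, batch_ids = NULL, acceptance_k = NULL) {
  if (length(vial_deltas) < 1) stop("at least one vial response required", call. = FALSE)
  ref <- as.list(ref)
  k <- acceptance_k %||% ref$acceptance_k %||% 2
  lo <- ref$reference_mean_delta - k * ref$reference_sd
  hi <- ref$reference_mean_delta + k * ref$reference_sd
  m <- mean(vial_deltas)
  n <- length(vial_deltas)
  if (n < 2) {
    pass <- FALSE; reason <- "n_vials < 2"
  } else if (m >= lo && m <= hi) {
    pass <- TRUE; reason <- "within range"
  } else {
    pass <- FALSE
    reason <- sprintf("mean %.1f outside [%.1f, %.1f]", m, lo, hi)
  }
  inter <- intra <- NA_real_
  if (!is.null(batch_ids) && length(unique(batch_ids)) >= 2) {
    vc <- batch_variance_components(vial_deltas, batch_ids)
    inter <- vc[["inter_batch_sd"]]; intra <- vc[["intra_batch_sd"]]
  }
  structure(list(cell_line = ref$cell_line, mean = m, n_vials = n,
                 pass = pass, reason = reason, lower = lo, upper = hi,
                 inter_batch_sd = inter, intra_batch_sd = intra),
            class = "bh3_qc")
}

#' One-way random-effects variance components
#'
#' Method-of-moments estimates from the one-way ANOVA expected mean squares:
#' `sigma2_within = MSW`, `sigma2_between = (MSB - MSW) / n0` with `n0` the
#' effective per-group size for unbalanced data; negative between-group
#' estimates truncate to 0.
#'
#' @param values Numeric responses.
#' @param groups Group (batch) assignment.
#' @return Named vector `c(inter_batch_sd=, intra_batch_sd=)`.
#' @export
batch_variance_components <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two batches", call. = FALSE)
  fit <- aov(values ~ groups)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  ni <- as.vector(table(groups))
  n0 <- (sum(ni) - sum(ni^2) / sum(ni)) / (nlevels(groups) - 1)
  c(inter_batch_sd = sqrt(max((msb - msw) / n0, 0)),
    intra_batch_sd = sqrt(msw))
}

#' @export
print.bh3_qc <- function(x, ...) {
  cat(sprintf("QC %s: mean %.1f over %d vials -> %s (%s; range [%.1f, %.1f])\n",
              x$cell_line, x$mean, x$n_vials,
              if (x$pass) "PASS" else "FAIL", x$reason, x$lower, x$upper))
  if (!is.na(x$inter_batch_sd)) {
    cat(sprintf("  inter-batch SD %.2f, intra-batch SD %.2f\n",
                x$inter_batch_sd, x$intra_batch_sd))
  }
  invisible(x)
}
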