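#' Build a single well specification
#'
#' @param well_id Plate position, row letter + column number (e.g. `"A1"`;
#'   case-insensitive).
#' @param sample_id Sample identifier.
#' @param drug Toolkit drug or `"vehicle"`.
#' @param dose_nM Dose in nM; must be 0 iff `drug == "vehicle"`.
#' @param sample_kind `"primary"` or `"control_line"`.
#' @param control_target For control lines, the targeted anti-apoptotic
#'   protein (`"BCL-2"`, `"MCL-1"`, `"BCL-XL"`).
#' @param pretreatment `"none"`, `"vehicle"` or `"drug_of_interest"`.
#' @param pretreatment_name Name of the pre-treatment drug, when any.
#' @param timepoint_h Hours after toolkit addition: 4 (profiling plate) or 28
#'   (the plate processed 24 h later); aliases `"4h"` and `"24h-later"`.
#' @param cells_seeded Cells seeded per well.
#' @param beads_added Counting beads added per well.
#' @param plate_id Plate identifier.
#' @return One-row tibble.
#' @export
well_spec <- function(well_id, sample_id, drug, dose_nM,
                      sample_kind = "primary", control_target = NA_character_,
                      pretreatment = "none", pretreatment_name = NA_character_,
                      timepoint_h = 4, cells_seeded = 20000,
                      beads_added = 10000, plate_id = "P1") {
  tibble::tibble(plate_id = plate_id, well_id = toupper(well_id),
                 sample_id = sample_id, sample_kind = sample_kind,
                 control_target = control_target, drug = drug,
                 dose_nM = as.numeric(dose_nM), pretreatment = pretreatment,
                 pretreatment_name = pretreatment_name,
                 timepoint_h = normalize_timepoint(timepoint_h),
                 cells_seeded = cells_seeded, beads_added = beads_added)
}

normalize_timepoint <- function(tp) {
  if (is.character(tp)) {
    tp <- switch(tolower(tp), "4h" = 4, "24h-later" = 28, suppressWarnings(as.numeric(tp)))
  }
  as.numeric(tp)
}

#' Assemble and validate a plate layout
#'
#' @param wells Tibble of well specs (rows as produced by [well_spec()]).
#' @param channel_map Named logical-to-physical channel map covering
#'   `fsc, ssc, annexin, viability_dye, bead`.
#' @param bead_lot Optional list `list(concentration_per_ul=, volume_ul=)`;
#'   used to fill missing `beads_added` as concentration x volume. There is no
#'   default concentration — wells without `beads_added` require a bead lot.
#' @param allow_custom_doses Accept doses outside the assay grid
#'   `{0, 10, 100, 1000}` nM.
#' @return A `bh3_layout` object (list with `wells`, `channel_map`,
#'   `bead_lot`).
#' @export
plate_layout <- function(wells, channel_map = default_channel_map(),
                         bead_lot = NULL, allow_custom_doses = FALSE) {
  wells <- tibble::as_tibble(wells)
  need <- c("well_id", "sample_id", "drug", "dose_nM")
  missing_cols <- setdiff(need, names(wells))
  if (length(missing_cols) > 0) {
    stop("layout is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"plate_id" %in% names(wells)) wells$plate_id <- "P1"
  if (!"sample_kind" %in% names(wells)) wells$sample_kind <- "primary"
  if (!"control_target" %in% names(wells)) wells$control_target <- NA_character_
  if (!"pretreatment" %in% names(wells)) wells$pretreatment <- "none"
  if (!"pretreatment_name" %in% names(wells)) wells$pretreatment_name <- NA_character_
  if (!"timepoint_h" %in% names(wells)) wells$timepoint_h <- 4
  if (!"cells_seeded" %in% names(wells)) wells$cells_seeded <- 20000
  wells$well_id <- toupper(as.character(wells$well_id))
  wells$dose_nM <- as.numeric(wells$dose_nM)
  wells$timepoint_h <- vapply(wells$timepoint_h, normalize_timepoint, 0,
                              USE.NAMES = FALSE)
  if (!"beads_added" %in% names(wells)) wells$beads_added <- NA_real_
  fill <- is.na(wells$beads_added)
  if (any(fill)) {
    if (is.null(bead_lot)) {
      stop("wells without `beads_added` require a bead lot ",
           "(concentration_per_ul and volume_ul)", call. = FALSE)
    }
    wells$beads_added[fill] <- bead_lot$concentration_per_ul * bead_lot$volume_ul
  }

  probs <- character(0)
  bad <- function(mask, what) {
    if (any(mask)) {
      probs <<- c(probs, paste0(what, ": ",
                                paste(wells$well_id[mask], collapse = ", ")))
    }
  }
  dup <- duplicated(paste(wells$plate_id, wells$well_id))
  bad(dup, "duplicate well id")
  bad(!grepl("^[A-H]([1-9]|1[0-9]|2[0-4])$", wells$well_id), "malformed well id")
  bad(!wells$drug %in% BH3_DRUGS, "unknown drug")
  bad((wells$dose_nM == 0) != (wells$drug == "vehicle"),
      "dose 0 iff vehicle violated")
  if (!allow_custom_doses) {
    bad(!wells$dose_nM %in% BH3_DOSES, "dose outside {0,10,100,1000} nM")
  }
  bad(!wells$sample_kind %in% c("primary", "control_line"), "unknown sample_kind")
  bad((wells$sample_kind == "control_line") != !is.na(wells$control_target),
      "control_target defined iff control_line")
  bad(!is.na(wells$control_target) & !wells$control_target %in% BH3_TARGETS,
      "unknown control_target")
  bad(!wells$pretreatment %in% c("none", "vehicle", "drug_of_interest"),
      "unknown pretreatment")
  bad(!wells$timepoint_h %in% c(4, 24, 28, 48), "unknown timepoint")
  if (length(probs) > 0) {
    stop("invalid plate layout:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  miss_ch <- setdiff(BH3_CHANNELS, names(channel_map))
  if (length(miss_ch) > 0) {
    stop("channel_map missing logical channels: ",
         paste(miss_ch, collapse = ", "), call. = FALSE)
  }
  structure(list(wells = wells, channel_map = channel_map, bead_lot = bead_lot),
            class = "bh3_layout")
}

#' Read a plate layout from YAML
#'
#' Schema: top-level keys `plate_id` (optional), `channel_map` (logical name
#' to physical `$PnN` name), `bead_lot` (`concentration_per_ul`, `volume_ul`),
#' `wells` (list of well records with the [well_spec()] fields). Validation is
#' total: every enum and invariant is checked and all offending wells are
#' listed before anything reaches downstream modules.
#'
#' @param path YAML file.
#' @param allow_custom_doses Accept doses outside the assay grid.
#' @return A `bh3_layout`.
#' @export
read_layout <- function(path, allow_custom_doses = FALSE) {
  y <- yaml::read_yaml(path)
  if (is.null(y$wells) || length(y$wells) == 0) {
    stop("layout file has no wells: ", path, call. = FALSE)
  }
  wells <- dplyr::bind_rows(lapply(y$wells, function(w) {
    tibble::as_tibble(lapply(w, function(x) if (is.null(x)) NA else x))
  }))
  if (!is.null(y$plate_id) && !"plate_id" %in% names(wells)) {
    wells$plate_id <- y$plate_id
  }
  cm <- if (!is.null(y$channel_map)) unlist(y$channel_map) else default_channel_map()
  plate_layout(wells, channel_map = cm, bead_lot = y$bead_lot,
               allow_custom_doses = allow_custom_doses)
}

#' Read per-well events into the pipeline's data model
#'
#' Accepts FCS 3.0/3.1 or the package's CSV event dialect (one row per event,
#' header = channel names). Physical channel names are translated to the five
#' logical channels through `channel_map`; a CSV already using logical names
#' needs no mapping.
#'
#' @param path Event file.
#' @param channel_map Named logical-to-physical map.
#' @return EventTable tibble with logical channel columns; CSV sidecar truth
#'   labels (`<path>_truth.csv`), when present, are attached as a
#'   `.truth_class` column.
#' @export
read_events <- function(path, channel_map = default_channel_map()) {
  is_fcs <- grepl("\\.fcs$", path, ignore.case = TRUE) ||
    identical(substr(readChar(path, 3, useBytes = TRUE), 1, 3), "FCS")
  raw <- if (is_fcs) {
    read_fcs(path)
  } else {
    tibble::as_tibble(read.csv(path, check.names = FALSE))
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (ch in BH3_CHANNELS) {
    phys <- channel_map[[ch]]
    col <- if (ch %in% names(raw)) ch else phys
    if (is.null(col) || !col %in% names(raw)) {
      stop("event file ", path, " lacks a channel for '", ch, "'",
           if (!is.null(phys)) paste0(" (expected '", phys, "')"),
           call. = FALSE)
    }
    out[[ch]] <- as.numeric(raw[[col]])
  }
  if (".truth_class" %in% names(raw)) out$.truth_class <- raw$.truth_class
  sidecar <- sub("\\.[^.]+$", "_truth.csv", path)
  if (!".truth_class" %in% names(out) && file.exists(sidecar)) {
    lab <- read.csv(sidecar)
    if (nrow(lab) == nrow(out)) out$.truth_class <- lab$X__truth_class %||% lab[[1]]
  }
  if (is_fcs) {
    tot <- as.integer(attr(raw, "keywords")[["$TOT"]])
    if (!is.na(tot) && tot != nrow(out)) {
      stop("FCS $TOT (", tot, ") does not match events read (", nrow(out), ")",
           call. = FALSE)
    }
  }
  out
}

#' Write events as CSV, with ground-truth labels in a sidecar
#'
#' The main file holds only channel intensities (header = logical channel
#' names); hidden generator labels, when present, go to
#' `<path minus extension>_truth.csv` with a single `__truth_class` column, so
#' labels can never leak into an analysis that reads only the event file.
#'
#' @param events EventTable.
#' @param path Output CSV path.
#' @param sidecar Write the truth sidecar when labels are present.
#' @return `path`, invisibly.
#' @export
write_csv_events <- function(events, path, sidecar = TRUE) {
  if (nrow(events) == 0) stop("cannot write an empty event table", call. = FALSE)
  chans <- intersect(BH3_CHANNELS, names(events))
  write.csv(events[, chans, drop = FALSE], path, row.names = FALSE)
  if (sidecar && ".truth_class" %in% names(events)) {
    sc <- sub("\\.[^.]+$", "_truth.csv", path)
    write.csv(data.frame(`__truth_class` = events$.truth_class,
                         check.names = FALSE),
              sc, row.names = FALSE)
  }
  invisible(path)
}

#' Read a CellTiter-Glo luminescence table
#'
#' CSV with columns `well_id, sample_id, drug, dose_nM, luminescence` and
#' optional `pretreatment`.
#'
#' @param path CSV file.
#' @return Validated tibble.
#' @export
read_luminescence <- function(path) {
  x <- tibble::as_tibble(read.csv(path))
  need <- c("well_id", "sample_id", "drug", "dose_nM", "luminescence")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("luminescence table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"pretreatment" %in% names(x)) x$pretreatment <- "none"
  if (any(x$luminescence < 0)) {
    stop("negative luminescence in wells: ",
         paste(x$well_id[x$luminescence < 0], collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a pipeline output table
#'
#' CSV and JSON serializations round-trip losslessly (full double precision).
#'
#' @param table Any pipeline output table (data frame).
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, format = NULL) {
  format <- format %||% tolower(sub(".*\\.", "", path))
  if (format == "csv") {
    write.csv(table, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    stop("unknown report format '", format, "'", call. = FALSE)
  }
  invisible(path)
}

#' Read back a table written by [write_report()]
#' @param path CSV or JSON file.
#' @param format `"csv"` or `"json"` (default from the extension).
#' @return Tibble.
#' @export
read_report <- function(path, format = NULL) {
  format <- format %||% tolower(sub(".*\\.", "", path))
  if (format == "csv") {
    tibble::as_tibble(read.csv(path))
  } else if (format == "json") {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    stop("unknown report format '", format, "'", call. = FALSE)
  }
}
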