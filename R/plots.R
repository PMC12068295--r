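# Report rendering: radar charts of dependency profiles and delta Annexin V
# heatmaps. Every renderer also writes the plotted numbers as a CSV sidecar
# (same path with `_data.csv`), and is a pure function of its inputs so
# reruns produce identical files.

radar_axes <- c("BCL-2", "MCL-1", "BCL-XL")

profile_to_axes <- function(profile, arm = "sample") {
  if (inherits(profile, "bh3_profile")) {
    tibble::tibble(arm = arm, axis = radar_axes,
                   value = unname(profile$scores[c("BCL2_score", "MCL1_score",
                                                   "BCLXL_score")]))
  } else {
    df <- tibble::as_tibble(profile)
    stopifnot(all(c("axis", "value") %in% names(df)))
    if (!"arm" %in% names(df)) df$arm <- arm
    df[, c("arm", "axis", "value")]
  }
}

open_device <- function(path, width = 6, height = 6) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 100, height = height * 100, res = 100),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported plot format '", ext, "'", call. = FALSE))
}

sidecar_path <- function(path) sub("\\.[^.]+$", "_data.csv", path)

#' Render a dependency-score radar chart
#'
#' Three axes (BCL-2, MCL-1, BCL-XL) on a polar layout with the internal
#' control response drawn as the dotted reference polygon at score 100. Two
#' or more overlaid polygons (e.g. vehicle vs pre-treated arms in dynamic
#' mode) are supported by passing a named list of profiles; legend order
#' follows list order.
#'
#' @param profile A `bh3_profile`, a named list of them (one polygon each),
#'   or a tibble with columns `axis`, `value` and optional `arm`.
#' @param path Output file (`.svg`, `.png` or `.pdf`); the plotted numbers go
#'   to `<path>_data.csv`.
#' @param reference Reference level drawn as the dotted polygon (default 100
#'   = matched control response).
#' @return `path`, invisibly.
#' @export
render_radar <- function(profile, path, reference = 100) {
  if (is.list(profile) && !inherits(profile, "bh3_profile") &&
      !is.data.frame(profile)) {
    arms <- names(profile) %||% paste0("arm", seq_along(profile))
    df <- dplyr::bind_rows(Map(profile_to_axes, profile, arms))
  } else {
    df <- profile_to_axes(profile)
  }
  if (!all(radar_axes %in% df$axis)) {
    stop("radar chart needs all three axes (",
         paste(setdiff(radar_axes, df$axis), collapse = ", "), " missing)",
         call. = FALSE)
  }
  df$axis <- factor(df$axis, levels = radar_axes)
  df$arm <- factor(df$arm, levels = unique(df$arm))
  ref <- tibble::tibble(axis = factor(radar_axes, levels = radar_axes),
                        value = reference)
  # close the polygons by repeating the first vertex
  close_poly <- function(d) dplyr::bind_rows(d, d[d$axis == radar_axes[1], ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis, y = .data$value,
                                        group = .data$arm, colour = .data$arm,
                                        fill = .data$arm)) +
    ggplot2::geom_polygon(data = close_poly(ref),
                          ggplot2::aes(x = .data$axis, y = .data$value, group = 1),
                          inherit.aes = FALSE,
                          colour = "grey30", fill = NA, linetype = "dotted") +
    ggplot2::geom_polygon(alpha = 0.25) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, max(df$value, reference) * 1.05) +
    ggplot2::labs(x = NULL, y = "dependency score",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  open_device(path)
  print(p)
  grDevices::dev.off()
  write.csv(df[, c("arm", "axis", "value")], sidecar_path(path), row.names = FALSE)
  invisible(path)
}

#' Render a delta Annexin V heatmap
#'
#' Drug x dose grid per sample with a fixed colour scale over [0, 100]
#' percentage points; incomplete grids render missing cells blank with a
#' warning.
#'
#' @param delta_table Tibble with columns `sample_id, drug, dose_nM,
#'   delta_pct`.
#' @param path Output file (`.svg`, `.png` or `.pdf`); numbers go to
#'   `<path>_data.csv`.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(delta_table, path) {
  df <- tibble::as_tibble(delta_table)
  stopifnot(all(c("sample_id", "drug", "dose_nM", "delta_pct") %in% names(df)))
  full <- tidyr::expand_grid(sample_id = unique(df$sample_id),
                             drug = setdiff(unique(df$drug), "vehicle"),
                             dose_nM = sort(unique(df$dose_nM[df$dose_nM > 0])))
  df <- dplyr::left_join(full, df, by = c("sample_id", "drug", "dose_nM"))
  if (any(is.na(df$delta_pct))) {
    warning("incomplete drug x dose grid; missing cells rendered blank",
            call. = FALSE)
  }
  df$dose <- factor(df$dose_nM, levels = sort(unique(df$dose_nM)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$drug,
                                        fill = .data$delta_pct)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), na.value = "grey92",
                                  name = "Δ Annexin V (%)") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "dose (nM)", y = NULL) +
    ggplot2::theme_minimal()
  open_device(path, width = 7, height = 5)
  print(p)
  grDevices::dev.off()
  write.csv(df[, c("sample_id", "drug", "dose_nM", "delta_pct")],
            sidecar_path(path), row.names = FALSE)
  invisible(path)
}
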