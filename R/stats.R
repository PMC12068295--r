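#' Significance stars
#'
#' Figure-legend convention: `*` p <= 0.05, `**` <= 0.01, `***` <= 0.001,
#' `****` <= 0.0001.
#' @param p Numeric p-values.
#' @return Character vector of stars (`"ns"` above 0.05).
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Two-way ANOVA with per-dose contrasts against the control
#'
#' Fits a two-way fixed-effects ANOVA with interaction over two crossed
#' factors (condition x dose, where the dose-0 cell of each condition is its
#' matched vehicle control), then tests every treated cell against its
#' control cell. Contrast p-values are multiplicity-adjusted per condition
#' (default Sidak, emulating common two-way-ANOVA dose-response workflows;
#' `"none"` and `"holm"` selectable — the choice is stamped into the output).
#'
#' @param measurements Tibble with columns `value` (response, e.g. Annexin V
#'   percentage), `condition` (first factor, e.g. drug), `dose_nM` (second
#'   factor; 0 marks the control cell).
#' @param adjust `"sidak"`, `"holm"` or `"none"`.
#' @return A `bh3_comparison`: list with `anova` (the two-way ANOVA table)
#'   and `contrasts` (tibble: `condition, dose_nM, estimate, p_value,
#'   adjusted_p, stars, adjust`).
#' @export
compare_to_control <- function(measurements, adjust = c("sidak", "holm", "none")) {
  adjust <- match.arg(adjust)
  m <- tibble::as_tibble(measurements)
  stopifnot(all(c("value", "condition", "dose_nM") %in% names(m)))
  m$condition <- factor(m$condition)
  m$dose <- factor(m$dose_nM)
  cell_n <- table(m$condition, m$dose)
  used <- cell_n[cell_n > 0]
  if (any(used < 2)) {
    stop("fewer than 2 replicates in some design cells; cannot compare",
         call. = FALSE)
  }
  if (length(unique(used)) > 1) {
    warning("unbalanced design: cell sizes differ (type II-like behaviour not guaranteed)",
            call. = FALSE)
  }
  fit <- if (nlevels(m$condition) >= 2) {
    lm(value ~ condition * dose, data = m)
  } else {
    # a single condition leaves only the dose factor
    lm(value ~ dose, data = m)
  }
  an <- stats::anova(fit)
  emm <- if (nlevels(m$condition) >= 2) {
    emmeans::emmeans(fit, ~ dose | condition)
  } else {
    emmeans::emmeans(fit, ~ dose)
  }
  ctr <- summary(emmeans::contrast(emm, method = "trt.vs.ctrl", ref = 1,
                                   adjust = if (adjust == "sidak") "sidak" else "none"))
  out <- tibble::tibble(
    condition = if (!is.null(ctr$condition)) as.character(ctr$condition)
                else levels(m$condition)[1],
    # contrast labels look like "dose1000 - dose0"; keep the treated level
    dose_nM = as.numeric(gsub("[^0-9.]", "", sub(" - .*", "", as.character(ctr$contrast)))),
    estimate = ctr$estimate,
    adjusted_p = ctr$p.value)
  if (adjust == "holm") {
    out <- out |>
      dplyr::group_by(.data$condition) |>
      dplyr::mutate(adjusted_p = p.adjust(.data$adjusted_p, "holm")) |>
      dplyr::ungroup()
  }
  # degenerate data with zero residual variance: a zero difference is never
  # significant
  out$adjusted_p[!is.finite(out$adjusted_p) & abs(out$estimate) < 1e-8] <- 1
  # an essentially perfect fit leaves numerically meaningless p-values; a
  # zero difference is never significant
  if (stats::sigma(fit) < 1e-8) out$adjusted_p[abs(out$estimate) < 1e-8] <- 1
  if (any(!is.finite(out$adjusted_p))) {
    warning("zero residual variance with non-zero differences; p-values undefined",
            call. = FALSE)
  }
  out$stars <- significance_stars(out$adjusted_p)
  out$adjust <- adjust
  structure(list(anova = an, contrasts = out), class = "bh3_comparison")
}

#' @export
print.bh3_comparison <- function(x, ...) {
  cat("Two-way ANOVA\n")
  print(x$anova)
  cat("\nContrasts vs control (", x$contrasts$adjust[1], "-adjusted)\n", sep = "")
  print(as.data.frame(x$contrasts[, c("condition", "dose_nM", "estimate",
                                      "adjusted_p", "stars")]))
  invisible(x)
}

#' Pearson correlation with least-squares fit
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return Tibble row: `r`, `p_value`, `slope`, `intercept`, `r_squared`, `n`.
#'   For simple regression `r_squared` equals `r^2` exactly.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared, n = length(x))
}
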