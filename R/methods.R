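# broom-style accessors and plots for fitted objects.

#' Tidy a multi-zone NPS analysis
#'
#' Returns the long per-(cell, zone) results table - frequency, pre-stress,
#' storage and loss moduli, loss tangent, residual, QC flags - joined with
#' each cell's sized diameter and cell-level flags. This is the
#' `PopulationTable` shape consumed by the population statistics and the
#' heatmap plots.
#'
#' @param x An [nps_analyze()] result.
#' @param ... Unused.
#' @return A tibble with one row per fitted (cell, zone).
#' @export
tidy.nps_result <- function(x, ...) {
  if (!nrow(x$zones)) return(x$zones)
  x$zones |>
    dplyr::left_join(x$cells |>
      dplyr::select("cell_id", "D_cell", "coincident", "unstrained"),
      by = "cell_id") |>
    dplyr::select("cell_id", "zone", "D_cell", "f_applied", "sigma_p",
      "Gp", "Gpp", "eta", "residual_rms", "negative_modulus",
      "below_detection", "coincident", "unstrained")
}

#' Summarize a multi-zone NPS analysis in one row
#'
#' @inheritParams tidy.nps_result
#' @return A one-row tibble with cell counts and population medians.
#' @export
glance.nps_result <- function(x, ...) {
  z <- x$zones
  tibble::tibble(
    n_cells = x$log$cells_detected,
    n_fitted = x$log$cells_fitted,
    n_excluded = x$log$cells_excluded,
    n_coincident = x$log$coincident,
    median_D_cell = median(x$cells$D_cell, na.rm = TRUE),
    median_Gp = if (nrow(z)) median(z$Gp) else NA_real_,
    median_Gpp = if (nrow(z)) median(z$Gpp) else NA_real_,
    median_eta = if (nrow(z)) median(z$eta, na.rm = TRUE) else NA_real_)
}

#' Plot an analysis as a storage/loss-modulus heatmap
#'
#' @param object An [nps_analyze()] result.
#' @param value Which modulus to display, `"Gp"` or `"Gpp"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nps_result <- function(object, value = c("Gp", "Gpp"), ...) {
  value <- match.arg(value)
  td <- tidy(object)
  if (!nrow(td)) abort("No fitted zones to plot.", class = "nps_plot_error")
  plot_modulus_heatmap(td, !!rlang::sym(value))
}

#' Plot a raw or simulated trace
#'
#' Stacked per-channel resistance time series, the standard way to inspect
#' cascading resistive pulses. Long traces are windowed with `tlim`.
#'
#' @param trace Trace tibble (`t` plus channel columns).
#' @param tlim Optional length-2 time window (s).
#' @param normalize Subtract each channel's median before plotting.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, tlim = NULL, normalize = TRUE) {
  df <- trace
  if (!is.null(tlim)) df <- dplyr::filter(df, .data$t >= tlim[1], .data$t <= tlim[2])
  long <- tidyr::pivot_longer(df, -"t", names_to = "channel", values_to = "R")
  if (normalize) {
    long <- long |> dplyr::group_by(.data$channel) |>
      dplyr::mutate(R = .data$R - median(.data$R)) |> dplyr::ungroup()
  }
  long$channel <- factor(long$channel, levels = setdiff(names(trace), "t"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$R)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "resistance (centered, ohm)") +
    ggplot2::theme_minimal()
}
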