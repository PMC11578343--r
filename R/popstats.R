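# Population-level statistics: Tukey-fence outlier removal, rank tests, and
# the per-cell cross-zone heterogeneity score.

#' Tukey-fence (IQR) outlier removal
#'
#' Removes exactly the values falling below `Q1 - 1.5 IQR` or above
#' `Q3 + 1.5 IQR`. Quartiles use linear interpolation (R quantile type 7).
#' With fewer than 4 values no filtering is attempted (pass-through with a
#' warning). For a Gaussian population the expected removal rate is ~0.7%.
#'
#' @param values Numeric vector.
#' @return A list: `values` (kept), `removed` (indices into the input that
#'   were removed), and `fences` (lower, upper).
#' @examples
#' iqr_filter(c(1:10, 100))$removed # the 100 is removed
#' @export
iqr_filter <- function(values) {
  if (length(values) < 4) {
    warn("Fewer than 4 values: IQR filter passed through without removal.")
    return(list(values = values, removed = integer(0),
      fences = c(-Inf, Inf)))
  }
  qs <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  iqr <- qs[2] - qs[1]
  fences <- c(qs[1] - 1.5 * iqr, qs[2] + 1.5 * iqr)
  removed <- which(values < fences[1] | values > fences[2])
  kept <- if (length(removed)) values[-removed] else values
  list(values = kept, removed = removed, fences = fences)
}

#' Rank-based group comparisons
#'
#' `rank_sum_test()` compares two independent groups with the Wilcoxon
#' rank-sum (Mann-Whitney) test; `signed_rank_test()` is the paired Wilcoxon
#' signed-rank variant (only meaningful for paired designs);
#' `kruskal_rank_test()` compares k groups with the Kruskal-Wallis rank test.
#' All take a long-format data frame and return a one-row tibble with the
#' statistic, p-value, and method, so results bind rows cleanly.
#'
#' @param data A data frame.
#' @param value Column with the measured values (tidy-eval).
#' @param group Column with the group labels (tidy-eval); exactly two levels
#'   for the two-sample tests.
#' @param exact Passed to [stats::wilcox.test()]; exact p-values are used by
#'   default for small samples.
#' @return A one-row tibble: `statistic`, `p.value`, `method`, `n`.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 10, 11, 12))
#' rank_sum_test(df, y, g)
#' @export
rank_sum_test <- function(data, value, group, exact = NULL) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    abort("`group` must have exactly two non-empty levels.",
      class = "nps_stats_error")
  }
  ht <- wilcox.test(v[g == levels(g)[1]], v[g == levels(g)[2]], exact = exact)
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
    method = "Wilcoxon rank-sum", n = length(v))
}

#' @rdname rank_sum_test
#' @export
signed_rank_test <- function(data, value, group, exact = NULL) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) != 2 || length(unique(table(g))) != 1) {
    abort("Signed-rank test needs two equal-sized (paired) groups.",
      class = "nps_stats_error")
  }
  ht <- wilcox.test(v[g == levels(g)[1]], v[g == levels(g)[2]],
    paired = TRUE, exact = exact)
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
    method = "Wilcoxon signed-rank (paired)", n = length(v))
}

#' @rdname rank_sum_test
#' @export
kruskal_rank_test <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (any(table(g) == 0) || nlevels(g) < 2) {
    abort("All groups must be non-empty.", class = "nps_stats_error")
  }
  ht <- kruskal.test(v, g)
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
    method = "Kruskal-Wallis rank", n = length(v))
}

#' Per-cell cross-zone heterogeneity score
#'
#' Quantifies how much a single cell's modulus varies across the measured
#' frequency zones, on a population-standardized scale: each zone's values
#' are standardized (z-scored) across the population so every zone has unit
#' variance, then the variance of each cell's standardized values across its
#' zones is reported. A cell tracking the population zone-by-zone scores 0;
#' zone-to-zone alternation scores high. Cells with fewer than two zone
#' values get `NA`.
#'
#' @param data Long-format data frame with one row per (cell, zone).
#' @param value Modulus column to score (tidy-eval), e.g. `Gp` or `Gpp`.
#' @param cell,zone Identifier columns (tidy-eval).
#' @return A tibble `cell_id`, `n_zones`, `score`.
#' @export
cross_zone_variance <- function(data, value, cell = cell_id, zone = zone) {
  df <- tibble::tibble(
    cell_id = rlang::eval_tidy(rlang::enquo(cell), data),
    zone = rlang::eval_tidy(rlang::enquo(zone), data),
    value = rlang::eval_tidy(rlang::enquo(value), data))
  df |>
    dplyr::group_by(.data$zone) |>
    dplyr::mutate(z = as.numeric(scale(.data$value))) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_zones = sum(!is.na(.data$z)),
      score = if (sum(!is.na(.data$z)) >= 2) var(.data$z, na.rm = TRUE)
        else NA_real_)
}

#' Heatmap of a modulus across cells and zones
#'
#' The reporting convention of the platform: one column per cell, one row per
#' zone, optionally grouped (faceted) by condition, with a log10 fill scale.
#'
#' @param data Long-format tibble with columns `cell_id`, `zone`, the modulus
#'   column, and optionally a grouping column.
#' @param value Modulus column (tidy-eval).
#' @param group Optional grouping column (tidy-eval) used for facets.
#' @return A ggplot object.
#' @export
plot_modulus_heatmap <- function(data, value, group = NULL) {
  qv <- rlang::enquo(value)
  qg <- rlang::enquo(group)
  p <- ggplot2::ggplot(data, ggplot2::aes(
      x = factor(.data$cell_id), y = factor(.data$zone), fill = !!qv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "cell", y = "zone", fill = rlang::as_label(qv)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!rlang::quo_is_null(qg)) {
    p <- p + ggplot2::facet_grid(cols = ggplot2::vars(!!qg), scales = "free_x",
      space = "free_x")
  }
  p
}
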