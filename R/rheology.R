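# Rheology: Coulter sizing, stress-series reconstruction, and least-squares
# extraction of the storage and loss moduli.

#' Size every detected cell from its sizing-pore pulse
#'
#' Applies the Coulter relation ([coulter_diameter()]) to the guarded mean
#' relative pulse height of each cell's sizing-pore pulse.
#'
#' @param events An [detect_events()] result.
#' @param geometry The device geometry.
#' @return A tibble `cell_id`, `D_cell` (um).
#' @export
size_cells <- function(events, geometry) {
  stopifnot(inherits(events, "nps_events"))
  tibble::tibble(cell_id = events$cells$cell_id,
    D_cell = coulter_diameter(pmax(events$cells$pore_mean_drr, 0),
      geometry$pore$D_eff, geometry$pore$L_pore))
}

#' Reconstruct the contact-stress series of one zone pulse
#'
#' For each in-pulse sample, the cell position is `x = v * (t - t_entry)`,
#' the local wall width `w(x)` and deformed diameter `D_d` follow from the
#' geometry and the sized diameter, the pressure drop across the cell comes
#' from the pressure-partition model applied to the measured relative
#' blockage, and the contact stress is
#' `sigma = 2 * dP * w / (mu_f * pi * D_d)`. The regression basis columns
#' `eps_cos = eps0 * cos(omega * tau)` and `eps_sin = eps0 * sin(omega * tau)`
#' (with `eps0 = a / D_cell`, `omega = 2 * pi * v / L_p`, and `tau` measured
#' from zone entry) are attached for the least-squares fit.
#'
#' @param samples Tibble with columns `t` (s) and `drr` (relative blockage)
#'   covering one zone pulse.
#' @param zone One-row zone tibble from the geometry.
#' @param D_cell Free cell diameter, um.
#' @param geometry The device geometry (for pressure, friction, sampling).
#' @param t_entry Zone-entry time, s (phase reference: widest point).
#' @param transit Transit time through the zone, s.
#' @param control An [nps_control()].
#' @return A tibble of class `nps_stress_series` with columns `t`, `tau`,
#'   `sigma` (Pa), `eps_cos`, `eps_sin`; attributes `eps0`, `omega`, `f`,
#'   `n_dropped` (samples outside the guarded zone interior).
#' @export
compute_stress_series <- function(samples, zone, D_cell, geometry, t_entry,
                                  transit, control = nps_control()) {
  if (D_cell <= zone$w0 + zone$a) {
    abort("Cell is unstrained in this zone (D_cell <= w0 + a); no rheology.",
      class = "nps_unstrained_error")
  }
  v <- zone$L_zone / transit
  f <- v / zone$L_p
  omega <- 2 * pi * f
  eps0 <- zone$a / D_cell
  guard <- control$edge_guard_s
  tau <- samples$t - t_entry
  keep <- tau >= guard & tau <= transit - guard
  x <- v * tau[keep]
  inzone <- x >= 0 & x <= zone$L_zone
  tau_k <- tau[keep][inzone]
  x <- x[inzone]
  drr <- samples$drr[keep][inzone]
  w <- zone$w0 + zone$a * cos(2 * pi * x / zone$L_p)
  dd <- sqrt(2 * D_cell^3 / (3 * w))
  if (control$partition_mode == "constant") {
    drr <- rep(mean(drr), length(drr))
  }
  dp <- .dp_from_drr(drr, geometry$applied_pressure, control$partition_scale)
  bad <- dp >= geometry$applied_pressure
  if (any(bad)) {
    warn(sprintf("%d unphysical samples (dP >= P) dropped.", sum(bad)))
    tau_k <- tau_k[!bad]; w <- w[!bad]; dd <- dd[!bad]; dp <- dp[!bad]
  }
  sigma <- .stress_from_dp(dp, w, dd, geometry$mu_f)
  out <- tibble::tibble(t = tau_k + t_entry, tau = tau_k, sigma = sigma,
    eps_cos = eps0 * cos(omega * tau_k), eps_sin = eps0 * sin(omega * tau_k))
  structure(out, eps0 = eps0, omega = omega, f = f,
    n_dropped = nrow(samples) - nrow(out),
    class = c("nps_stress_series", class(out)))
}

#' Fit the oscillatory-rheology relationship to a stress series
#'
#' Ordinary linear least squares of the reconstructed stress on
#' `[1, eps0 * cos(omega * tau), eps0 * sin(omega * tau)]`, i.e. the standard
#' relationship `sigma = sigma_p + Gp * eps0 * cos + Gpp * eps0 * sin`. On a
#' noiseless synthetic series the recovery is exact to numerical precision.
#'
#' @param series An [compute_stress_series()] result (or any tibble with
#'   columns `sigma`, `eps_cos`, `eps_sin`).
#' @return A one-row tibble: `sigma_p`, `Gp`, `Gpp` (Pa), `residual_rms`
#'   (Pa), `n` (samples used).
#' @examples
#' z <- zone_spec(1, 6000, 500, 11.25, 2.75)
#' tau <- seq(0, 0.5, by = 1e-4)
#' eps0 <- 0.15; omega <- 2 * pi * 13
#' series <- tibble::tibble(sigma = 10 + 500 * eps0 * cos(omega * tau) +
#'   50 * eps0 * sin(omega * tau),
#'   eps_cos = eps0 * cos(omega * tau), eps_sin = eps0 * sin(omega * tau))
#' fit_rheology(series)
#' @export
fit_rheology <- function(series) {
  if (nrow(series) < 3) {
    abort("Need at least 3 samples to fit the rheological relationship.",
      class = "nps_fit_error")
  }
  X <- cbind(1, series$eps_cos, series$eps_sin)
  if (sd(series$eps_cos) < 1e-14 || sd(series$eps_sin) < 1e-14) {
    abort("Rank-deficient basis (omega ~ 0 or eps0 = 0).", class = "nps_fit_error")
  }
  fit <- stats::.lm.fit(X, series$sigma)
  r <- fit$residuals
  tibble::tibble(sigma_p = fit$coefficients[1], Gp = fit$coefficients[2],
    Gpp = fit$coefficients[3], residual_rms = sqrt(mean(r^2)),
    n = nrow(series))
}

# residual-RMS objective used to refine (t_entry, transit) of one pulse;
# exact timing matters because a phase error omega*dt leaks G' into G''.
# Lean numeric version of compute_stress_series + fit_rheology: it runs a
# hundred times per pulse inside the optimizer.
.zone_objective <- function(par, st, sdrr, zone, D_cell, geometry, control,
                            t0_init, T_init) {
  t0 <- par[1]; Tt <- par[2]
  # large finite penalty (not Inf) keeps optimize() quiet at the bounds
  if (abs(t0 - t0_init) > control$refine_t0_s ||
      abs(Tt - T_init) > control$refine_T_s || Tt <= 0) {
    return(1e12)
  }
  v <- zone$L_zone / Tt
  omega <- 2 * pi * v / zone$L_p
  eps0 <- zone$a / D_cell
  guard <- control$edge_guard_s
  tau <- st - t0
  keep <- tau >= guard & tau <= Tt - guard
  tau <- tau[keep]
  if (length(tau) < 16) return(1e12)
  drr <- sdrr[keep]
  w <- zone$w0 + zone$a * cos(2 * pi * v * tau / zone$L_p)
  dd <- sqrt(2 * D_cell^3 / (3 * w))
  dp <- (drr / (1 + drr)) * geometry$applied_pressure / control$partition_scale
  sigma <- 2 * dp * w / (geometry$mu_f * pi * dd)
  X <- cbind(1, eps0 * cos(omega * tau), eps0 * sin(omega * tau))
  sqrt(mean(stats::.lm.fit(X, sigma)$residuals^2))
}

# fit one (cell, zone) pulse, optionally refining the pulse timing
.fit_zone <- function(samples, t_start, t_end, zone, D_cell, geometry, control) {
  t0 <- t_start; Tt <- t_end - t_start
  if (isTRUE(control$refine)) {
    # coordinate descent on (pulse-centre time, transit): the centre-time
    # parameterization decouples the entry-phase and frequency directions,
    # which form a ridge in (entry time, transit) coordinates
    tc <- t0 + Tt / 2
    st <- samples$t; sdrr <- samples$drr
    for (it in 1:3) {
      tc <- stats::optimize(function(p) .zone_objective(c(p - Tt / 2, Tt),
          st, sdrr, zone, D_cell, geometry, control, t_start, t_end - t_start),
        interval = tc + c(-1, 1) * control$refine_t0_s, tol = 5e-7)$minimum
      Tt <- stats::optimize(function(p) .zone_objective(c(tc - p / 2, p),
          st, sdrr, zone, D_cell, geometry, control, t_start, t_end - t_start),
        interval = Tt + c(-1, 1) * control$refine_T_s, tol = 5e-7)$minimum
    }
    t0 <- tc - Tt / 2
  }
  ser <- compute_stress_series(samples, zone, D_cell, geometry, t0, Tt, control)
  fit <- fit_rheology(ser)
  dplyr::mutate(fit, t_entry = t0, transit_time = Tt,
    velocity = zone$L_zone / Tt, f_applied = velocity / zone$L_p)
}

#' Assemble per-cell viscoelastic results
#'
#' Combines the per-zone fits and the sized diameters into the final result:
#' the loss tangent `eta = Gpp / Gp` per zone, QC flags (negative fitted
#' moduli are flagged, never clipped), and the per-cell `below_detection`
#' flag (fitted loss modulus below `detection_gpp` Pa in at least one zone).
#'
#' @param zone_fits Tibble of per-zone fits (from the internal fitting stage
#'   or a user pipeline), with columns `cell_id`, `zone`, `sigma_p`, `Gp`,
#'   `Gpp`, `residual_rms`, `f_applied`.
#' @param sizes Tibble `cell_id`, `D_cell` from [size_cells()].
#' @param control An [nps_control()] (for the detection threshold).
#' @return A list with `zones` (per cell x zone, including `eta` and flags)
#'   and `cells` (per cell, including `below_detection`).
#' @export
assemble_result <- function(zone_fits, sizes, control = nps_control()) {
  zones <- zone_fits |>
    dplyr::mutate(
      negative_modulus = .data$Gp < 0 | .data$Gpp < 0,
      eta = dplyr::if_else(.data$Gp > 0, .data$Gpp / .data$Gp, NA_real_),
      below_detection = .data$Gpp < control$detection_gpp)
  cells <- sizes |>
    dplyr::left_join(
      zones |>
        dplyr::group_by(.data$cell_id) |>
        dplyr::summarise(
          n_zones_fit = dplyr::n(),
          below_detection = any(.data$below_detection),
          any_negative = any(.data$negative_modulus)),
      by = "cell_id") |>
    dplyr::mutate(n_zones_fit = dplyr::coalesce(.data$n_zones_fit, 0L),
      fitted = .data$n_zones_fit > 0)
  list(zones = zones, cells = cells)
}

#' Analyze a raw multi-zone NPS trace end to end
#'
#' Runs the full inverse pipeline: zero-phase low-pass filtering, moving
#' median, baseline normalization, event detection and cross-channel
#' matching, Coulter sizing, per-zone stress reconstruction, and the
#' least-squares rheological fit. Cells that are coincident, incomplete, or
#' unstrained (smaller than the widest contraction) are excluded from
#' fitting, each with a machine-readable reason.
#'
#' @param trace Raw trace tibble: column `t` (s) plus one resistance channel
#'   (ohm) per device channel, sizing pore first, zones in order.
#' @param geometry The device [device_geometry()].
#' @param control An [nps_control()].
#' @return An object of class `nps_result` with tibbles `cells` (per-cell
#'   diameter, flags, exclusion reason) and `zones` (per cell x zone:
#'   `f_applied`, `sigma_p`, `Gp`, `Gpp`, `eta`, `residual_rms`, QC flags),
#'   plus `features`, `events`, a `log` of stage counts, and the
#'   configuration used. Supports [tidy()], [glance()], and [autoplot()].
#' @examples
#' sim <- simulate_trace(sim_config(n_cells = 2, seed = 7, event_rate = 3600))
#' res <- nps_analyze(sim$trace, sim$config$geometry)
#' tidy(res)
#' @export
nps_analyze <- function(trace, geometry, control = nps_control()) {
  events <- detect_events(trace, geometry, control)
  features <- extract_zone_features(events, geometry, control)
  sizes <- size_cells(events, geometry)

  wmax <- max(geometry$zones$w0 + geometry$zones$a)
  cells <- events$cells |>
    dplyr::left_join(sizes, by = "cell_id") |>
    dplyr::mutate(unstrained = .data$D_cell <= wmax)

  eligible <- cells$cell_id[cells$complete & !cells$coincident & !cells$unstrained]
  fit_rows <- events$pulses |>
    dplyr::filter(.data$cell_id %in% eligible) |>
    dplyr::left_join(features |>
      dplyr::select("cell_id", "zone", "insufficient_periods"),
      by = c("cell_id", "zone")) |>
    dplyr::filter(!.data$insufficient_periods)

  zone_fits <- purrr::pmap_dfr(fit_rows, function(cell_id, zone, t_start, t_end,
                                                  n_samples, mean_drr, samples,
                                                  insufficient_periods) {
    zg <- geometry$zones[zone, ]
    D <- cells$D_cell[cells$cell_id == cell_id]
    fit <- tryCatch(
      .fit_zone(samples, t_start, t_end, zg, D, geometry, control),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    dplyr::mutate(fit, cell_id = cell_id, zone = zone, .before = 1)
  })

  if (!nrow(zone_fits)) {
    zone_fits <- tibble::tibble(cell_id = integer(), zone = integer(),
      sigma_p = numeric(), Gp = numeric(), Gpp = numeric(),
      residual_rms = numeric(), n = integer(), t_entry = numeric(),
      transit_time = numeric(), velocity = numeric(), f_applied = numeric())
  }
  asm <- assemble_result(zone_fits, sizes, control)

  cells <- cells |>
    dplyr::left_join(asm$cells |> dplyr::select(-"D_cell"), by = "cell_id") |>
    dplyr::mutate(
      fitted = dplyr::coalesce(.data$fitted, FALSE),
      exclude_reason = dplyr::case_when(
        !complete ~ "incomplete",
        coincident ~ "coincident",
        unstrained ~ "unstrained",
        !fitted ~ "fit_failed",
        TRUE ~ NA_character_))

  log <- tibble::tibble(
    cells_detected = nrow(cells),
    cells_fitted = sum(cells$fitted),
    cells_excluded = sum(!cells$fitted),
    coincident = sum(cells$coincident),
    incomplete = sum(!cells$complete),
    unstrained = sum(cells$unstrained, na.rm = TRUE),
    orphan_pulses = if (is.null(events$unmatched)) 0L else nrow(events$unmatched))

  structure(list(cells = cells, zones = asm$zones, features = features,
    events = events, log = log, geometry = geometry, control = control),
    class = "nps_result")
}

#' @export
print.nps_result <- function(x, ...) {
  cat(sprintf("<nps_result> %d cells detected, %d fitted (%d excluded)\n",
    x$log$cells_detected, x$log$cells_fitted, x$log$cells_excluded))
  if (nrow(x$zones)) {
    s <- x$zones |> dplyr::group_by(.data$zone) |>
      dplyr::summarise(f_Hz = median(.data$f_applied),
        Gp = median(.data$Gp), Gpp = median(.data$Gpp))
    cat("Median per-zone moduli (Pa):\n")
    print(as.data.frame(s), row.names = FALSE)
  }
  invisible(x)
}
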