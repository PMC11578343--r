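# Forward model: cells -> multi-channel resistance traces with ground truth.
# The simulator and the analysis pipeline share one stress<->blockage map so
# that a noiseless trace is exactly invertible.

#' Population modulus model for the simulator
#'
#' Describes how true per-cell rheological parameters are drawn. Medians are
#' log-normal medians; `sdlog_*` set the cell-to-cell scatter. With
#' `type = "powerlaw"`, each cell's moduli scale with the zone frequency as
#' `(f / f_ref)^alpha`; the default is frequency-independent moduli.
#'
#' @param type "constant" or "powerlaw".
#' @param gp,gpp,sigma_p Population median storage modulus, loss modulus, and
#'   pre-stress (Pa).
#' @param sdlog_gp,sdlog_gpp,sdlog_sigma Log-scale standard deviations of the
#'   cell-to-cell scatter.
#' @param alpha_gp,alpha_gpp Power-law exponents (used when
#'   `type = "powerlaw"`).
#' @param f_ref Reference frequency (Hz) for the power law.
#' @return A list of class `nps_modulus_model`.
#' @export
modulus_model <- function(type = c("constant", "powerlaw"),
                          gp = 200, gpp = 20, sigma_p = 50,
                          sdlog_gp = 0.4, sdlog_gpp = 0.4, sdlog_sigma = 0.3,
                          alpha_gp = 0, alpha_gpp = 0, f_ref = 30) {
  type <- match.arg(type)
  stopifnot(gp > 0, gpp >= 0, sigma_p > 0)
  structure(list(type = type, gp = gp, gpp = gpp, sigma_p = sigma_p,
    sdlog_gp = sdlog_gp, sdlog_gpp = sdlog_gpp, sdlog_sigma = sdlog_sigma,
    alpha_gp = alpha_gp, alpha_gpp = alpha_gpp, f_ref = f_ref),
    class = "nps_modulus_model")
}

#' Simulation configuration
#'
#' Defaults emulate the reference experiment: MCF-7-like diameters
#' (18.4 +/- 0.9 um), transit velocities around 6.5 mm/s with a mild
#' zone-to-zone speed-up (so the four default zones probe ~13/30/47/65 Hz),
#' 13.8 kPa driving pressure, 10 kHz sampling, and a throughput of 600 cells
#' per hour. `noise_sd` is the white-noise standard deviation expressed as a
#' fraction of the nominal pulse height of each channel (so 0.05 means 5%
#' relative resistance noise on the pulse scale); `drift_amp` is a slow
#' sinusoidal baseline drift relative to the baseline resistance.
#'
#' @param geometry An [device_geometry()] (default [default_geometry()]).
#' @param n_cells Number of cells to simulate.
#' @param seed Integer seed; mandatory, every draw is reproducible from it.
#' @param diameter_mean,diameter_sd Free-diameter population (um).
#' @param moduli A [modulus_model()].
#' @param velocity_mean,velocity_sd Base transit velocity population (um/s).
#' @param velocity_drift Optional per-zone velocity multipliers (length =
#'   number of zones). Default reproduces the observed zone-to-zone
#'   frequency drift in a four-zone device.
#' @param noise_sd Relative resistance noise (fraction of nominal pulse
#'   height per channel).
#' @param drift_amp,drift_period Baseline drift relative amplitude and
#'   period (s).
#' @param event_rate Cell throughput (cells per hour); arrivals are regularly
#'   spaced with +/-15% jitter.
#' @param r_base Baseline resistance per channel (ohm), recycled.
#' @param partition_scale Scaling constant of the pressure-partition model
#'   (see Details).
#' @param partition_mode `"time-resolved"` (default) maps the instantaneous
#'   blockage to the instantaneous pressure drop; `"constant"` uses the
#'   pulse-mean blockage, a sensitivity-analysis mode.
#' @param zone_gp_pattern Optional per-zone multipliers applied to each
#'   cell's true storage modulus (for heterogeneity studies).
#'
#' @details The pressure drop across a strained cell is tied to its
#' fractional electrical blockage,
#' `dP(t) / P = partition_scale * dR(t) / (R_base + dR(t))`,
#' on the rationale that the electrical and hydraulic constrictions co-scale
#' in a series channel. This declared partition model is what makes the
#' simulator and the analysis exact inverses of each other.
#'
#' @return A list of class `nps_sim_config`.
#' @export
sim_config <- function(geometry = default_geometry(), n_cells = 20, seed,
                       diameter_mean = 18.4, diameter_sd = 0.9,
                       moduli = modulus_model(),
                       velocity_mean = 6500, velocity_sd = 400,
                       velocity_drift = NULL,
                       noise_sd = 0, drift_amp = 1e-3, drift_period = 120,
                       event_rate = 600, r_base = 6e5,
                       partition_scale = 1,
                       partition_mode = c("time-resolved", "constant"),
                       zone_gp_pattern = NULL) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("`seed` is mandatory for reproducible simulation.",
      class = "nps_config_error")
  }
  stopifnot(inherits(geometry, "nps_geometry"), n_cells >= 1, noise_sd >= 0,
    diameter_mean > 0, velocity_mean > 0, event_rate > 0)
  nz <- nrow(geometry$zones)
  if (is.null(velocity_drift)) {
    velocity_drift <- if (nz == 4) c(1, 1.155, 1.208, 1.25) else
      seq(1, 1.25, length.out = max(nz, 2))[seq_len(nz)]
  }
  stopifnot(length(velocity_drift) == nz, all(velocity_drift > 0))
  if (!is.null(zone_gp_pattern)) stopifnot(length(zone_gp_pattern) == nz)
  structure(list(geometry = geometry, n_cells = as.integer(n_cells),
    seed = as.integer(seed), diameter_mean = diameter_mean,
    diameter_sd = diameter_sd, moduli = moduli,
    velocity_mean = velocity_mean, velocity_sd = velocity_sd,
    velocity_drift = velocity_drift, noise_sd = noise_sd,
    drift_amp = drift_amp, drift_period = drift_period,
    event_rate = event_rate,
    r_base = rep_len(r_base, nz + 1),
    partition_scale = partition_scale,
    partition_mode = match.arg(partition_mode),
    zone_gp_pattern = zone_gp_pattern), class = "nps_sim_config")
}

#' Oscillatory stress at the true rheological parameters
#'
#' Evaluates the standard oscillatory-rheology relationship
#' `sigma(t) = sigma_p + Gp * eps0 * cos(omega t + phase0) +
#' Gpp * eps0 * sin(omega t + phase0)` for a strain wave and a set of true
#' parameters; `t` is measured from zone entry.
#'
#' @param wave An [strain_wave()].
#' @param sigma_p,Gp,Gpp True pre-stress, storage and loss moduli (Pa).
#' @param t Time(s) since zone entry, s.
#' @return Stress in Pa.
#' @examples
#' z <- zone_spec(1, 6000, 500, 11.25, 2.75)
#' w <- strain_wave(z, 18.4, 6500)
#' synth_stress(w, sigma_p = 10, Gp = 500 * 0.15 / w$eps0,
#'   Gpp = 0, t = 0)
#' @export
synth_stress <- function(wave, sigma_p, Gp, Gpp, t) {
  ph <- wave$omega * t + wave$phase0
  sigma_p + Gp * wave$eps0 * cos(ph) + Gpp * wave$eps0 * sin(ph)
}

# --- shared stress <-> blockage map (Eq. 1 + pressure partition) -----------

# pressure drop across the cell from contact stress (inverse of Eq. 1)
.dp_from_stress <- function(sigma, w, D_d, mu_f) sigma * mu_f * pi * D_d / (2 * w)

# contact stress from pressure drop (Eq. 1)
.stress_from_dp <- function(dp, w, D_d, mu_f) 2 * dp * w / (mu_f * pi * D_d)

# partition model: fractional pressure drop <-> relative blockage
.drr_from_dp <- function(dp, P, scale = 1) {
  q <- scale * dp / P
  if (any(q >= 1)) {
    abort("Unphysical stress: pressure drop reaches the applied pressure (cell would stall).",
      class = "nps_unphysical_error")
  }
  q / (1 - q)
}
.dp_from_drr <- function(drr, P, scale = 1) {
  (drr / (1 + drr)) * P / scale
}

#' Map contact stress to an excess resistance
#'
#' Forward counterpart of the stress reconstruction used by the analysis:
#' the stress model gives the pressure drop across the strained cell,
#' `dP = sigma * mu_f * pi * D_d / (2 * w)`, and the pressure-partition model
#' converts it into an excess resistance,
#' `dR = R_base * (dP/P) / (1 - dP/P)` (for `partition_scale = 1`).
#'
#' @param sigma Contact stress, Pa.
#' @param w Contraction width at the cell, um.
#' @param D_d Deformed (wall-contact) diameter, um.
#' @param mu_f Friction coefficient.
#' @param P_applied Applied driving pressure, Pa.
#' @param R_base Baseline channel resistance, ohm.
#' @param partition_scale Scaling constant of the partition model.
#' @return Excess resistance dR, ohm.
#' @examples
#' stress_to_blockage(372.76, w = 11.25, D_d = 19.21, mu_f = 0.1,
#'   P_applied = 13800, R_base = 6e5)
#' @export
stress_to_blockage <- function(sigma, w, D_d, mu_f, P_applied, R_base,
                               partition_scale = 1) {
  dp <- .dp_from_stress(sigma, w, D_d, mu_f)
  R_base * .drr_from_dp(dp, P_applied, partition_scale)
}

#' @rdname stress_to_blockage
#' @param dR_over_R Relative excess resistance (dimensionless).
#' @export
blockage_to_stress <- function(dR_over_R, w, D_d, mu_f, P_applied,
                               partition_scale = 1) {
  dp <- .dp_from_drr(dR_over_R, P_applied, partition_scale)
  .stress_from_dp(dp, w, D_d, mu_f)
}

# draw the cell population and its event timeline
.draw_cells <- function(config) {
  g <- config$geometry
  m <- config$moduli
  n <- config$n_cells
  nz <- nrow(g$zones)
  D <- rnorm(n, config$diameter_mean, config$diameter_sd)
  D <- pmin(pmax(D, 2), 0.95 * g$pore$D_eff)
  v_base <- pmax(rnorm(n, config$velocity_mean, config$velocity_sd),
    0.2 * config$velocity_mean)
  gp_cell <- rlnorm(n, log(m$gp), m$sdlog_gp)
  gpp_cell <- rlnorm(n, log(m$gpp), m$sdlog_gpp)
  sp_cell <- rlnorm(n, log(m$sigma_p), m$sdlog_sigma)
  spacing <- 3600 / config$event_rate
  arrival <- 3 + (seq_len(n) - 1) * spacing + runif(n, -0.15, 0.15) * spacing

  cells <- tibble::tibble(cell_id = seq_len(n), D_cell = D, v_base = v_base,
    arrival = arrival, gp_cell = gp_cell, gpp_cell = gpp_cell,
    sigma_p = sp_cell,
    unstrained = D <= (g$zones$w0[1] + g$zones$a[1]))

  zones <- purrr::map_dfr(seq_len(n), function(i) {
    v_zone <- v_base[i] * config$velocity_drift
    t_pore_start <- arrival[i]
    t_pore_end <- t_pore_start + g$pore$L_pore / v_base[i]
    t_start <- numeric(nz); t_end <- numeric(nz)
    t_prev_end <- t_pore_end
    v_prev <- v_base[i]
    for (z in seq_len(nz)) {
      t_start[z] <- t_prev_end + g$node_length / v_prev
      t_end[z] <- t_start[z] + g$zones$L_zone[z] / v_zone[z]
      t_prev_end <- t_end[z]
      v_prev <- v_zone[z]
    }
    f <- v_zone / g$zones$L_p
    scale_f <- function(alpha) if (m$type == "powerlaw") (f / m$f_ref)^alpha else 1
    gp_z <- gp_cell[i] * scale_f(m$alpha_gp)
    if (!is.null(config$zone_gp_pattern)) gp_z <- gp_z * config$zone_gp_pattern
    tibble::tibble(cell_id = i, zone = seq_len(nz),
      t_start = t_start, t_end = t_end, v_true = v_zone, f_true = f,
      eps0_true = g$zones$a / D[i],
      Gp_true = gp_z,
      Gpp_true = gpp_cell[i] * scale_f(m$alpha_gpp),
      sigma_p_true = sp_cell[i],
      pore_start = t_pore_start, pore_end = t_pore_end)
  })

  # occupancy overlap (two cells in the device at once) -> coincidence flag
  occ_start <- cells$arrival
  occ_end <- vapply(split(zones$t_end, zones$cell_id), max, numeric(1))
  coincident <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (occ_end[i] > occ_start[i + 1]) coincident[c(i, i + 1)] <- TRUE
    }
  }
  cells$coincident <- coincident
  cells$pore_start <- zones$pore_start[match(cells$cell_id, zones$cell_id)]
  cells$pore_end <- zones$pore_end[match(cells$cell_id, zones$cell_id)]
  list(cells = cells, zones = zones)
}

# nominal per-channel pulse heights (relative) used to scale the noise
.nominal_pulse_heights <- function(config) {
  g <- config$geometry
  pore_h <- forward_blockage(config$diameter_mean, g$pore$D_eff, g$pore$L_pore)
  zone_h <- vapply(seq_len(nrow(g$zones)), function(z) {
    w <- g$zones$w0[z]
    dd <- deformed_diameter(config$diameter_mean, w)
    dp <- .dp_from_stress(config$moduli$sigma_p, w, dd, g$mu_f)
    .drr_from_dp(dp, g$applied_pressure, config$partition_scale)
  }, numeric(1))
  c(pore_h, zone_h)
}

#' Simulate the cell population only
#'
#' Draws the ground-truth population (diameters, velocities, moduli, arrival
#' times, per-zone event times) of a simulation without synthesizing the
#' trace. The draws are identical to those embedded in [simulate_trace()]
#' for the same configuration.
#'
#' @param config An [sim_config()].
#' @return A list with tibbles `cells` and `zones`.
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "nps_sim_config"))
  withr::with_seed(config$seed, .draw_cells(config))
}

#' Generate a multi-channel resistance trace with ground truth
#'
#' Synthesizes the full forward model: each cell produces a top-hat pulse in
#' the sizing-pore channel (height set by the Coulter relation) followed by
#' one pulse per contraction zone whose in-pulse oscillation encodes the
#' cell's true viscoelastic stress response through the stress model and the
#' pressure-partition map. White Gaussian noise (scaled to the nominal pulse
#' height of each channel) and a slow sinusoidal baseline drift are added.
#' Identical configurations (including seed) give identical output.
#'
#' @param config An [sim_config()].
#' @return A list of class `nps_simulation`: `trace` (tibble with column `t`
#'   and one resistance column per channel, ohm), `cells` and `zones`
#'   ground-truth tibbles, and the `config`.
#' @examples
#' sim <- simulate_trace(sim_config(n_cells = 2, seed = 1, event_rate = 3600))
#' dplyr::glimpse(sim$zones)
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "nps_sim_config"))
  g <- config$geometry
  nz <- nrow(g$zones)
  sr <- g$sample_rate

  withr::with_seed(config$seed, {
    truth <- .draw_cells(config)
    cells <- truth$cells
    zones <- truth$zones

    t_end_all <- max(zones$t_end) + 2
    n <- ceiling(t_end_all * sr)
    tt <- (seq_len(n) - 1) / sr
    ch_names <- c("pore", paste0("zone", seq_len(nz)))
    heights <- .nominal_pulse_heights(config)

    sig <- matrix(0, nrow = n, ncol = nz + 1)
    idx_range <- function(t0, t1) {
      i0 <- max(1L, as.integer(ceiling(t0 * sr - 1e-9)) + 1L)
      i1 <- min(n, as.integer(floor(t1 * sr - 1e-9)) + 1L)
      if (i1 < i0) integer(0) else i0:i1
    }

    for (i in seq_len(nrow(cells))) {
      # sizing-pore top hat
      idx <- idx_range(cells$pore_start[i], cells$pore_end[i])
      sig[idx, 1] <- sig[idx, 1] +
        forward_blockage(cells$D_cell[i], g$pore$D_eff, g$pore$L_pore)
      zi <- zones[zones$cell_id == cells$cell_id[i], ]
      for (z in seq_len(nz)) {
        idx <- idx_range(zi$t_start[z], zi$t_end[z])
        if (!length(idx)) next
        if (cells$unstrained[i]) {
          # no wall contact: plain volumetric blockage, no oscillation
          sig[idx, z + 1] <- sig[idx, z + 1] +
            forward_blockage(cells$D_cell[i], g$zones$D_eff[z], g$zones$L_zone[z])
          next
        }
        tau <- tt[idx] - zi$t_start[z]
        x <- zi$v_true[z] * tau
        w <- g$zones$w0[z] + g$zones$a[z] * cos(2 * pi * x / g$zones$L_p[z])
        dd <- sqrt(2 * cells$D_cell[i]^3 / (3 * w))
        omega <- 2 * pi * zi$f_true[z]
        sigma <- zi$sigma_p_true[z] +
          zi$Gp_true[z] * zi$eps0_true[z] * cos(omega * tau) +
          zi$Gpp_true[z] * zi$eps0_true[z] * sin(omega * tau)
        dp <- .dp_from_stress(sigma, w, dd, g$mu_f)
        if (config$partition_mode == "constant") dp <- rep(mean(dp), length(dp))
        sig[idx, z + 1] <- sig[idx, z + 1] +
          .drr_from_dp(dp, g$applied_pressure, config$partition_scale)
      }
    }

    out <- matrix(0, nrow = n, ncol = nz + 1)
    for (ch in seq_len(nz + 1)) {
      rb <- config$r_base[ch]
      base <- rb * (1 + config$drift_amp *
        sin(2 * pi * tt / config$drift_period + (ch - 1) * pi / 3))
      noise <- if (config$noise_sd > 0) {
        rnorm(n, 0, config$noise_sd * heights[ch] * rb)
      } else 0
      out[, ch] <- base + rb * sig[, ch] + noise
    }
    colnames(out) <- ch_names
    trace <- tibble::as_tibble(out)
    trace <- dplyr::bind_cols(tibble::tibble(t = tt), trace)
  })

  structure(list(trace = trace, cells = cells, zones = zones, config = config),
    class = "nps_simulation")
}

#' @export
print.nps_simulation <- function(x, ...) {
  cat(sprintf("<nps_simulation> %d cells, %d channels, %.1f s at %g Hz (seed %d)\n",
    nrow(x$cells), ncol(x$trace) - 1, max(x$trace$t),
    x$config$geometry$sample_rate, x$config$seed))
  invisible(x)
}
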