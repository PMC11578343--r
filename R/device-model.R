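#' Contraction-zone width at a position
#'
#' The zone wall follows `w(x) = w0 + a * cos(2 * pi * x / L_p)`. Position 0
#' (zone entry) is the widest point, `w0 + a`, so a cell entering from the
#' relaxation node meets a monotonically narrowing wall; this also fixes the
#' phase reference used by the rheological fit.
#'
#' @param zone A one-row zone tibble ([zone_spec()]) or a list with `L_zone`,
#'   `L_p`, `w0`, `a`.
#' @param x Position(s) within the zone, um; must lie in `[0, L_zone]`.
#' @return Width(s) in um.
#' @examples
#' z <- zone_spec(1, 6000, 500, 11.25, 2.75)
#' contraction_width(z, c(0, 125, 250)) # 14, 11.25, 8.5
#' @export
contraction_width <- function(zone, x) {
  if (any(x < 0 | x > zone$L_zone)) {
    abort("Position `x` must lie within the zone [0, L_zone].",
      class = "nps_range_error")
  }
  zone$w0 + zone$a * cos(2 * pi * x / zone$L_p)
}

#' Strain waveform experienced by a transiting cell
#'
#' A cell of free diameter `D_cell` compressed to width `w` carries strain
#' `eps = (D_cell - w) / D_cell`, so transit through a sinusoidal zone at
#' velocity `v` applies `eps(t) = eps_mean - eps0 * cos(omega * t)` with
#' `eps_mean = (D_cell - w0) / D_cell`, `eps0 = a / D_cell`, and
#' `omega = 2 * pi * v / L_p` (t = 0 at zone entry, the widest point).
#' For the reference geometry (w0 = 11.25, a = 2.75) and an 18.4 um cell this
#' is approximately the 0.4 + 0.15 cos waveform the device was designed for.
#'
#' Cells no larger than the widest contraction (`D_cell <= w0 + a`) never make
#' full wall contact; they are flagged `unstrained` and must be excluded from
#' rheological fitting.
#'
#' @inheritParams contraction_width
#' @param D_cell Free cell diameter, um.
#' @param v Transit velocity, um/s.
#' @return A list of class `nps_strain_wave` with fields `eps_mean`, `eps0`,
#'   `f` (Hz), `omega` (rad/s), `phase0` (rad, 0 at entry), and `unstrained`.
#' @examples
#' z <- zone_spec(1, 6000, 500, 11.25, 2.75)
#' strain_wave(z, D_cell = 18.4, v = 6500)
#' @export
strain_wave <- function(zone, D_cell, v) {
  stopifnot(D_cell > 0, v > 0)
  unstrained <- D_cell <= zone$w0 + zone$a
  structure(list(
    eps_mean = max(0, (D_cell - zone$w0) / D_cell),
    eps0 = zone$a / D_cell,
    f = v / zone$L_p,
    omega = 2 * pi * v / zone$L_p,
    phase0 = 0,
    unstrained = unstrained), class = "nps_strain_wave")
}

#' Applied strain frequency
#'
#' The strain frequency in a zone is set by the transit velocity and the
#' period length: `f = v / L_p`. At fixed velocity, frequency is exactly
#' inversely proportional to `L_p`, which is how a multi-zone device probes
#' several frequencies in one pass.
#'
#' @param v Transit velocity, um/s.
#' @param L_p Period length, um.
#' @return Frequency in Hz.
#' @examples
#' applied_frequency(15000, 500) # 30 Hz
#' @export
applied_frequency <- function(v, L_p) {
  if (any(v <= 0) || any(L_p <= 0)) {
    abort("`v` and `L_p` must be positive.", class = "nps_range_error")
  }
  v / L_p
}

#' Deformed (wall-contact) diameter of a compressed cell
#'
#' A sphere of diameter `D_cell` squeezed to a gap `w` spreads laterally; by
#' conservation of volume its wall-contact diameter is
#' `D_d = sqrt(2 * D_cell^3 / (3 * w))`. The relation is the identity at
#' `w = 2 * D_cell / 3` and `D_d > D_cell` for any narrower gap. If
#' `w > D_cell` the cell is not touching both walls: `D_cell` is returned
#' unchanged with attribute `unstrained = TRUE`.
#'
#' @param D_cell Free cell diameter, um.
#' @param w Gap (contraction width), um.
#' @return Deformed diameter(s), um (attribute `unstrained` marks gaps wider
#'   than the cell).
#' @examples
#' deformed_diameter(18.4, 11.25) # 19.21 um
#' @export
deformed_diameter <- function(D_cell, w) {
  stopifnot(all(D_cell > 0), all(w > 0))
  unstr <- w > D_cell
  out <- sqrt(2 * D_cell^3 / (3 * w))
  if (any(unstr)) {
    out[unstr] <- (D_cell + 0 * w)[unstr]
    attr(out, "unstrained") <- TRUE
  }
  out
}

#' Free cell diameter from a relative resistance pulse (Coulter sizing)
#'
#' A cell in a current-carrying pore raises the pore resistance in proportion
#' to the displaced volume. With the finite-size (Deblois-Bean-type)
#' correction the relative pulse height is
#' `dR/R = D^3 / (D_eff^2 * L) * 1 / (1 - 0.8 * D^3 / (D_eff^3))`,
#' where `D_eff` is the empirically calibrated effective pore diameter and
#' `L` the pore length. `coulter_diameter()` is the exact algebraic inverse:
#' `D^3 = (dR/R) * D_eff^2 * L / (1 + 0.8 * (dR/R) * L / D_eff)`.
#'
#' @param dR_over_R Relative pulse height (dimensionless, >= 0).
#' @param D_eff Effective pore diameter, um.
#' @param L Pore length, um.
#' @return Free cell diameter(s), um. Zero iff `dR_over_R` is zero.
#' @examples
#' coulter_diameter(0.008293, 25, 1000) # 16.0 um
#' forward_blockage(16, 25, 1000)       # 0.008293
#' @export
coulter_diameter <- function(dR_over_R, D_eff, L) {
  if (any(dR_over_R < 0)) {
    abort("`dR_over_R` must be non-negative.", class = "nps_range_error")
  }
  denom <- 1 + 0.8 * dR_over_R * L / D_eff
  if (any(denom <= 0)) {
    abort("Blockage too large for the finite-size correction (saturation).",
      class = "nps_saturation_error")
  }
  (dR_over_R * D_eff^2 * L / denom)^(1 / 3)
}

#' @rdname coulter_diameter
#' @param D_cell Free cell diameter, um; must be smaller than `D_eff`.
#' @export
forward_blockage <- function(D_cell, D_eff, L) {
  if (any(D_cell < 0)) {
    abort("`D_cell` must be non-negative.", class = "nps_range_error")
  }
  if (any(D_cell >= D_eff)) {
    abort("`D_cell` must be smaller than the effective pore diameter.",
      class = "nps_range_error")
  }
  D_cell^3 / (D_eff^2 * L - 0.8 * D_cell^3 * L / D_eff)
}

#' Calibrate an effective diameter from reference cells
#'
#' Devices are calibrated by measuring particles or cells of independently
#' known diameter and fitting the effective diameter `D_eff` that makes the
#' sizing relation reproduce them. This solves the one-parameter least-squares
#' problem `min_Deff sum (coulter_diameter(r_i, D_eff, L) - D_i)^2`.
#'
#' @param D_ref Reference diameters, um.
#' @param dR_over_R Observed relative pulse heights for the same particles.
#' @param L Pore (or zone) length, um.
#' @param interval Search interval for `D_eff`, um.
#' @return Fitted `D_eff` (um).
#' @export
fit_effective_diameter <- function(D_ref, dR_over_R, L,
                                   interval = c(max(D_ref) + 0.5, 200)) {
  stopifnot(length(D_ref) == length(dR_over_R), length(D_ref) >= 1)
  obj <- function(deff) {
    sum((coulter_diameter(dR_over_R, deff, L) - D_ref)^2)
  }
  stats::optimize(obj, interval = interval)$minimum
}
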