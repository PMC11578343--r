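#' Describe one sinusoidal contraction zone
#'
#' A contraction zone is a channel segment whose width varies sinusoidally
#' along its length, `w(x) = w0 + a * cos(2 * pi * x / L_p)`, so that a cell
#' transiting at velocity `v` experiences an oscillatory compressive strain at
#' frequency `f = v / L_p`. All lengths are in micrometres.
#'
#' @param zone Ordinal index of the zone (1-based, in flow order).
#' @param L_zone Total zone length (um); must contain at least one full
#'   strain period (`L_zone >= L_p`).
#' @param L_p Period length of the width oscillation (um); sets the strain
#'   frequency for a given transit velocity.
#' @param w0 Mean contraction width (um).
#' @param a Width-oscillation amplitude (um), `0 < a < w0`.
#' @param w_node Width of the relaxation node downstream of the zone (um);
#'   must exceed `w0 + a` so cells relax between zones.
#' @param D_eff Effective (calibration) diameter of the zone channel (um).
#'
#' @return A one-row tibble with the validated zone parameters.
#' @examples
#' zone_spec(1, L_zone = 6000, L_p = 500, w0 = 11.25, a = 2.75)
#' @export
zone_spec <- function(zone, L_zone, L_p, w0, a, w_node = 21, D_eff = 25) {
  stopifnot(length(zone) == 1, length(L_zone) == 1, length(L_p) == 1)
  if (L_zone <= 0 || L_p <= 0) {
    abort("`L_zone` and `L_p` must be positive.", class = "nps_geometry_error")
  }
  if (!(a > 0 && a < w0)) {
    abort("Width amplitude must satisfy 0 < a < w0.", class = "nps_geometry_error")
  }
  if (L_zone / L_p < 1) {
    abort("A zone must contain at least one full strain period (L_zone >= L_p).",
      class = "nps_geometry_error")
  }
  if (w_node <= w0 + a) {
    abort("Node width must exceed the widest contraction (w_node > w0 + a).",
      class = "nps_geometry_error")
  }
  tibble::tibble(zone = as.integer(zone), L_zone = L_zone, L_p = L_p,
    w0 = w0, a = a, w_node = w_node, D_eff = D_eff)
}

#' Describe the Coulter sizing pore
#'
#' @param L_pore Pore length (um), the `L` of the sizing relation.
#' @param D_eff Effective diameter of the pore (um), determined by
#'   calibration; must exceed the largest expected cell diameter.
#'
#' @return A list with class `nps_pore`.
#' @export
pore_spec <- function(L_pore = 1000, D_eff = 25) {
  if (L_pore <= 0 || D_eff <= 0) {
    abort("Pore dimensions must be positive.", class = "nps_geometry_error")
  }
  structure(list(L_pore = L_pore, D_eff = D_eff), class = "nps_pore")
}

#' Assemble a device geometry
#'
#' Bundles the sizing pore, the ordered contraction zones, and the operating
#' conditions shared by the simulator and the analysis pipeline. Zone order
#' must match the electrode/channel order of the recorded trace.
#'
#' @param pore A [pore_spec()].
#' @param zones A tibble of zones, one row per zone, as returned by
#'   [zone_spec()] (rows are bound in flow order).
#' @param sample_rate Acquisition rate in samples per second (default 1e4).
#' @param applied_pressure Driving pressure in Pa (default 13800).
#' @param mu_f Friction coefficient between the strained cell and the channel
#'   wall (dimensionless, default 0.1).
#' @param node_length Length of each inter-zone node (um), used only for
#'   event timing in the simulator and for matching windows.
#' @param device_id Free-text device identifier carried into trace headers.
#'
#' @return An object of class `nps_geometry`.
#' @examples
#' geo <- default_geometry()
#' geo$zones
#' @export
device_geometry <- function(pore, zones, sample_rate = 1e4,
                            applied_pressure = 13800, mu_f = 0.1,
                            node_length = 300, device_id = "device") {
  if (!inherits(pore, "nps_pore")) abort("`pore` must be a pore_spec().",
    class = "nps_geometry_error")
  zones <- tibble::as_tibble(zones)
  req <- c("zone", "L_zone", "L_p", "w0", "a", "w_node", "D_eff")
  if (!all(req %in% names(zones)) || nrow(zones) < 1) {
    abort("`zones` must have columns zone, L_zone, L_p, w0, a, w_node, D_eff.",
      class = "nps_geometry_error")
  }
  if (!identical(zones$zone, seq_len(nrow(zones)))) {
    zones$zone <- seq_len(nrow(zones))
  }
  if (sample_rate <= 0 || applied_pressure <= 0 || mu_f <= 0 || node_length <= 0) {
    abort("Operating parameters must be positive.", class = "nps_geometry_error")
  }
  structure(
    list(pore = pore, zones = zones, sample_rate = sample_rate,
      applied_pressure = applied_pressure, mu_f = mu_f,
      node_length = node_length, device_id = device_id),
    class = "nps_geometry")
}

#' Default four-zone device geometry
#'
#' The reference device: a 1 mm sizing pore (effective diameter 25 um) followed
#' by four 6 mm contraction zones with period lengths 500, 250, 167, and
#' 125 um and width profile `11.25 + 2.75 cos` um, separated by 21 um nodes,
#' driven at 13.8 kPa and sampled at 10 kHz. With typical transit velocities
#' of 6-8 mm/s this spans strain frequencies of roughly 13-65 Hz.
#'
#' @param n_zones Number of zones to keep (1-4), counted from the first.
#' @param L_zone Zone length (um) applied to all zones.
#' @return An `nps_geometry`.
#' @export
default_geometry <- function(n_zones = 4, L_zone = 6000) {
  stopifnot(n_zones >= 1, n_zones <= 4)
  L_p <- c(500, 250, 167, 125)[seq_len(n_zones)]
  zones <- purrr::map2_dfr(seq_len(n_zones), L_p, function(i, lp) {
    zone_spec(i, L_zone = L_zone, L_p = lp, w0 = 11.25, a = 2.75,
      w_node = 21, D_eff = 25)
  })
  device_geometry(pore_spec(L_pore = 1000, D_eff = 25), zones,
    device_id = sprintf("mz%d-%gmm", n_zones, L_zone / 1000))
}

#' @export
print.nps_geometry <- function(x, ...) {
  cat(sprintf("<nps_geometry> %s: pore L=%g um (D_eff=%g), %d zone(s), %g Hz sampling, %g Pa\n",
    x$device_id, x$pore$L_pore, x$pore$D_eff, nrow(x$zones),
    x$sample_rate, x$applied_pressure))
  print(x$zones)
  invisible(x)
}

#' Read / write a device geometry configuration file
#'
#' The configuration is a plain-text YAML document with a `pore` block
#' (`L_pore`, `D_eff`), an ordered `zones` list (each with `L_zone`, `L_p`,
#' `w0`, `a`, `w_node`, `D_eff`), and top-level `sample_rate`,
#' `applied_pressure`, `mu_f`, `node_length`, and `device_id` keys. Unknown
#' keys are rejected.
#'
#' @param path File path.
#' @return `read_geometry()` returns an `nps_geometry`; `write_geometry()`
#'   returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Geometry file not found: %s", path), class = "nps_config_error")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("pore", "zones", "sample_rate", "applied_pressure", "mu_f",
    "node_length", "device_id")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(sprintf("Unknown geometry keys: %s", paste(extra, collapse = ", ")),
      class = "nps_config_error")
  }
  if (is.null(cfg$pore) || is.null(cfg$zones)) {
    abort("Geometry file must contain `pore` and `zones` blocks.",
      class = "nps_config_error")
  }
  zones <- purrr::imap_dfr(cfg$zones, function(z, i) {
    do.call(zone_spec, c(list(zone = i), z))
  })
  device_geometry(
    pore = pore_spec(cfg$pore$L_pore, cfg$pore$D_eff),
    zones = zones,
    sample_rate = cfg$sample_rate %||% 1e4,
    applied_pressure = cfg$applied_pressure %||% 13800,
    mu_f = cfg$mu_f %||% 0.1,
    node_length = cfg$node_length %||% 300,
    device_id = cfg$device_id %||% "device")
}

#' @rdname read_geometry
#' @param geometry An `nps_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "nps_geometry"))
  zones <- purrr::pmap(geometry$zones, function(zone, L_zone, L_p, w0, a, w_node, D_eff) {
    list(L_zone = L_zone, L_p = L_p, w0 = w0, a = a, w_node = w_node, D_eff = D_eff)
  })
  yaml::write_yaml(list(
    device_id = geometry$device_id,
    sample_rate = geometry$sample_rate,
    applied_pressure = geometry$applied_pressure,
    mu_f = geometry$mu_f,
    node_length = geometry$node_length,
    pore = list(L_pore = geometry$pore$L_pore, D_eff = geometry$pore$D_eff),
    zones = zones), path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
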