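# Shared fixtures: a small two-zone device and quick simulation configs keep
# the unit tests fast; the acceptance tests use the full reference device.

small_geometry <- function(L_zone = 2000) {
  zones <- dplyr::bind_rows(
    zone_spec(1, L_zone = L_zone, L_p = 500, w0 = 11.25, a = 2.75),
    zone_spec(2, L_zone = L_zone, L_p = 250, w0 = 11.25, a = 2.75))
  device_geometry(pore_spec(L_pore = 1000, D_eff = 25), zones,
    device_id = "test-mz2")
}

quick_sim <- function(n_cells = 3, seed = 1, noise_sd = 0, ...) {
  simulate_trace(sim_config(geometry = small_geometry(), n_cells = n_cells,
    seed = seed, noise_sd = noise_sd, event_rate = 1800, ...))
}

# join recovered per-zone fits with simulation truth
join_truth <- function(sim, res) {
  dplyr::inner_join(sim$zones, res$zones, by = c("cell_id", "zone"))
}
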