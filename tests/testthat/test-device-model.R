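test_that("contraction width follows the sinusoidal wall profile", {
  z <- zone_spec(1, L_zone = 6000, L_p = 500, w0 = 11.25, a = 2.75)
  expect_equal(contraction_width(z, 0), 14.0)          # entry = widest point
  expect_equal(contraction_width(z, 250), 8.5)         # half period = narrowest
  expect_equal(contraction_width(z, 125), 11.25)       # quarter period = mean
  # periodic with period L_p, bounded by w0 +/- a
  x <- seq(0, 5000, by = 7)
  expect_equal(contraction_width(z, x), contraction_width(z, x + 500))
  expect_true(all(contraction_width(z, x) >= 8.5 - 1e-12))
  expect_true(all(contraction_width(z, x) <= 14 + 1e-12))
  expect_error(contraction_width(z, -1), class = "nps_range_error")
  expect_error(contraction_width(z, 6001), class = "nps_range_error")
})

test_that("strain wave reproduces the design strain for typical cells", {
  z <- zone_spec(1, L_zone = 6000, L_p = 500, w0 = 11.25, a = 2.75)
  # 18.4 um cell in the reference contraction: ~0.4 + 0.15 cos
  w <- strain_wave(z, D_cell = 18.4, v = 6500)
  expect_equal(w$eps_mean, (18.4 - 11.25) / 18.4)
  expect_equal(round(w$eps_mean, 1), 0.4)
  expect_equal(w$eps0, 2.75 / 18.4)
  expect_equal(round(w$eps0, 2), 0.15)
  expect_equal(w$omega, 2 * pi * w$f)
  expect_false(w$unstrained)
  # bracketing across the plausible diameter range
  for (D in seq(18, 19.2, by = 0.2)) {
    ww <- strain_wave(z, D, v = 6500)
    expect_true(ww$eps_mean > 0.37 && ww$eps_mean < 0.42)
    expect_true(ww$eps0 > 0.14 && ww$eps0 < 0.16)
  }
  # definition f = v / L_p
  expect_equal(strain_wave(z, 18.4, v = 500)$f, 1)
  # small cells never reach full wall contact
  expect_true(strain_wave(z, D_cell = 13.9, v = 6500)$unstrained)
})

test_that("applied frequency is inversely proportional to the period length", {
  expect_equal(applied_frequency(15000, 500), 30)
  expect_equal(applied_frequency(6250, 500), 12.5)
  v <- 8000
  expect_equal(applied_frequency(v, 125) / applied_frequency(v, 500), 4)
  expect_equal(applied_frequency(v, 250), 2 * applied_frequency(v, 500))
  expect_error(applied_frequency(0, 500), class = "nps_range_error")
})

test_that("deformed diameter conserves volume and is the identity at w = 2D/3", {
  expect_equal(deformed_diameter(18, 12), 18, ignore_attr = TRUE)
  expect_equal(deformed_diameter(18.4, 11.25), sqrt(2 * 18.4^3 / (3 * 11.25)),
    ignore_attr = TRUE)
  expect_equal(deformed_diameter(18.4, 11.25), 19.2134, tolerance = 1e-4,
    ignore_attr = TRUE)
  expect_equal(deformed_diameter(20, 10), 23.094, tolerance = 1e-4,
    ignore_attr = TRUE)
  # monotone decreasing in w; exceeds D for any gap below 2D/3
  D <- 17
  w <- seq(8, 2 * D / 3, length.out = 40)
  dd <- deformed_diameter(D, w)
  expect_true(all(diff(dd) < 0))
  expect_true(all(dd >= D))
  # wider gap than the cell: unstrained, D returned unchanged
  out <- deformed_diameter(15, 16)
  expect_equal(as.numeric(out), 15)
  expect_true(attr(out, "unstrained"))
})

test_that("Coulter sizing inverts the forward blockage exactly", {
  expect_equal(coulter_diameter(0, 25, 1000), 0)
  expect_equal(forward_blockage(0, 25, 1000), 0)
  expect_equal(forward_blockage(16, 25, 1000), 0.008293, tolerance = 1e-4)
  expect_equal(coulter_diameter(0.008293, 25, 1000), 16, tolerance = 1e-4)
  # forward/inverse roundtrip over the physical range
  D <- seq(8, 22, by = 0.25)
  r <- forward_blockage(D, 25, 1000)
  expect_true(all(diff(r) > 0))
  expect_equal(coulter_diameter(r, 25, 1000), D, tolerance = 1e-9)
  # small-particle limit: volume ratio without correction
  expect_equal(forward_blockage(2, 25, 1000), 2^3 / (25^2 * 1000),
    tolerance = 1e-2)
  # half the volume gives about half the blockage in the uncorrected limit
  expect_equal(
    forward_blockage(3 * 0.5^(1 / 3), 25, 1000) / forward_blockage(3, 25, 1000),
    0.5, tolerance = 1e-3)
  expect_error(forward_blockage(25, 25, 1000), class = "nps_range_error")
  expect_error(coulter_diameter(-0.1, 25, 1000), class = "nps_range_error")
})

test_that("effective-diameter calibration recovers the true value", {
  D_ref <- c(10, 13, 16, 19, 21)
  r <- forward_blockage(D_ref, 25, 1000)
  expect_equal(fit_effective_diameter(D_ref, r, 1000), 25, tolerance = 1e-4)
  # still close under mild measurement scatter
  withr::with_seed(3, r_noisy <- r * (1 + rnorm(5, 0, 0.01)))
  expect_equal(fit_effective_diameter(D_ref, r_noisy, 1000), 25, tolerance = 0.05)
})

test_that("geometry invariants are enforced and config files round-trip", {
  expect_error(zone_spec(1, 6000, 500, w0 = 11.25, a = 12), class = "nps_geometry_error")
  expect_error(zone_spec(1, 400, 500, w0 = 11.25, a = 2.75), class = "nps_geometry_error")
  expect_error(zone_spec(1, 6000, 500, w0 = 11.25, a = 2.75, w_node = 13),
    class = "nps_geometry_error")
  expect_error(pore_spec(L_pore = -1), class = "nps_geometry_error")

  geo <- default_geometry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_geometry(geo, path)
  geo2 <- read_geometry(path)
  expect_equal(geo2$zones, geo$zones)
  expect_equal(geo2$pore$D_eff, geo$pore$D_eff)
  expect_equal(geo2$sample_rate, geo$sample_rate)

  writeLines("pore: {L_pore: 1000, D_eff: 25}\nzones:\n- {L_zone: 6000, L_p: 500, w0: 11.25, a: 2.75}\nbogus_key: 1",
    path)
  expect_error(read_geometry(path), class = "nps_config_error")
  expect_error(read_geometry("no/such/file.yaml"), class = "nps_config_error")
})
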