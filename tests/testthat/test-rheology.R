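test_that("rheological least squares recovers coefficients exactly", {
  eps0 <- 0.15
  omega <- 2 * pi * 13
  tau <- seq(0, 0.5, length.out = 200)
  mk <- function(sp, gp, gpp) tibble::tibble(
    sigma = sp + gp * eps0 * cos(omega * tau) + gpp * eps0 * sin(omega * tau),
    eps_cos = eps0 * cos(omega * tau), eps_sin = eps0 * sin(omega * tau))
  fit <- fit_rheology(mk(10, 500, 50))
  expect_equal(fit$sigma_p, 10, tolerance = 1e-9)
  expect_equal(fit$Gp, 500, tolerance = 1e-9)
  expect_equal(fit$Gpp, 50, tolerance = 1e-9)
  expect_lt(fit$residual_rms, 1e-9)
  # constant stress: pure pre-stress
  fitc <- fit_rheology(mk(42, 0, 0))
  expect_equal(c(fitc$sigma_p, fitc$Gp, fitc$Gpp), c(42, 0, 0), tolerance = 1e-9)
  # pure sine input loads only the loss modulus
  fits <- fit_rheology(mk(0, 0, 77))
  expect_equal(fits$Gp, 0, tolerance = 1e-9)
  expect_equal(fits$Gpp, 77, tolerance = 1e-9)
  # rank-deficient basis
  bad <- tibble::tibble(sigma = 1:10, eps_cos = rep(0, 10), eps_sin = rep(0, 10))
  expect_error(fit_rheology(bad), class = "nps_fit_error")
  expect_error(fit_rheology(mk(1, 1, 1)[1:2, ]), class = "nps_fit_error")
})

test_that("least squares agrees with a normal-equations oracle", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(10:50, 1)
      tau <- sort(runif(n, 0, 1))
      eps0 <- runif(1, 0.05, 0.3)
      omega <- runif(1, 10, 400)
      X <- cbind(1, eps0 * cos(omega * tau), eps0 * sin(omega * tau))
      y <- rnorm(n)
      fit <- fit_rheology(tibble::tibble(sigma = y, eps_cos = X[, 2],
        eps_sin = X[, 3]))
      beta <- solve(t(X) %*% X, t(X) %*% y) # brute-force normal equations
      expect_equal(c(fit$sigma_p, fit$Gp, fit$Gpp), as.numeric(beta),
        tolerance = 1e-9)
    }
  })
})

test_that("stress reconstruction matches the worked pressure-drop example", {
  # a 100 Pa drop across an 18.4 um cell in the 11.25 um contraction
  dd <- deformed_diameter(18.4, 11.25)
  sigma <- blockage_to_stress((100 / 13800) / (1 - 100 / 13800),
    w = 11.25, D_d = dd, mu_f = 0.1, P_applied = 13800)
  expect_equal(sigma, 2 * 100 * 11.25 / (0.1 * pi * dd), tolerance = 1e-12)
  expect_equal(sigma, 372.8, tolerance = 1e-3)
  expect_equal(blockage_to_stress(0, 11.25, dd, 0.1, 13800), 0)
  # friction is inversely proportional
  expect_equal(blockage_to_stress(0.005, 11.25, dd, 0.2, 13800),
    blockage_to_stress(0.005, 11.25, dd, 0.1, 13800) / 2)
})

test_that("stress series requires a strained cell and builds a valid basis", {
  geo <- small_geometry()
  smp <- tibble::tibble(t = seq(1, 1.4, by = 1e-4), drr = 1e-3)
  expect_error(compute_stress_series(smp, geo$zones[1, ], D_cell = 13,
    geometry = geo, t_entry = 1, transit = 0.4),
    class = "nps_unstrained_error")
  ser <- compute_stress_series(smp, geo$zones[1, ], D_cell = 18,
    geometry = geo, t_entry = 1, transit = 0.4)
  expect_s3_class(ser, "nps_stress_series")
  expect_equal(attr(ser, "eps0"), 2.75 / 18)
  expect_equal(attr(ser, "f"), (2000 / 0.4) / 500)
  expect_true(all(ser$tau >= 0 & ser$tau <= 0.4))
})

test_that("sizing from simulated pore pulses matches the true diameters", {
  sim <- quick_sim(n_cells = 5, seed = 23)
  ev <- detect_events(sim$trace, sim$config$geometry)
  sizes <- size_cells(ev, sim$config$geometry)
  expect_equal(sizes$D_cell, sim$cells$D_cell, tolerance = 1e-3)
  expect_equal(coulter_diameter(0, 25, 1000), 0) # no blockage, no cell
})

test_that("assembly computes loss tangent and detection flags", {
  fits <- tibble::tibble(cell_id = c(1L, 1L, 2L), zone = c(1L, 2L, 1L),
    sigma_p = c(10, 10, 8), Gp = c(500, 480, -5), Gpp = c(50, 0.05, 20),
    residual_rms = 0.1, f_applied = c(13, 30, 13))
  sizes <- tibble::tibble(cell_id = 1:3, D_cell = c(18, 17, 16))
  asm <- assemble_result(fits, sizes)
  expect_equal(asm$zones$eta[1], 0.1)
  expect_true(asm$zones$below_detection[2])  # Gpp = 0.05 < 0.1 Pa
  expect_false(asm$zones$below_detection[1])
  expect_true(asm$zones$negative_modulus[3]) # flagged, not clipped
  expect_equal(asm$zones$Gp[3], -5)
  expect_true(is.na(asm$zones$eta[3]))
  cells <- asm$cells
  expect_true(cells$below_detection[cells$cell_id == 1])
  expect_false(cells$fitted[cells$cell_id == 3]) # no zone fits at all
  expect_equal(cells$n_zones_fit, c(2L, 1L, 0L))
})

test_that("noiseless end-to-end recovery is exact to within one percent", {
  sim <- quick_sim(n_cells = 4, seed = 31)
  res <- nps_analyze(sim$trace, sim$config$geometry)
  expect_equal(res$log$cells_fitted, 4)
  m <- join_truth(sim, res)
  expect_equal(nrow(m), 8)
  expect_true(all(abs(m$Gp / m$Gp_true - 1) < 0.01))
  expect_true(all(abs(m$Gpp / m$Gpp_true - 1) < 0.01))
  expect_true(all(abs(m$sigma_p / m$sigma_p_true - 1) < 0.01))
  cells <- dplyr::inner_join(sim$cells, res$cells, by = "cell_id")
  expect_true(all(abs(cells$D_cell.y / cells$D_cell.x - 1) < 0.01))
})

test_that("doubling the population stiffness doubles the recovered medians", {
  run_median_gp <- function(gp) {
    sim <- simulate_trace(sim_config(geometry = small_geometry(), n_cells = 6,
      seed = 37, noise_sd = 0.05, event_rate = 1800,
      moduli = modulus_model(gp = gp, gpp = gp / 10)))
    res <- nps_analyze(sim$trace, sim$config$geometry)
    median(res$zones$Gp)
  }
  ratio <- run_median_gp(400) / run_median_gp(200)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("tidy, glance, and autoplot expose the results", {
  sim <- quick_sim(n_cells = 3, seed = 41)
  res <- nps_analyze(sim$trace, sim$config$geometry)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_true(all(c("cell_id", "zone", "D_cell", "f_applied", "Gp", "Gpp",
    "eta") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_cells, 3)
  expect_equal(gl$n_fitted, 3)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  p2 <- plot_trace(sim$trace, tlim = c(0, 5))
  expect_s3_class(p2, "ggplot")
})
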