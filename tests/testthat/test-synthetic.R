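test_that("the extinction fixture has the landmark spectral features", {
  tab <- make_extinction_fixture()
  expect_s3_class(tab, "extinction_table")
  expect_equal(nrow(tab), 401)  # 500-700 nm at 0.5 nm steps
  expect_equal(range(tab$wavelength_nm), c(500, 700))
  expect_true(all(tab$eps_hbo2 >= 0 & tab$eps_hb >= 0 & tab$eps_methb >= 0))
  eps_at <- function(col, wl) tab[[col]][tab$wavelength_nm == wl]
  # MetHb: local diagnostic peak at 630 nm
  expect_gt(eps_at("eps_methb", 630), eps_at("eps_methb", 600))
  expect_gt(eps_at("eps_methb", 630), eps_at("eps_methb", 660))
  # HbO2: double peak between 540 and 580 nm
  expect_gt(eps_at("eps_hbo2", 542), eps_at("eps_hbo2", 560))
  expect_gt(eps_at("eps_hbo2", 577), eps_at("eps_hbo2", 560))
  expect_gt(eps_at("eps_hbo2", 542), eps_at("eps_hbo2", 520))
  expect_gt(eps_at("eps_hbo2", 577), eps_at("eps_hbo2", 600))
})

test_that("methb time-series generator is exact at zero noise and seeded", {
  p <- kinetic_params(a = 9e-4, beta = 0.973, gamma = 3e-3, y0 = 1700, z0 = 5)
  cfg0 <- simulation_config(kinetic_params = p, methb_noise_sd_percent = 0,
                            n_replicates = 2, seed = 4L)
  sim0 <- simulate_methb_timeseries(cfg0)
  expect_equal(sim0$methb_um, sim0$methb_true_um)
  expect_equal(sim0$methb_true_um[sim0$replicate == 1],
               methb_time(cfg0$t_grid_min, p))
  cfg <- simulation_config(kinetic_params = p, seed = 8L)
  expect_identical(simulate_methb_timeseries(cfg),
                   simulate_methb_timeseries(cfg))
  cfg2 <- simulation_config(kinetic_params = p, seed = 9L)
  expect_false(identical(simulate_methb_timeseries(cfg)$methb_um,
                         simulate_methb_timeseries(cfg2)$methb_um))
  # noise is bounded by the physical range [0, z0]
  expect_true(all(simulate_methb_timeseries(cfg)$methb_um >= 0))
  expect_true(all(simulate_methb_timeseries(cfg)$methb_um <= 5))
})

test_that("replicate means converge to the closed form", {
  p <- kinetic_params(a = 9e-4, beta = 0.973, gamma = 3e-3, y0 = 850, z0 = 5)
  cfg <- simulation_config(kinetic_params = p, n_replicates = 200, seed = 12L)
  sim <- simulate_methb_timeseries(cfg)
  truth <- methb_time(cfg$t_grid_min, p)
  sigma <- 0.01 * 5
  for (i in seq_along(cfg$t_grid_min)) {
    at_t <- sim$methb_um[sim$time_min == cfg$t_grid_min[i]]
    se <- sd(at_t) / sqrt(length(at_t))
    if (truth[i] > 3 * sigma && truth[i] < 5 - 3 * sigma) {
      # interior points: unbiased within Monte Carlo error
      expect_lt(abs(mean(at_t) - truth[i]), 3 * se)
    } else {
      # boundary points are clipped; the bias is at most the half-normal
      # mean sigma / sqrt(2 pi)
      expect_lt(abs(mean(at_t) - truth[i]), sigma / sqrt(2 * pi) + 3 * se)
    }
  }
})

test_that("spectra series couples the kinetic model to the forward model", {
  p <- kinetic_params(a = 9e-4, beta = 0.973, gamma = 3e-3, y0 = 1700, z0 = 5)
  cfg <- simulation_config(kinetic_params = p, spectrum_noise_sd = 0,
                           seed = 14L)
  out <- simulate_spectra_series(cfg)
  tab <- make_extinction_fixture()
  expect_length(out$spectra, length(cfg$t_grid_min))
  expect_equal(out$truth$c_methb, methb_time(cfg$t_grid_min, p))
  # conservation by construction
  expect_equal(out$truth$c_hbo2 + out$truth$c_methb,
               rep(5, nrow(out$truth)))
  for (i in seq_along(out$spectra)) {
    fit <- fit_spectrum(out$spectra[[i]], tab, allow_scatter = FALSE)
    expect_equal(fit$c_methb, out$truth$c_methb[i], tolerance = 1e-6)
    expect_equal(fit$c_hbo2, out$truth$c_hbo2[i], tolerance = 1e-6)
    expect_equal(fit$c_hbo2 + fit$c_methb, 5, tolerance = 1e-6)
  }
  # at t = 0 no methemoglobin has formed yet
  fit0 <- fit_spectrum(out$spectra[[1]], tab, allow_scatter = FALSE)
  expect_equal(fit0$c_methb, 0, tolerance = 1e-8)
})

test_that("force-curve ensembles carry their ground truth", {
  cfg <- simulation_config(n_cells = 30, seed = 16L)
  probe <- probe_params()
  ens0 <- simulate_force_curves(cfg, probe, noise_cv = 0)
  expect_named(ens0, c("control_1h", "exposed_1h", "control_24h",
                       "exposed_24h"))
  g <- ens0$exposed_1h
  expect_length(g$e_true_kpa, 30)
  expect_true(all(g$e_true_kpa > 1))
  # zero noise: the fitted modulus equals the drawn one
  for (i in c(1, 15, 30)) {
    expect_equal(fit_youngs_modulus(g$curves[[i]], probe), g$e_true_kpa[i],
                 tolerance = 1e-9)
  }
  # determinism under a fixed seed
  ens0b <- simulate_force_curves(cfg, probe, noise_cv = 0)
  expect_identical(ens0$exposed_24h$e_true_kpa, ens0b$exposed_24h$e_true_kpa)
})

test_that("drawn moduli match the configured group moments", {
  cfg <- simulation_config(n_cells = 100, seed = 18L)
  ens <- simulate_force_curves(cfg, probe_params())
  for (gname in names(ens)) {
    m <- cfg$force_group_means_kpa[[gname]]
    s <- cfg$force_group_sds_kpa[[gname]]
    draws <- ens[[gname]]$e_true_kpa
    # truncation at 1 kPa shifts the mean upward by well under one SE here
    expect_lt(abs(mean(draws) - m), 3 * s / sqrt(100) + 0.15)
  }
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  cfg <- simulation_config(seed = 5L)
  invisible(simulate_methb_timeseries(cfg))
  invisible(simulate_force_curves(cfg, probe_params()))
  invisible(recovery_experiment(n_replicates = 1L, y0_grid = c(1700),
                                seed = 2L))
  expect_identical(.Random.seed, before)
})
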