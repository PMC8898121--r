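#' Seeded synthetic-data generators
#'
#' Generators that emulate each measurement type in the iron-exposure
#' pipeline so that every stage (unmixing, kinetic fitting, stiffness
#' estimation) can be exercised end-to-end with known ground truth: a
#' literature-shaped extinction table, MetHb time courses driven by the
#' closed-form kinetic model, absorbance spectra built from those
#' concentrations, and Hertz force-curve ensembles. All generators are pure
#' functions of their configuration and seed.
#'
#' @name synthetic_data
NULL

#' Default simulation configuration
#'
#' Collects the study conditions used by the generators: the fitted kinetic
#' parameter set (a = 0.00090 µM, beta = 0.973 µM^-1 min^-1,
#' gamma = 0.0030 µM^-2 min^-1, Z0 = 5 µM), the hemolysate incubation grid
#' (0, 15, 30, 45, 60, 90, 120 min and 24 h), spectrophotometer noise (additive
#' Gaussian, SD 0.002 absorbance), MetHb measurement noise (1% of Z0),
#' force-curve group moments (control 11 +/- 4 and 15 +/- 5 kPa at 1 h and
#' 24 h; iron-exposed 17 +/- 5 and 23 +/- 8 kPa) and 100 cells per group.
#'
#' @param kinetic_params a [kinetic_params()]; default is the fitted set
#'   with `y0 = 1700` µM.
#' @param t_grid_min incubation time grid, minutes.
#' @param spectrum_noise_sd additive absorbance noise SD.
#' @param methb_noise_sd_percent MetHb noise SD as percent of `z0`.
#' @param n_replicates replicate curves per condition.
#' @param force_group_means_kpa,force_group_sds_kpa named numeric vectors of
#'   per-group modulus moments, kPa.
#' @param n_cells force curves (cells) per group.
#' @param seed integer seed recorded in every generated object.
#' @return a list of class `"simulation_config"`.
#' @export
simulation_config <- function(
    kinetic_params = ferrokin::kinetic_params(a = 9e-4, beta = 0.973,
                                              gamma = 3e-3, y0 = 1700, z0 = 5),
    t_grid_min = c(0, 15, 30, 45, 60, 90, 120, 1440),
    spectrum_noise_sd = 0.002,
    methb_noise_sd_percent = 1.0,
    n_replicates = 20L,
    force_group_means_kpa = c(control_1h = 11, exposed_1h = 17,
                              control_24h = 15, exposed_24h = 23),
    force_group_sds_kpa = c(control_1h = 4, exposed_1h = 5,
                            control_24h = 5, exposed_24h = 8),
    n_cells = 100L,
    seed = 1L) {
  stopifnot(inherits(kinetic_params, "kinetic_params"))
  if (spectrum_noise_sd < 0 || methb_noise_sd_percent < 0) {
    stop("simulation_config(): noise SDs must be >= 0", call. = FALSE)
  }
  if (n_replicates < 1L || n_cells < 1L) {
    stop("simulation_config(): n_replicates and n_cells must be >= 1",
         call. = FALSE)
  }
  if (length(force_group_means_kpa) != length(force_group_sds_kpa)) {
    stop("simulation_config(): force group means and sds lengths differ",
         call. = FALSE)
  }
  structure(
    list(kinetic_params = kinetic_params,
         t_grid_min = as.numeric(t_grid_min),
         spectrum_noise_sd = spectrum_noise_sd,
         methb_noise_sd_percent = methb_noise_sd_percent,
         n_replicates = as.integer(n_replicates),
         force_group_means_kpa = force_group_means_kpa,
         force_group_sds_kpa = force_group_sds_kpa,
         n_cells = as.integer(n_cells),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# smooth positive Gaussian bump helper for the fixture curves
.bump <- function(x, center, width, height) {
  height * exp(-0.5 * ((x - center) / width)^2)
}

#' Literature-shaped extinction coefficient fixture
#'
#' A smooth synthetic stand-in for published hemoglobin molar-absorptivity
#' tables on the 500-700 nm grid at 0.5 nm steps (401 rows), built from
#' Gaussian bands placed at the landmark wavelengths of the real
#' chromophores: the HbO2 double peak near 542 and 577 nm, the single broad
#' Hb band near 555 nm, and the MetHb bands near 500 and 630 nm (the 630 nm
#' band is the diagnostic MetHb feature). Values are in mM^-1 cm^-1 with
#' realistic magnitudes; the curves are synthetic, not digitized data, and
#' users with a measured table should load it with [read_extinction_csv()].
#'
#' @return an [extinction_table()] with 401 rows.
#' @export
make_extinction_fixture <- function() {
  wl <- seq(500, 700, by = 0.5)
  # HbO2: double peak (542, 577), weak red-region tail
  eps_hbo2 <- .bump(wl, 542, 12, 14.5) + .bump(wl, 577, 10, 15.5) +
    .bump(wl, 500, 40, 4.5) + 0.05
  # Hb: single broad band at 555, larger red-region absorbance than HbO2
  eps_hb <- .bump(wl, 555, 22, 13.0) + .bump(wl, 500, 45, 4.0) +
    .bump(wl, 650, 60, 0.9) + 0.05
  # MetHb: strong band toward 500 nm and the diagnostic 630 nm peak
  eps_methb <- .bump(wl, 500, 30, 9.0) + .bump(wl, 630, 18, 3.9) +
    .bump(wl, 578, 25, 1.2) + 0.05
  extinction_table(wl, eps_hbo2, eps_hb, eps_methb)
}

#' Simulate noisy methemoglobin time courses
#'
#' Draws `n_replicates` noisy realizations of the closed-form MetHb curve:
#' `x_noisy(t) = clip(x(t) + e_t, 0, z0)` with
#' `e_t ~ N(0, (methb_noise_sd_percent/100) z0)`.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` with columns `replicate`, `time_min`, `methb_um`,
#'   `methb_true_um`; attributes `params` and `seed`.
#' @export
simulate_methb_timeseries <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$kinetic_params
  t <- config$t_grid_min
  truth <- methb_time(t, p)
  sigma <- config$methb_noise_sd_percent / 100 * p$z0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    noisy <- pmin(pmax(truth + stats::rnorm(length(t), 0, sigma), 0), p$z0)
    data.frame(replicate = r, time_min = t, methb_um = noisy,
               methb_true_um = truth)
  })
  out <- do.call(rbind, reps)
  attr(out, "params") <- p
  attr(out, "seed") <- config$seed
  out
}

#' Simulate an absorbance-spectrum time series
#'
#' Couples the kinetic model to the Beer-Lambert mixture: at each time
#' point, `C_MetHb = x(t)`, `C_HbO2 = Z0 - x(t)` and `C_Hb = 0` (the
#' default hemolysate scenario tracks the HbO2 -> MetHb conversion), and a
#' spectrum is built with [model_spectrum()] plus additive Gaussian
#' absorbance noise.
#'
#' @param config a [simulation_config()].
#' @param table an [extinction_table()]; default the bundled fixture.
#' @param k,s scattering baseline used in the forward model (default 0,
#'   hemolysate).
#' @return a list with `spectra` (list of [hb_spectrum()], one per time
#'   point) and `truth` (data.frame of generating concentrations per time
#'   point).
#' @export
simulate_spectra_series <- function(config, table = make_extinction_fixture(),
                                    k = 0, s = 0) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$kinetic_params
  t <- config$t_grid_min
  x <- methb_time(t, p)
  truth <- data.frame(time_min = t, c_hbo2 = p$z0 - x, c_hb = 0, c_methb = x,
                      k = k, s = s)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  spectra <- lapply(seq_along(t), function(i) {
    sp <- model_spectrum(truth$c_hbo2[i], 0, truth$c_methb[i], k, s, table)
    noisy <- sp$optical_density +
      stats::rnorm(nrow(sp), 0, config$spectrum_noise_sd)
    hb_spectrum(sp$wavelength_nm, noisy)
  })
  list(spectra = spectra, truth = truth, seed = config$seed)
}

#' Simulate Hertz force-curve ensembles
#'
#' For each group, draws `n_cells` Young's moduli from
#' `Normal(mean, sd)` truncated below at 1 kPa (moduli are physically
#' positive), then samples each cell's force curve on `n_points` depths
#' over \[0, `h_max_nm`\] with multiplicative Gaussian noise
#' `F_noisy = F (1 + e)`, `e ~ N(0, noise_cv)`.
#'
#' @param config a [simulation_config()] (group moments, n_cells, seed).
#' @param probe a [probe_params()].
#' @param h_max_nm maximum indentation, nm.
#' @param n_points samples per curve.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @return a list with one element per group, each containing `e_true_kpa`
#'   (length `n_cells`) and `curves` (list of [force_curve()]).
#' @export
simulate_force_curves <- function(config, probe = probe_params(),
                                  h_max_nm = 1000, n_points = 50L,
                                  noise_cv = 0.02) {
  stopifnot(inherits(config, "simulation_config"))
  means <- config$force_group_means_kpa
  sds <- config$force_group_sds_kpa
  if (any(means <= 0) || any(sds <= 0)) {
    stop("simulate_force_curves(): group means and sds must be positive",
         call. = FALSE)
  }
  h <- seq(0, h_max_nm, length.out = n_points)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  out <- lapply(seq_along(means), function(g) {
    e_true <- .rnorm_trunc(config$n_cells, means[g], sds[g], lower = 1)
    curves <- lapply(e_true, function(e) {
      f <- hertz_force(e, probe, h)
      if (noise_cv > 0) {
        f <- f * (1 + stats::rnorm(length(h), 0, noise_cv))
      }
      force_curve(h, f)
    })
    list(e_true_kpa = e_true, curves = curves)
  })
  names(out) <- names(means)
  attr(out, "seed") <- config$seed
  out
}

# truncated-normal draws by rejection (truncation far in the lower tail for
# the default group moments, so rejection is cheap)
.rnorm_trunc <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw > lower])
  }
  out[seq_len(n)]
}

# save/restore the global RNG state so generators are pure in (config, seed)
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
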