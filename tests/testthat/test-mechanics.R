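probe <- probe_params(radius_nm = 150, poisson_ratio = 0.5)

test_that("hertz force has the spherical-indenter form and units", {
  expect_equal(hertz_force(17, probe, 0), 0)
  # worked value: E = 17 kPa, R = 150 nm, nu = 0.5, h = 1000 nm -> 11.7 nN
  expect_equal(hertz_force(17, probe, 1000), 11.705, tolerance = 1e-4)
  # linear in E, h^(3/2) in indentation
  expect_equal(hertz_force(34, probe, 500), 2 * hertz_force(17, probe, 500))
  expect_equal(hertz_force(17, probe, 400) / hertz_force(17, probe, 100),
               4^1.5, tolerance = 1e-12)
  expect_error(hertz_force(17, probe, -5), ">= 0")
  expect_error(probe_params(radius_nm = -1), "positive")
  expect_error(probe_params(poisson_ratio = 0.7), "0.5")
})

test_that("modulus fitting inverts the Hertz forward model", {
  h <- seq(0, 1000, length.out = 50)
  for (e_true in c(11, 17, 23, 1, 100)) {
    curve <- force_curve(h, hertz_force(e_true, probe, h))
    expect_equal(fit_youngs_modulus(curve, probe), e_true, tolerance = 1e-6)
  }
  # round-trip across the physiological range
  set.seed(13)
  for (i in 1:20) {
    e_true <- runif(1, 1, 100)
    curve <- force_curve(h, hertz_force(e_true, probe, h))
    expect_equal(fit_youngs_modulus(curve, probe), e_true, tolerance = 1e-9)
  }
})

test_that("modulus fitting is accurate under multiplicative noise", {
  set.seed(17)
  h <- seq(0, 1000, length.out = 50)
  e_true <- 17
  clean <- hertz_force(e_true, probe, h)
  est <- replicate(100, {
    fit_youngs_modulus(force_curve(h, clean * (1 + rnorm(50, 0, 0.02))),
                       probe)
  })
  expect_lt(abs(mean(est) - e_true) / e_true, 0.02)
})

test_that("modulus fitting rejects unusable curves", {
  h <- seq(0, 1000, length.out = 50)
  expect_error(fit_youngs_modulus(force_curve(c(0, 1, 2, 3), c(0, 1, 2, 3)),
                                  probe), ">= 5")
  expect_error(fit_youngs_modulus(force_curve(h, -hertz_force(5, probe, h)),
                                  probe), "not positive")
})

test_that("modulus distributions normalize and match the rank ECDF", {
  set.seed(19)
  values <- rnorm(100, 15, 5)
  values <- values[values > 0]
  d <- modulus_distribution(values, bins = 12)
  # histogram densities integrate to one
  expect_equal(sum(d$density * diff(d$breaks)), 1, tolerance = 1e-12)
  expect_equal(sum(d$counts), length(values))
  # ECDF equals the sorted-rank oracle at every sample point
  sorted <- sort(values)
  expect_equal(d$ecdf(sorted), seq_along(sorted) / length(sorted))
  expect_equal(d$ecdf(max(values)), 1)
  # single value: unit step
  d1 <- modulus_distribution(5, bins = 4)
  expect_equal(d1$ecdf(4.999), 0)
  expect_equal(d1$ecdf(5), 1)
  expect_error(modulus_distribution(numeric(0)), "nonempty")
})

test_that("histogram mass below a cut agrees with the ECDF", {
  set.seed(23)
  values <- rgamma(400, shape = 9, rate = 0.5)
  d <- modulus_distribution(values, bins = 20)
  w <- diff(d$breaks)
  for (k in c(5, 10, 15, 20)) {
    cut <- d$breaks[k + 1]
    mass <- sum(d$density[seq_len(k)] * w[seq_len(k)])
    expect_equal(mass, d$ecdf(cut), tolerance = max(w))
  }
})

test_that("fraction beyond control behaves like an empirical quantile", {
  set.seed(29)
  same <- rnorm(2000, 15, 5)
  # treatment identical to control: ~ (1 - level) of values exceed
  expect_equal(fraction_beyond_control(same, same, 0.95), 5, tolerance = 0.5)
  shifted <- same + 100
  expect_equal(fraction_beyond_control(shifted, same, 0.95), 100)
  # direct-counting oracle on seeded draws matching the 24 h group moments
  control <- rnorm(100, 15, 5)
  treat <- rnorm(100, 23, 8)
  q <- sort(control)[ceiling(0.95 * 100)]  # conservative rank bound
  got <- fraction_beyond_control(treat, control, 0.95)
  oracle <- 100 * sum(treat > stats::quantile(control, 0.95, type = 7)) / 100
  expect_equal(got, oracle)
  # sanity: well within (0, 100), in the vicinity of one third
  expect_gt(got, 10)
  expect_lt(got, 70)
  expect_error(fraction_beyond_control(treat, control, 1), "strictly")
})

test_that("fraction beyond control is invariant under monotone rescaling", {
  set.seed(37)
  control <- rgamma(150, 8, 0.5)
  treat <- rgamma(150, 12, 0.5)
  base <- fraction_beyond_control(treat, control)
  expect_equal(fraction_beyond_control(log(treat), log(control)), base)
  expect_equal(fraction_beyond_control(treat^3, control^3), base)
  expect_equal(fraction_beyond_control(2 * treat + 7, 2 * control + 7), base)
})

test_that("profile features recover period and height of a cosine", {
  pos <- seq(0, 5000, by = 5)
  period_true <- 900
  amp <- 120
  z <- amp * cos(2 * pi * pos / period_true)
  pf <- profile_features(z, pos)
  expect_equal(pf$period_nm, period_true, tolerance = 0.01)
  expect_equal(pf$height_nm, 2 * amp, tolerance = 0.01)
  expect_error(profile_features(rep(3, 100), seq_len(100)), "flat")
  expect_error(profile_features(seq_len(100), seq_len(100)), "flat|monotone")
})

test_that("profile features match a brute-force extrema scan", {
  set.seed(41)
  pos <- seq(0, 8000, by = 4)
  z <- 100 * cos(2 * pi * pos / 1100) + 30 * cos(2 * pi * pos / 230 + 1)
  pf <- profile_features(z, pos)
  # brute force: interior strict extrema
  n <- length(z)
  is_min <- which(z[2:(n - 1)] < z[1:(n - 2)] & z[2:(n - 1)] < z[3:n]) + 1
  is_max <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] > z[3:n]) + 1
  expect_equal(pf$n_minima, length(is_min))
  expect_equal(pf$period_nm, mean(diff(pos[is_min])), tolerance = 1e-9)
  hts <- vapply(is_max, function(m) {
    left <- is_min[is_min < m]; right <- is_min[is_min > m]
    if (length(left) && length(right)) {
      z[m] - mean(c(z[max(left)], z[min(right)]))
    } else NA_real_
  }, numeric(1))
  expect_equal(pf$height_nm, mean(hts, na.rm = TRUE), tolerance = 1e-9)
})
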