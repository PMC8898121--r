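#' Membrane stiffness from force-indentation curves
#'
#' Atomic force spectroscopy presses a spherical probe of radius R into the
#' cell membrane and records force F against indentation depth h. Under the
#' Hertz contact model for a spherical (paraboloidal) indenter on an
#' elastic half-space,
#'
#'   F(h) = (4/3) * E / (1 - nu^2) * sqrt(R) * h^(3/2),
#'
#' so the Young's modulus E is recovered by least squares from a measured
#' curve. Group-level stiffness is then described by histograms, empirical
#' distribution functions, and the fraction of treated cells whose modulus
#' exceeds a high quantile of the control distribution.
#'
#' @name mechanics
NULL

#' Probe parameters
#'
#' @param radius_nm probe tip radius R, nm (> 0). The cantilever used for
#'   deep membrane indentation has a 150 nm tip.
#' @param poisson_ratio Poisson ratio nu of the sample, dimensionless in
#'   \[0, 0.5\]. Default 0.5 (incompressible cell membrane).
#' @return a list of class `"probe_params"`.
#' @export
probe_params <- function(radius_nm = 150, poisson_ratio = 0.5) {
  if (!is.numeric(radius_nm) || length(radius_nm) != 1L || radius_nm <= 0) {
    stop("probe_params(): radius_nm must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio < 0 || poisson_ratio > 0.5 + 1e-9) {
    stop("probe_params(): poisson_ratio must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(radius_nm = radius_nm, poisson_ratio = poisson_ratio),
            class = "probe_params")
}

#' Hertz force for a spherical indenter
#'
#' Force in nN at indentation depth(s) `indentation_nm` for a sample of
#' Young's modulus `e_kpa` (kPa). Unit bookkeeping: with E in kPa, R and h
#' in nm, `F[nN] = (4/3) E* sqrt(R * 1e-9) (h * 1e-9)^1.5 * 1e12` where
#' `E* = E / (1 - nu^2)` in kPa.
#'
#' @param e_kpa Young's modulus, kPa (> 0).
#' @param probe a [probe_params()].
#' @param indentation_nm indentation depth(s) h, nm (>= 0; vectorized).
#' @return force(s), nN.
#' @export
hertz_force <- function(e_kpa, probe, indentation_nm) {
  stopifnot(inherits(probe, "probe_params"))
  if (!is.numeric(e_kpa) || length(e_kpa) != 1L || e_kpa <= 0) {
    stop("hertz_force(): e_kpa must be a positive scalar", call. = FALSE)
  }
  if (any(!is.finite(indentation_nm)) || any(indentation_nm < 0)) {
    stop("hertz_force(): indentation must be finite and >= 0", call. = FALSE)
  }
  e_kpa * .hertz_shape(probe, indentation_nm)
}

# force per unit modulus: (4/3) sqrt(R) h^1.5 / (1 - nu^2) with kPa/nm -> nN
# conversion (kPa = 1e3 Pa; sqrt(m) m^1.5 Pa = N; N -> nN is 1e9)
.hertz_shape <- function(probe, indentation_nm) {
  (4 / 3) / (1 - probe$poisson_ratio^2) *
    sqrt(probe$radius_nm * 1e-9) * (indentation_nm * 1e-9)^1.5 * 1e3 * 1e9
}

#' Force-indentation curve
#'
#' @param indentation_nm nonnegative, nondecreasing indentation depths, nm.
#' @param force_nn measured force at each depth, nN.
#' @return a `data.frame` of class `"force_curve"`.
#' @export
force_curve <- function(indentation_nm, force_nn) {
  if (length(indentation_nm) != length(force_nn)) {
    stop("force_curve(): column lengths differ", call. = FALSE)
  }
  if (any(!is.finite(indentation_nm)) || any(indentation_nm < 0) ||
      any(diff(indentation_nm) < 0)) {
    stop("force_curve(): indentation must be nonnegative and nondecreasing",
         call. = FALSE)
  }
  structure(data.frame(indentation_nm = as.numeric(indentation_nm),
                       force_nn = as.numeric(force_nn)),
            class = c("force_curve", "data.frame"))
}

#' Young's modulus from a force curve
#'
#' Least-squares estimate of E under the spherical Hertz model with the
#' contact point at h = 0. Because the model is linear in E, the estimate
#' is the exact projection `E = sum(F phi) / sum(phi^2)` with
#' `phi(h) = F(h; E = 1)`.
#'
#' @param curve a [force_curve()] (or a data.frame with columns
#'   `indentation_nm`, `force_nn`), at least 5 points with h > 0.
#' @param probe a [probe_params()].
#' @return fitted Young's modulus, kPa.
#' @export
fit_youngs_modulus <- function(curve, probe) {
  stopifnot(inherits(probe, "probe_params"))
  h <- curve$indentation_nm
  f <- curve$force_nn
  if (is.null(h) || is.null(f)) {
    stop("fit_youngs_modulus(): curve needs indentation_nm and force_nn",
         call. = FALSE)
  }
  if (sum(h > 0) < 5L) {
    stop("fit_youngs_modulus(): need >= 5 points with positive indentation",
         call. = FALSE)
  }
  phi <- .hertz_shape(probe, h)
  e_hat <- sum(f * phi) / sum(phi^2)
  if (!is.finite(e_hat) || e_hat <= 0) {
    stop("fit_youngs_modulus(): fitted modulus is not positive (",
         signif(e_hat, 4), " kPa); curve inconsistent with the Hertz model",
         call. = FALSE)
  }
  e_hat
}

#' Histogram and empirical distribution of a modulus sample
#'
#' @param values_kpa positive Young's moduli, kPa (one per cell).
#' @param bins number of histogram bins (equal width over the data range).
#' @return a list of class `"modulus_distribution"`: `breaks`, `density`
#'   (relative frequency density, integrates to 1), `counts`, `ecdf`
#'   (a right-continuous step function from [stats::ecdf()]), `values`.
#' @export
modulus_distribution <- function(values_kpa, bins = 10L) {
  v <- as.numeric(values_kpa)
  if (length(v) == 0L || any(!is.finite(v)) || any(v <= 0)) {
    stop("modulus_distribution(): need a nonempty sample of positive moduli",
         call. = FALSE)
  }
  if (bins < 1L) stop("modulus_distribution(): bins must be >= 1", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)  # degenerate single value
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  hh <- graphics::hist(v, breaks = breaks, plot = FALSE,
                       include.lowest = TRUE, right = TRUE)
  structure(list(breaks = hh$breaks, density = hh$density,
                 counts = hh$counts, ecdf = stats::ecdf(v), values = v),
            class = "modulus_distribution")
}

#' Fraction of a treated sample beyond the control quantile
#'
#' Computes the empirical `level` quantile of the control modulus sample
#' (type-7 interpolation) and returns the percentage of treatment values
#' strictly exceeding it. With `level = 0.95` this is the share of treated
#' cells whose stiffness lies beyond the control range at the 0.95 level.
#'
#' @param treatment,control numeric vectors of Young's moduli, kPa.
#' @param level quantile level in (0, 1); default 0.95.
#' @return percentage of treatment values above the control quantile.
#' @export
fraction_beyond_control <- function(treatment, control, level = 0.95) {
  if (length(treatment) == 0L || length(control) == 0L) {
    stop("fraction_beyond_control(): both samples must be nonempty",
         call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("fraction_beyond_control(): level must lie strictly in (0, 1)",
         call. = FALSE)
  }
  q <- stats::quantile(control, probs = level, type = 7, names = FALSE)
  100 * mean(treatment > q)
}

#' Spatial features of a membrane surface profile
#'
#' Scans a height profile for interior local extrema and reports the mean
#' spacing between successive local minima (the spatial period of the
#' surface structure) and the mean rise from the concaves to the adjacent
#' maxima (the structure height): for each local maximum the height
#' contribution is `z_max - mean(z of the two flanking minima)`.
#'
#' @param heights profile heights, nm.
#' @param positions sample positions along the scan line, nm (strictly
#'   increasing, same length as `heights`).
#' @return a list of class `"profile_features"`: `period_nm`, `height_nm`,
#'   `n_minima`, `n_maxima`.
#' @export
profile_features <- function(heights, positions) {
  z <- as.numeric(heights)
  p <- as.numeric(positions)
  n <- length(z)
  if (n != length(p) || n < 5L) {
    stop("profile_features(): need >= 5 (position, height) samples",
         call. = FALSE)
  }
  if (any(diff(p) <= 0)) {
    stop("profile_features(): positions must be strictly increasing",
         call. = FALSE)
  }
  s <- sign(diff(z))
  s <- s[s != 0]
  if (length(s) < 2L) {
    stop("profile_features(): flat profile, no structure to measure",
         call. = FALSE)
  }
  # interior extrema via sign changes of the first difference
  d <- diff(z)
  idx_min <- integer(0); idx_max <- integer(0)
  last_sign <- 0
  for (i in seq_len(n - 1L)) {
    si <- sign(d[i])
    if (si == 0) next
    if (last_sign < 0 && si > 0) idx_min <- c(idx_min, i)
    if (last_sign > 0 && si < 0) idx_max <- c(idx_max, i)
    last_sign <- si
  }
  if (length(idx_min) < 3L) {
    stop("profile_features(): need >= 3 resolvable local minima; ",
         "profile is flat or monotone", call. = FALSE)
  }
  period <- mean(diff(p[idx_min]))
  # maxima flanked by minima on both sides
  heights_rel <- c()
  for (m in idx_max) {
    left <- idx_min[idx_min < m]
    right <- idx_min[idx_min > m]
    if (length(left) && length(right)) {
      heights_rel <- c(heights_rel,
                       z[m] - mean(c(z[max(left)], z[min(right)])))
    }
  }
  if (length(heights_rel) == 0L) {
    stop("profile_features(): no maxima flanked by minima", call. = FALSE)
  }
  structure(list(period_nm = period, height_nm = mean(heights_rel),
                 n_minima = length(idx_min), n_maxima = length(idx_max)),
            class = "profile_features")
}
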