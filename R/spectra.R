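#' Hemoglobin-derivative quantification from visible absorbance spectra
#'
#' The absorbance of a hemolysate or cell suspension between 500 and 700 nm
#' is modeled as a Beer-Lambert mixture of three hemoglobin derivatives
#' (oxyhemoglobin HbO2, deoxyhemoglobin Hb, methemoglobin MetHb) on top of a
#' two-term scattering baseline:
#'
#' ```
#' D(lambda) = (eps_HbO2(lambda) C_HbO2 + eps_Hb(lambda) C_Hb +
#'              eps_MetHb(lambda) C_MetHb) * 1e-3 * L + K + S g(lambda)
#' ```
#'
#' with eps in mM^-1 cm^-1, concentrations in µM, path length L in cm, K a
#' wavelength-flat scattering term and S the Rayleigh-scattering coefficient
#' multiplying g(lambda) = (lambda/550)^p (p = -4 by default; Rayleigh
#' scattering scales as lambda^-4). Unmixing inverts this model by bounded
#' Levenberg-Marquardt least squares.
#'
#' @name spectra
NULL

# reference wavelength used to normalize the scattering basis (nm)
.SCATTER_REF_NM <- 550

#' Extinction coefficient table
#'
#' Per-wavelength molar absorptivities of the three hemoglobin derivatives.
#'
#' @param wavelength_nm strictly increasing wavelengths, nm.
#' @param eps_hbo2,eps_hb,eps_methb molar absorptivities, mM^-1 cm^-1,
#'   nonnegative, one value per wavelength.
#' @return a `data.frame` of class `"extinction_table"` with columns
#'   `wavelength_nm`, `eps_hbo2`, `eps_hb`, `eps_methb`.
#' @seealso [make_extinction_fixture()] for the bundled literature-shaped
#'   table, [read_extinction_csv()] to load one from disk.
#' @export
extinction_table <- function(wavelength_nm, eps_hbo2, eps_hb, eps_methb) {
  n <- length(wavelength_nm)
  if (n < 1L || length(eps_hbo2) != n || length(eps_hb) != n ||
      length(eps_methb) != n) {
    stop("extinction_table(): all columns must have equal, positive length",
         call. = FALSE)
  }
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0)) {
    stop("extinction_table(): wavelengths must be finite and strictly increasing",
         call. = FALSE)
  }
  eps <- c(eps_hbo2, eps_hb, eps_methb)
  if (any(!is.finite(eps)) || any(eps < 0)) {
    stop("extinction_table(): extinction coefficients must be finite and >= 0",
         call. = FALSE)
  }
  structure(
    data.frame(wavelength_nm = as.numeric(wavelength_nm),
               eps_hbo2 = as.numeric(eps_hbo2),
               eps_hb = as.numeric(eps_hb),
               eps_methb = as.numeric(eps_methb)),
    class = c("extinction_table", "data.frame")
  )
}

#' Absorbance spectrum
#'
#' @param wavelength_nm wavelengths, nm (strictly increasing).
#' @param optical_density dimensionless absorbance at each wavelength.
#' @param path_length_cm optical path length L, cm (default 1).
#' @return a `data.frame` of class `"hb_spectrum"` with attribute
#'   `path_length_cm`.
#' @export
hb_spectrum <- function(wavelength_nm, optical_density, path_length_cm = 1) {
  if (length(wavelength_nm) != length(optical_density)) {
    stop("hb_spectrum(): wavelength and optical density lengths differ",
         call. = FALSE)
  }
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0)) {
    stop("hb_spectrum(): wavelengths must be finite and strictly increasing",
         call. = FALSE)
  }
  if (!is.numeric(path_length_cm) || length(path_length_cm) != 1L ||
      path_length_cm <= 0) {
    stop("hb_spectrum(): path_length_cm must be a positive scalar",
         call. = FALSE)
  }
  structure(
    data.frame(wavelength_nm = as.numeric(wavelength_nm),
               optical_density = as.numeric(optical_density)),
    path_length_cm = path_length_cm,
    class = c("hb_spectrum", "data.frame")
  )
}

# scattering basis g(lambda); exponent -4 for Rayleigh, +4 for the literal
# lambda^4 reading; normalized at 550 nm so S stays on the absorbance scale
scatter_basis <- function(wavelength_nm, scatter_exponent = -4) {
  if (!scatter_exponent %in% c(-4, 4)) {
    stop("scatter_exponent must be -4 or 4", call. = FALSE)
  }
  (wavelength_nm / .SCATTER_REF_NM)^scatter_exponent
}

# linearly interpolate an extinction table onto a target wavelength grid
interpolate_extinction <- function(table, wavelength_nm) {
  stopifnot(inherits(table, "extinction_table"))
  if (length(wavelength_nm) == nrow(table) &&
      isTRUE(all.equal(wavelength_nm, table$wavelength_nm))) {
    return(table)
  }
  rng <- range(table$wavelength_nm)
  if (min(wavelength_nm) < rng[1] || max(wavelength_nm) > rng[2]) {
    stop("extinction table does not cover the spectrum wavelength range [",
         min(wavelength_nm), ", ", max(wavelength_nm), "] nm", call. = FALSE)
  }
  extinction_table(
    wavelength_nm,
    stats::approx(table$wavelength_nm, table$eps_hbo2, wavelength_nm)$y,
    stats::approx(table$wavelength_nm, table$eps_hb, wavelength_nm)$y,
    stats::approx(table$wavelength_nm, table$eps_methb, wavelength_nm)$y
  )
}

#' Forward Beer-Lambert mixture model
#'
#' Computes the theoretical absorbance spectrum of a mixture of the three
#' hemoglobin derivatives plus the scattering baseline.
#'
#' @param c_hbo2,c_hb,c_methb derivative concentrations, µM (>= 0).
#' @param k flat scattering coefficient K, absorbance units.
#' @param s Rayleigh scattering coefficient S, absorbance units at 550 nm.
#' @param table an [extinction_table()].
#' @param path_length_cm optical path length, cm.
#' @param scatter_exponent exponent of the scattering basis, `-4` (Rayleigh,
#'   default) or `4`.
#' @return an [hb_spectrum()] on the table's wavelength grid.
#' @export
model_spectrum <- function(c_hbo2, c_hb, c_methb, k = 0, s = 0, table,
                           path_length_cm = 1, scatter_exponent = -4) {
  stopifnot(inherits(table, "extinction_table"))
  conc <- c(c_hbo2, c_hb, c_methb)
  if (length(conc) != 3L || any(!is.finite(conc)) || any(conc < 0)) {
    stop("model_spectrum(): concentrations must be nonnegative scalars",
         call. = FALSE)
  }
  absorb <- (table$eps_hbo2 * c_hbo2 + table$eps_hb * c_hb +
               table$eps_methb * c_methb) * 1e-3 * path_length_cm
  od <- absorb + k + s * scatter_basis(table$wavelength_nm, scatter_exponent)
  hb_spectrum(table$wavelength_nm, od, path_length_cm)
}

#' Unmix an absorbance spectrum into hemoglobin-derivative concentrations
#'
#' Bounded Levenberg-Marquardt least squares of the Beer-Lambert mixture
#' model against a measured spectrum. Concentrations, K and S are
#' constrained nonnegative. With `allow_scatter = FALSE` (hemolysate mode,
#' where no cells remain to scatter light) K and S are fixed at zero and
#' only the three concentrations are free.
#'
#' @param spectrum an [hb_spectrum()].
#' @param table an [extinction_table()]; interpolated onto the spectrum grid
#'   if the grids differ.
#' @param allow_scatter logical; free the K and S baseline terms?
#' @param scatter_exponent scattering basis exponent, `-4` or `4`.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return a list of class `"spectral_fit"`: `c_hbo2`, `c_hb`, `c_methb`
#'   (µM), `k_scatter`, `s_scatter`, `r2`, `r2_adjusted`, `residuals`,
#'   `fitted`, `n_free`, `converged`.
#' @export
fit_spectrum <- function(spectrum, table, allow_scatter = TRUE,
                         scatter_exponent = -4, max_iter = 200) {
  stopifnot(inherits(spectrum, "hb_spectrum"))
  n <- nrow(spectrum)
  n_free <- if (allow_scatter) 5L else 3L
  if (n < max(10L, n_free + 1L)) {
    stop("fit_spectrum(): need at least ", max(10L, n_free + 1L),
         " wavelengths, got ", n, call. = FALSE)
  }
  tab <- interpolate_extinction(table, spectrum$wavelength_nm)
  L <- attr(spectrum, "path_length_cm")
  d <- spectrum$optical_density
  g <- scatter_basis(spectrum$wavelength_nm, scatter_exponent)
  eps <- cbind(tab$eps_hbo2, tab$eps_hb, tab$eps_methb)

  predict_od <- function(p) {
    drop(eps %*% p[1:3]) * 1e-3 * L + p[4] + p[5] * g
  }

  # initial guess: equal split of the peak absorbance over the three
  # derivatives; K starts at the spectrum minimum when the baseline is free
  mean_eps <- mean(eps)
  c0 <- max(max(d), 0) / max(mean_eps * 1e-3 * L, .Machine$double.eps) / 3
  start <- c(c0, c0, c0,
             if (allow_scatter) max(min(d), 0) else 0, 0)
  lower <- rep(0, 5)
  upper <- if (allow_scatter) rep(Inf, 5) else c(Inf, Inf, Inf, 0, 0)

  fit <- minpack.lm::nls.lm(
    par = start,
    lower = lower, upper = upper,
    fn = function(p) d - predict_od(p),
    control = minpack.lm::nls.lm.control(maxiter = max_iter)
  )
  # info codes 1:4 signal convergence (4 = gradient orthogonal to residual,
  # e.g. a perfect fit); 0 and > 5 are failures
  converged <- fit$info %in% 1:4
  if (!converged && fit$info != 5) {
    stop("fit_spectrum(): Levenberg-Marquardt failed (info = ", fit$info,
         ", residual norm = ", signif(sqrt(fit$deviance), 6), ")",
         call. = FALSE)
  }
  p <- fit$par

  # the model is linear in all five parameters, so refine the iterate with
  # an active-set pass on the bounded linear problem: solve the
  # unconstrained least squares on the currently free columns, dropping any
  # column whose coefficient goes negative; keeps nested fits (K, S fixed
  # vs free) exactly ordered
  X <- cbind(eps * 1e-3 * L, 1, g)
  free0 <- if (allow_scatter) 1:5 else 1:3
  p_lin <- tryCatch({
    free <- free0
    coef <- rep(0, 5)
    while (length(free)) {
      sol <- qr.coef(qr(X[, free, drop = FALSE]), d)
      if (anyNA(sol)) break
      if (all(sol >= 0)) {
        coef[free] <- sol
        break
      }
      free <- free[sol >= 0]
    }
    coef
  }, error = function(e) NULL)
  if (!is.null(p_lin) &&
      sum((d - predict_od(p_lin))^2) < sum((d - predict_od(p))^2)) {
    p <- p_lin
    converged <- TRUE
  }
  fitted <- predict_od(p)
  res <- d - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((d - mean(d))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  r2_adj <- if (!is.na(r2) && n - n_free - 1L >= 1L) {
    1 - (1 - r2) * (n - 1) / (n - n_free - 1)
  } else {
    NA_real_
  }
  structure(
    list(c_hbo2 = p[1], c_hb = p[2], c_methb = p[3],
         k_scatter = p[4], s_scatter = p[5],
         r2 = r2, r2_adjusted = r2_adj,
         residuals = res, fitted = fitted,
         n_free = n_free, converged = converged),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("Hemoglobin-derivative spectral fit\n")
  cat(sprintf("  C_HbO2  = %.4g uM\n  C_Hb    = %.4g uM\n  C_MetHb = %.4g uM\n",
              x$c_hbo2, x$c_hb, x$c_methb))
  cat(sprintf("  K = %.4g, S = %.4g\n", x$k_scatter, x$s_scatter))
  cat(sprintf("  adjusted R-squared = %.5f\n", x$r2_adjusted))
  invisible(x)
}

#' Derivative percentages of total hemoglobin
#'
#' Total hemoglobin is the sum of the three derivative concentrations; each
#' derivative is reported as a percentage of that total.
#'
#' @param fit a `"spectral_fit"` from [fit_spectrum()], or a numeric vector
#'   `c(c_hbo2, c_hb, c_methb)` in µM.
#' @return a list of class `"derivative_fractions"`: `c_total` (µM),
#'   `hbo2_percent`, `hb_percent`, `methb_percent`.
#' @export
derivative_fractions <- function(fit) {
  conc <- if (inherits(fit, "spectral_fit")) {
    c(fit$c_hbo2, fit$c_hb, fit$c_methb)
  } else if (is.numeric(fit) && length(fit) == 3L) {
    fit
  } else {
    stop("derivative_fractions(): expected a spectral_fit or 3 concentrations",
         call. = FALSE)
  }
  if (any(conc < 0)) {
    stop("derivative_fractions(): concentrations must be >= 0", call. = FALSE)
  }
  c_total <- sum(conc)
  if (c_total <= 0) {
    stop("derivative_fractions(): total hemoglobin is zero; fractions undefined",
         call. = FALSE)
  }
  structure(
    list(c_total = c_total,
         hbo2_percent = 100 * conc[1] / c_total,
         hb_percent = 100 * conc[2] / c_total,
         methb_percent = 100 * conc[3] / c_total),
    class = "derivative_fractions"
  )
}

#' Hemolysis level from paired spectra
#'
#' Convention: the hemolysis level at time t is the fractional loss of
#' cell-associated total hemoglobin pigment relative to time zero,
#' `100 * (1 - c_total(t) / c_total(0))`, with totals obtained by unmixing
#' each spectrum; the result is clipped to \[0, 100\]. The spectrophotometric
#' definition of "residual level" is a convention of this package (the
#' published description of the measurement leaves the estimator open).
#'
#' @param spectrum_t spectrum of the sample at time t ([hb_spectrum()]).
#' @param spectrum_0 spectrum of the same sample at time zero.
#' @param table an [extinction_table()].
#' @param ... passed to [fit_spectrum()] (e.g. `allow_scatter`).
#' @return hemolysis level in percent, in \[0, 100\].
#' @export
hemolysis_level <- function(spectrum_t, spectrum_0, table, ...) {
  tot <- function(sp) {
    if (all(sp$optical_density == 0)) return(0)
    fit <- fit_spectrum(sp, table, ...)
    fit$c_hbo2 + fit$c_hb + fit$c_methb
  }
  c0 <- tot(spectrum_0)
  if (c0 <= 0) {
    stop("hemolysis_level(): total pigment at time zero is zero; undefined",
         call. = FALSE)
  }
  ct <- tot(spectrum_t)
  min(max(100 * (1 - ct / c0), 0), 100)
}
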