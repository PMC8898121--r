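#' Kinetic parameter estimation from methemoglobin time courses
#'
#' Least-squares fitting of the closed-form MetHb solution (see
#' [methb_time()]) to measured (t, x) data.
#'
#' The MetHb curve depends on (a, beta, gamma) only through the two
#' combinations u = beta a (min^-1) and v = gamma / beta (µM^-1): any
#' rescaling (a, beta, gamma) -> (k a, beta/k, gamma/k) leaves the curve
#' unchanged, so the three-parameter problem sits on an identifiability
#' ridge. The fitter therefore always works internally in (u, v). Passing
#' `fix_a` (the independently known H2O2 concentration) resolves the ridge
#' and returns beta = u / a and gamma = v u / a; without it the fit is
#' returned on the (u, v) scale with a ridge diagnostic and no (a, beta,
#' gamma) triple is invented.
#'
#' @name fitting
NULL

# closed-form model and its analytic Jacobian in the identifiable
# parameters u = beta*a, v = gamma/beta
.methb_uv <- function(t, u, v, y0, z0) {
  w <- -expm1(-u * t)  # 1 - exp(-u t) without cancellation
  z0 * (-expm1(-v * y0 * w))
}

.methb_uv_jac <- function(t, u, v, y0, z0) {
  w <- -expm1(-u * t)
  e <- exp(-v * y0 * w)
  cbind(u = z0 * e * v * y0 * t * exp(-u * t),
        v = z0 * e * y0 * w)
}

#' Fit the kinetic model to a methemoglobin time course
#'
#' @param time_min time points, minutes (>= 4 points).
#' @param methb observed MetHb at each time point, in µM (default) or in
#'   percent of `z0` (`methb_unit = "percent"`).
#' @param y0 initial Fe2+ concentration, µM (known, fixed).
#' @param z0 initial HbO2 concentration, µM (known, fixed).
#' @param fix_a H2O2 concentration in µM at which to resolve the
#'   identifiability ridge, or `NULL` to report the fit on the (u, v) scale
#'   only (with a warning).
#' @param methb_unit `"um"` or `"percent"`.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return a list of class `"curve_fit_result"` with elements
#'   `u`, `v` (identifiable parameters), `params` (a [kinetic_params()]
#'   when `fix_a` is given, otherwise `NULL`), `r2`, `n_points`,
#'   `converged`, `ridge` (TRUE when the (a, beta, gamma) triple is not
#'   identified), `covariance` (2 x 2, on the (beta, gamma) scale when
#'   `fix_a` is given, else on (u, v)), `fitted`, `residuals`.
#' @export
fit_methb_curve <- function(time_min, methb, y0, z0, fix_a = NULL,
                            methb_unit = c("um", "percent"), max_iter = 2000) {
  methb_unit <- match.arg(methb_unit)
  t <- as.numeric(time_min)
  x <- as.numeric(methb)
  if (methb_unit == "percent") x <- x * z0 / 100
  n <- length(t)
  if (n != length(x) || n < 4L) {
    stop("fit_methb_curve(): need >= 4 (time, methb) pairs", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0) || any(!is.finite(x))) {
    stop("fit_methb_curve(): times must be nonnegative and values finite",
         call. = FALSE)
  }
  if (any(x < -0.05 * z0) || any(x > 1.05 * z0)) {
    stop("fit_methb_curve(): MetHb values outside [0, 1.05 * z0]",
         call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("fit_methb_curve(): flat series, kinetic parameters are degenerate",
         call. = FALSE)
  }
  if (y0 <= 0 || z0 <= 0) {
    stop("fit_methb_curve(): y0 and z0 must be positive", call. = FALSE)
  }

  # initial guesses: v from the observed plateau via the steady-state
  # relation x_ss = z0 (1 - exp(-v y0)); u from the initial slope
  # V(0) = z0 v y0 u
  frac <- min(max(max(x) / z0, 1e-4), 1 - 1e-8)
  v0 <- -log(1 - frac) / y0
  pos <- which(t > 0 & x > 0)
  slope0 <- if (length(pos)) x[pos[1]] / t[pos[1]] else frac * z0 / max(t)
  u0 <- max(slope0 / (z0 * v0 * y0), 1e-8)

  # minpack.lm caps maxiter at 1024; restart from the last iterate when the
  # cap is hit (the ridge geometry can make progress slow but steady)
  ctrl <- minpack.lm::nls.lm.control(maxiter = min(max_iter, 1024L),
                                     maxfev = 200000)
  par <- c(u = u0, v = v0)
  restarts <- max(ceiling(max_iter / 1024), 1) + 10L
  for (attempt in seq_len(restarts)) {
    # muffle the solver's iteration-cap warning; the cap is handled by the
    # restart loop and a genuine failure is turned into an error below
    fit <- withCallingHandlers(
      minpack.lm::nls.lm(
        par = par,
        lower = c(0, 0),
        fn = function(p) x - .methb_uv(t, p[1], p[2], y0, z0),
        jac = function(p) -.methb_uv_jac(t, p[1], p[2], y0, z0),
        control = ctrl
      ),
      warning = function(w) {
        if (grepl("info = -1", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    if (fit$info != -1L) break
    par <- stats::setNames(fit$par, c("u", "v"))
  }
  converged <- fit$info %in% 1:4
  if (!converged && !fit$info %in% c(5L)) {
    stop("fit_methb_curve(): Levenberg-Marquardt failed (info = ", fit$info,
         "), residual norm = ", signif(sqrt(fit$deviance), 6), call. = FALSE)
  }
  u <- fit$par[["u"]]; v <- fit$par[["v"]]
  fitted <- .methb_uv(t, u, v, y0, z0)
  res <- x - fitted
  r2 <- r_squared(x, fitted)

  # covariance of (u, v) from the analytic Jacobian at the optimum
  J <- .methb_uv_jac(t, u, v, y0, z0)
  sigma2 <- sum(res^2) / max(n - 2L, 1L)
  jtj <- crossprod(J)
  cov_uv <- tryCatch(solve(jtj) * sigma2,
                     error = function(e) matrix(NA_real_, 2, 2))

  if (is.null(fix_a)) {
    warning("fit_methb_curve(): the MetHb curve identifies only u = beta*a ",
            "and v = gamma/beta; supply fix_a (the known H2O2 concentration) ",
            "to resolve beta and gamma", call. = FALSE)
    out <- list(u = u, v = v, params = NULL, ridge = TRUE,
                covariance = cov_uv)
  } else {
    if (fix_a <= 0) stop("fit_methb_curve(): fix_a must be > 0", call. = FALSE)
    beta <- u / fix_a
    gamma <- v * u / fix_a
    # delta-method transport of the (u, v) covariance to (beta, gamma)
    G <- rbind(beta = c(1 / fix_a, 0),
               gamma = c(v / fix_a, u / fix_a))
    cov_bg <- G %*% cov_uv %*% t(G)
    dimnames(cov_bg) <- list(c("beta", "gamma"), c("beta", "gamma"))
    out <- list(u = u, v = v,
                params = kinetic_params(a = fix_a, beta = beta, gamma = gamma,
                                        y0 = y0, z0 = z0),
                ridge = FALSE, covariance = cov_bg)
  }
  out$r2 <- r2
  out$n_points <- n
  out$converged <- converged
  out$fitted <- fitted
  out$residuals <- res
  class(out) <- "curve_fit_result"
  out
}

#' @export
print.curve_fit_result <- function(x, ...) {
  cat("MetHb kinetic curve fit (n =", x$n_points, "points)\n")
  cat(sprintf("  u = beta*a    = %.6g min^-1\n  v = gamma/beta = %.6g uM^-1\n",
              x$u, x$v))
  if (!is.null(x$params)) {
    cat(sprintf("  a = %.4g uM, beta = %.4g uM^-1 min^-1, gamma = %.4g uM^-2 min^-1\n",
                x$params$a, x$params$beta, x$params$gamma))
  } else {
    cat("  (a, beta, gamma) not resolved: identifiability ridge\n")
  }
  cat(sprintf("  R-squared = %.5f, converged = %s\n", x$r2, x$converged))
  invisible(x)
}

#' Summarize an ensemble of curve fits
#'
#' Arithmetic mean and sample standard deviation of the fitted parameters
#' and goodness of fit across curves (one curve per initial iron
#' concentration, typically).
#'
#' @param fits a list of `"curve_fit_result"` objects from
#'   [fit_methb_curve()], each with a resolved parameter set.
#' @param converged_only drop non-converged fits first (default TRUE).
#' @return a `data.frame` of class `"param_summary"` with one row per
#'   parameter (`a`, `beta`, `gamma`, `r2`) and columns `mean`, `sd`, `n`.
#' @export
summarize_fits <- function(fits, converged_only = TRUE) {
  if (inherits(fits, "curve_fit_result")) fits <- list(fits)
  if (!is.list(fits) || length(fits) == 0L) {
    stop("summarize_fits(): need at least one fit", call. = FALSE)
  }
  ok <- vapply(fits, function(f) inherits(f, "curve_fit_result"), logical(1))
  if (!all(ok)) {
    stop("summarize_fits(): all elements must be curve_fit_result objects",
         call. = FALSE)
  }
  if (converged_only) fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0L) {
    stop("summarize_fits(): no converged fits", call. = FALSE)
  }
  if (any(vapply(fits, function(f) is.null(f$params), logical(1)))) {
    stop("summarize_fits(): fits on the (u, v) ridge cannot be summarized; ",
         "refit with fix_a", call. = FALSE)
  }
  grab <- function(fun) vapply(fits, fun, numeric(1))
  vals <- list(a = grab(function(f) f$params$a),
               beta = grab(function(f) f$params$beta),
               gamma = grab(function(f) f$params$gamma),
               r2 = grab(function(f) f$r2))
  n <- length(fits)
  out <- data.frame(
    parameter = names(vals),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, function(x) if (n > 1L) stats::sd(x) else 0, numeric(1)),
    n = n,
    row.names = NULL
  )
  class(out) <- c("param_summary", "data.frame")
  out
}

#' Parameter-recovery experiment across initial iron concentrations
#'
#' Regenerates the full fitting study on synthetic data: for each initial
#' Fe2+ concentration in `y0_grid`, draws `n_replicates` noisy MetHb time
#' courses from the closed-form model at `true_params` (via
#' [simulate_methb_timeseries()]), fits each curve with
#' [fit_methb_curve()] holding the H2O2 concentration fixed at its
#' generating value, and summarizes the recovered rate constants with
#' [summarize_fits()].
#'
#' @param true_params generating [kinetic_params()] (the `y0` element is
#'   replaced by each value of `y0_grid` in turn).
#' @param y0_grid initial Fe2+ concentrations, µM.
#' @param t_grid_min sampling grid, minutes.
#' @param n_replicates noisy replicates per concentration.
#' @param noise_sd_percent MetHb noise SD, percent of `z0`.
#' @param seed master seed; per-concentration generator seeds are derived
#'   from it reproducibly.
#' @return a list with `summary` (a `"param_summary"` data.frame), `fits`
#'   (all `"curve_fit_result"` objects) and `per_curve` (data.frame of
#'   per-curve `y0`, `replicate`, `beta`, `gamma`, `r2`, `converged`).
#' @export
recovery_experiment <- function(
    true_params = kinetic_params(a = 9e-4, beta = 0.973, gamma = 3e-3,
                                 y0 = 1700, z0 = 5),
    y0_grid = c(212.5, 425, 850, 1700, 3400, 6800, 13600),
    t_grid_min = c(0, 15, 30, 45, 60, 90, 120, 1440),
    n_replicates = 20L,
    noise_sd_percent = 1.0,
    seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(y0_grid))
  fits <- list()
  rows <- list()
  for (i in seq_along(y0_grid)) {
    p <- kinetic_params(a = true_params$a, beta = true_params$beta,
                        gamma = true_params$gamma, y0 = y0_grid[i],
                        z0 = true_params$z0)
    cfg <- simulation_config(kinetic_params = p, t_grid_min = t_grid_min,
                             methb_noise_sd_percent = noise_sd_percent,
                             n_replicates = n_replicates, seed = sub_seeds[i])
    sim <- simulate_methb_timeseries(cfg)
    for (r in unique(sim$replicate)) {
      d <- sim[sim$replicate == r, ]
      f <- fit_methb_curve(d$time_min, d$methb_um, y0 = y0_grid[i],
                           z0 = p$z0, fix_a = true_params$a)
      fits[[length(fits) + 1L]] <- f
      rows[[length(rows) + 1L]] <- data.frame(
        y0 = y0_grid[i], replicate = r, beta = f$params$beta,
        gamma = f$params$gamma, r2 = f$r2, converged = f$converged)
    }
  }
  list(summary = summarize_fits(fits),
       fits = fits,
       per_curve = do.call(rbind, rows))
}

#' Coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot`; the adjusted form is
#' `1 - (1 - R2) (n - 1) / (n - n_params - 1)`.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 2).
#' @param n_params number of fitted parameters (used by the adjusted form).
#' @param adjusted logical; return the adjusted statistic.
#' @return R-squared (numeric scalar).
#' @export
r_squared <- function(observed, predicted, n_params = 0L, adjusted = FALSE) {
  n <- length(observed)
  if (n != length(predicted) || n < 2L) {
    stop("r_squared(): observed and predicted must have equal length >= 2",
         call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("r_squared(): zero total variance, R-squared undefined",
         call. = FALSE)
  }
  r2 <- 1 - sum((observed - predicted)^2) / ss_tot
  if (!adjusted) return(r2)
  if (n - n_params - 1L < 1L) {
    stop("r_squared(): need n - n_params - 1 >= 1 for the adjusted form",
         call. = FALSE)
  }
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the degenerate cases made
#' explicit: two points always give r = +/-1 (a warning is raised) and zero
#' variance in either vector is an error rather than `NA`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_corr <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 2L) {
    stop("pearson_corr(): need equal lengths >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_corr(): zero variance, correlation undefined", call. = FALSE)
  }
  if (n == 2L) {
    warning("pearson_corr(): two points give r = +/-1 degenerately",
            call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}
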