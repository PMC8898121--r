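#' Mass-action kinetics of Fenton-driven methemoglobin formation
#'
#' A two-step mass-action model of hemolysate exposed to excess ferrous
#' iron. The Fenton reaction Fe2+ + H2O2 -> OH. + OH- + Fe3+ consumes
#' ferrous iron at a rate proportional to the product of Fe2+ and H2O2
#' concentrations; the hydroxyl radical then oxidizes oxyhemoglobin to
#' methemoglobin. With the H2O2 concentration held constant at `a`
#' (quasi-steady state), the coupled system
#'
#'   dy/dt = -beta a y,            y(0) = y0      (Fe2+)
#'   dx/dt = gamma a y (Z0 - x),   x(0) = 0       (MetHb)
#'
#' has the closed-form solution
#'
#'   y(t) = y0 exp(-beta a t)
#'   x(t) = Z0 (1 - exp(-gamma y0 (1 - exp(-beta a t)) / beta))
#'
#' with steady state x_ss = Z0 (1 - exp(-gamma y0 / beta)). Oxyhemoglobin is
#' Z0 - x(t): the model conserves total hemoglobin.
#'
#' Identifiability: x(t) depends on (a, beta, gamma) only through
#' u = beta a and v = gamma / beta, so the map
#' (a, beta, gamma) -> (k a, beta / k, gamma / k) leaves every MetHb curve
#' unchanged. Fitting all three parameters from a MetHb time course alone is
#' therefore degenerate; see [fit_methb_curve()].
#'
#' Units: time in minutes; concentrations in µM; beta in µM^-1 min^-1;
#' gamma in µM^-2 min^-1.
#'
#' @name kinetics
NULL

#' Kinetic parameter set
#'
#' @param a constant H2O2 concentration, µM (>= 0).
#' @param beta Fenton rate constant, µM^-1 min^-1 (>= 0).
#' @param gamma HbO2 oxidation rate constant, µM^-2 min^-1 (>= 0).
#' @param y0 initial Fe2+ concentration, µM (>= 0).
#' @param z0 initial HbO2 concentration Z0, µM (> 0).
#' @return a list of class `"kinetic_params"`.
#' @examples
#' # the fitted parameter set for hemolysate exposed to ferrous sulfate
#' kinetic_params(a = 9e-4, beta = 0.973, gamma = 0.003, y0 = 1700, z0 = 5)
#' @export
kinetic_params <- function(a, beta, gamma, y0, z0) {
  vals <- c(a = a, beta = beta, gamma = gamma, y0 = y0, z0 = z0)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("kinetic_params(): all parameters must be finite and >= 0",
         call. = FALSE)
  }
  if (z0 <= 0) {
    stop("kinetic_params(): z0 must be > 0", call. = FALSE)
  }
  structure(as.list(vals), class = "kinetic_params")
}

.check_time <- function(t) {
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0)) {
    stop("time must be nonnegative", call. = FALSE)
  }
}

#' Ferrous iron decay
#'
#' `y(t) = y0 exp(-beta a t)`: first-order consumption of Fe2+ by the
#' Fenton reaction at constant H2O2.
#'
#' @param t time, minutes (vectorized, >= 0).
#' @param params a [kinetic_params()].
#' @return Fe2+ concentration(s), µM.
#' @export
fe_decay <- function(t, params) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_time(t)
  params$y0 * exp(-params$beta * params$a * t)
}

#' Methemoglobin time course
#'
#' The closed-form solution
#' `x(t) = Z0 (1 - exp(-gamma y0 (1 - exp(-beta a t)) / beta))`.
#' In the degenerate limit `beta -> 0` the expression
#' `(1 - exp(-beta a t)) / beta` tends to `a t` and the continuous limit
#' `x(t) = Z0 (1 - exp(-gamma a y0 t))` is used instead.
#'
#' @inheritParams fe_decay
#' @return MetHb concentration(s), µM, in \[0, Z0\].
#' @export
methb_time <- function(t, params) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_time(t)
  with(params, {
    if (beta * a > 0) {
      # -expm1(-x) = 1 - exp(-x) without cancellation for small x
      z0 * (-expm1(-gamma * y0 * (-expm1(-beta * a * t)) / beta))
    } else if (beta == 0) {
      # series limit of the closed form as beta -> 0
      z0 * (-expm1(-gamma * a * y0 * t))
    } else {
      # a == 0: no Fenton reaction, no oxidation
      rep(0, length(t))
    }
  })
}

#' Steady-state methemoglobin level
#'
#' `x_ss = Z0 (1 - exp(-gamma y0 / beta))`, the t -> Inf limit of
#' [methb_time()]. It increases monotonically with the initial iron load
#' `y0` and saturates at `Z0` (all oxyhemoglobin oxidized); at low `y0` the
#' plateau is set by iron exhaustion instead.
#'
#' @param params a [kinetic_params()] with `beta > 0`.
#' @param percent logical; report as percent of Z0 instead of µM.
#' @return steady-state MetHb, µM (or % of Z0).
#' @export
methb_steady_state <- function(params, percent = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$beta <= 0) {
    stop("methb_steady_state(): beta must be > 0 (degenerate parameter)",
         call. = FALSE)
  }
  x_ss <- params$z0 * (1 - exp(-params$gamma * params$y0 / params$beta))
  if (percent) 100 * x_ss / params$z0 else x_ss
}

#' Initial methemoglobin formation rate
#'
#' `V(0) = gamma a y0 Z0`, the slope of the MetHb curve at t = 0 (the
#' tangent of the initial rise).
#'
#' @param params a [kinetic_params()].
#' @return initial rate, µM/min.
#' @export
initial_rate <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  with(params, gamma * a * y0 * z0)
}

#' Instantaneous methemoglobin formation rate
#'
#' `V(t) = dx/dt = gamma a y(t) (Z0 - x(t))` along the closed-form
#' trajectory.
#'
#' @inheritParams fe_decay
#' @return rate(s), µM/min.
#' @export
methb_rate <- function(t, params) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_time(t)
  with(params, gamma * a * fe_decay(t, params) * (z0 - methb_time(t, params)))
}

#' Numerical integration of the kinetic system
#'
#' Integrates the coupled ODEs with `deSolve::lsoda` and returns the full
#' trajectory. Used as an independent cross-check of the closed forms; the
#' two agree to solver tolerance.
#'
#' @param params a [kinetic_params()].
#' @param t_grid nondecreasing time grid, minutes, starting at 0.
#' @param rtol,atol relative and absolute solver tolerances.
#' @return a `data.frame` of class `"kinetic_timeseries"` with columns
#'   `time_min`, `methb_um` (x), `fe_um` (y), `hbo2_um` (Z0 - x),
#'   `rate_um_per_min` (dx/dt).
#' @export
ode_solve <- function(params, t_grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(t_grid) < 2L || t_grid[1] != 0 || any(diff(t_grid) < 0)) {
    stop("ode_solve(): t_grid must be nondecreasing and start at 0",
         call. = FALSE)
  }
  deriv <- function(t, state, p) {
    with(as.list(c(state, p)), {
      dy <- -beta * a * y
      dx <- gamma * a * y * (z0 - x)
      list(c(dx, dy))
    })
  }
  sol <- deSolve::lsoda(
    y = c(x = 0, y = params$y0),
    times = t_grid, func = deriv, parms = params,
    rtol = rtol, atol = atol
  )
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    stop("ode_solve(): lsoda failed (istate = ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  }
  x <- sol[, "x"]; y <- sol[, "y"]
  structure(
    data.frame(time_min = sol[, "time"],
               methb_um = x,
               fe_um = y,
               hbo2_um = params$z0 - x,
               rate_um_per_min = params$gamma * params$a * y * (params$z0 - x)),
    class = c("kinetic_timeseries", "data.frame"),
    params = params
  )
}

#' Closed-form kinetic time series
#'
#' Evaluates the analytic solution on a time grid and returns the same
#' container as [ode_solve()].
#'
#' @inheritParams ode_solve
#' @return a `"kinetic_timeseries"` data.frame.
#' @export
kinetic_timeseries <- function(params, t_grid) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_time(t_grid)
  if (any(diff(t_grid) < 0)) {
    stop("kinetic_timeseries(): t_grid must be nondecreasing", call. = FALSE)
  }
  x <- methb_time(t_grid, params)
  structure(
    data.frame(time_min = t_grid,
               methb_um = x,
               fe_um = fe_decay(t_grid, params),
               hbo2_um = params$z0 - x,
               rate_um_per_min = methb_rate(t_grid, params)),
    class = c("kinetic_timeseries", "data.frame"),
    params = params
  )
}
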