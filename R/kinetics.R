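# Forward simulation of irreversible denaturation kinetics.
#
# Every transition obeys a first-order rate law with an Arrhenius rate
# constant reparameterised by (E_a, T*), where T* is the temperature at
# which k = 1 min^-1.  This replaces the ill-conditioned pre-exponential
# factor and keeps both parameters on interpretable scales.

#' Arrhenius parameters of a first-order transition
#'
#' @param E_a Activation energy, kJ/mol (> 0).
#' @param T_star Special temperature at which the rate constant equals
#'   1 min^-1, in K (> 0).
#' @return Object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(E_a, T_star) {
  if (!is.finite(E_a) || E_a <= 0) stop("E_a must be positive")
  if (!is.finite(T_star) || T_star <= 0) stop("T_star must be positive")
  structure(list(E_a = E_a, T_star = T_star), class = "kinetic_params")
}

#' Arrhenius rate constant
#'
#' \deqn{k(T) = \exp[(E_a/R)(1/T^* - 1/T)]}
#' in min^-1, with \eqn{R = 8.314\times 10^{-3}} kJ/(mol K); by
#' construction \eqn{k(T^*) = 1} exactly.
#'
#' @param p A [kinetic_params()] object.
#' @param T_K Temperature(s), K (> 0).
#' @return Rate constant(s), min^-1.
#' @export
arrhenius_rate <- function(p, T_K) {
  if (any(T_K <= 0)) stop("temperature must be positive (kelvin)")
  exp((p$E_a / .R_GAS) * (1 / p$T_star - 1 / T_K))
}

#' Surviving native fraction along a constant-rate scan
#'
#' \deqn{x(T) = \exp[-(1/\nu)\int_{T_0}^{T} k(T')\,dT']}
#' evaluated by cumulative trapezoid on the supplied grid; x(T0) = 1 and
#' x is non-increasing.
#'
#' @param p [kinetic_params()].
#' @param grid Temperature grid, K (within `[T0, Inf)`).
#' @param nu Heating rate, K/min.
#' @param T0 Scan-start temperature; default: first grid point.
#' @return Fraction curve on `grid`.
#' @export
native_fraction_scan <- function(p, grid, nu = 1, T0 = grid[1]) {
  if (nu <= 0) stop("heating rate must be positive")
  if (grid[1] < T0 - 1e-9) stop("grid extends below the scan start T0")
  g <- if (abs(grid[1] - T0) > 1e-12) c(T0, grid) else grid
  k <- arrhenius_rate(p, g)
  x <- exp(-cumtrapz_vec(g, k) / nu)
  if (length(g) != length(grid)) x <- x[-1]
  x
}

#' A one-stage irreversible calorimetric domain (N -> D)
#'
#' @param kinetics [kinetic_params()] of the single stage.
#' @param dH Denaturation enthalpy, kJ/mol (> 0).
#' @return Object of class `c("one_stage_domain", "cal_domain")`.
#' @export
one_stage_domain <- function(kinetics, dH) {
  if (dH <= 0) stop("dH must be positive")
  structure(list(kinetics = kinetics, dH = dH),
            class = c("one_stage_domain", "cal_domain"))
}

#' A two-stage irreversible calorimetric domain (N -> I -> D)
#'
#' Sequential first-order scheme through a kinetic intermediate; both
#' stages absorb heat (dH1, dH2 > 0).  `x_N0`/`x_I0` are the state
#' fractions at the start of the scan (native preparation: 1 and 0;
#' annealed preparations carry partially converted populations).
#'
#' @param stage1,stage2 [kinetic_params()] for rate constants k1, k2.
#' @param dH1,dH2 Stage enthalpies, kJ/mol (> 0).
#' @param x_N0,x_I0 Initial fractions (non-negative, sum at most 1).
#' @return Object of class `c("two_stage_domain", "cal_domain")`.
#' @export
two_stage_domain <- function(stage1, stage2, dH1, dH2, x_N0 = 1, x_I0 = 0) {
  if (dH1 <= 0 || dH2 <= 0) stop("stage enthalpies must be positive")
  if (x_N0 < 0 || x_I0 < 0 || x_N0 + x_I0 > 1 + 1e-9)
    stop("initial fractions must be non-negative and sum to at most 1")
  structure(list(stage1 = stage1, stage2 = stage2, dH1 = dH1, dH2 = dH2,
                 x_N0 = x_N0, x_I0 = x_I0),
            class = c("two_stage_domain", "cal_domain"))
}

#' A multidomain model
#'
#' An ordered set of independent calorimetric domains (one- or two-stage),
#' conventionally numbered in order of increasing thermostability.  The
#' model thermogram is the algebraic sum of the domain signals and the
#' total enthalpy the sum of the domain enthalpies.
#'
#' @param ... `cal_domain` objects, least stable first.
#' @return Object of class `"domain_model"`.
#' @export
domain_model <- function(...) {
  domains <- list(...)
  if (length(domains) == 1 && is.list(domains[[1]]) &&
      !inherits(domains[[1]], "cal_domain"))
    domains <- domains[[1]]
  if (!all(vapply(domains, inherits, TRUE, "cal_domain")))
    stop("all components must be calorimetric domains")
  structure(list(domains = domains), class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf("<domain_model: %d domain(s), %d transition(s), total dH = %.0f kJ/mol>\n",
              length(x$domains), length(model_transitions(x)),
              model_enthalpy(x)))
  for (i in seq_along(x$domains)) {
    d <- x$domains[[i]]
    if (inherits(d, "one_stage_domain"))
      cat(sprintf("  domain %d (one-stage): E_a=%.0f kJ/mol, T*=%.2f K, dH=%.0f kJ/mol\n",
                  i, d$kinetics$E_a, d$kinetics$T_star, d$dH))
    else
      cat(sprintf(
        "  domain %d (two-stage): stage1 E_a=%.0f, T*=%.2f, dH1=%.0f; stage2 E_a=%.0f, T*=%.2f, dH2=%.0f; x_N0=%.3g, x_I0=%.3g\n",
        i, d$stage1$E_a, d$stage1$T_star, d$dH1,
        d$stage2$E_a, d$stage2$T_star, d$dH2, d$x_N0, d$x_I0))
  }
  invisible(x)
}

#' Total enthalpy deposited by a model at full conversion from native state
#' @param model A [domain_model()].
#' @return Sum of all stage enthalpies, kJ/mol.
#' @export
model_enthalpy <- function(model) {
  sum(vapply(model$domains, function(d)
    if (inherits(d, "one_stage_domain")) d$dH else d$dH1 + d$dH2, 0))
}

# Flatten a model into its thermal transitions, least stable first within
# the model's domain order.  Each entry: kinetics, domain index, stage.
model_transitions <- function(model) {
  out <- list()
  for (i in seq_along(model$domains)) {
    d <- model$domains[[i]]
    if (inherits(d, "one_stage_domain")) {
      out[[length(out) + 1]] <- list(kinetics = d$kinetics, dH = d$dH,
                                     domain = i, stage = 1L)
    } else {
      out[[length(out) + 1]] <- list(kinetics = d$stage1, dH = d$dH1,
                                     domain = i, stage = 1L)
      out[[length(out) + 1]] <- list(kinetics = d$stage2, dH = d$dH2,
                                     domain = i, stage = 2L)
    }
  }
  out
}

#' Simulate a one-stage domain scan
#'
#' \deqn{C_p^{ex}(T) = \Delta H\, k(T)\, x(T) / \nu,}
#' with the native fraction scaled by `initial_fraction` (annealed
#' preparations).  The area under the curve equals
#' `initial_fraction * dH` up to quadrature error.
#'
#' @param d [one_stage_domain()].
#' @param grid Temperature grid, K.
#' @param nu Heating rate, K/min.
#' @param T0 Scan start, K (default first grid point).
#' @param initial_fraction Surviving native fraction at scan start, (0, 1].
#' @return An [excess_curve()].
#' @export
simulate_one_stage <- function(d, grid, nu = 1, T0 = grid[1],
                               initial_fraction = 1) {
  if (initial_fraction <= 0 || initial_fraction > 1)
    stop("initial_fraction must be in (0, 1]")
  x <- initial_fraction * native_fraction_scan(d$kinetics, grid, nu, T0)
  k <- arrhenius_rate(d$kinetics, grid)
  excess_curve(grid, d$dH * k * x / nu, heating_rate = nu)
}

# State fractions of a two-stage domain along a scan, as the linear ODE
#   dxN/dT = -k1 xN / nu ;  dxI/dT = (k1 xN - k2 xI) / nu
# integrated with lsoda.  Returns list(x_N, x_I) on `grid`.
two_stage_fractions_scan <- function(d, grid, nu = 1, T0 = grid[1],
                                     rtol = 1e-10, atol = 1e-12) {
  g <- if (abs(grid[1] - T0) > 1e-12) c(T0, grid) else grid
  if (g[1] > min(grid)) stop("grid extends below the scan start T0")
  deriv <- function(T_K, y, parms) {
    k1 <- arrhenius_rate(d$stage1, T_K)
    k2 <- arrhenius_rate(d$stage2, T_K)
    list(c(-k1 * y[1] / nu, (k1 * y[1] - k2 * y[2]) / nu))
  }
  sol <- deSolve::lsoda(c(xN = d$x_N0, xI = d$x_I0), g, deriv, NULL,
                        rtol = rtol, atol = atol)
  idx <- if (length(g) != length(grid)) -1L else TRUE
  list(x_N = pmax(sol[idx, "xN"], 0), x_I = pmax(sol[idx, "xI"], 0))
}

#' Simulate a two-stage domain scan
#'
#' \deqn{C_p^{ex}(T) = [\Delta H_1 k_1(T) x_N(T) + \Delta H_2 k_2(T) x_I(T)]/\nu,}
#' with the state fractions obtained by integrating the sequential
#' first-order system along the temperature ramp.  The area equals
#' `x_N0*(dH1 + dH2) + x_I0*dH2` up to quadrature error.
#'
#' @param d [two_stage_domain()].
#' @inheritParams simulate_one_stage
#' @return An [excess_curve()].
#' @export
simulate_two_stage <- function(d, grid, nu = 1, T0 = grid[1]) {
  fr <- two_stage_fractions_scan(d, grid, nu, T0)
  k1 <- arrhenius_rate(d$stage1, grid)
  k2 <- arrhenius_rate(d$stage2, grid)
  excess_curve(grid, (d$dH1 * k1 * fr$x_N + d$dH2 * k2 * fr$x_I) / nu,
               heating_rate = nu)
}

#' Simulate a full multidomain model scan
#'
#' Sum of the individual domain signals.
#'
#' @param model [domain_model()].
#' @inheritParams simulate_one_stage
#' @return An [excess_curve()].
#' @export
simulate_model <- function(model, grid, nu = 1, T0 = grid[1]) {
  cp <- rep(0, length(grid))
  for (d in model$domains) {
    cp <- cp + if (inherits(d, "one_stage_domain"))
      simulate_one_stage(d, grid, nu, T0)$excess
    else simulate_two_stage(d, grid, nu, T0)$excess
  }
  excess_curve(grid, cp, heating_rate = nu)
}

#' State fractions after an isothermal hold
#'
#' One-stage domains: \eqn{x = x_0 \exp(-k t)}.  Two-stage domains: the
#' closed-form solution of the sequential first-order system at constant
#' k1, k2, including the removable k1 = k2 singularity
#' (switched when |k1 - k2| < 1e-10 k1).
#'
#' @param model [domain_model()].
#' @param T_hold Hold temperature, K.
#' @param t_hold Hold duration, min (>= 0).
#' @return List, one element per domain: for one-stage domains `x`;
#'   for two-stage domains `c(x_N, x_I)`.
#' @export
isothermal_fractions <- function(model, T_hold, t_hold) {
  if (t_hold < 0) stop("hold time must be non-negative")
  lapply(model$domains, function(d) {
    if (inherits(d, "one_stage_domain")) {
      k <- arrhenius_rate(d$kinetics, T_hold)
      c(x = exp(-k * t_hold))
    } else {
      k1 <- arrhenius_rate(d$stage1, T_hold)
      k2 <- arrhenius_rate(d$stage2, T_hold)
      xN <- d$x_N0 * exp(-k1 * t_hold)
      xI <- if (abs(k1 - k2) < 1e-10 * k1) {
        (d$x_I0 + d$x_N0 * k1 * t_hold) * exp(-k1 * t_hold)
      } else {
        d$x_I0 * exp(-k2 * t_hold) +
          d$x_N0 * k1 / (k2 - k1) * (exp(-k1 * t_hold) - exp(-k2 * t_hold))
      }
      c(x_N = xN, x_I = unname(xI))
    }
  })
}

#' Apply an isothermal annealing step to a model
#'
#' Returns a copy of the model whose initial state fractions are those
#' surviving a hold of `t_hold` minutes at `T_hold`; simulating the result
#' reproduces the thermogram of the annealed preparation.
#'
#' @inheritParams isothermal_fractions
#' @return A [domain_model()] with updated initial fractions; one-stage
#'   domain survival is stored in the `initial_fraction` attribute used by
#'   [simulate_annealed_model()].
#' @export
anneal_model <- function(model, T_hold, t_hold) {
  fr <- isothermal_fractions(model, T_hold, t_hold)
  domains <- model$domains
  for (i in seq_along(domains)) {
    d <- domains[[i]]
    if (inherits(d, "one_stage_domain")) {
      attr(domains[[i]], "initial_fraction") <-
        (attr(d, "initial_fraction") %||% 1) * fr[[i]][["x"]]
    } else {
      # the hold acts on the current (possibly already annealed) state
      start <- c(d$x_N0, d$x_I0)
      k1 <- arrhenius_rate(d$stage1, T_hold)
      k2 <- arrhenius_rate(d$stage2, T_hold)
      xN <- start[1] * exp(-k1 * t_hold)
      xI <- if (abs(k1 - k2) < 1e-10 * k1)
        (start[2] + start[1] * k1 * t_hold) * exp(-k1 * t_hold)
      else start[2] * exp(-k2 * t_hold) +
        start[1] * k1 / (k2 - k1) * (exp(-k1 * t_hold) - exp(-k2 * t_hold))
      domains[[i]]$x_N0 <- xN
      domains[[i]]$x_I0 <- unname(xI)
    }
  }
  out <- model
  out$domains <- domains
  out
}

#' Simulate a (possibly annealed) model scan
#'
#' Like [simulate_model()] but honouring one-stage `initial_fraction`
#' attributes set by [anneal_model()].
#'
#' @inheritParams simulate_model
#' @return An [excess_curve()].
#' @export
simulate_annealed_model <- function(model, grid, nu = 1, T0 = grid[1]) {
  cp <- rep(0, length(grid))
  for (d in model$domains) {
    cp <- cp + if (inherits(d, "one_stage_domain")) {
      f <- attr(d, "initial_fraction") %||% 1
      if (f <= 0) 0 else simulate_one_stage(d, grid, nu, T0,
                                            initial_fraction = f)$excess
    } else simulate_two_stage(d, grid, nu, T0)$excess
  }
  excess_curve(grid, cp, heating_rate = nu)
}

#' Half-life of a first-order transition
#'
#' \eqn{t_{0.5} = \ln 2 / k(T)}; at \eqn{T = T^*} this is ln 2 minutes.
#'
#' @param p [kinetic_params()].
#' @param T_K Temperature(s), K.
#' @return Half-life, min.
#' @export
half_life <- function(p, T_K) log(2) / arrhenius_rate(p, T_K)

#' Default temperature grid for synthetic scans
#'
#' 0.05 K spacing over `[T0, T0 + span]`.
#'
#' @param T0 Scan start, K.
#' @param span Scan span, K.
#' @param by Grid spacing, K.
#' @return Numeric grid.
#' @export
default_grid <- function(T0 = 288.15, span = 70, by = 0.05) {
  seq(T0, T0 + span, by = by)
}
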