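# Aggregate-growth analysis of isothermal dynamic light scattering traces.
#
# After a lag t0 (nucleation of start aggregates) the mean hydrodynamic
# radius grows exponentially,
#   R_h(t) = R_h0 exp[ln(2)/t_2R (t - t0)],  t > t0,
# so log R_h is flat up to t0 and linear beyond it.  t_2R (the radius
# doubling time) characterises the growth rate; t0 is irreproducible
# between runs and treated as a nuisance parameter estimated jointly.

#' Fit exponential aggregate growth to an isothermal DLS trace
#'
#' Joint change-point fit of `log R_h` as flat-then-linear: the lag `t0`
#' is profiled over a fine grid between observations and the triple
#' `(t0, R_h0, t_2R)` polished by Levenberg-Marquardt.  By construction
#' `R_h(t0 + t_2R) = 2 R_h0`.
#'
#' @param trace A [probe_trace()] of kind `"dls"` (time in min, radius in
#'   nm) with at least 6 points after the apparent lag.
#' @param conf Confidence level for the half-widths (default 0.95).
#' @return Object of class `"aggregation_fit"`: `t0` (min), `R_h0` (nm),
#'   `t_2R` (min), `temperature` (K), `conf_halfwidth` (named, from the
#'   linear-theory covariance of the polish), `growing` (FALSE when no
#'   growth was detected, in which case the fit fields are NA).
#' @export
fit_growth <- function(trace, conf = 0.95) {
  stopifnot(inherits(trace, "probe_trace"), trace$kind == "dls")
  t <- trace$abscissa
  r <- trace$ordinate
  if (any(r <= 0)) stop("radii must be positive")
  lr <- log(r)
  n <- length(t)
  # overall growth check on the second half of the trace
  late <- t >= median(t)
  if (coef(lm(lr[late] ~ t[late]))[2] <= 0) {
    return(structure(list(t0 = NA_real_, R_h0 = NA_real_, t_2R = NA_real_,
                          temperature = trace$temperature,
                          conf_halfwidth = NULL, growing = FALSE),
                     class = "aggregation_fit"))
  }
  model <- function(p, tt) p[2] + p[3] * pmax(tt - p[1], 0)
  # geometric change-point start: fit the clear-growth region of the
  # log-radius, extrapolate its line back to the plateau level; the lag
  # is where they intersect.  Refined once, then polished by LM.
  lr0 <- median(head(lr, max(3, round(0.05 * n))))
  t0_hat <- t[1]
  slope0 <- NA_real_
  for (pass in 1:2) {
    grow <- lr > lr0 + 0.25 * (max(lr) - lr0)
    if (sum(grow) < 6) grow <- seq_len(n) > n - 6
    cf <- coef(lm(lr[grow] ~ t[grow]))
    slope0 <- max(cf[2], 1e-10)
    t0_hat <- (lr0 - cf[1]) / slope0
    pre <- t < t0_hat
    if (any(pre)) lr0 <- mean(lr[pre])
  }
  fit <- minpack.lm::nls.lm(par = c(t0_hat, lr0, slope0),
                            fn = function(p) lr - model(p, t),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  p <- fit$par
  if (p[3] <= 0) {
    return(structure(list(t0 = NA_real_, R_h0 = NA_real_, t_2R = NA_real_,
                          temperature = trace$temperature,
                          conf_halfwidth = NULL, growing = FALSE),
                     class = "aggregation_fit"))
  }
  dof <- max(n - 3, 1)
  sig2 <- sum(fit$fvec^2) / dof
  hw <- tryCatch({
    cv <- sig2 * solve(fit$hessian)
    se <- sqrt(pmax(diag(cv), 0))
    tq <- qt(1 - (1 - conf) / 2, dof)
    c(t0 = tq * se[1], R_h0 = exp(p[2]) * tq * se[2],
      t_2R = log(2) / p[3]^2 * tq * se[3])
  }, error = function(e) NULL)
  structure(list(t0 = p[1], R_h0 = exp(p[2]), t_2R = log(2) / p[3],
                 temperature = trace$temperature, conf_halfwidth = hw,
                 growing = TRUE),
            class = "aggregation_fit")
}

#' @export
print.aggregation_fit <- function(x, ...) {
  if (!x$growing) cat("<aggregation_fit: no growth detected>\n")
  else cat(sprintf(
    "<aggregation_fit at %.2f K: t0 = %.2f min, R_h0 = %.1f nm, t_2R = %.3f min>\n",
    x$temperature, x$t0, x$R_h0, x$t_2R))
  invisible(x)
}

#' Arrhenius parameters of the aggregate-growth process
#'
#' Converts each doubling time to a first-order growth rate
#' \eqn{k_{agg}(T) = \ln 2 / t_{2R}(T)} (the convention under which
#' \eqn{t_{2R}(T^*) = \ln 2} min, matching the half-life relation) and
#' fits the Arrhenius law to the (T, k) pairs by nonlinear least squares
#' initialised from the log-linear regression.
#'
#' @param fits List of growing [fit_growth()] results at >= 3
#'   temperatures spanning >= 4 K.
#' @return Object of class `"aggregation_arrhenius"`: `E_a` (kJ/mol),
#'   `T_star` (K), `table` (per-temperature `temperature`, `t_2R`,
#'   `k_agg`).
#' @export
fit_aggregation_arrhenius <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$growing), fits)
  Tv <- vapply(fits, function(f) f$temperature, 0)
  t2 <- vapply(fits, function(f) f$t_2R, 0)
  if (length(Tv) < 3 || diff(range(Tv)) < 4)
    stop("need at least 3 usable temperatures spanning at least 4 K")
  k <- log(2) / t2
  lf <- coef(lm(log(k) ~ I(1 / Tv)))  # ln k = Ea/(R T*) - (Ea/R)/T
  E0 <- max(-.R_GAS * lf[2], 10)
  T0 <- E0 / (.R_GAS * max(lf[1], 1e-6))
  resid_fn <- function(p) k - arrhenius_rate(kinetic_params(
    max(p[1], 1), max(p[2], 100)), Tv)
  fit <- minpack.lm::nls.lm(
    par = c(E0, T0), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  # on exactly consistent data the log-linear start is already optimal;
  # keep whichever parameter pair leaves the smaller residual
  par <- if (sum(resid_fn(c(E0, T0))^2) < sum(fit$fvec^2)) c(E0, T0)
  else fit$par
  structure(list(E_a = unname(par[1]), T_star = unname(par[2]),
                 table = data.frame(temperature = Tv, t_2R = t2,
                                    k_agg = k)),
            class = "aggregation_arrhenius")
}

#' @export
print.aggregation_arrhenius <- function(x, ...) {
  cat(sprintf("<aggregation_arrhenius: E_a = %.0f kJ/mol, T* = %.2f K over %d temperature(s)>\n",
              x$E_a, x$T_star, nrow(x$table)))
  invisible(x)
}

#' Compare aggregation doubling times with denaturation half-lives
#'
#' Tabulates, per temperature, the aggregation doubling time against the
#' half-life \eqn{t_{0.5} = \ln 2 / k} of every transition in a domain
#' model, with relative deviations: the transition whose half-lives track
#' the doubling times is the rate-limiting denaturation step.
#'
#' @param agg An [fit_aggregation_arrhenius()] result.
#' @param model A [domain_model()].
#' @return Data frame with one row per (temperature, transition):
#'   `temperature`, `transition`, `t_2R`, `t_half`, `rel_dev`.
#' @export
compare_with_denaturation <- function(agg, model) {
  tr <- model_transitions(model)
  do.call(rbind, lapply(seq_len(nrow(agg$table)), function(i) {
    Tv <- agg$table$temperature[i]
    data.frame(temperature = Tv,
               transition = seq_along(tr),
               t_2R = agg$table$t_2R[i],
               t_half = vapply(tr, function(x)
                 half_life(x$kinetics, Tv), 0),
               rel_dev = vapply(tr, function(x)
                 abs(half_life(x$kinetics, Tv) - agg$table$t_2R[i]) /
                   agg$table$t_2R[i], 0))
  }))
}

#' Overlay a temperature-scan growth trace on the model conversions
#'
#' For a radius trace recorded during a constant-rate ramp, computes the
#' fraction-of-conversion curves of every transition on the trace's
#' temperature axis (one-stage: 1 - x; two-stage stage 1: 1 - x_N;
#' stage 2: x_D = 1 - x_N - x_I) and reports the temperature offset
#' between the onset of radius growth (first upward crossing of
#' `threshold`) and each conversion midpoint.  A positive delay for the
#' rate-limiting transition reflects the nucleation lag.
#'
#' @param trace A [probe_trace()] of kind `"dls"` whose abscissa is
#'   temperature (K) from a constant-rate scan.
#' @param model A [domain_model()].
#' @param nu Heating rate of the scan, K/min.
#' @param threshold Radius onset threshold, nm (default 100).
#' @return List `onset_K`, and `delays`: data frame `transition`,
#'   `midpoint_K`, `delay_K` (= onset - midpoint).
#' @export
scan_growth_overlay <- function(trace, model, nu = 1, threshold = 100) {
  stopifnot(inherits(trace, "probe_trace"))
  tg <- trace$abscissa
  r <- trace$ordinate
  above <- which(r >= threshold)
  if (length(above) == 0) stop("trace never reaches the radius threshold")
  i <- above[1]
  onset <- if (i == 1) tg[1]
  else approx(r[(i - 1):i], tg[(i - 1):i], xout = threshold)$y
  conv <- transition_conversions(model, tg, nu)
  mids <- vapply(conv, function(cc)
    approx(cc, tg, xout = 0.5, ties = "ordered")$y, 0)
  list(onset_K = onset,
       delays = data.frame(transition = seq_along(conv),
                           midpoint_K = mids,
                           delay_K = onset - mids))
}

# Fraction-of-conversion curves per transition along a scan.
transition_conversions <- function(model, grid, nu = 1) {
  out <- list()
  for (d in model$domains) {
    if (inherits(d, "one_stage_domain")) {
      out[[length(out) + 1]] <-
        1 - native_fraction_scan(d$kinetics, grid, nu)
    } else {
      fr <- two_stage_fractions_scan(d, grid, nu)
      out[[length(out) + 1]] <- 1 - fr$x_N
      out[[length(out) + 1]] <- pmax(1 - fr$x_N - fr$x_I, 0)
    }
  }
  out
}
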