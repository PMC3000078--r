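# W(T) diagnostic and recursive peeling of multi-transition curves.
#
# For a one-stage irreversible transition the function
#   W(T) = T (ln nu + ln Cp_ex(T) - ln \int_T^end Cp_ex dT)
# is linear in T: W = (E_a/(R T*)) T - E_a/R.  Deviations from linearity
# reject the one-stage hypothesis, and the high-temperature end of a
# multi-transition curve - where only the most thermostable transition is
# left - yields that transition's Arrhenius parameters from the linear
# segment.  Subtracting the simulated transition and repeating peels the
# curve down to the least stable transition.

#' Rate-constant curve from an excess heat-capacity curve
#'
#' \deqn{k(T) = \nu C_p^{ex}(T) / \int_T^{end} C_p^{ex}\,dT.}
#' Points where the remaining (tail) area falls below `floor` times the
#' total area are masked, never extrapolated, because the ratio blows up
#' as the tail area vanishes.
#'
#' @param ex An [excess_curve()].
#' @param nu Heating rate, K/min (default: the curve's).
#' @param floor Tail-area mask threshold as a fraction of the total area
#'   (default 0.01).
#' @return Data frame `temperature`, `k` over the unmasked window.
#' @export
rate_from_curve <- function(ex, nu = ex$heating_rate, floor = 0.01) {
  stopifnot(inherits(ex, "excess_curve"))
  tail_area <- ex$enthalpy - ex$cumulative
  ok <- tail_area > floor * ex$enthalpy & ex$excess > 0
  data.frame(temperature = ex$temperature[ok],
             k = nu * ex$excess[ok] / tail_area[ok])
}

#' Compute the W(T) diagnostic
#'
#' Evaluates W(T) on all usable points (positive excess, tail area above
#' the mask floor), locates the longest high-temperature window on which
#' W is linear, and fits that segment: the slope and intercept give
#' \eqn{E_a = -R\cdot intercept} and \eqn{T^* = E_a/(R\cdot slope)}.
#' W is invariant to scaling the excess curve by a constant.
#'
#' @inheritParams rate_from_curve
#' @param min_pts Minimum linear-window length in points (default 15).
#' @param sd_factor Linear-window residual-SD acceptance threshold as a
#'   multiple of the median local noise estimate (default 2).
#' @return Object of class `"wt_curve"`: `temperature`, `W`, `window`
#'   (K range or NULL), `slope`, `intercept`, `E_a`, `T_star`,
#'   `residual_sd`, `noise_sd` (the local noise estimate).
#' @export
compute_wt <- function(ex, nu = ex$heating_rate, floor = 0.01,
                       min_pts = 15, sd_factor = 2) {
  stopifnot(inherits(ex, "excess_curve"))
  tail_area <- ex$enthalpy - ex$cumulative
  ok <- tail_area > floor * ex$enthalpy & ex$excess > 0
  tg <- ex$temperature[ok]
  W <- tg * (log(nu) + log(ex$excess[ok]) - log(tail_area[ok]))
  out <- list(temperature = tg, W = W, window = NULL,
              window_forced = FALSE,
              slope = NA_real_, intercept = NA_real_,
              E_a = NA_real_, T_star = NA_real_,
              residual_sd = NA_real_, noise_sd = NA_real_)
  if (length(tg) >= min_pts) {
    det <- linear_tail_window(tg, W, min_pts, sd_factor)
    out$noise_sd <- det$noise_sd
    if (!is.null(det$idx)) {
      f <- lm(W[det$idx] ~ tg[det$idx])
      cf <- coef(f)
      E_a <- -.R_GAS * cf[1]
      if (is.finite(E_a) && E_a > 0 && cf[2] > 0) {
        out$window <- range(tg[det$idx])
        out$window_forced <- det$forced
        out$slope <- unname(cf[2]); out$intercept <- unname(cf[1])
        out$E_a <- unname(E_a)
        out$T_star <- unname(E_a / (.R_GAS * cf[2]))
        out$residual_sd <- sd(residuals(f))
      }
    }
  }
  structure(out, class = "wt_curve")
}

#' @export
print.wt_curve <- function(x, ...) {
  cat(sprintf("<wt_curve: %d points", length(x$temperature)))
  if (!is.null(x$window))
    cat(sprintf("; linear tail %.2f-%.2f K -> E_a = %.1f kJ/mol, T* = %.2f K (resid SD %.3g)",
                x$window[1], x$window[2], x$E_a, x$T_star, x$residual_sd))
  else cat("; no linear tail window found")
  cat(">\n")
  invisible(x)
}

#' Residual SD of a linear fit of W(T) over a fixed window
#'
#' Used to compare linearity between curves (a one-stage curve is linear
#' over the whole transition; a multi-transition curve is not).
#'
#' @inheritParams compute_wt
#' @param window `c(Tmin, Tmax)`; default: the central 80% of the peak
#'   area (between the 10% and 90% quantiles of the cumulative heat).
#' @return Residual standard deviation of the linear fit.
#' @export
wt_linearity_sd <- function(ex, nu = ex$heating_rate, window = NULL,
                            floor = 0.01) {
  if (is.null(window)) {
    q <- approx(ex$cumulative / ex$enthalpy, ex$temperature,
                xout = c(0.1, 0.9), ties = "ordered")$y
    window <- q
  }
  tail_area <- ex$enthalpy - ex$cumulative
  ok <- tail_area > floor * ex$enthalpy & ex$excess > 0 &
    ex$temperature >= window[1] & ex$temperature <= window[2]
  tg <- ex$temperature[ok]
  W <- tg * (log(nu) + log(ex$excess[ok]) - log(tail_area[ok]))
  sd(residuals(lm(W ~ tg)))
}

# Longest window anchored at the high-temperature end of (tg, W) whose
# linear-fit residual SD stays below max(sd_factor * local noise,
# sd_floor).  The local noise is the median residual SD of short local
# linear fits; the absolute floor keeps the quadrature bias of the W
# integrals (largest near the mask edges) from vetoing clean curves,
# while staying far below the W excursions of a genuine extra
# transition (which are of order slope x kelvins, i.e. tens of units).
linear_tail_window <- function(tg, W, min_pts = 15, sd_factor = 2,
                               sd_floor = 0.05) {
  n <- length(tg)
  if (n < min_pts) return(list(idx = NULL, noise_sd = NA_real_))
  w <- min_pts
  starts <- seq(1, n - w + 1, by = max(1, floor(w / 3)))
  local_sd <- vapply(starts, function(i) {
    idx <- i:(i + w - 1)
    sd(residuals(lm(W[idx] ~ tg[idx])))
  }, 0)
  noise_sd <- median(local_sd)
  thresh <- max(sd_factor * noise_sd, sd_floor)
  # expand downward from the top; keep the largest acceptable window
  best <- NULL
  lo <- n - min_pts + 1
  step <- max(1, floor(n / 200))
  while (lo >= 1) {
    idx <- lo:n
    s <- sd(residuals(lm(W[idx] ~ tg[idx])))
    if (s <= thresh) best <- idx else break
    lo <- lo - step
  }
  forced <- FALSE
  if (is.null(best)) {
    # best-effort fallback: later peeling steps inherit subtraction
    # error that perturbs the deep tail, so the strict criterion can
    # fail even though the top segment still encodes the next
    # transition; use the shortest top window and flag it.
    best <- (n - min_pts + 1):n
    forced <- TRUE
  }
  list(idx = best, noise_sd = noise_sd, forced = forced)
}

#' Single one-stage fit of a full excess curve
#'
#' Fits the one-stage irreversible model
#' \eqn{C_p^{ex} = \Delta H k(T) x(T)/\nu} to the whole curve by
#' Levenberg-Marquardt least squares, initialised from the W(T) tail fit
#' (or from peak moments if no linear tail is found).  Used to validate
#' annealed preparations and to reject multi-transition curves (which fit
#' poorly).
#'
#' @inheritParams rate_from_curve
#' @return List `E_a`, `T_star`, `dH`, `residual_sd`, `fitted`
#'   (excess_curve), `converged`.
#' @export
check_one_stage <- function(ex, nu = ex$heating_rate) {
  wt <- compute_wt(ex, nu)
  if (!is.na(wt$E_a)) {
    p0 <- c(E_a = wt$E_a, T_star = wt$T_star, dH = ex$enthalpy)
  } else {
    Tm <- ex$temperature[which.max(ex$excess)]
    p0 <- c(E_a = 300, T_star = Tm, dH = ex$enthalpy)
  }
  fit <- one_stage_lsq(ex$temperature, ex$excess, nu, p0)
  fitted <- simulate_one_stage(
    one_stage_domain(kinetic_params(fit$par[["E_a"]], fit$par[["T_star"]]),
                     fit$par[["dH"]]),
    ex$temperature, nu)
  list(E_a = fit$par[["E_a"]], T_star = fit$par[["T_star"]],
       dH = fit$par[["dH"]],
       residual_sd = sd(ex$excess - fitted$excess),
       fitted = fitted, converged = fit$converged)
}

# Bounded LM least squares of the one-stage model; residuals restricted
# to `idx` but the fraction integral always runs over the full grid from
# T0, so windowed fits stay consistent with the whole scan.  Returns
# list(par, converged, ssr).  Bounds keep narrow-window refits from
# running away.
one_stage_lsq <- function(tg, cp, nu, p0, T0 = tg[1],
                          idx = seq_along(tg),
                          lower = c(50, 280, 1e-3),
                          upper = c(1000, 380, 5000)) {
  resid_fn <- function(p) {
    kp <- kinetic_params(p[1], p[2])
    x <- native_fraction_scan(kp, tg, nu, T0)
    (cp - p[3] * arrhenius_rate(kp, tg) * x / nu)[idx]
  }
  p0 <- pmin(pmax(unname(p0), lower), upper)
  out <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  list(par = setNames(out$par, c("E_a", "T_star", "dH")),
       converged = out$info %in% 1:4,
       ssr = sum(out$fvec^2))
}

#' Recursive peeling of transitions from a multi-transition curve
#'
#' Repeatedly (1) finds the longest high-temperature linear window of
#' W(T), (2) estimates (E_a, T*) there, (3) estimates the enthalpy by
#' least squares of \eqn{C_p^{ex}} against \eqn{k(T)x(T)/\nu} on the
#' window, (4) re-optimises the triple locally on the window, and (5)
#' subtracts the simulated one-stage curve, until the remaining area
#' drops below `stop_frac` of the total or no linear window is found.
#' The parameters are null approximations: their role is to count the
#' apparent transitions and seed annealing design and the joint fit.
#'
#' @inheritParams rate_from_curve
#' @param stop_frac Stop when the residual area falls below this fraction
#'   of the total (default 0.03).
#' @param min_pts,sd_factor Passed to the linear-window search.
#' @param max_transitions Safety cap (default 8).
#' @param min_dH_frac Resolution floor: a peeled transition whose
#'   enthalpy falls below this fraction of the total area is taken to be
#'   subtraction debris rather than a real transition; it is discarded
#'   and the recursion stops (default 0.05).
#' @return Object of class `"peeling_result"`: `transitions` (data frame
#'   `E_a`, `T_star`, `dH`, `window_lo`, `window_hi`, most thermostable
#'   first), `count`, `residuals` (list of residual vectors per step),
#'   `residual_area_frac`, `complete` (FALSE if the search stopped for
#'   want of a linear window).
#' @export
peel_transitions <- function(ex, nu = ex$heating_rate, stop_frac = 0.03,
                             floor = 0.01, min_pts = 15, sd_factor = 2,
                             max_transitions = 8, min_dH_frac = 0.05) {
  stopifnot(inherits(ex, "excess_curve"))
  tg <- ex$temperature
  cp <- ex$excess
  A_tot <- ex$enthalpy
  trans <- list()
  resids <- list()
  complete <- TRUE
  repeat {
    A_rem <- trapz_vec(tg, pmax(cp, 0))
    if (A_rem < stop_frac * A_tot || length(trans) >= max_transitions) break
    exr <- excess_curve(tg, pmax(cp, 0), heating_rate = nu, tol = 1)
    wt <- compute_wt(exr, nu, floor = floor, min_pts = min_pts,
                     sd_factor = sd_factor)
    if (is.null(wt$window) || is.na(wt$E_a)) {
      complete <- FALSE
      break
    }
    kp <- kinetic_params(wt$E_a, wt$T_star)
    x <- native_fraction_scan(kp, tg, nu)
    z <- arrhenius_rate(kp, tg) * x / nu
    win <- tg >= wt$window[1] & tg <= wt$window[2]
    dH <- sum(cp[win] * z[win]) / sum(z[win]^2)
    if (!is.finite(dH) || dH <= 0) {
      complete <- FALSE
      break
    }
    # local re-optimisation on the estimation window: counteracts the
    # error accumulated by subtracting earlier (inexact) simulations.
    # Kept only when it actually improves the window residuals.
    p0 <- c(wt$E_a, wt$T_star, dH)
    ssr0 <- sum((cp[win] - dH * z[win])^2)
    ref <- one_stage_lsq(tg, cp, nu, p0, idx = which(win))
    p <- if (ref$ssr < ssr0) ref$par
    else setNames(p0, c("E_a", "T_star", "dH"))
    if (p[["dH"]] < min_dH_frac * A_tot) break  # resolution floor
    kp <- kinetic_params(p[["E_a"]], p[["T_star"]])
    sim <- p[["dH"]] * arrhenius_rate(kp, tg) *
      native_fraction_scan(kp, tg, nu) / nu
    cp <- cp - sim
    trans[[length(trans) + 1]] <-
      data.frame(E_a = p[["E_a"]], T_star = p[["T_star"]], dH = p[["dH"]],
                 window_lo = wt$window[1], window_hi = wt$window[2],
                 window_forced = wt$window_forced)
    resids[[length(resids) + 1]] <- cp
  }
  structure(list(transitions = do.call(rbind, trans),
                 count = length(trans),
                 residuals = resids,
                 residual_area_frac = trapz_vec(tg, pmax(cp, 0)) / A_tot,
                 complete = complete),
            class = "peeling_result")
}

#' @export
print.peeling_result <- function(x, ...) {
  cat(sprintf("<peeling_result: %d apparent transition(s)%s, residual area %.1f%%>\n",
              x$count, if (x$complete) "" else " [stopped early]",
              100 * x$residual_area_frac))
  if (x$count > 0) print(x$transitions, row.names = FALSE)
  invisible(x)
}
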