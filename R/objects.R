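#' @importFrom stats approx coef confint lm median qt quantile residuals rnorm runif sd setNames uniroot
#' @importFrom utils head modifyList read.table tail write.table
NULL

# Gas constant, kJ/(mol K).  All activation energies are kJ/mol, all rate
# constants min^-1, all temperatures absolute (K).
.R_GAS <- 8.314e-3

#' Universal gas constant used throughout the package
#'
#' @return The gas constant in kJ/(mol K), `8.314e-3`.
#' @export
gas_constant <- function() .R_GAS

#' Construct a DSC thermogram
#'
#' A thermogram is a heat-capacity curve recorded while the temperature is
#' ramped at a constant rate, together with the scan metadata needed for
#' kinetic analysis: the heating rate and, if the preparation was
#' pre-incubated (annealed) before the scan, the annealing temperature and
#' duration.
#'
#' @param temperature Strictly increasing temperature grid in kelvin
#'   (at least 16 points).
#' @param heat_capacity Heat capacity at each grid point, kJ/(mol K).
#' @param heating_rate Scan rate \eqn{\nu} in K/min (> 0).
#' @param annealing Optional annealing history: `NULL` for a native
#'   preparation, otherwise `c(T_ann = <K>, t_ann = <min>)`.
#' @param label Free-text label.
#' @return An object of class `"thermogram"`.
#' @export
thermogram <- function(temperature, heat_capacity, heating_rate = 1,
                       annealing = NULL, label = "") {
  temperature <- as.numeric(temperature)
  heat_capacity <- as.numeric(heat_capacity)
  if (length(temperature) != length(heat_capacity))
    stop("temperature and heat_capacity must have equal length")
  if (length(temperature) < 16)
    stop("thermogram grid must have at least 16 points")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  if (!all(is.finite(heat_capacity)))
    stop("heat_capacity must be finite everywhere")
  if (!is.finite(heating_rate) || heating_rate <= 0)
    stop("heating_rate must be positive")
  if (!is.null(annealing)) {
    annealing <- c(T_ann = unname(annealing[["T_ann"]]),
                   t_ann = unname(annealing[["t_ann"]]))
    if (annealing[["T_ann"]] <= 0 || annealing[["t_ann"]] < 0)
      stop("invalid annealing history")
  }
  structure(list(temperature = temperature, heat_capacity = heat_capacity,
                 heating_rate = heating_rate, annealing = annealing,
                 label = label),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram%s: %d points, %.2f-%.2f K, rate %.3g K/min",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$temperature), min(x$temperature), max(x$temperature),
              x$heating_rate))
  if (!is.null(x$annealing))
    cat(sprintf(", annealed %.2f K / %.1f min",
                x$annealing[["T_ann"]], x$annealing[["t_ann"]]))
  cat(">\n")
  invisible(x)
}

#' Construct an excess heat-capacity curve
#'
#' Holds the baseline-corrected signal \eqn{C_p^{ex}(T)} attributable to the
#' denaturation transitions, its cumulative integral \eqn{Q^{ex}(T)} and the
#' total transition enthalpy (the area under the curve).
#'
#' @param temperature Strictly increasing grid, K.
#' @param excess Excess heat capacity, kJ/(mol K).  Small negative
#'   excursions from noise are tolerated (and flagged) up to `tol`.
#' @param heating_rate Scan rate in K/min carried over from the thermogram.
#' @param tol Tolerance for negative values, as a fraction of the maximum.
#' @return An object of class `"excess_curve"` with fields `temperature`,
#'   `excess`, `cumulative` (\eqn{Q^{ex}}), `enthalpy` (\eqn{\Delta H_{trans}}),
#'   `heating_rate` and `negative_flag`.
#' @export
excess_curve <- function(temperature, excess, heating_rate = 1, tol = 0.02) {
  temperature <- as.numeric(temperature)
  excess <- as.numeric(excess)
  if (length(temperature) != length(excess))
    stop("temperature and excess must have equal length")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  if (!all(is.finite(excess)))
    stop("excess heat capacity must be finite")
  floor_neg <- -tol * max(abs(excess))
  if (any(excess < floor_neg))
    stop("excess heat capacity has large negative values; check the baseline")
  cum <- cumtrapz_vec(temperature, pmax(excess, 0))
  structure(list(temperature = temperature, excess = excess,
                 cumulative = cum, enthalpy = cum[length(cum)],
                 heating_rate = heating_rate,
                 negative_flag = any(excess < 0)),
            class = "excess_curve")
}

#' @export
print.excess_curve <- function(x, ...) {
  cat(sprintf("<excess_curve: %d points, %.2f-%.2f K, dH_trans = %.1f kJ/mol>\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              x$enthalpy))
  invisible(x)
}

#' Construct a probe trace
#'
#' Container for the non-calorimetric probes: an isothermal dynamic light
#' scattering trace (time vs hydrodynamic radius), an isothermal residual
#' activity time course, or a temperature-scan fluorescence intensity pair.
#'
#' @param abscissa Strictly increasing time (min) or temperature (K) axis.
#' @param ordinate Primary ordinate (R_h in nm, activity fraction, or I320).
#' @param ordinate2 Optional second channel (I365 for fluorescence scans).
#' @param kind One of `"dls"`, `"activity"`, `"fluorescence"`.
#' @param temperature Incubation temperature in K for isothermal traces.
#' @param label Free-text label.
#' @return An object of class `"probe_trace"`.
#' @export
probe_trace <- function(abscissa, ordinate, ordinate2 = NULL,
                        kind = c("dls", "activity", "fluorescence"),
                        temperature = NA_real_, label = "") {
  kind <- match.arg(kind)
  abscissa <- as.numeric(abscissa)
  ordinate <- as.numeric(ordinate)
  if (any(diff(abscissa) <= 0)) stop("abscissa must be strictly increasing")
  if (!all(is.finite(ordinate))) stop("ordinate must be finite")
  if (length(abscissa) != length(ordinate))
    stop("abscissa and ordinate must have equal length")
  if (!is.null(ordinate2)) {
    ordinate2 <- as.numeric(ordinate2)
    if (length(ordinate2) != length(abscissa))
      stop("both fluorescence channels must have the same length")
    if (!all(is.finite(ordinate2))) stop("ordinate2 must be finite")
  } else if (kind == "fluorescence") {
    stop("fluorescence traces need both intensity channels")
  }
  structure(list(abscissa = abscissa, ordinate = ordinate,
                 ordinate2 = ordinate2, kind = kind,
                 temperature = temperature, label = label),
            class = "probe_trace")
}

# trapezoid quadrature helpers on a (possibly non-uniform) grid
trapz_vec <- function(x, y) pracma::trapz(x, y)

cumtrapz_vec <- function(x, y) as.numeric(pracma::cumtrapz(x, y))
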