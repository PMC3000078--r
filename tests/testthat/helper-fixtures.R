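# Shared fixtures and independent oracles, built in code at test time.

# Independent quadrature oracle for the two-stage scan fractions:
# evaluates the nested-integral solution (integrating-factor form) by
# stepwise trapezoid on a refined grid -- a different route from the
# package's ODE integration.
two_stage_oracle <- function(d, grid, nu = 1, refine = 4) {
  g <- seq(grid[1], grid[length(grid)],
           length.out = refine * (length(grid) - 1) + 1)
  k1 <- arrhenius_rate(d$stage1, g)
  k2 <- arrhenius_rate(d$stage2, g)
  xN <- d$x_N0 * exp(-cumsum(c(0, diff(g) * (head(k1, -1) + tail(k1, -1)) / 2)) / nu)
  xI <- numeric(length(g))
  xI[1] <- d$x_I0
  gg <- k1 * xN / nu
  for (j in 2:length(g)) {
    h <- g[j] - g[j - 1]
    dK2 <- h * (k2[j - 1] + k2[j]) / 2 / nu
    xI[j] <- xI[j - 1] * exp(-dK2) +
      h / 2 * (gg[j - 1] * exp(-dK2) + gg[j])
  }
  idx <- seq(1, length(g), by = refine)
  cp <- (d$dH1 * k1 * xN + d$dH2 * k2 * xI) / nu
  list(temperature = g[idx], x_N = xN[idx], x_I = xI[idx],
       excess = cp[idx])
}

# Excess-curve observations (native + the two training annealings) from
# a generated thermogram set without baseline.
obs_from_set <- function(s) {
  mk <- function(cu) excess_curve(cu$temperature, cu$heat_capacity,
                                  heating_rate = cu$heating_rate)
  list(list(curve = mk(s$curves$native), annealing = NULL),
       list(curve = mk(s$curves$ann1), annealing = s$curves$ann1$annealing),
       list(curve = mk(s$curves$ann2), annealing = s$curves$ann2$annealing))
}

# Solve the one-stage peak-maximum condition k(T_max) = nu E_a/(R T_max^2)
# by bisection (analytic differentiation of the excess-curve formula).
peak_condition_oracle <- function(p, nu = 1, lo = 280, hi = 360) {
  f <- function(T_K) arrhenius_rate(p, T_K) -
    nu * p$E_a / (gas_constant() * T_K^2)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}
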