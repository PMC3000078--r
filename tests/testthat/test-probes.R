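# Fluorescence spectral parameter, phase-plot segmentation and
# inactivation kinetics.

make_channels <- function(A, tg, noise = 0, quench = 0.01, seed = 1) {
  set.seed(seed)
  q <- 1 - quench * (tg - tg[1])
  I365 <- 100 * q / (1 + A) * exp(rnorm(length(tg), 0, noise))
  I320 <- A * 100 * q / (1 + A) * exp(rnorm(length(tg), 0, noise))
  probe_trace(tg, I320, I365, kind = "fluorescence")
}

test_that("parameter A normalises between its plateaus", {
  tg <- seq(293.15, 333.15, by = 0.5)
  A <- 1.06 + 0.26 * plogis((tg - 315) / 1.5)
  pa <- compute_parameter_a(make_channels(A, tg))
  expect_equal(pa$A, A, tolerance = 1e-12)
  expect_equal(range(pa$A_norm), c(0, 1))

  # invariant to a common detector gain
  tr <- make_channels(A, tg)
  tr2 <- probe_trace(tg, 3.7 * tr$ordinate, 3.7 * tr$ordinate2,
                     kind = "fluorescence")
  expect_equal(compute_parameter_a(tr2)$A_norm, pa$A_norm,
               tolerance = 1e-12)

  flat <- probe_trace(tg, rep(5, length(tg)), rep(5, length(tg)),
                      kind = "fluorescence")
  expect_error(compute_parameter_a(flat), "undefined")
})

test_that("phase plots separate state quenching from transitions", {
  tg <- seq(293.15, 333.15, by = 0.5)

  # two-state: through-origin, transition, through-origin
  A2 <- 1.06 + 0.26 * plogis((tg - 315) / 1.2)
  seg2 <- parametric_plot(make_channels(A2, tg, noise = 0.005, seed = 3))
  expect_equal(nrow(seg2), 3)
  expect_equal(seg2$through_origin, c(TRUE, FALSE, TRUE))

  # pure single-state quenching: one through-origin segment
  seg1 <- parametric_plot(make_channels(rep(1.2, length(tg)), tg,
                                        noise = 0.005, seed = 4))
  expect_equal(nrow(seg1), 1)
  expect_true(seg1$through_origin)

  # three-state scan: two adjacent transition segments in the expected
  # temperature ranges (boundary resolution is a few grid steps)
  f1 <- pmin(pmax((tg - 317.15) / 5, 0), 1)
  f2 <- pmin(pmax((tg - 322.15) / 5, 0), 1)
  A3 <- 1.06 + 0.18 * f1 + 0.08 * f2
  seg3 <- parametric_plot(make_channels(A3, tg, noise = 0.003, seed = 4))
  off <- seg3[!seg3$through_origin, ]
  expect_equal(nrow(off), 2)
  expect_lt(abs(min(off$T_lo) - 317.15), 1)
  expect_lt(abs(max(off$T_hi) - 327.15), 1)
  expect_lt(abs(off$T_hi[1] - 322.15), 2.5)
})

test_that("inactivation time courses yield first-order rate constants", {
  tt <- seq(0, 20, by = 1)
  tr <- probe_trace(tt, exp(-0.2 * tt), kind = "activity",
                    temperature = 317.15)
  s <- fit_inactivation(list(tr))
  expect_lt(abs(s$rates$k - 0.2), 1e-10)

  # rates drawn from the stage-1 law of the stable domain, 5% noise
  law <- kinetic_params(400, 321.2)
  set.seed(9)
  temps <- 273.15 + seq(39, 47, by = 2)
  traces <- lapply(temps, function(Tv) {
    k <- arrhenius_rate(law, Tv)
    tt <- seq(0, 2.5 / k, length.out = 12)
    probe_trace(tt, pmax(exp(-k * tt) + rnorm(12, 0, 0.05), 1e-4),
                kind = "activity", temperature = Tv)
  })
  s2 <- fit_inactivation(traces)
  expect_true(all(abs(s2$rates$k - arrhenius_rate(law, temps)) /
                    arrhenius_rate(law, temps) < 0.1))

  # two traces at one temperature pool consistently
  t1 <- seq(0, 15, by = 1.5)
  t2 <- seq(0.7, 15.7, by = 1.5)
  set.seed(12)
  a1 <- pmax(exp(-0.15 * t1) + rnorm(length(t1), 0, 0.02), 1e-4)
  a2 <- pmax(exp(-0.15 * t2) + rnorm(length(t2), 0, 0.02), 1e-4)
  sep <- fit_inactivation(list(
    probe_trace(t1, a1, kind = "activity", temperature = 317.15),
    probe_trace(t2, a2, kind = "activity", temperature = 317.15)))
  ord <- order(c(t1, t2))
  pooled <- fit_inactivation(list(
    probe_trace(c(t1, t2)[ord], c(a1, a2)[ord], kind = "activity",
                temperature = 317.15)))
  expect_true(abs(mean(sep$rates$k) - pooled$rates$k) <
                pooled$rates$ci_hi - pooled$rates$k)

  # non-decaying trace hits the k = 0 boundary with a flag
  up <- fit_inactivation(list(probe_trace(tt, 1 + 0.01 * tt,
                                          kind = "activity")))
  expect_true(up$rates$at_boundary)
})

test_that("probe results overlay onto the calorimetric model", {
  m <- s1_reference_model()
  ps <- make_probe_set(seed = 2, inactivation_noise = 0.02)
  s <- fit_inactivation(ps$inactivation)
  ov <- overlay_with_dsc(s, m)
  mean_lr <- vapply(split(abs(ov$log_ratio), ov$transition), mean, 0)
  expect_lt(mean_lr[["2"]], 0.1)      # tracks stage 1 of the stable domain
  expect_gt(mean_lr[["1"]], 1)        # not the least stable domain

  # fluorescence rise confined to the stable domain's transitions
  ovf <- overlay_with_dsc(ps$fluorescence, m)
  expect_true(ovf$contained)

  empty <- structure(list(rates = NULL, residuals = list()),
                     class = "inactivation_series")
  expect_equal(nrow(overlay_with_dsc(empty, m)), 0)
})
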