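# Aggregate-growth fitting from DLS traces.

test_that("exponential growth parameters are recovered from exact traces", {
  tt <- seq(0, 25, by = 0.25)
  r <- 20 * exp(log(2) / 4.5 * pmax(tt - 5, 0))
  f <- fit_growth(probe_trace(tt, r, kind = "dls", temperature = 317.15))
  expect_true(f$growing)
  expect_lt(abs(f$t0 - 5), 1e-8)
  expect_lt(abs(f$R_h0 - 20) / 20, 1e-8)
  expect_lt(abs(f$t_2R - 4.5) / 4.5, 1e-8)
  # doubling by construction
  expect_equal(2 * f$R_h0,
               f$R_h0 * exp(log(2) / f$t_2R * f$t_2R))

  # time translation moves only the lag
  f2 <- fit_growth(probe_trace(tt + 3, r, kind = "dls",
                               temperature = 317.15))
  expect_lt(abs(f2$t0 - 8), 1e-6)
  expect_lt(abs(f2$t_2R - f$t_2R), 1e-8)

  # a flat trace is flagged as non-aggregating
  flat <- probe_trace(tt, rep(20, length(tt)) *
                        exp(sin(tt) * 0), kind = "dls")
  expect_false(fit_growth(flat)$growing)
})

test_that("doubling time survives realistic multiplicative noise", {
  set.seed(5)
  tt <- seq(0, 25, by = 0.25)
  r <- 20 * exp(log(2) / 4.5 * pmax(tt - 5, 0))
  for (i in 1:5) {
    rn <- r * exp(rnorm(length(r), 0, 0.03))
    f <- fit_growth(probe_trace(tt, rn, kind = "dls",
                                temperature = 317.15))
    expect_lt(abs(f$t_2R - 4.5), 0.4)
  }
})

test_that("traces differing only in lag give the same doubling time", {
  s <- make_dls_set(noise_sd = 0.02, seed = 3)
  fits <- lapply(s$concentration, fit_growth)
  t2 <- vapply(fits, function(f) f$t_2R, 0)
  hw <- vapply(fits, function(f) f$conf_halfwidth[["t_2R"]], 0)
  truth <- log(2) / arrhenius_rate(s$truth$growth_law,
                                   fits[[1]]$temperature)
  expect_true(all(abs(t2 - truth) <= pmax(hw, 0.2)))
})

test_that("the growth Arrhenius law is recovered across temperatures", {
  s <- make_dls_set(noise_sd = 0, seed = 1)
  fits <- lapply(s$isothermal, fit_growth)
  a <- fit_aggregation_arrhenius(fits)
  expect_lt(abs(a$E_a - 430) / 430, 1e-6)
  expect_lt(abs(a$T_star - 320.8) / 320.8, 1e-6)

  # t_2R at T* equals ln 2 minutes by definition of the rate convention
  expect_equal(log(2) / arrhenius_rate(kinetic_params(a$E_a, a$T_star),
                                       a$T_star), log(2))

  # an extra consistent temperature leaves the estimates unchanged
  T_new <- 321.15
  t2_new <- log(2) / arrhenius_rate(s$truth$growth_law, T_new)
  extra <- structure(list(t0 = 3, R_h0 = 20, t_2R = t2_new,
                          temperature = T_new, conf_halfwidth = NULL,
                          growing = TRUE), class = "aggregation_fit")
  a2 <- fit_aggregation_arrhenius(c(fits, list(extra)))
  expect_lt(abs(a2$E_a - a$E_a), 1e-3)

  expect_error(fit_aggregation_arrhenius(fits[1:2]), "at least 3")
})

test_that("doubling times are matched to the rate-limiting transition", {
  s <- make_dls_set(noise_sd = 0, seed = 1)
  # include the 44 degC concentration-series trace so the comparison
  # covers the reference hold temperature
  fits <- c(lapply(s$isothermal, fit_growth),
            list(fit_growth(s$concentration[[1]])))
  a <- fit_aggregation_arrhenius(fits)
  cmp <- compare_with_denaturation(a, s1_reference_model())
  at44 <- cmp[abs(cmp$temperature - 317.15) < 1e-6, ]
  # stage 1 of the stable domain (transition 2) is the rate-limiting step
  expect_lt(abs(at44$t_half[at44$transition == 2] - 4.6939), 0.01)
  expect_true(abs(at44$t_half[at44$transition == 2] - 4.5) <= 0.4)
  expect_gt(at44$rel_dev[at44$transition == 1],
            3 * at44$rel_dev[at44$transition == 2])

  # identical laws deviate nowhere
  same <- compare_with_denaturation(
    a, domain_model(one_stage_domain(kinetic_params(a$E_a, a$T_star),
                                     100)))
  expect_lt(max(same$rel_dev), 1e-5)
})

test_that("scan overlays report the nucleation delay", {
  m <- s1_reference_model()
  s <- make_dls_set(noise_sd = 0, seed = 1, scan_delay_K = 3)
  ov <- scan_growth_overlay(s$scan, m)
  expect_lt(abs(ov$delays$delay_K[ov$delays$transition == 2] - 3), 0.2)

  s0 <- make_dls_set(noise_sd = 0, seed = 1, scan_delay_K = 0)
  ov0 <- scan_growth_overlay(s0$scan, m)
  expect_lt(abs(ov0$delays$delay_K[ov0$delays$transition == 2]), 0.2)

  conv <- calorikin:::transition_conversions(m, default_grid())
  for (cc in conv) expect_true(all(diff(cc) >= -1e-9))
})
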