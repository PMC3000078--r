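test_that("Arrhenius rate constant matches its reparameterisation", {
  kp <- kinetic_params(400, 321.2)
  expect_identical(arrhenius_rate(kp, 321.2), 1)
  # frozen independent scalar evaluation of the rate law
  expect_equal(arrhenius_rate(kp, 317.15), 0.1476694769906582,
               tolerance = 1e-12)
  expect_true(all(arrhenius_rate(kp, seq(300, 321, by = 1)) < 1))
  expect_true(all(arrhenius_rate(kp, seq(321.3, 340, by = 1)) > 1))
  expect_error(arrhenius_rate(kp, -1), "positive")
})

test_that("native fraction along a scan behaves as the kinetic integral", {
  kp <- kinetic_params(300, 320)
  g <- seq(288, 350, by = 0.05)
  x <- native_fraction_scan(kp, g, nu = 1)
  expect_equal(x[1], 1)
  expect_true(all(diff(x) <= 0))
  # far below T* the protein is kinetically frozen
  expect_gt(x[g == 295], 0.999)

  # grid refinement moves the half-conversion point by < 0.01 K
  cross <- function(grid, nu = 1) {
    xx <- native_fraction_scan(kp, grid, nu = nu)
    i <- which(xx <= 0.5)[1]
    grid[i - 1] + (grid[i] - grid[i - 1]) *
      (xx[i - 1] - 0.5) / (xx[i - 1] - xx[i])
  }
  g2 <- seq(288, 350, by = 0.025)
  expect_lt(abs(cross(g) - cross(g2)), 0.01)

  # doubling the heating rate shifts the crossing to higher temperature
  expect_gt(cross(g, nu = 2), cross(g))

  expect_error(native_fraction_scan(kp, g, T0 = 300), "below")
})

test_that("one-stage simulation conserves enthalpy and peak condition", {
  g <- seq(288, 358, by = 0.05)
  d <- one_stage_domain(kinetic_params(290, 317.5), 200)
  ex <- simulate_one_stage(d, g)
  expect_lt(abs(ex$enthalpy - 200) / 200, 0.005)

  # linearity in the initial fraction is exact
  ex_half <- simulate_one_stage(d, g, initial_fraction = 0.5)
  expect_equal(ex_half$excess, ex$excess / 2, tolerance = 1e-12)

  # peak maximum satisfies k(T_max) = nu E_a / (R T_max^2)
  T_max <- g[which.max(ex$excess)]
  expect_lt(abs(T_max - peak_condition_oracle(d$kinetics)), 0.05)
})

test_that("two-stage simulation agrees with the quadrature oracle", {
  g <- seq(288.15, 358.15, by = 0.05)
  d <- two_stage_domain(kinetic_params(400, 321.2),
                        kinetic_params(340, 324.5), 1030, 500)
  ex <- simulate_two_stage(d, g)
  # both stages complete from the native state
  expect_lt(abs(ex$enthalpy - 1530) / 1530, 0.005)

  orc <- two_stage_oracle(d, g)
  expect_lt(max(abs(ex$excess - orc$excess)) / max(orc$excess), 1e-4)

  # a pure-intermediate preparation is a one-stage transition of stage 2
  # (fine grid so both quadratures converge to the shared limit)
  gf <- seq(310, 340, by = 0.005)
  d2 <- two_stage_domain(d$stage1, d$stage2, d$dH1, d$dH2,
                         x_N0 = 0, x_I0 = 1)
  ex2 <- simulate_two_stage(d2, gf)
  one <- simulate_one_stage(one_stage_domain(d$stage2, d$dH2), gf)
  expect_lt(max(abs(ex2$excess - one$excess)) / max(one$excess), 1e-6)
  expect_lt(abs(ex2$enthalpy - 500) / 500, 0.005)
})

test_that("isothermal fractions solve the sequential first-order system", {
  m <- s1_reference_model()
  fr0 <- isothermal_fractions(m, 319.15, 0)
  expect_equal(fr0[[1]][["x"]], 1)
  expect_equal(unname(fr0[[2]]), c(1, 0))

  # the 46 degC / 15 min hold eliminates the least stable domain
  fr <- isothermal_fractions(m, 319.15, 15)
  expect_lt(fr[[1]][["x"]], 0.01)

  # k2 -> 0 limit: everything funnels into the intermediate
  slow2 <- two_stage_domain(kinetic_params(400, 321.2),
                            kinetic_params(400, 500), 100, 100)
  k1 <- arrhenius_rate(slow2$stage1, 319.15)
  fr2 <- isothermal_fractions(domain_model(slow2), 319.15, 5)[[1]]
  expect_equal(fr2[["x_I"]], 1 - exp(-k1 * 5), tolerance = 1e-3)

  # degenerate k1 = k2 branch is continuous with the generic formula
  mk <- function(eps) {
    d <- two_stage_domain(kinetic_params(300, 320),
                          kinetic_params(300, 320 + eps), 100, 100)
    isothermal_fractions(domain_model(d), 318, 7)[[1]][["x_I"]]
  }
  expect_equal(mk(0), mk(1e-4), tolerance = 1e-3)
})

test_that("half-life follows t_0.5 = ln 2 / k", {
  kp <- kinetic_params(400, 321.2)
  expect_equal(half_life(kp, 321.2), log(2))
  # frozen scalar: stage-1 half-life of the stable domain at 44 degC
  expect_equal(half_life(kp, 317.15), 4.6939096330909, tolerance = 1e-10)
  tt <- half_life(kp, seq(310, 330, by = 1))
  expect_true(all(diff(tt) < 0))
})

test_that("enthalpy is conserved across domain types and fractions", {
  g <- seq(285, 355, by = 0.05)
  set.seed(11)
  for (i in 1:5) {
    d1 <- one_stage_domain(kinetic_params(runif(1, 250, 450),
                                          runif(1, 312, 320)),
                           runif(1, 100, 600))
    f <- runif(1, 0.2, 1)
    ex1 <- simulate_one_stage(d1, g, initial_fraction = f)
    expect_lt(abs(ex1$enthalpy - f * d1$dH) / (f * d1$dH), 0.005)

    xN0 <- runif(1, 0, 1); xI0 <- runif(1, 0, 1 - xN0)
    d2 <- two_stage_domain(kinetic_params(runif(1, 300, 450),
                                          runif(1, 318, 324)),
                           kinetic_params(runif(1, 300, 450),
                                          runif(1, 322, 328)),
                           runif(1, 200, 1000), runif(1, 100, 600),
                           x_N0 = xN0, x_I0 = xI0)
    truth <- xN0 * (d2$dH1 + d2$dH2) + xI0 * d2$dH2
    if (truth > 10) {
      ex2 <- simulate_two_stage(d2, g)
      expect_lt(abs(ex2$enthalpy - truth) / truth, 0.005)
    }
  }
})

test_that("annealing a one-stage domain scales its curve exactly", {
  g <- seq(288, 350, by = 0.05)
  d <- one_stage_domain(kinetic_params(290, 317.5), 200)
  m <- domain_model(d)
  ann <- anneal_model(m, 314.15, 12)
  x <- isothermal_fractions(m, 314.15, 12)[[1]][["x"]]
  sim_ann <- simulate_annealed_model(ann, g)
  sim_nat <- simulate_model(m, g)
  expect_equal(sim_ann$excess, x * sim_nat$excess, tolerance = 1e-12)
})
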