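# Annealing design: schedule selection, resolving power, enthalpy
# correction, and the triangular decomposition it enables.

test_that("a feasible schedule isolates the stable domain of the reference model", {
  m <- s1_reference_model()
  pl <- plan_annealing(m, target_index = 3, A = 0.02,
                       T_ann_grid = seq(312.15, 324.15, by = 0.5))
  row <- pl[abs(pl$T_ann - 319.15) < 1e-9, ]
  expect_true(row$feasible)
  expect_lt(abs(row$t_ann - 15), 0.5)
  expect_lt(row$x1, 0.01)       # least stable domain erased
  expect_gt(row$x3, 0.1)        # target stage survives usably
})

test_that("indistinguishable transitions admit no plan", {
  m <- domain_model(one_stage_domain(kinetic_params(300, 318), 200),
                    one_stage_domain(kinetic_params(300, 318), 300))
  pl <- plan_annealing(m, target_index = 2, A = 0.05)
  expect_false(any(pl$feasible))
})

test_that("relaxing the survival ratio shortens the required hold", {
  m <- s1_reference_model()
  grid_T <- seq(312, 324, by = 0.5)
  p_small <- plan_annealing(m, 3, A = 0.02, T_ann_grid = grid_T)
  p_large <- plan_annealing(m, 3, A = 0.08, T_ann_grid = grid_T)
  expect_true(all(p_large$t_ann < p_small$t_ann))
})

test_that("resolving power reproduces the minimum T* separation", {
  rp <- resolving_power(300, 320)
  expect_lt(abs(rp$min_dT_star - 2), 0.1)
  # the equal-E_a limit does not depend on the candidate hold range
  rp2 <- resolving_power(300, 320, T_ann_range = c(300, 325))
  expect_equal(rp$min_dT_star, rp2$min_dT_star, tolerance = 1e-3)
  # doubling E_a approximately halves the minimal gap
  rp3 <- resolving_power(600, 320)
  expect_lt(abs(rp3$min_dT_star / rp$min_dT_star - 0.5), 0.05)
  # the equal-T* minimum E_a gap is finite once the hold is bounded
  expect_true(is.finite(rp$min_dE_a))
  expect_gt(rp$min_dE_a, 0)
})

test_that("annealing enthalpy losses are corrected by the survival factor", {
  kp <- kinetic_params(290, 317.5)
  expect_equal(correct_enthalpy(150, kp, 317.15, 0), 150)
  expect_gte(correct_enthalpy(150, kp, 310, 30), 150)

  # end-to-end: anneal, rescan, measure the area, restore the enthalpy
  g <- seq(288, 350, by = 0.05)
  m <- domain_model(one_stage_domain(kp, 200))
  ann <- anneal_model(m, 314.65, 12)
  area <- simulate_annealed_model(ann, g)$enthalpy
  expect_lt(abs(correct_enthalpy(area, kp, 314.65, 12) - 200) / 200, 0.01)
})

test_that("simulated annealed areas match the predicted survivals", {
  m <- s1_reference_model()
  g <- default_grid()
  pl <- plan_annealing(m, 3, A = 0.02, T_ann_grid = seq(314, 322, by = 1))
  feas <- pl[pl$feasible, ]
  expect_gt(nrow(feas), 0)
  for (i in seq_len(min(nrow(feas), 3))) {
    fr <- isothermal_fractions(m, feas$T_ann[i], feas$t_ann[i])
    predicted <- fr[[1]][["x"]] * 200 +
      fr[[2]][["x_N"]] * 1530 + fr[[2]][["x_I"]] * 500
    ann <- anneal_model(m, feas$T_ann[i], feas$t_ann[i])
    measured <- simulate_annealed_model(ann, g)$enthalpy
    expect_lt(abs(measured - predicted) / predicted, 0.01)
  }
})

test_that("the triangular system back-substitutes to the domain curves", {
  # three well-separated one-stage domains in increasing thermostability
  m <- domain_model(one_stage_domain(kinetic_params(300, 312), 250),
                    one_stage_domain(kinetic_params(320, 319), 350),
                    one_stage_domain(kinetic_params(340, 326), 450))
  g <- seq(285, 355, by = 0.05)
  plan3 <- plan_annealing(m, 3, A = 0.02,
                          T_ann_grid = seq(300, 330, by = 0.25))
  plan2 <- plan_annealing(m, 2, A = 0.02,
                          T_ann_grid = seq(295, 325, by = 0.25))
  p3 <- plan3[plan3$feasible, ][1, ]   # leaves only domain 3
  p2 <- plan2[plan2$feasible, ][1, ]   # leaves domains 2 and 3

  sim_cond <- function(Ta, ta) simulate_annealed_model(
    anneal_model(m, Ta, ta), g)$excess
  nat <- simulate_model(m, g)$excess
  cur3 <- sim_cond(p3$T_ann, p3$t_ann)
  cur2 <- sim_cond(p2$T_ann, p2$t_ann)

  x3 <- c(p3$x3, p2$x3)   # survivals of domain 3 under the two holds
  x2 <- p2$x2
  # back-substitution of the triangular system
  est3 <- cur3 / x3[1]
  est2 <- (cur2 - x3[2] * est3) / x2
  est1 <- nat - est2 - est3

  truth <- lapply(m$domains, function(d) simulate_one_stage(d, g)$excess)
  areas <- vapply(truth, function(y) pracma::trapz(g, y), 0)
  for (j in 1:3) {
    est <- list(est1, est2, est3)[[j]]
    expect_lt(abs(pracma::trapz(g, est) - areas[j]) / areas[j], 0.03)
  }
})
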