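# Joint multi-thermogram fitting.  One noiseless observation set
# (native + two annealed scans of the reference model) is shared across
# the blocks; the fit is deterministic, so two starts suffice here.

set_g <- make_thermogram_set(noise_sd = 0, baseline = NULL, seed = 1)
obs_g <- obs_from_set(set_g)
peel_g <- peel_transitions(obs_g[[1]]$curve)
problem_g <- fit_problem(obs_g, model_from_peeling(peel_g))
fit_g <- fit_model(problem_g, n_starts = 2)
truth_g <- model_to_par(set_g$truth$model)

test_that("the joint fit recovers the generating parameters", {
  expect_true(fit_g$converged)
  par <- fit_g$par
  is_T <- grepl("T_star", names(par))
  is_E <- grepl("E_a", names(par))
  is_H <- grepl("dH", names(par))
  expect_lt(max(abs(par[is_T] - truth_g[is_T])), 0.1)
  expect_lt(max(abs(par[is_E] - truth_g[is_E])), 10)
  expect_lt(max(abs(par[is_H] - truth_g[is_H]) / truth_g[is_H]), 0.02)
})

test_that("a single one-stage observation reduces to the direct fit", {
  g <- default_grid()
  ex <- simulate_one_stage(one_stage_domain(kinetic_params(290, 317.5),
                                            200), g)
  direct <- check_one_stage(ex)
  tpl <- domain_model(one_stage_domain(kinetic_params(280, 316), 180))
  res <- fit_model(fit_problem(list(list(curve = ex, annealing = NULL)),
                               tpl), n_starts = 1)
  expect_lt(abs(res$par[["d1.E_a"]] - direct$E_a), 0.5)
  expect_lt(abs(res$par[["d1.T_star"]] - direct$T_star), 0.01)
  expect_lt(abs(res$par[["d1.dH"]] - direct$dH) / direct$dH, 0.002)
})

test_that("freezing every parameter returns residuals without moving", {
  frozen <- setNames(rep(FALSE, length(truth_g)), names(truth_g))
  pr <- fit_problem(obs_g, set_g$truth$model, free = frozen)
  res <- fit_model(pr)
  expect_identical(res$par, model_to_par(set_g$truth$model))
  expect_lt(max(res$per_curve_sd), 1e-10)
})

test_that("holdout annealing conditions are predicted out of sample", {
  hold <- set_g$truth$schedule$holdout
  pred <- predict_holdout(fit_g$model, hold, default_grid())
  truth_curve <- simulate_annealed_model(
    anneal_model(set_g$truth$model, hold[["T_ann"]], hold[["t_ann"]]),
    default_grid())
  expect_lt(max(abs(pred$excess - truth_curve$excess)) /
              max(truth_curve$excess), 0.01)

  # a zero-duration hold is the native prediction
  pred0 <- predict_holdout(fit_g$model, c(T_ann = 317.15, t_ann = 0),
                           default_grid())
  nat <- simulate_model(fit_g$model, default_grid())
  expect_equal(pred0$excess, nat$excess, tolerance = 1e-12)

  # harsher annealing than any training condition stays non-negative
  harsh <- predict_holdout(fit_g$model, c(T_ann = 321.15, t_ann = 60),
                           default_grid())
  expect_true(all(harsh$excess >= -1e-9))
})

test_that("a wrong frozen T* is rejected by holdout prediction", {
  hold <- set_g$truth$schedule$holdout
  m_hold <- anneal_model(set_g$truth$model, hold[["T_ann"]],
                         hold[["t_ann"]])
  holdout <- list(curve = simulate_annealed_model(m_hold, default_grid()),
                  annealing = hold)

  cf_wrong <- constrained_counterfit(problem_g, "d1.T_star", 318.3,
                                     holdout, unconstrained = fit_g,
                                     n_starts = 1)
  expect_gt(cf_wrong$sd_ratio, 3)
  # removing the constraint never worsens the training objective
  expect_lte(fit_g$objective, cf_wrong$constrained$objective)

  cf_true <- constrained_counterfit(problem_g, "d1.T_star", 317.5,
                                    holdout, unconstrained = fit_g,
                                    n_starts = 1)
  expect_lt(cf_true$sd_ratio, 1.2)

  frozen <- setNames(rep(FALSE, length(truth_g)), names(truth_g))
  pr <- fit_problem(obs_g, set_g$truth$model, free = frozen)
  expect_error(constrained_counterfit(pr, "d1.T_star", 318.3, holdout),
               "already frozen")
})

test_that("uncertainties fall back to the conventional floors", {
  unc <- estimate_uncertainty(problem_g, fit_g)
  is_T <- grepl("T_star", unc$parameter)
  is_E <- grepl("E_a", unc$parameter)
  is_H <- grepl("dH", unc$parameter)
  # noiseless data: single-curve spread is negligible, floors apply
  expect_equal(unc$uncertainty[is_T], rep(0.4, sum(is_T)))
  expect_equal(unc$uncertainty[is_E], rep(40, sum(is_E)))
  expect_equal(unc$uncertainty[is_H], 0.1 * abs(unc$joint[is_H]))
  # the reported uncertainty never undercuts the observed spread
  expect_true(all(unc$uncertainty >= unc$spread - 1e-12))
})
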