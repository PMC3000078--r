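# Joint nonlinear fitting of a multidomain model to a set of thermograms
# (native plus annealed preparations).  All curves share one parameter
# vector; each observation's annealing history is mapped to initial state
# fractions through the isothermal solution, so the annealed curves
# constrain the Arrhenius parameters far more strongly than any single
# scan could.

#' Flatten a domain model into a named parameter vector
#'
#' One-stage domain i contributes `d<i>.E_a`, `d<i>.T_star`, `d<i>.dH`;
#' a two-stage domain contributes the six analogues suffixed `1`/`2`.
#' Initial fractions are not parameters: they derive from annealing
#' histories.
#'
#' @param model A [domain_model()].
#' @return Named numeric vector.
#' @export
model_to_par <- function(model) {
  out <- numeric()
  for (i in seq_along(model$domains)) {
    d <- model$domains[[i]]
    pre <- sprintf("d%d.", i)
    if (inherits(d, "one_stage_domain")) {
      v <- c(d$kinetics$E_a, d$kinetics$T_star, d$dH)
      names(v) <- paste0(pre, c("E_a", "T_star", "dH"))
    } else {
      v <- c(d$stage1$E_a, d$stage1$T_star, d$dH1,
             d$stage2$E_a, d$stage2$T_star, d$dH2)
      names(v) <- paste0(pre, c("E_a1", "T_star1", "dH1",
                                "E_a2", "T_star2", "dH2"))
    }
    out <- c(out, v)
  }
  out
}

#' Rebuild a domain model from a parameter vector
#'
#' @param par Named vector as produced by [model_to_par()].
#' @param template A [domain_model()] fixing the domain structure.
#' @return A [domain_model()] in its native state (x_N0 = 1, x_I0 = 0).
#' @export
par_to_model <- function(par, template) {
  domains <- vector("list", length(template$domains))
  for (i in seq_along(template$domains)) {
    pre <- sprintf("d%d.", i)
    if (inherits(template$domains[[i]], "one_stage_domain")) {
      domains[[i]] <- one_stage_domain(
        kinetic_params(par[[paste0(pre, "E_a")]],
                       par[[paste0(pre, "T_star")]]),
        par[[paste0(pre, "dH")]])
    } else {
      domains[[i]] <- two_stage_domain(
        kinetic_params(par[[paste0(pre, "E_a1")]],
                       par[[paste0(pre, "T_star1")]]),
        kinetic_params(par[[paste0(pre, "E_a2")]],
                       par[[paste0(pre, "T_star2")]]),
        par[[paste0(pre, "dH1")]], par[[paste0(pre, "dH2")]])
    }
  }
  domain_model(domains)
}

#' Assemble a joint fitting problem
#'
#' @param observations List of observations, each a list with `curve`
#'   (an [excess_curve()]) and `annealing` (`NULL` for a native scan or
#'   `c(T_ann = , t_ann = )`).
#' @param template [domain_model()] giving the structure and initial
#'   parameter values (typically from recursive peeling).
#' @param free Named logical vector flagging free parameters; defaults to
#'   all free.  Frozen parameters never move.
#' @param lower,upper Named bound overrides; defaults:
#'   E_a in \[50, 1000\] kJ/mol, T* in \[280, 360\] K, dH in (0, 5000\].
#' @return Object of class `"fit_problem"`.
#' @export
fit_problem <- function(observations, template, free = NULL,
                        lower = NULL, upper = NULL) {
  if (length(observations) < 1) stop("at least one observation is required")
  for (ob in observations) {
    if (!inherits(ob$curve, "excess_curve"))
      stop("each observation needs an excess_curve in $curve")
  }
  par <- model_to_par(template)
  if (any(!is.finite(par))) stop("initial parameter values must be finite")
  f <- setNames(rep(TRUE, length(par)), names(par))
  if (!is.null(free)) f[names(free)] <- free
  lo <- ifelse(grepl("E_a", names(par)), 50,
               ifelse(grepl("T_star", names(par)), 280, 1e-3))
  hi <- ifelse(grepl("E_a", names(par)), 1000,
               ifelse(grepl("T_star", names(par)), 360, 5000))
  lo <- setNames(lo, names(par)); hi <- setNames(hi, names(par))
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(par < lo - 1e-9) || any(par > hi + 1e-9))
    stop("initial parameter values must lie within bounds")
  structure(list(observations = observations, template = template,
                 par = par, free = f, lower = lo, upper = hi),
            class = "fit_problem")
}

# Residual vector of a parameter vector over all observations.
problem_residuals <- function(problem, par) {
  model <- par_to_model(par, problem$template)
  unlist(lapply(problem$observations, function(ob) {
    m <- if (is.null(ob$annealing)) model
    else anneal_model(model, ob$annealing[["T_ann"]],
                      ob$annealing[["t_ann"]])
    pred <- simulate_annealed_model(m, ob$curve$temperature,
                                    nu = ob$curve$heating_rate)
    ob$curve$excess - pred$excess
  }), use.names = FALSE)
}

#' Fit a multidomain model jointly to all observations
#'
#' Levenberg-Marquardt least squares (uniform point weights) over all
#' curves simultaneously, with optional multi-start: additional starts
#' jitter the free initial values (activation energies and enthalpies by
#' a relative factor, special temperatures by up to 2 K) to guard
#' against the roughness of the peeled null approximation.
#'
#' @param problem A [fit_problem()].
#' @param n_starts Number of starts (default 8; the first is unjittered).
#' @param jitter Relative jitter for E_a and dH (default 0.2).
#' @param seed Seed for the jitter draws (default 1234).
#' @param maxiter LM iteration cap per start.
#' @return Object of class `"fit_result"`: `model` (native state),
#'   `par`, `objective` (sum of squares), `per_curve_sd`, `converged`,
#'   `at_bound` (names of parameters within 1e-6 of a bound), `problem`.
#' @export
fit_model <- function(problem, n_starts = 8, jitter = 0.2, seed = 1234,
                      maxiter = 150) {
  stopifnot(inherits(problem, "fit_problem"))
  free <- problem$free
  p_full <- problem$par
  if (!any(free)) {
    r <- problem_residuals(problem, p_full)
    return(finish_fit(problem, p_full, sum(r^2), TRUE))
  }
  resid_free <- function(pf) {
    p <- p_full
    p[names(pf)] <- pf
    problem_residuals(problem, p)
  }
  set.seed(seed)
  starts <- list(p_full[free])
  if (n_starts > 1) {
    for (s in 2:n_starts) {
      p <- p_full[free]
      rel <- grepl("E_a|dH", names(p))
      p[rel] <- p[rel] * runif(sum(rel), 1 - jitter, 1 + jitter)
      p[!rel] <- p[!rel] + runif(sum(!rel), -2, 2)
      starts[[s]] <- pmin(pmax(p, problem$lower[free]), problem$upper[free])
    }
  }
  best <- NULL
  for (p0 in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_free,
                         lower = unname(problem$lower[free]),
                         upper = unname(problem$upper[free]),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(out)) next
    ssr <- sum(out$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(par = out$par, ssr = ssr, info = out$info)
  }
  if (is.null(best)) stop("all optimisation starts failed")
  p_full[names(best$par)] <- best$par
  finish_fit(problem, p_full, best$ssr, best$info %in% 1:4)
}

finish_fit <- function(problem, par, ssr, converged) {
  per_sd <- vapply(problem$observations, function(ob) {
    model <- par_to_model(par, problem$template)
    m <- if (is.null(ob$annealing)) model
    else anneal_model(model, ob$annealing[["T_ann"]],
                      ob$annealing[["t_ann"]])
    pred <- simulate_annealed_model(m, ob$curve$temperature,
                                    nu = ob$curve$heating_rate)
    sd(ob$curve$excess - pred$excess)
  }, 0)
  at_bound <- names(par)[problem$free &
                           (abs(par - problem$lower) < 1e-6 |
                              abs(par - problem$upper) < 1e-6)]
  if (length(at_bound))
    warning("parameter(s) at bound: ", paste(at_bound, collapse = ", "))
  structure(list(model = par_to_model(par, problem$template), par = par,
                 objective = ssr, per_curve_sd = per_sd,
                 converged = converged, at_bound = at_bound,
                 problem = problem),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: SSR = %.4g over %d curve(s)%s>\n", x$objective,
              length(x$problem$observations),
              if (x$converged) "" else " [NOT converged]"))
  print(round(x$par, 3))
  invisible(x)
}

#' Predict the thermogram of an annealing condition
#'
#' Simulates the excess curve expected for a preparation annealed under
#' conditions excluded from fitting - the out-of-sample validation of a
#' fitted model.
#'
#' @param model A fitted [domain_model()] (native state).
#' @param annealing `c(T_ann = , t_ann = )`, or `NULL` for a native scan.
#' @param grid Temperature grid, K.
#' @param nu Heating rate, K/min.
#' @return An [excess_curve()].
#' @export
predict_holdout <- function(model, annealing, grid, nu = 1) {
  m <- if (is.null(annealing) || annealing[["t_ann"]] == 0) model
  else anneal_model(model, annealing[["T_ann"]], annealing[["t_ann"]])
  simulate_annealed_model(m, grid, nu)
}

#' Refit under a frozen parameter-equality constraint
#'
#' Freezes one parameter at a prescribed value, refits, and compares the
#' constrained and unconstrained models on a holdout observation.  A
#' constrained holdout residual much larger than the unconstrained one
#' rejects the constraint - prediction-based hypothesis testing in place
#' of regression statistics.
#'
#' @param problem A [fit_problem()].
#' @param param Name of the parameter to freeze (must currently be free).
#' @param value Frozen value.
#' @param holdout Observation list (`curve`, `annealing`) excluded from
#'   fitting.
#' @param unconstrained Optional precomputed unconstrained [fit_model()]
#'   result (refitted if missing).
#' @param ... Passed to [fit_model()].
#' @return List `constrained`, `unconstrained` (fit results),
#'   `holdout_sd_constrained`, `holdout_sd_unconstrained`, `sd_ratio`.
#' @export
constrained_counterfit <- function(problem, param, value, holdout,
                                   unconstrained = NULL, ...) {
  if (!param %in% names(problem$par)) stop("unknown parameter: ", param)
  if (!problem$free[[param]])
    stop("parameter ", param, " is already frozen")
  if (is.null(unconstrained)) unconstrained <- fit_model(problem, ...)
  cproblem <- problem
  cproblem$par[[param]] <- value
  cproblem$free[[param]] <- FALSE
  constrained <- fit_model(cproblem, ...)
  hsd <- function(res) {
    pred <- predict_holdout(res$model, holdout$annealing,
                            holdout$curve$temperature,
                            holdout$curve$heating_rate)
    sd(holdout$curve$excess - pred$excess)
  }
  su <- hsd(unconstrained)
  sc <- hsd(constrained)
  list(constrained = constrained, unconstrained = unconstrained,
       holdout_sd_constrained = sc, holdout_sd_unconstrained = su,
       sd_ratio = sc / su)
}

#' Estimate parameter uncertainties by single-curve refits
#'
#' Refits each observation on its own (starting from the joint optimum)
#' and reports, per parameter, the largest deviation of a single-curve
#' estimate from the joint estimate, floored at the conventional values
#' 0.4 K for T*, 40 kJ/mol for E_a and 10% for enthalpies - the
#' systematic error of the calorimetric experiment dominates the random
#' error, so regression-based confidence intervals are not meaningful.
#'
#' @param problem A [fit_problem()].
#' @param result Converged [fit_model()] result.
#' @param floor_T_star,floor_E_a Absolute floors (K, kJ/mol).
#' @param floor_dH_rel Relative enthalpy floor.
#' @return Data frame `parameter`, `joint`, `spread`, `floor`,
#'   `uncertainty` (= max(spread, floor)).
#' @export
estimate_uncertainty <- function(problem, result, floor_T_star = 0.4,
                                 floor_E_a = 40, floor_dH_rel = 0.1) {
  stopifnot(inherits(result, "fit_result"))
  spread <- setNames(rep(0, length(result$par)), names(result$par))
  tpl <- par_to_model(result$par, problem$template)
  for (ob in problem$observations) {
    sub <- tryCatch({
      pr <- fit_problem(list(ob), tpl, free = problem$free,
                        lower = problem$lower, upper = problem$upper)
      fit_model(pr, n_starts = 1)
    }, error = function(e) NULL)
    if (is.null(sub)) {
      warning("single-curve refit failed for one observation; skipped")
      next
    }
    spread <- pmax(spread, abs(sub$par - result$par))
  }
  floors <- ifelse(grepl("T_star", names(spread)), floor_T_star,
                   ifelse(grepl("E_a", names(spread)), floor_E_a,
                          floor_dH_rel * abs(result$par)))
  data.frame(parameter = names(spread), joint = unname(result$par),
             spread = unname(spread), floor = unname(floors),
             uncertainty = unname(pmax(spread, floors)),
             row.names = NULL)
}

#' Build a two-domain model template from a peeling result
#'
#' Interprets three peeled apparent transitions (most thermostable
#' first) as a one-stage domain (the least stable transition) plus a
#' two-stage domain (the middle and most stable transitions as stages 1
#' and 2): the structure under which an apparent third transition is the
#' second stage of the more stable domain.
#'
#' @param peel A [peel_transitions()] result with `count >= 3`.
#' @return A [domain_model()] usable as a fit template.
#' @export
model_from_peeling <- function(peel) {
  if (peel$count < 3) stop("need at least three peeled transitions")
  tr <- peel$transitions
  domain_model(
    one_stage_domain(kinetic_params(tr$E_a[3], tr$T_star[3]), tr$dH[3]),
    two_stage_domain(kinetic_params(tr$E_a[2], tr$T_star[2]),
                     kinetic_params(tr$E_a[1], tr$T_star[1]),
                     tr$dH[2], tr$dH[1]))
}
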