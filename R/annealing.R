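# Design of annealing (pre-incubation) schedules.
#
# To isolate transition i, the hold must essentially erase transition
# i-1 (survival < 0.01) while preserving a usable amount of transition i
# (survival > 0.1), and last at least 10 minutes - shorter holds are
# dominated by the heat-up/cool-down transients.  Fixing the survival
# ratio A = x_{i-1}/x_i < 0.1 turns the feasible set into an explicit
# curve t_ann(T_ann).

#' Plan annealing conditions that isolate a target transition
#'
#' For each candidate hold temperature the hold time solving
#' \eqn{x_{i-1}/x_i = A} is \eqn{t_{ann} = |\ln A| / (k_{i-1} - k_i)},
#' which is positive only where \eqn{k_{i-1} > k_i} (transitions are
#' numbered by increasing thermostability, so the less stable one must
#' denature faster at the hold temperature).  A plan is feasible when
#' additionally \eqn{t_{ann} \le -\ln(\min x_i)/k_i} and
#' \eqn{t_{ann} \ge 10} min.
#'
#' @param model A [domain_model()].
#' @param target_index Index of the transition to preserve, in the
#'   flattened transition list ordered as in the model (must be >= 2).
#' @param A Survival ratio `x_{i-1}/x_i` (< 0.1).
#' @param T_ann_grid Candidate hold temperatures, K.
#' @param min_x_target Minimum usable survival of the target (default 0.1).
#' @param min_time Minimum hold, min (default 10).
#' @return Data frame of class `"annealing_plan"`: `T_ann`, `t_ann`,
#'   `ratio_A`, `feasible`, `x_target`, `x_below`, plus per-transition
#'   survival columns `x1 ... xn` from [isothermal_fractions()].  If no
#'   plan is feasible all rows carry `feasible = FALSE` and the closest
#'   candidate is flagged in the `"closest"` attribute.
#' @export
plan_annealing <- function(model, target_index, A = 0.05,
                           T_ann_grid = seq(305, 330, by = 0.5),
                           min_x_target = 0.1, min_time = 10) {
  if (A >= 0.1) stop("the survival ratio A must be below 0.1")
  tr <- model_transitions(model)
  if (target_index < 2 || target_index > length(tr))
    stop("target_index must be between 2 and the number of transitions")
  ki <- function(i, T_K) arrhenius_rate(tr[[i]]$kinetics, T_K)
  rows <- lapply(T_ann_grid, function(Ta) {
    k_t <- ki(target_index, Ta)
    k_b <- ki(target_index - 1, Ta)
    if (k_b <= k_t) return(NULL)
    t_ann <- abs(log(A)) / (k_b - k_t)
    x_t <- exp(-k_t * t_ann)
    x_b <- exp(-k_b * t_ann)
    feas <- t_ann >= min_time & t_ann <= -log(min_x_target) / k_t
    # per-transition survivals with full two-stage bookkeeping: stage 1
    # survives as x_N, stage 2 as x_N + x_I (native material still feeds
    # the intermediate during the subsequent scan)
    fr <- isothermal_fractions(model, Ta, t_ann)
    surv <- vapply(tr, function(x) {
      f <- fr[[x$domain]]
      if (x$stage == 1L && length(f) == 1L) f[["x"]]
      else if (x$stage == 1L) f[["x_N"]]
      else f[["x_N"]] + f[["x_I"]]
    }, 0)
    c(T_ann = Ta, t_ann = t_ann, ratio_A = A, feasible = as.numeric(feas),
      x_target = x_t, x_below = x_b,
      setNames(surv, paste0("x", seq_along(tr))))
  })
  rows <- do.call(rbind, rows)
  out <- if (is.null(rows)) {
    df <- data.frame(T_ann = numeric(), t_ann = numeric(),
                     ratio_A = numeric(), feasible = logical(),
                     x_target = numeric(), x_below = numeric())
    df
  } else {
    df <- as.data.frame(rows)
    df$feasible <- df$feasible > 0
    df
  }
  if (!any(out$feasible) && nrow(out) > 0) {
    # diagnostic: candidate whose hold time is closest to the feasible band
    miss <- pmax(min_time - out$t_ann, 0) +
      pmax(out$t_ann - (-log(min_x_target) /
                          vapply(out$T_ann, function(Ta)
                            ki(target_index, Ta), 0)), 0)
    attr(out, "closest") <- out[which.min(miss), , drop = FALSE]
  }
  class(out) <- c("annealing_plan", class(out))
  out
}

#' Resolving power of the annealing method
#'
#' Smallest parameter gap between two adjacent transitions that still
#' admits a feasible annealing schedule (survivals x_below < 0.01 and
#' x_target > 0.1, hold between `min_time` and `max_time` minutes),
#' found by bisection over the gap with a grid feasibility search over
#' (T_ann, t_ann) at each step.  Reported separately for the equal-E_a
#' case (minimum T* separation; for this case the rate-constant ratio is
#' independent of temperature) and the equal-T* case (minimum E_a
#' separation, which depends on the allowed maximum hold time).
#'
#' @param E_a_base Common activation energy, kJ/mol.
#' @param T_star_base T* of the less stable transition, K.
#' @param min_time,max_time Allowed hold times, min (defaults 10 and 60).
#' @param T_ann_range Candidate hold temperatures searched, K.
#' @return List `min_dT_star` (K, at equal E_a) and `min_dE_a` (kJ/mol,
#'   at equal T*, for the given `max_time`).
#' @export
resolving_power <- function(E_a_base, T_star_base, min_time = 10,
                            max_time = 60,
                            T_ann_range = c(280, 340)) {
  stopifnot(E_a_base > 0, T_star_base > 0)
  Ta_grid <- seq(T_ann_range[1], T_ann_range[2], by = 0.25)
  feasible <- function(p_lo, p_hi) {
    k_lo <- arrhenius_rate(p_lo, Ta_grid)  # less stable: must vanish
    k_hi <- arrhenius_rate(p_hi, Ta_grid)  # target: must survive
    # need a t in [max(min_time, 2 ln10 / k_lo), min(max_time, ln10 / k_hi)]
    t_min <- pmax(min_time, 2 * log(10) / k_lo)
    t_max <- pmin(max_time, log(10) / k_hi)
    any(t_min <= t_max)
  }
  gap_feasible_T <- function(gap)
    feasible(kinetic_params(E_a_base, T_star_base),
             kinetic_params(E_a_base, T_star_base + gap))
  # equal T*: below T* the lower-E_a transition has the larger rate
  # constant, so it is the one annealed away
  gap_feasible_E <- function(gap)
    feasible(kinetic_params(E_a_base, T_star_base),
             kinetic_params(E_a_base + gap, T_star_base))
  bisect_gap <- function(pred, hi) {
    if (!pred(hi)) return(NA_real_)
    lo <- 0
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (pred(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  list(min_dT_star = bisect_gap(gap_feasible_T, 30),
       min_dE_a = bisect_gap(gap_feasible_E, 1000))
}

#' Correct a measured enthalpy for annealing losses
#'
#' An annealed preparation deposits only the surviving fraction of the
#' domain enthalpy; the full value is restored as
#' \deqn{\Delta H = \Delta H_{trans}\,
#'   \exp[t_{ann}\exp((E_a/R)(1/T^* - 1/T_{ann}))].}
#' The correction factor is always >= 1.
#'
#' @param dH_trans Measured (annealed) transition enthalpy, kJ/mol.
#' @param p [kinetic_params()] of the transition.
#' @param T_ann Annealing temperature, K.
#' @param t_ann Annealing time, min (>= 0).
#' @return Corrected enthalpy, kJ/mol.
#' @export
correct_enthalpy <- function(dH_trans, p, T_ann, t_ann) {
  if (t_ann < 0) stop("t_ann must be non-negative")
  dH_trans * exp(t_ann * arrhenius_rate(p, T_ann))
}
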