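# Iterative estimation of the chemical (sigmoidal) baseline.
#
# The recorded heat capacity is
#   Cp(T) = CpN(T)(1 - xi(T)) + CpD(T) xi(T) + Cp_ex(T)
# where CpN/CpD are the (locally linear) native- and denatured-state heat
# capacities and xi the degree of completeness of the transition.  For a
# multi-transition curve the same single-xi form applies under the
# assumption that each transition's heat-capacity jump is proportional to
# its enthalpy contribution, with xi = sum(dH_i xi_i)/dH; no
# per-transition jump is estimated.

#' Fit the chemical baseline of a thermogram
#'
#' Four anchor temperatures `T1 < T2 < T3 < T4` delimit the pre-transition
#' linear run (`[T1,T2]`), the peak region (`[T2,T3]`) and the
#' post-transition linear run (`[T3,T4]`).  The null approximation takes
#' the pre-peak line as the native heat capacity, the post-peak line as
#' the denatured one, and a straight chord of the experimental curve
#' across the peak; the transition enthalpy and completeness curve
#' \eqn{\xi(T)} are then computed by integration and the baseline rebuilt
#' as \eqn{C_{CBL} = C_p^N(1-\xi) + C_p^D \xi}, iterating until the
#' enthalpy changes by less than `tol` relative (default 0.01%).
#'
#' @param curve A [thermogram()].
#' @param anchors Four strictly increasing temperatures inside the grid;
#'   each linear run must contain at least 3 grid points.
#' @param max_iter Iteration cap (default 100).
#' @param tol Relative enthalpy convergence tolerance (default 1e-4).
#' @return Object of class `"baseline_fit"`: `anchors`, `pre_line` /
#'   `post_line` (intercept, slope), `temperature` and `baseline` on the
#'   anchor window, `xi` (unclipped), `dH`, `iterations`, `converged`,
#'   and `dH_history`.
#' @export
fit_baseline <- function(curve, anchors, max_iter = 100, tol = 1e-4) {
  stopifnot(inherits(curve, "thermogram"))
  anchors <- sort(as.numeric(anchors))
  if (length(anchors) != 4 || any(diff(anchors) <= 0))
    stop("anchors must be four strictly increasing temperatures")
  tg <- curve$temperature
  cp <- curve$heat_capacity
  if (anchors[1] < min(tg) - 1e-9 || anchors[4] > max(tg) + 1e-9)
    stop("anchors must lie inside the temperature grid")

  seg <- function(a, b) which(tg >= a - 1e-12 & tg <= b + 1e-12)
  i_pre <- seg(anchors[1], anchors[2])
  i_post <- seg(anchors[3], anchors[4])
  if (length(i_pre) < 3 || length(i_post) < 3)
    stop("each linear run must contain at least 3 grid points")

  pre <- coef(lm(cp[i_pre] ~ tg[i_pre]))
  post <- coef(lm(cp[i_post] ~ tg[i_post]))
  win <- seg(anchors[1], anchors[4])
  tw <- tg[win]; cw <- cp[win]
  cpN <- pre[1] + pre[2] * tw
  cpD <- post[1] + post[2] * tw

  # null approximation: native line, chord over the peak, denatured line
  cbl <- cpN
  mid <- tw > anchors[2] & tw < anchors[3]
  cp2 <- approx(tg, cp, xout = anchors[2])$y
  cp3 <- approx(tg, cp, xout = anchors[3])$y
  cbl[mid] <- cp2 + (cp3 - cp2) * (tw[mid] - anchors[2]) /
    (anchors[3] - anchors[2])
  cbl[tw >= anchors[3]] <- cpD[tw >= anchors[3]]

  ex <- cw - cbl
  dH <- trapz_vec(tw, ex)
  dH_floor <- 1e-8 * max(abs(cw), 1e-12) * diff(range(tw))
  if (dH <= dH_floor)
    stop("non-positive (zero-amplitude) enthalpy at the null step; anchors likely misplaced")
  xi <- cumtrapz_vec(tw, ex) / dH
  dH_hist <- dH
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    xi_c <- pmin(pmax(xi, 0), 1)  # clipped for baseline construction only
    ex <- cw - cpN * (1 - xi_c) - cpD * xi_c
    dH_new <- trapz_vec(tw, ex)
    if (dH_new <= 0)
      stop("enthalpy became non-positive during iteration; anchors likely misplaced")
    xi <- cumtrapz_vec(tw, ex) / dH_new
    dH_hist <- c(dH_hist, dH_new)
    if (abs(dH_new - dH) < tol * abs(dH_new)) {
      converged <- TRUE
      dH <- dH_new
      break
    }
    dH <- dH_new
  }
  xi_c <- pmin(pmax(xi, 0), 1)
  structure(list(anchors = anchors,
                 pre_line = unname(pre), post_line = unname(post),
                 temperature = tw,
                 baseline = cpN * (1 - xi_c) + cpD * xi_c,
                 xi = xi, dH = dH, iterations = iter,
                 converged = converged, dH_history = dH_hist),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit: dH = %.2f kJ/mol after %d iteration(s)%s>\n",
              x$dH, x$iterations,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Baseline-corrected excess curve from a baseline fit
#'
#' Convenience wrapper: subtracts the fitted chemical baseline on the
#' anchor window.
#'
#' @param curve The [thermogram()] the fit was made on.
#' @param fit A [fit_baseline()] result.
#' @return An [excess_curve()] on `[T1, T4]`.
#' @export
apply_baseline <- function(curve, fit) {
  stopifnot(inherits(fit, "baseline_fit"))
  compute_excess(curve, fit, window = range(fit$anchors))
}

#' Suggest baseline anchors
#'
#' Heuristic: slides a window of `width` points over the curve, scores
#' each by the residual standard deviation of a local linear fit, and
#' returns the inner edges of the best near-linear runs before and after
#' the global peak together with the window's outer limits.
#'
#' @param curve A [thermogram()].
#' @param width Sliding-window width in points (default 25).
#' @return Four anchor temperatures.
#' @export
suggest_anchors <- function(curve, width = 25) {
  tg <- curve$temperature; cp <- curve$heat_capacity
  n <- length(tg)
  width <- min(width, floor(n / 4))
  peak <- which.max(cp)
  score <- function(idx) {
    f <- lm(cp[idx] ~ tg[idx])
    sd(residuals(f))
  }
  best_run <- function(from, to) {
    starts <- seq(from, max(from, to - width + 1))
    if (length(starts) == 0) return(c(from, to))
    s <- vapply(starts, function(i) score(i:(i + width - 1)), 0)
    i0 <- starts[which.min(s)]
    c(i0, i0 + width - 1)
  }
  lo <- best_run(1, max(2, peak - width))
  hi <- best_run(min(n - 1, peak + width), n - width + 1)
  c(tg[lo[1]], tg[lo[2]], tg[hi[1]], tg[hi[2]])
}
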