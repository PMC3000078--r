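# Intrinsic-fluorescence spectral analysis and enzyme-inactivation fits.
#
# The spectral parameter A = I320/I365 tracks the position/shape of the
# tryptophan emission spectrum; on the (I320, I365) phase plot, linear
# segments extrapolating through the origin are pure thermal quenching of
# a fixed structural state, while off-origin segments are transitions
# between states.  Residual-activity time courses are first-order decays
# whose rate constants can be matched against the calorimetric
# transitions.

#' Spectral parameter A and its normalisation
#'
#' \eqn{A = I_{320}/I_{365}} pointwise and
#' \eqn{A_{norm} = (A - A_{min})/(A_{max} - A_{min})}, so the normalised
#' series attains 0 and 1 at its extremes.  Both are invariant to a
#' common detector gain on the two channels.
#'
#' @param scan A [probe_trace()] of kind `"fluorescence"` (abscissa:
#'   temperature K; channels I320, I365, both positive).
#' @return List `temperature`, `A`, `A_norm`, `A_min`, `A_max`.
#' @export
compute_parameter_a <- function(scan) {
  stopifnot(inherits(scan, "probe_trace"), scan$kind == "fluorescence")
  if (any(scan$ordinate <= 0) || any(scan$ordinate2 <= 0))
    stop("both fluorescence channels must be positive")
  A <- scan$ordinate / scan$ordinate2
  if (max(A) - min(A) < 1e-12 * max(abs(A)))
    stop("A is constant; normalisation undefined")
  list(temperature = scan$abscissa, A = A,
       A_norm = (A - min(A)) / (max(A) - min(A)),
       A_min = min(A), A_max = max(A))
}

#' Parametric (phase) plot segmentation
#'
#' Segments the temperature-ordered (I320, I365) polyline into piecewise
#' linear parts by exact dynamic-programming change-point detection with
#' an orthogonal (principal-axis) residual cost, the number of segments
#' chosen by BIC.  Both channels carry noise, so ordinary regression of
#' one intensity on the other is attenuation-biased over short segments;
#' the errors-in-variables analogue of the intercept test classifies a
#' segment as "through-origin" (pure quenching of a fixed state) when
#' the perpendicular distance from the origin to the segment's principal
#' line is small against both the segment's noise and its distance from
#' the origin, and as a "transition" otherwise.
#'
#' @param scan A [probe_trace()] of kind `"fluorescence"` with at least
#'   20 points.
#' @param max_segments Upper bound on the segment count (default 6).
#' @param min_pts Minimum points per segment (default 5; candidate
#'   segments smaller than this are merged into a neighbour by
#'   construction of the search).
#' @param penalty BIC penalty multiplier per segment (default 3).
#' @param origin_tol Relative through-origin tolerance: the origin
#'   distance as a fraction of the segment's mean radial distance
#'   (default 0.06).
#' @return Data frame, one row per segment: `T_lo`, `T_hi`, `n`,
#'   `origin_distance` (perpendicular distance of the fitted line from
#'   the origin), `perp_sd` (orthogonal residual SD), `through_origin`.
#' @export
parametric_plot <- function(scan, max_segments = 6, min_pts = 5,
                            penalty = 3, origin_tol = 0.06) {
  stopifnot(inherits(scan, "probe_trace"), scan$kind == "fluorescence")
  x <- scan$ordinate; y <- scan$ordinate2; tg <- scan$abscissa
  n <- length(x)
  if (n < 20) stop("need at least 20 scan points")
  kmax <- min(max_segments, floor(n / min_pts))
  if (kmax < max_segments)
    warning("too few points for ", max_segments,
            " segments; capped at ", kmax)

  # orthogonal RSS of the principal line through points i..j: the
  # smaller eigenvalue of the scatter matrix, O(1) from prefix sums
  cs <- function(v) c(0, cumsum(v))
  Sx <- cs(x); Sy <- cs(y); Sxx <- cs(x^2); Syy <- cs(y^2); Sxy <- cs(x * y)
  seg_cost <- function(i, j) {
    m <- j - i + 1
    sx <- Sx[j + 1] - Sx[i]; sy <- Sy[j + 1] - Sy[i]
    cxx <- Sxx[j + 1] - Sxx[i] - sx^2 / m
    cyy <- Syy[j + 1] - Syy[i] - sy^2 / m
    cxy <- Sxy[j + 1] - Sxy[i] - sx * sy / m
    tr <- cxx + cyy
    max((tr - sqrt(max(tr^2 - 4 * (cxx * cyy - cxy^2), 0))) / 2, 0)
  }
  INF <- Inf
  D <- matrix(INF, kmax, n)      # D[k, j]: best cost of first j pts, k segs
  B <- matrix(NA_integer_, kmax, n)
  for (j in min_pts:n) D[1, j] <- seg_cost(1, j)
  if (kmax > 1) for (k in 2:kmax) for (j in seq(k * min_pts, n)) {
    i_opts <- seq((k - 1) * min_pts, j - min_pts)
    vals <- D[k - 1, i_opts] + vapply(i_opts, function(i)
      seg_cost(i + 1, j), 0)
    b <- which.min(vals)
    D[k, j] <- vals[b]
    B[k, j] <- i_opts[b]
  }
  scale2 <- mean(x^2 + y^2)
  bic <- vapply(seq_len(kmax), function(k)
    n * log(D[k, n] / n + 1e-9 * scale2) + penalty * k * log(n), 0)
  kbest <- which.min(bic)
  bounds <- n
  k <- kbest
  j <- n
  while (k > 1) {
    j <- B[k, j]
    bounds <- c(j, bounds)
    k <- k - 1
  }
  starts <- c(1, head(bounds, -1) + 1)
  ends <- bounds
  out <- lapply(seq_along(starts), function(s) {
    idx <- starts[s]:ends[s]
    m <- length(idx)
    mx <- mean(x[idx]); my <- mean(y[idx])
    cxx <- var(x[idx]); cyy <- var(y[idx]); cxy <- cov(x[idx], y[idx])
    theta <- 0.5 * atan2(2 * cxy, cxx - cyy)  # principal direction
    d0 <- abs(-mx * sin(theta) + my * cos(theta))
    perp_sd <- sqrt(seg_cost(starts[s], ends[s]) / max(m - 2, 1))
    rad <- mean(sqrt(x[idx]^2 + y[idx]^2))
    data.frame(T_lo = tg[starts[s]], T_hi = tg[ends[s]], n = m,
               origin_distance = d0, perp_sd = perp_sd,
               through_origin = d0 <= max(origin_tol * rad, 3 * perp_sd),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Fit first-order inactivation time courses
#'
#' Per-trace mono-exponential decay fit, `activity(t) = a exp(-k t)`
#' with the amplitude `a` fixed at 1 by default (activities are
#' pre-normalised) or free; `k >= 0` is enforced, with a boundary flag
#' for non-decaying traces.
#'
#' @param traces List of [probe_trace()] objects of kind `"activity"`
#'   (each >= 4 points) with their incubation temperatures set.
#' @param free_amplitude Fit the amplitude too (default FALSE).
#' @param conf Confidence level for the rate CI (default 0.95).
#' @return Object of class `"inactivation_series"`: data frame `rates`
#'   (`temperature`, `k`, `ci_lo`, `ci_hi`, `residual_sd`,
#'   `at_boundary`), list `residuals`.
#' @export
fit_inactivation <- function(traces, free_amplitude = FALSE, conf = 0.95) {
  rows <- list()
  resids <- list()
  for (tr in traces) {
    stopifnot(inherits(tr, "probe_trace"), tr$kind == "activity")
    t <- tr$abscissa; a <- tr$ordinate
    if (length(t) < 4) stop("each trace needs at least 4 points")
    p0 <- c(k = max(-coef(lm(log(pmax(a, 1e-6)) ~ t))[2], 1e-6),
            if (free_amplitude) c(amp = 1))
    fn <- function(p) a - (if (free_amplitude) p[2] else 1) * exp(-p[1] * t)
    fit <- minpack.lm::nls.lm(par = unname(p0), fn = fn,
                              lower = c(0, if (free_amplitude) 0),
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200))
    k <- fit$par[1]
    dof <- max(length(t) - length(fit$par), 1)
    sig2 <- sum(fit$fvec^2) / dof
    se <- tryCatch(sqrt(diag(sig2 * solve(fit$hessian)))[1],
                   error = function(e) NA_real_)
    tq <- qt(1 - (1 - conf) / 2, dof)
    rows[[length(rows) + 1]] <- data.frame(
      temperature = tr$temperature, k = k,
      ci_lo = max(k - tq * se, 0), ci_hi = k + tq * se,
      residual_sd = sqrt(sig2), at_boundary = k <= 1e-10)
    resids[[length(resids) + 1]] <- fit$fvec
  }
  structure(list(rates = do.call(rbind, rows), residuals = resids),
            class = "inactivation_series")
}

#' Overlay probe results on the calorimetric model
#'
#' For an inactivation series: per temperature, the ratio of the
#' measured inactivation rate to the Arrhenius rate of every transition
#' in the model - the transition with log-ratio near 0 is the one probed.
#' For a fluorescence scan: whether the 5-95% rise window of A_norm sits
#' inside the union of the conversion windows of the transitions of the
#' most thermostable (two-stage) domain, with its midpoint beyond the
#' completion of the least stable transition.
#'
#' @param series An `inactivation_series` or a fluorescence
#'   [probe_trace()].
#' @param model A [domain_model()].
#' @param nu Heating rate for conversion curves, K/min (fluorescence).
#' @return For inactivation: data frame `temperature`, `transition`,
#'   `k_measured`, `k_transition`, `log_ratio` (empty for an empty
#'   series).  For fluorescence: list `rise_window_K`, `rise_mid_K`,
#'   `window_23_K`, `transition1_end_K`, `contained`.
#' @export
overlay_with_dsc <- function(series, model, nu = 1) {
  tr <- model_transitions(model)
  if (inherits(series, "inactivation_series")) {
    if (is.null(series$rates) || nrow(series$rates) == 0)
      return(data.frame(temperature = numeric(), transition = integer(),
                        k_measured = numeric(), k_transition = numeric(),
                        log_ratio = numeric()))
    do.call(rbind, lapply(seq_len(nrow(series$rates)), function(i) {
      Tv <- series$rates$temperature[i]
      km <- series$rates$k[i]
      data.frame(temperature = Tv, transition = seq_along(tr),
                 k_measured = km,
                 k_transition = vapply(tr, function(x)
                   arrhenius_rate(x$kinetics, Tv), 0),
                 log_ratio = vapply(tr, function(x)
                   log(km / arrhenius_rate(x$kinetics, Tv)), 0))
    }))
  } else if (inherits(series, "probe_trace") &&
             series$kind == "fluorescence") {
    pa <- compute_parameter_a(series)
    tg <- pa$temperature
    # light smoothing so channel noise cannot fake an early crossing
    smooth5 <- function(y) {
      f <- stats::filter(y, rep(1 / 5, 5), sides = 2)
      ifelse(is.na(f), y, as.numeric(f))
    }
    cross <- function(y, lev) {
      i <- which(y >= lev)[1]
      if (is.na(i)) return(NA_real_)
      if (i == 1) return(tg[1])
      approx(y[(i - 1):i], tg[(i - 1):i], xout = lev)$y
    }
    # renormalise against plateau medians so that noise extremes do not
    # compress the working range of the thresholds
    as_ <- smooth5(pa$A)
    n_pl <- max(5, round(length(as_) / 10))
    lo <- median(head(as_, n_pl)); hi <- median(tail(as_, n_pl))
    an <- (as_ - lo) / (hi - lo)
    rise_mid <- cross(an, 0.5)
    # anchor the 5% and 95% crossings at the midpoint: the last time the
    # curve sits below 5% before the midpoint, the first time it exceeds
    # 95% after it
    i_mid <- which(tg >= rise_mid)[1]
    below <- which(an[seq_len(i_mid)] <= 0.05)
    t05 <- if (length(below)) {
      i <- max(below)
      approx(an[i:(i + 1)], tg[i:(i + 1)], xout = 0.05, ties = "ordered")$y
    } else NA_real_
    after <- which(an >= 0.95 & seq_along(an) >= i_mid)
    t95 <- if (length(after)) {
      i <- min(after)
      if (i == 1) tg[1]
      else approx(an[(i - 1):i], tg[(i - 1):i], xout = 0.95,
                  ties = "ordered")$y
    } else NA_real_
    rise <- c(t05, t95)
    conv <- transition_conversions(model, tg, nu)
    win <- lapply(conv, function(cc) c(cross(cc, 0.05), cross(cc, 0.95)))
    # transitions of the two-stage domain: the last two in model order
    n <- length(win)
    w23 <- c(min(win[[n - 1]][1], win[[n]][1]),
             max(win[[n - 1]][2], win[[n]][2]))
    t1_end <- win[[1]][2]
    contained <- !anyNA(rise) && rise[1] >= w23[1] - 1 &&
      rise[2] <= w23[2] + 1 && rise_mid > t1_end
    list(rise_window_K = rise, rise_mid_K = rise_mid, window_23_K = w23,
         transition1_end_K = t1_end, contained = contained)
  } else stop("unsupported series type")
}
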