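# Seeded synthetic-data generation with ground truth.
#
# Every generator emulates the study conditions of the reference
# experiment: constant-rate scans at 1 K/min of a protein with one
# one-stage domain plus one two-stage domain, isothermal DLS growth
# traces at 39-47 degC, a fluorescence scan tracking the two-stage
# domain's conversion, and first-order inactivation time courses.  Each
# dataset ships a machine-readable truth record, and generation is
# bit-reproducible under a fixed seed.

#' Reference two-domain model (high ionic strength fit)
#'
#' The default simulation model: a one-stage domain (E_a = 290 kJ/mol,
#' T* = 317.5 K, dH = 200 kJ/mol) plus a two-stage domain (stage 1:
#' 400 kJ/mol, 321.2 K, 1030 kJ/mol; stage 2: 340 kJ/mol, 324.5 K,
#' 500 kJ/mol), the fitted parameter set for the A1 isoform of the
#' myosin head at 100 mM KCl.
#'
#' @return A [domain_model()].
#' @export
s1_reference_model <- function() {
  domain_model(
    one_stage_domain(kinetic_params(290, 317.5), 200),
    two_stage_domain(kinetic_params(400, 321.2),
                     kinetic_params(340, 324.5), 1030, 500))
}

#' Default annealing schedule used by the thermogram generator
#'
#' Two training conditions (319.15 K / 15 min and 315.15 K / 20 min)
#' plus a holdout condition (317.15 K / 17 min) reserved for
#' out-of-sample validation.
#'
#' @return Named list of `c(T_ann, t_ann)` vectors.
#' @export
default_annealing_schedule <- function() {
  list(ann1 = c(T_ann = 319.15, t_ann = 15),
       ann2 = c(T_ann = 315.15, t_ann = 20),
       holdout = c(T_ann = 317.15, t_ann = 17))
}

#' Generate a native + annealed thermogram set with ground truth
#'
#' Simulates the excess signal of `model` for the native preparation and
#' each annealing condition, adds a sigmoidal chemical baseline (native
#' and denatured heat-capacity lines whose jump is apportioned across
#' transitions in proportion to enthalpy, i.e. a single completeness
#' curve) and additive Gaussian noise, and returns full thermograms plus
#' the truth record.
#'
#' @param model A [domain_model()] (default [s1_reference_model()]).
#' @param nu Heating rate, K/min.
#' @param grid Temperature grid, K (default [default_grid()]).
#' @param schedule Named list of annealing conditions
#'   (default [default_annealing_schedule()]); the native scan is always
#'   included as `native`.
#' @param baseline List `intercept`, `slope` of the native heat-capacity
#'   line (kJ/(mol K) at 0 K, and per K) and `dCp` - the total
#'   heat-capacity jump; `dCp = NULL` defaults to 0.1 x the native peak
#'   height.  `NULL` for no baseline.
#' @param noise_sd Additive Gaussian noise SD as a fraction of the
#'   native peak height (default 0.01; 0 for noiseless sets).
#' @param seed Integer seed (default 1).
#' @return List `curves` (named list of [thermogram()]s), `truth`
#'   (model, schedule, baseline, noise_sd, seed, and per-condition
#'   surviving fractions).
#' @export
make_thermogram_set <- function(model = s1_reference_model(), nu = 1,
                                grid = default_grid(),
                                schedule = default_annealing_schedule(),
                                baseline = list(intercept = 20,
                                                slope = 0.05, dCp = NULL),
                                noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  native <- simulate_model(model, grid, nu)
  peak <- max(native$excess)
  if (!is.null(baseline) && is.null(baseline$dCp))
    baseline$dCp <- 0.1 * peak
  conditions <- c(list(native = NULL), schedule)
  curves <- list()
  fractions <- list()
  for (nm in names(conditions)) {
    ann <- conditions[[nm]]
    m <- if (is.null(ann)) model
    else anneal_model(model, ann[["T_ann"]], ann[["t_ann"]])
    ex <- simulate_annealed_model(m, grid, nu)
    cp <- ex$excess
    if (!is.null(baseline)) {
      # single-xi sigmoidal baseline: the jump follows the cumulative
      # fraction of the total enthalpy absorbed
      xi <- if (ex$enthalpy > 0) ex$cumulative / ex$enthalpy else 0
      cpN <- baseline$intercept + baseline$slope * grid
      cp <- cp + cpN + baseline$dCp * xi
    }
    if (noise_sd > 0) cp <- cp + rnorm(length(cp), 0, noise_sd * peak)
    curves[[nm]] <- thermogram(grid, cp, heating_rate = nu,
                               annealing = ann, label = nm)
    fractions[[nm]] <- if (is.null(ann)) NULL
    else isothermal_fractions(model, ann[["T_ann"]], ann[["t_ann"]])
  }
  list(curves = curves,
       truth = list(model = model, nu = nu, schedule = schedule,
                    baseline = baseline, noise_sd = noise_sd, seed = seed,
                    fractions = fractions))
}

#' Generate isothermal and scan DLS growth traces with ground truth
#'
#' Isothermal traces follow exponential radius growth after a lag, with
#' the doubling time set by an Arrhenius law for the growth rate
#' (k_agg = ln2 / t_2R); lags vary per trace (they are irreproducible in
#' the real experiment), and several "concentrations" at the reference
#' temperature differ only in lag.  A constant-rate scan trace grows the
#' radius according to the conversion of the rate-limiting first stage
#' of the most thermostable domain, onset-delayed by `scan_delay_K` to
#' emulate nucleation.
#'
#' @param growth_law [kinetic_params()] of the growth process (default
#'   E_a = 430 kJ/mol, T* = 320.8 K).
#' @param temperatures Isothermal hold temperatures, K (default
#'   39-47 degC in 2 K steps).
#' @param R_h0 Start-aggregate radius, nm (default 20).
#' @param lag_range Range the lags are drawn from, min (default 2-8).
#' @param n_conc Number of same-temperature traces differing only in lag
#'   (default 3, at `conc_temperature`).
#' @param conc_temperature Hold temperature of the concentration series,
#'   K (default 317.15, i.e. 44 degC).
#' @param noise_sd Multiplicative log-normal noise SD (default 0.02;
#'   0 for noiseless).
#' @param dt Sampling interval, min.
#' @param seed Integer seed.
#' @return List `isothermal` (list of [probe_trace()]), `concentration`
#'   (same-temperature traces), `scan` (temperature-scan trace), `truth`.
#' @export
make_dls_set <- function(growth_law = kinetic_params(430, 320.8),
                         temperatures = 273.15 + seq(39, 47, by = 2),
                         R_h0 = 20, lag_range = c(2, 8), n_conc = 3,
                         conc_temperature = 317.15,
                         noise_sd = 0.02, dt = 0.25, seed = 1,
                         scan_delay_K = 3, model = s1_reference_model()) {
  set.seed(seed)
  t2R <- log(2) / arrhenius_rate(growth_law, temperatures)
  make_trace <- function(Tv, t2, lag, label) {
    t_end <- lag + 4 * t2
    tt <- seq(0, t_end, by = min(dt, t2 / 10))
    r <- R_h0 * exp(log(2) / t2 * pmax(tt - lag, 0))
    if (noise_sd > 0) r <- r * exp(rnorm(length(r), 0, noise_sd))
    probe_trace(tt, r, kind = "dls", temperature = Tv, label = label)
  }
  lags <- runif(length(temperatures), lag_range[1], lag_range[2])
  iso <- lapply(seq_along(temperatures), function(i)
    make_trace(temperatures[i], t2R[i], lags[i],
               sprintf("iso_%.0fK", temperatures[i])))
  Tc <- conc_temperature
  t2c <- log(2) / arrhenius_rate(growth_law, Tc)
  conc <- lapply(seq_len(n_conc), function(j)
    make_trace(Tc, t2c, runif(1, lag_range[1], lag_range[2]),
               sprintf("conc%d", j)))
  # temperature-scan trace: radius tracks the shifted conversion of the
  # rate-limiting stage (stage 1 of the most stable domain)
  grid <- default_grid()
  conv <- transition_conversions(model, grid)
  lim <- conv[[length(conv) - 1]]
  conv_shift <- approx(grid + scan_delay_K, lim, xout = grid, rule = 2)$y
  # exponential radius growth pinned so that the 100 nm onset threshold
  # is crossed exactly at the shifted conversion midpoint
  onset_radius <- 100
  r_scan <- R_h0 * exp(2 * log(onset_radius / R_h0) * conv_shift)
  if (noise_sd > 0)
    r_scan <- r_scan * exp(rnorm(length(r_scan), 0, noise_sd))
  scan <- probe_trace(grid, r_scan, kind = "dls", label = "scan")
  list(isothermal = iso, concentration = conc, scan = scan,
       truth = list(growth_law = growth_law, temperatures = temperatures,
                    t_2R = t2R, lags = lags, R_h0 = R_h0,
                    scan_delay_K = scan_delay_K, noise_sd = noise_sd,
                    seed = seed))
}

#' Generate a fluorescence scan and inactivation traces with truth
#'
#' The spectral parameter A tracks the mean conversion of the two stages
#' of the most thermostable domain between the native and denatured
#' plateaus (defaults 1.06 and 1.32); the two intensity channels are
#' built from per-state emission ratios under a common linear thermal
#' quench, so state segments of the phase plot extrapolate through the
#' origin.  Inactivation rate constants follow the Arrhenius law of the
#' rate-limiting stage (stage 1 of the most stable domain).
#'
#' @param model A [domain_model()].
#' @param nu Heating rate, K/min.
#' @param grid Temperature grid for the scan, K (default 1 K steps over
#'   the usual span).
#' @param A_plateaus `c(A_native, A_denatured)` (default `c(1.06, 1.32)`).
#' @param quench Linear quench coefficient per K (default 0.01).
#' @param inactivation_temperatures Hold temperatures, K.
#' @param inactivation_noise Additive activity noise SD (default 0.02).
#' @param fluor_noise Relative channel noise SD (default 0).
#' @param seed Integer seed.
#' @return List `fluorescence` ([probe_trace()]), `inactivation` (list
#'   of [probe_trace()]), `truth`.
#' @export
make_probe_set <- function(model = s1_reference_model(), nu = 1,
                           grid = seq(288.15, 343.15, by = 0.5),
                           A_plateaus = c(1.06, 1.32), quench = 0.01,
                           inactivation_temperatures =
                             273.15 + seq(39, 47, by = 2),
                           inactivation_noise = 0.02, fluor_noise = 0,
                           seed = 1) {
  set.seed(seed)
  conv <- transition_conversions(model, grid, nu)
  n <- length(conv)
  f <- (conv[[n - 1]] + conv[[n]]) / 2  # mean conversion of the 2 stages
  A <- A_plateaus[1] + (A_plateaus[2] - A_plateaus[1]) * f
  q <- 1 - quench * (grid - grid[1])
  I_total <- 100 * q
  I365 <- I_total / (1 + A)
  I320 <- A * I365
  if (fluor_noise > 0) {
    I320 <- I320 * exp(rnorm(length(I320), 0, fluor_noise))
    I365 <- I365 * exp(rnorm(length(I365), 0, fluor_noise))
  }
  fluor <- probe_trace(grid, I320, I365, kind = "fluorescence",
                       label = "A-scan")
  # rate-limiting stage of the most stable domain
  tr <- model_transitions(model)
  law <- tr[[length(tr) - 1]]$kinetics
  inact <- lapply(inactivation_temperatures, function(Tv) {
    k <- arrhenius_rate(law, Tv)
    tt <- seq(0, 2.5 * log(2) / k, length.out = 12)
    a <- exp(-k * tt)
    if (inactivation_noise > 0)
      a <- pmax(a + rnorm(length(a), 0, inactivation_noise), 1e-4)
    probe_trace(tt, a, kind = "activity", temperature = Tv,
                label = sprintf("inact_%.0fK", Tv))
  })
  list(fluorescence = fluor, inactivation = inact,
       truth = list(model = model, A_plateaus = A_plateaus,
                    quench = quench, inactivation_law = law,
                    inactivation_temperatures = inactivation_temperatures,
                    noise = c(inactivation = inactivation_noise,
                              fluorescence = fluor_noise),
                    seed = seed))
}
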