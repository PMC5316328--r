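#' Scenario configuration for synthetic monitoring data
#'
#' Describes a data-generating scenario: the true model and parameters, the
#' DAYS climatology, the harvest actually taken each year, observation error
#' and any survey undercount (e.g. flocks missed after a range shift, entering
#' as a year-specific downward bias of unknown size).
#'
#' @param truth_spec True [model_spec()].
#' @param truth_params True [parameter_set()] (its `process_sd` and `obs_cv`
#'   are used for simulation).
#' @param clim An [climatology()].
#' @param n_years Number of monitored years (>= 1).
#' @param initial_N Starting spring abundance, thousands.
#' @param harvest Annual harvest in thousands; scalar or vector recycled to
#'   `n_years`.
#' @param first_year Calendar year of the first record (default 2013).
#' @param undercount_years Named numeric vector mapping calendar year to an
#'   undercount fraction in `[0, 1)`; observed counts in those years are
#'   multiplied by `1 - fraction`.
#' @param shares Country shares used to split the realized harvest.
#' @param seed Integer seed.
#' @return An object of class `ahm_scenario`.
#' @export
scenario_config <- function(truth_spec, truth_params, clim = climatology(),
                            n_years = 20L, initial_N = 81.6, harvest = 0,
                            first_year = 2013L,
                            undercount_years = numeric(0),
                            shares = c(Norway = 0.3, Denmark = 0.7),
                            seed = 1L) {
  stopifnot(n_years >= 1L, initial_N >= 0, all(harvest >= 0),
            all(undercount_years >= 0), all(undercount_years < 1))
  structure(
    list(truth_spec = truth_spec, truth_params = truth_params, clim = clim,
         n_years = as.integer(n_years), initial_N = initial_N,
         harvest = rep_len(harvest, n_years), first_year = as.integer(first_year),
         undercount_years = undercount_years, shares = shares,
         seed = as.integer(seed)),
    class = "ahm_scenario"
  )
}

#' Generate a DAYS series from a climatology
#'
#' @param n_years Number of years (>= 1).
#' @param clim An [climatology()].
#' @param seed Integer seed.
#' @return Integer vector of non-negative DAYS values.
#' @export
generate_days_series <- function(n_years, clim = climatology(), seed = NULL) {
  stopifnot(n_years >= 1L)
  if (!is.null(seed)) set.seed(seed)
  draw_days(n_years, clim)
}

#' Generate a synthetic monitoring series
#'
#' Simulates the true population under the scenario's truth model and emits
#' the monitoring streams the assessment consumes: spring and autumn counts
#' with multiplicative lognormal observation error (log-SD `obs_cv`) and any
#' configured undercount, the proportion of young implied by the realized
#' reproduction rate, the DAYS covariate, and the realized harvest split
#' between countries. The autumn count is taken post-breeding, before harvest.
#'
#' @param scenario An [scenario_config()].
#' @return Data frame of monitoring records (one row per year) with
#'   attributes `true_N` (true spring abundance, thousands) and `true_r`
#'   (realized young per adult).
#' @export
generate_monitoring_series <- function(scenario) {
  stopifnot(inherits(scenario, "ahm_scenario"))
  set.seed(scenario$seed)
  p <- scenario$truth_params
  sp <- scenario$truth_spec
  clim <- scenario$clim
  n <- scenario$n_years
  years <- scenario$first_year + seq_len(n) - 1L
  days <- draw_days(n, clim)
  z <- days_z(days, clim)
  true_N <- numeric(n)
  true_r <- numeric(n)
  rows <- vector("list", n)
  N <- scenario$initial_N
  for (t in seq_len(n)) {
    true_N[t] <- N
    r <- reproduction_rate(N, z[t], p, sp)
    true_r[t] <- r
    post <- N * (1 + r)
    h <- min(scenario$harvest[t], post)
    uc <- scenario$undercount_years[as.character(years[t])]
    uc <- if (length(uc) == 1 && !is.na(uc)) uc else 0
    noise <- function() {
      if (p$obs_cv > 0) stats::rlnorm(1L, meanlog = 0, sdlog = p$obs_cv) else 1
    }
    spring_obs <- N * noise() * (1 - uc)
    autumn_obs <- post * noise() * (1 - uc)
    alloc <- allocate_quota(round(h * 1000), scenario$shares, rounding = 1)
    rows[[t]] <- monitoring_record(
      year = years[t], spring_count = spring_obs * 1000,
      autumn_count = autumn_obs * 1000, prop_young = r / (1 + r),
      harvest_norway = alloc[["Norway"]], harvest_denmark = alloc[["Denmark"]],
      days = days[t]
    )
    N <- transition(N, scenario$harvest[t], z[t], p, sp, stochastic = TRUE)
  }
  out <- do.call(rbind, rows)
  attr(out, "true_N") <- true_N
  attr(out, "true_r") <- true_r
  out
}

#' Deterministic first-crossing time of the target under constant harvest
#'
#' Iterates the deterministic null-dynamics transition (no DAYS or density
#' terms active) and returns the linearly interpolated first time the
#' trajectory reaches the target abundance, or `Inf` if it never does.
#'
#' @param params An [parameter_set()].
#' @param initial_N Starting abundance, thousands.
#' @param harvest Constant annual harvest, thousands.
#' @param target Target abundance, thousands (default 60).
#' @param max_years Iteration cap (default 200).
#' @return Crossing time in years (possibly fractional), or `Inf`.
#' @export
deterministic_crossing_time <- function(params, initial_N, harvest,
                                        target = 60, max_years = 200L) {
  null_spec <- model_spec("NULL", "NULL", 1L)
  N <- initial_N
  if (N <= target) return(0)
  for (t in seq_len(max_years)) {
    N_next <- transition(N, harvest, 0, params, null_spec)
    if (N_next <= target) {
      return((t - 1) + (N - target) / (N - N_next))
    }
    if (N_next >= N) return(Inf)   # non-declining: will never cross
    N <- N_next
  }
  Inf
}

#' Calibrate the default demographic parameters
#'
#' Anchors the package's default parameter set to the management programme's
#' published trajectory facts: starting from the 2013 peak spring abundance
#' (81.6 thousand) under the reference harvest (11.3 thousand/yr, the 2011-2013
#' average), the deterministic null-dynamics trajectory first reaches the
#' 60-thousand target after `crossing_target_years` years. Given a default
#' natural survival `s_bar`, a one-dimensional root find returns the
#' reproduction intercept `gamma0` that produces that crossing time. The
#' remaining coefficients (DAYS and density effects, process and observation
#' error) are documented package defaults with moderate effect sizes.
#'
#' @param s_bar Default annual natural survival in (0, 1) (default 0.95).
#' @param initial_N Anchor abundance, thousands (default 81.6).
#' @param H_ref Reference harvest, thousands/yr (default 11.3).
#' @param crossing_target_years Calibrated first-crossing time, years
#'   (default 8.5, the midpoint of the published 8-9 year projection).
#' @param target Target abundance, thousands (default 60).
#' @param alpha1,alpha2,gamma1,gamma2,K,process_sd,obs_cv Remaining defaults
#'   of the returned [parameter_set()].
#' @return A calibrated [parameter_set()].
#' @examples
#' p <- calibrate_defaults()
#' exp(p$gamma0)  # calibrated young per adult, roughly 0.17
#' @export
calibrate_defaults <- function(s_bar = 0.95, initial_N = 81.6, H_ref = 11.3,
                               crossing_target_years = 8.5, target = 60,
                               alpha1 = 0.15, alpha2 = 0.25,
                               gamma1 = 0.2, gamma2 = 0.3, K = 60,
                               process_sd = 0.05, obs_cv = 0.05) {
  stopifnot(s_bar > 0, s_bar < 1)
  alpha0 <- stats::qlogis(s_bar)
  make <- function(gamma0) {
    parameter_set(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                  gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2,
                  K = K, process_sd = process_sd, obs_cv = obs_cv)
  }
  f <- function(gamma0) {
    ct <- deterministic_crossing_time(make(gamma0), initial_N, H_ref, target)
    min(ct, 1e6) - crossing_target_years
  }
  lo <- log(1e-3); hi <- log(1 - 1e-6)
  if (f(lo) > 0 || f(hi) < 0) {
    stop("no reproduction intercept in (0, 1) young per adult matches the calibration anchor")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
  make(root$root)
}

#' Headline reference values of the management programme
#'
#' Key published numbers of the international adaptive harvest management
#' programme for the Svalbard pink-footed goose (all abundances and harvests
#' in thousands of individuals; shares as fractions): the 2013 spring peak,
#' the 2015 spring and autumn counts, the record 2014/15 harvest, the
#' reference harvest (2011-2013 average), the reduced 2015/16 one-year quota,
#' the 15-thousand optimum set for 2013-2015, the population target and
#' acceptance band, and the Norway/Denmark allocation shares.
#'
#' @return Named numeric vector.
#' @export
reference_values <- function() {
  c(spring_2013 = 81.6, spring_2015_count = 59.0, autumn_2015_count = 74.8,
    harvest_2014 = 14.8, harvest_ref = 11.3, quota_2015 = 6.7,
    optimum_2013_15 = 15.0, target = 60.0, band_low = 50.0, band_high = 70.0,
    share_norway = 0.3, share_denmark = 0.7)
}

#' The 2015 "stumble" scenario
#'
#' A named synthetic fixture reproducing the shape of the 2013-2016 narrative:
#' starting at the 2013 peak, harvests near the published realizations, and a
#' one-year survey undercount (default fraction 0.16, illustrative of the
#' missed flocks after the range shift into mid-Norway, Sweden and Finland)
#' in spring 2015. Running the assessment over this series exercises the
#' emergency-closure and re-opening logic end to end.
#'
#' @param params Truth [parameter_set()] (default [calibrate_defaults()]).
#' @param undercount Undercount fraction applied in 2015 (default 0.16).
#' @param seed Integer seed (default 42).
#' @return An [scenario_config()] spanning 2013-2016 under null-dynamics truth.
#' @export
stumble_scenario <- function(params = calibrate_defaults(),
                             undercount = 0.16, seed = 42L) {
  scenario_config(
    truth_spec = model_spec("NULL", "NULL", 1L),
    truth_params = params,
    n_years = 4L, initial_N = 81.6,
    harvest = c(11.3, 14.8, 6.7, 4.0),
    first_year = 2013L,
    undercount_years = c("2015" = undercount),
    seed = seed
  )
}
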