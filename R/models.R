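#' Structural forms available for the survival and reproduction processes
#'
#' Each demographic process (annual natural survival, per-adult reproduction)
#' can be constant (`"NULL"`), driven by spring temperature (`"DAYS"`, the
#' number of days above freezing in May in Svalbard), or driven by spring
#' temperature plus density dependence (`"DAYS_DENSITY"`).
#'
#' @format Character vector of length 3.
#' @export
ahm_forms <- c("NULL", "DAYS", "DAYS_DENSITY")

#' Create a single population-model specification
#'
#' A model specification pairs a structural form for survival with one for
#' reproduction. The nine-model set used throughout the package is the full
#' 3 x 3 factorial of [ahm_forms] over the two processes.
#'
#' @param survival_form One of `"NULL"`, `"DAYS"`, `"DAYS_DENSITY"`.
#' @param reproduction_form One of `"NULL"`, `"DAYS"`, `"DAYS_DENSITY"`.
#' @param id Integer model id in 1..9.
#' @return An object of class `ahm_model_spec`.
#' @seealso [enumerate_models()]
#' @export
model_spec <- function(survival_form, reproduction_form, id) {
  survival_form <- match.arg(survival_form, ahm_forms)
  reproduction_form <- match.arg(reproduction_form, ahm_forms)
  id <- as.integer(id)
  stopifnot(length(id) == 1L, id >= 1L, id <= 9L)
  structure(
    list(id = id, survival_form = survival_form,
         reproduction_form = reproduction_form),
    class = "ahm_model_spec"
  )
}

#' @exportS3Method base::print
print.ahm_model_spec <- function(x, ...) {
  cat(sprintf("<model %d> survival: %s | reproduction: %s\n",
              x$id, x$survival_form, x$reproduction_form))
  invisible(x)
}

#' Enumerate the nine-model set
#'
#' Returns the full 3 x 3 factorial set of structural hypotheses about
#' pink-footed goose dynamics: whether spring temperature (DAYS) and density
#' dependence act on survival and/or reproduction. Models are ordered
#' deterministically by id, with the survival form varying slowest.
#'
#' @return A list of 9 [model_spec()] objects, ordered by `id`.
#' @examples
#' specs <- enumerate_models()
#' length(specs)  # 9
#' @export
enumerate_models <- function() {
  out <- vector("list", 9L)
  k <- 0L
  for (sf in ahm_forms) {
    for (rf in ahm_forms) {
      k <- k + 1L
      out[[k]] <- model_spec(sf, rf, k)
    }
  }
  out
}

#' Demographic parameter set shared across the model set
#'
#' Coefficients parameterize survival on the logit scale and reproduction on
#' the log scale. Covariate terms are switched on or off by the structural
#' form of each [model_spec()]; the parameter values themselves are common to
#' all nine models, so the models differ only in which terms they include.
#'
#' @param alpha0 Survival intercept (logit scale).
#' @param alpha1 Survival coefficient per standardized DAYS unit.
#' @param alpha2 Survival density coefficient (per unit N/K), must be >= 0.
#' @param gamma0 Reproduction intercept (log scale; exp(gamma0) is young per
#'   adult at average spring conditions without density feedback).
#' @param gamma1 Reproduction coefficient per standardized DAYS unit.
#' @param gamma2 Reproduction density coefficient (>= 0).
#' @param K Density scaling abundance, thousands.
#' @param process_sd Lognormal process-error SD on the log scale.
#' @param obs_cv Observation CV of population counts.
#' @return An object of class `ahm_params`.
#' @seealso [calibrate_defaults()] for the packaged default values.
#' @export
parameter_set <- function(alpha0, alpha1 = 0, alpha2 = 0,
                          gamma0, gamma1 = 0, gamma2 = 0,
                          K = 60, process_sd = 0, obs_cv = 0.05) {
  stopifnot(alpha2 >= 0, gamma2 >= 0, K > 0, process_sd >= 0, obs_cv >= 0)
  s0 <- stats::plogis(alpha0)
  stopifnot(s0 > 0, s0 < 1)
  structure(
    list(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
         gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2,
         K = K, process_sd = process_sd, obs_cv = obs_cv),
    class = "ahm_params"
  )
}

#' @exportS3Method base::print
print.ahm_params <- function(x, ...) {
  cat("<ahm_params>\n")
  cat(sprintf("  survival:      logit(s) = %.4f %+.3f*z %+.3f*(N/K)\n",
              x$alpha0, x$alpha1, -x$alpha2))
  cat(sprintf("  reproduction:  log(r)   = %.4f %+.3f*z %+.3f*(N/K)\n",
              x$gamma0, x$gamma1, -x$gamma2))
  cat(sprintf("  K = %g thousand | process_sd = %g | obs_cv = %g\n",
              x$K, x$process_sd, x$obs_cv))
  invisible(x)
}

#' Climatology of days above freezing in May in Svalbard
#'
#' Discretizes a normal distribution of the DAYS covariate onto non-negative
#' integer support (probability mass below zero is lumped into zero), or
#' accepts a user-supplied support/probability pair. The climatology provides
#' both the random DAYS draws used in simulation and the standardization
#' (mean, SD) applied before DAYS enters the demographic models.
#'
#' @param days_mean Mean number of days above freezing (default 10).
#' @param days_sd SD of the number of days (default 4).
#' @param support Optional integer vector of support values (>= 0).
#' @param probs Optional probabilities matching `support` (must sum to 1).
#' @return An object of class `ahm_climatology` with elements `days_mean`,
#'   `days_sd`, `support`, `probs`.
#' @export
climatology <- function(days_mean = 10, days_sd = 4,
                        support = NULL, probs = NULL) {
  if (is.null(support)) {
    hi <- ceiling(days_mean + 4 * days_sd)
    support <- 0:hi
    edges_lo <- support - 0.5
    edges_hi <- support + 0.5
    edges_lo[1] <- -Inf
    edges_hi[length(support)] <- Inf
    probs <- stats::pnorm(edges_hi, days_mean, days_sd) -
      stats::pnorm(edges_lo, days_mean, days_sd)
    probs <- probs / sum(probs)
  } else {
    stopifnot(!is.null(probs), length(probs) == length(support),
              all(support >= 0), all(probs >= 0))
    stopifnot(abs(sum(probs) - 1) < 1e-9)
  }
  structure(
    list(days_mean = days_mean, days_sd = days_sd,
         support = support, probs = probs),
    class = "ahm_climatology"
  )
}

#' Standardize DAYS values against a climatology
#'
#' @param days Vector of DAYS values.
#' @param clim An [climatology()] object.
#' @return Standardized values `(days - days_mean) / days_sd`.
#' @export
days_z <- function(days, clim) {
  (days - clim$days_mean) / clim$days_sd
}

form_has_days <- function(form) form %in% c("DAYS", "DAYS_DENSITY")
form_has_density <- function(form) form == "DAYS_DENSITY"

#' Annual natural-survival probability under a model specification
#'
#' Survival is inverse-logit linear in standardized DAYS and relative density
#' N/K, with terms included only when the model's survival form carries them:
#' `s = plogis(alpha0 + alpha1 * z [DAYS in form] - alpha2 * (N/K) [density in form])`.
#'
#' @param N Abundance, thousands (vectorized; must be >= 0).
#' @param days_z Standardized DAYS covariate (vectorized).
#' @param params An [parameter_set()].
#' @param spec An [model_spec()].
#' @return Survival probabilities in (0, 1).
#' @export
survival_rate <- function(N, days_z, params, spec) {
  if (any(N < 0)) stop("abundance N must be non-negative")
  eta <- params$alpha0
  if (form_has_days(spec$survival_form)) eta <- eta + params$alpha1 * days_z
  if (form_has_density(spec$survival_form)) {
    eta <- eta - params$alpha2 * (N / params$K)
  }
  stats::plogis(eta + 0 * N + 0 * days_z)
}

#' Expected young per adult under a model specification
#'
#' Reproduction is log-linear:
#' `r = exp(gamma0 + gamma1 * z [DAYS in form] - gamma2 * (N/K) [density in form])`.
#'
#' @inheritParams survival_rate
#' @return Expected young per adult (>= 0).
#' @export
reproduction_rate <- function(N, days_z, params, spec) {
  if (any(N < 0)) stop("abundance N must be non-negative")
  eta <- params$gamma0
  if (form_has_days(spec$reproduction_form)) eta <- eta + params$gamma1 * days_z
  if (form_has_density(spec$reproduction_form)) {
    eta <- eta - params$gamma2 * (N / params$K)
  }
  exp(eta + 0 * N + 0 * days_z)
}

#' One-year population transition
#'
#' Spring-to-spring accounting: recruitment first (`N (1 + r)`), then harvest
#' (truncated so it cannot exceed the post-breeding population), then natural
#' survival. The stochastic variant multiplies the deterministic core by
#' mean-corrected lognormal process noise so that its expectation equals the
#' deterministic value.
#'
#' @param N Spring abundance, thousands (vectorized).
#' @param harvest Harvest quota, thousands (scalar or vector).
#' @param days_z Standardized DAYS covariate.
#' @param params An [parameter_set()].
#' @param spec An [model_spec()].
#' @param stochastic If `TRUE`, apply lognormal process error with SD
#'   `params$process_sd`.
#' @param seed Optional integer seed set before drawing process noise.
#' @return Next-spring abundance, thousands (>= 0).
#' @examples
#' p <- parameter_set(alpha0 = qlogis(0.95), gamma0 = log(0.16))
#' m <- model_spec("NULL", "NULL", 1)
#' transition(80, 10, 0, p, m)
#' @export
transition <- function(N, harvest, days_z, params, spec,
                       stochastic = FALSE, seed = NULL) {
  if (any(N < 0)) stop("abundance N must be non-negative")
  if (any(harvest < 0)) stop("harvest must be non-negative")
  r <- reproduction_rate(N, days_z, params, spec)
  s <- survival_rate(N, days_z, params, spec)
  post_breeding <- N * (1 + r)
  realized <- pmin(harvest, post_breeding)
  core <- (post_breeding - realized) * s
  if (stochastic && params$process_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- stats::rlnorm(length(core),
                           meanlog = -params$process_sd^2 / 2,
                           sdlog = params$process_sd)
    core <- core * noise
  }
  pmax(core, 0)
}

#' Split total abundance into adults and young
#'
#' Given total abundance and a per-adult reproduction rate, the post-breeding
#' composition is `A = N / (1 + r)` adults and `Y = N r / (1 + r)` young, so
#' that `A + Y = N` exactly.
#'
#' @param N Total abundance, thousands (>= 0).
#' @param r Young per adult (>= 0).
#' @return A list with elements `A` and `Y` (thousands).
#' @export
derive_age_split <- function(N, r) {
  stopifnot(all(N >= 0), all(r >= 0))
  list(A = N / (1 + r), Y = N * r / (1 + r))
}
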