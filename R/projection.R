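#' Draw DAYS values from a climatology
#'
#' @param n Number of draws.
#' @param clim An [climatology()].
#' @return Integer vector of DAYS values (>= 0).
#' @export
draw_days <- function(n, clim) {
  sample(clim$support, n, replace = TRUE, prob = clim$probs)
}

# Linearly interpolated first crossing of N <= target along one trajectory
# (row of abundances for years 0..horizon). 0 if already at/below the target,
# NA if the trajectory never crosses.
first_crossing <- function(traj, target) {
  if (traj[1] <= target) return(0)
  below <- which(traj <= target)
  if (!length(below)) return(NA_real_)
  t_hi <- below[1]                       # column index, year t_hi - 1
  n_prev <- traj[t_hi - 1]; n_next <- traj[t_hi]
  (t_hi - 2) + (n_prev - target) / (n_prev - n_next)
}

#' Stochastic open-loop projection under a fixed annual harvest
#'
#' Projects the population forward under a constant harvest, propagating
#' structural (model), environmental (DAYS) and process uncertainty. By
#' default one model is sampled per trajectory from the model weights, so
#' structural uncertainty appears as between-trajectory spread; with
#' `model_averaging = TRUE` every step instead uses the weight-averaged
#' deterministic core before process noise.
#'
#' @param initial_N Starting spring abundance, thousands.
#' @param harvest Fixed annual harvest, thousands.
#' @param specs Model set.
#' @param params An [parameter_set()].
#' @param weights An `ahm_weights` vector.
#' @param clim An [climatology()].
#' @param n_sims Number of trajectories (default 5000).
#' @param horizon Projection length, years (default 20).
#' @param seed Integer seed for reproducibility.
#' @param target Abundance whose first crossing is recorded, thousands
#'   (default 60).
#' @param model_averaging If `TRUE`, average the deterministic core over model
#'   weights at every step instead of sampling one model per trajectory.
#' @return An object of class `ahm_projection`: `trajectories`
#'   (`n_sims x (horizon + 1)`, year 0 first), per-year `summaries` (mean,
#'   median, interquartile range, 95% interval), `years_to_target` (the
#'   headline value: interpolated first crossing of the target by the
#'   median path), `years_to_target_mean_path` (same for the mean path), and
#'   the per-trajectory distribution in `years_to_target_traj` (interpolated)
#'   and `years_to_target_integer` (first whole year at or below the target).
#' @export
project_fixed_harvest <- function(initial_N, harvest, specs, params, weights,
                                  clim = climatology(), n_sims = 5000L,
                                  horizon = 20L, seed = NULL, target = 60,
                                  model_averaging = FALSE) {
  stopifnot(n_sims >= 1L, horizon >= 1L, initial_N >= 0, harvest >= 0)
  if (!is.null(seed)) set.seed(seed)
  w <- unclass(weights)
  model_idx <- if (model_averaging) NULL else
    sample(seq_along(specs), n_sims, replace = TRUE, prob = w)
  N <- matrix(NA_real_, n_sims, horizon + 1L)
  N[, 1] <- initial_N
  for (t in seq_len(horizon)) {
    days <- draw_days(n_sims, clim)
    z <- days_z(days, clim)
    cur <- N[, t]
    if (model_averaging) {
      core <- 0
      for (m in which(w > 0)) {
        r <- reproduction_rate(cur, z, params, specs[[m]])
        s <- survival_rate(cur, z, params, specs[[m]])
        post <- cur * (1 + r)
        core <- core + w[m] * (post - pmin(harvest, post)) * s
      }
    } else {
      core <- numeric(n_sims)
      for (m in unique(model_idx)) {
        sel <- model_idx == m
        r <- reproduction_rate(cur[sel], z[sel], params, specs[[m]])
        s <- survival_rate(cur[sel], z[sel], params, specs[[m]])
        post <- cur[sel] * (1 + r)
        core[sel] <- (post - pmin(harvest, post)) * s
      }
    }
    if (params$process_sd > 0) {
      core <- core * stats::rlnorm(n_sims, -params$process_sd^2 / 2,
                                   params$process_sd)
    }
    N[, t + 1L] <- pmax(core, 0)
  }
  q <- apply(N, 2, stats::quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  summaries <- data.frame(
    year = 0:horizon, mean = colMeans(N),
    lo95 = q[1, ], q25 = q[2, ], median = q[3, ], q75 = q[4, ], hi95 = q[5, ]
  )
  ytt_traj <- apply(N, 1, first_crossing, target = target)
  ytt_int <- apply(N, 1, function(tr) {
    below <- which(tr <= target)
    if (!length(below)) NA_integer_ else as.integer(below[1] - 1L)
  })
  structure(
    list(trajectories = N, summaries = summaries,
         years_to_target = first_crossing(summaries$median, target),
         years_to_target_mean_path = first_crossing(summaries$mean, target),
         years_to_target_traj = ytt_traj,
         years_to_target_integer = ytt_int, target = target,
         harvest = harvest, initial_N = initial_N, seed = seed),
    class = "ahm_projection"
  )
}

#' @exportS3Method base::print
print.ahm_projection <- function(x, ...) {
  cat(sprintf("<ahm_projection> %d trajectories x %d years | harvest %.1f k/yr from %.1f k\n",
              nrow(x$trajectories), ncol(x$trajectories) - 1L, x$harvest,
              x$initial_N))
  cat(sprintf("years to target (%.0f k), median path: %.2f\n", x$target,
              x$years_to_target))
  print(utils::head(x$summaries, 10), row.names = FALSE)
  invisible(x)
}

#' Closed-loop management strategy evaluation
#'
#' Simulates the full annual cycle against a known truth model: true dynamics,
#' noisy spring counts, Bayesian weight updates, [annual_assessment()]
#' decisions (with re-optimization each year in ONE_YEAR mode, or a block
#' quota with annual emergency-closure checks in THREE_YEAR mode) and realized
#' harvest. Scores the strategy with management-oriented metrics.
#'
#' @param truth_spec True model specification generating the data.
#' @param truth_params True [parameter_set()].
#' @param cfg An [strategy_config()].
#' @param specs Model set used by the manager (default [enumerate_models()]).
#' @param params Manager's [parameter_set()] (defaults to the truth).
#' @param utility_cfg An [utility_config()].
#' @param grids An [default_grids()] object.
#' @param clim An [climatology()].
#' @param initial_N Starting abundance, thousands (default 81.6).
#' @param horizon Years per simulation.
#' @param n_sims Number of replicate simulations.
#' @param seed Integer seed.
#' @param discount Discount factor for policy optimization.
#' @param control_sd Lognormal SD of the partial-controllability multiplier
#'   linking quota to realized harvest (default 0: harvest equals quota).
#' @return An object of class `ahm_mse` with `mean_N` (long-run mean true
#'   abundance), `frac_in_band`, `mean_harvest` (thousands/yr),
#'   `closure_freq`, `truth_weight` (`n_sims x horizon` matrix of the truth
#'   model's weight after each update), plus the simulated `N` and `harvest`
#'   matrices.
#' @export
closed_loop_simulate <- function(truth_spec, truth_params, cfg,
                                 specs = enumerate_models(),
                                 params = truth_params,
                                 utility_cfg = utility_config(),
                                 grids = default_grids(),
                                 clim = climatology(),
                                 initial_N = 81.6, horizon = 100L,
                                 n_sims = 1L, seed = NULL, discount = 0.95,
                                 control_sd = 0) {
  if (!is.null(seed)) set.seed(seed)
  kernels <- build_model_kernels(specs, params, grids, clim, utility_cfg)
  N_mat <- matrix(NA_real_, n_sims, horizon)
  H_mat <- matrix(NA_real_, n_sims, horizon)
  closure_mat <- matrix(FALSE, n_sims, horizon)
  tw_mat <- matrix(NA_real_, n_sims, horizon)
  for (sim in seq_len(n_sims)) {
    N_true <- initial_N
    weights <- uniform_weights()
    prev <- NULL
    V0 <- NULL
    block_quota <- NULL
    for (t in seq_len(horizon)) {
      days <- draw_days(1L, clim)
      z <- days_z(days, clim)
      observed <- N_true *
        stats::rlnorm(1L, meanlog = 0, sdlog = params$obs_cv)
      record <- monitoring_record(year = t, spring_count = observed * 1000,
                                  days = days)
      if (cfg$mode == "THREE_YEAR" && (t - 1L) %% cfg$block_length == 0L) {
        # start of a block: refresh the block quota from a new policy
        w_for_block <- if (is.null(prev)) weights else {
          z_prev <- days_z(prev$days, clim)
          preds <- vapply(specs, function(sp) {
            transition(prev$N, prev$harvest, z_prev, params, sp)
          }, numeric(1))
          update_weights(weights, preds, observed, params$obs_cv)
        }
        pol <- optimize_policy(specs, params, w_for_block, grids, utility_cfg,
                               clim, discount = discount, kernels = kernels,
                               V0 = V0)
        V0 <- pol$value
        block_quota <- lookup_quota(pol, observed, days)
      }
      dec <- annual_assessment(record, weights, specs, params, cfg,
                               utility_cfg, grids, clim,
                               block_quota = block_quota, prev = prev,
                               discount = discount, kernels = kernels,
                               V0 = V0)
      if (!is.null(dec$value_function)) V0 <- dec$value_function
      weights <- dec$weights
      quota_k <- dec$total_quota / 1000
      realized <- if (control_sd > 0) {
        quota_k * stats::rlnorm(1L, -control_sd^2 / 2, control_sd)
      } else quota_k
      N_true <- transition(N_true, realized, z, truth_params, truth_spec,
                           stochastic = TRUE)
      N_mat[sim, t] <- N_true
      H_mat[sim, t] <- realized
      closure_mat[sim, t] <- dec$closure
      tw_mat[sim, t] <- unclass(weights)[truth_spec$id]
      prev <- list(N = observed, days = days, harvest = realized)
    }
  }
  structure(
    list(mean_N = mean(N_mat),
         frac_in_band = mean(N_mat >= utility_cfg$band_low &
                               N_mat <= utility_cfg$band_high),
         mean_harvest = mean(H_mat),
         closure_freq = mean(closure_mat),
         truth_weight = tw_mat, N = N_mat, harvest = H_mat,
         closures = closure_mat, mode = cfg$mode, seed = seed),
    class = "ahm_mse"
  )
}

#' @exportS3Method base::print
print.ahm_mse <- function(x, ...) {
  cat(sprintf("<ahm_mse> %s strategy | %d sims x %d years\n", x$mode,
              nrow(x$N), ncol(x$N)))
  cat(sprintf("  long-run mean N: %.1f k | in band: %.0f%% | mean harvest: %.2f k/yr | closures: %.1f%%\n",
              x$mean_N, 100 * x$frac_in_band, x$mean_harvest,
              100 * x$closure_freq))
  invisible(x)
}

#' Write projection summaries as delimited text
#'
#' @param projection An `ahm_projection`.
#' @param path Output path (tab-separated).
#' @return The summary data frame, invisibly.
#' @export
write_projection <- function(projection, path) {
  utils::write.table(projection$summaries, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(projection$summaries)
}
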