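#' One year's monitoring record
#'
#' Counts are in individuals. The spring count and DAYS are required for a
#' June decision; the autumn count and proportion of young may be missing
#' (`NA`) in years without those surveys.
#'
#' @param year Calendar year.
#' @param spring_count Spring (early May) population count, individuals.
#' @param autumn_count Autumn (November) count, individuals, or `NA`.
#' @param prop_young Proportion of young in autumn flocks, in `[0, 1]` or `NA`.
#' @param harvest_norway,harvest_denmark Reported harvest in the preceding
#'   season, individuals.
#' @param days Days above freezing in May in Svalbard.
#' @return A one-row data frame of class `ahm_record`.
#' @export
monitoring_record <- function(year, spring_count, autumn_count = NA,
                              prop_young = NA, harvest_norway = 0,
                              harvest_denmark = 0, days) {
  stopifnot(is.na(spring_count) || spring_count >= 0,
            is.na(autumn_count) || autumn_count >= 0,
            is.na(prop_young) || (prop_young >= 0 && prop_young <= 1),
            harvest_norway >= 0, harvest_denmark >= 0, days >= 0)
  out <- data.frame(year = year, spring_count = spring_count,
                    autumn_count = autumn_count, prop_young = prop_young,
                    harvest_no = harvest_norway, harvest_dk = harvest_denmark,
                    days = days)
  class(out) <- c("ahm_record", class(out))
  out
}

#' Read / write monitoring records as tab-separated text
#'
#' Columns: `year`, `spring_count`, `autumn_count`, `prop_young`,
#' `harvest_no`, `harvest_dk`, `days`. Counts in individuals.
#'
#' @param path File path.
#' @return `read_monitoring` returns a data frame of records.
#' @export
read_monitoring <- function(path) {
  df <- utils::read.delim(path)
  needed <- c("year", "spring_count", "autumn_count", "prop_young",
              "harvest_no", "harvest_dk", "days")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("monitoring file lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' @rdname read_monitoring
#' @param records Data frame of monitoring records.
#' @export
write_monitoring <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Strategy configuration for the annual decision
#'
#' @param mode `"ONE_YEAR"` (quota re-optimized every year) or `"THREE_YEAR"`
#'   (a block quota held fixed for `block_length` years, with annual
#'   emergency-closure checks only).
#' @param block_length Length of the block in THREE_YEAR mode (default 3).
#' @param shares Named country shares of the total quota, summing to 1
#'   (default Norway 0.3, Denmark 0.7).
#' @param rounding Quota rounding unit in individuals (default 100).
#' @param closure_threshold Abundance (thousands) below which the predicted
#'   next-spring population triggers an emergency closure (default the 60
#'   thousand target).
#' @return An object of class `ahm_strategy`.
#' @export
strategy_config <- function(mode = c("ONE_YEAR", "THREE_YEAR"),
                            block_length = 3L,
                            shares = c(Norway = 0.3, Denmark = 0.7),
                            rounding = 100,
                            closure_threshold = 60) {
  mode <- match.arg(mode)
  stopifnot(abs(sum(shares) - 1) < 1e-9, all(shares >= 0),
            !is.null(names(shares)), block_length >= 1L, rounding > 0)
  structure(list(mode = mode, block_length = as.integer(block_length),
                 shares = shares, rounding = rounding,
                 closure_threshold = closure_threshold),
            class = "ahm_strategy")
}

#' Allocate a total quota between countries
#'
#' Largest-remainder apportionment in units of the rounding unit: each
#' country's exact share is floored to the unit, and leftover units go to the
#' largest fractional remainders, with deterministic ties broken by country
#' name. Parts always sum to the total (rounded to the unit).
#'
#' @param total Total quota, individuals (>= 0).
#' @param shares Named shares summing to 1 (default Norway 0.3, Denmark 0.7).
#' @param rounding Rounding unit in individuals (default 100).
#' @return Named vector of per-country quotas in individuals.
#' @examples
#' allocate_quota(6700)   # Norway 2000, Denmark 4700
#' @export
allocate_quota <- function(total, shares = c(Norway = 0.3, Denmark = 0.7),
                           rounding = 100) {
  stopifnot(total >= 0, abs(sum(shares) - 1) < 1e-9, all(shares >= 0))
  units <- round(total / rounding)
  exact <- shares * units
  base <- floor(exact)
  leftover <- units - sum(base)
  if (leftover > 0) {
    rem <- exact - base
    # order by remainder, ties broken by country name
    ord <- order(-rem, names(shares))
    take <- ord[seq_len(leftover)]
    base[take] <- base[take] + 1
  }
  base * rounding
}

# Model-averaged deterministic prediction of next spring's abundance.
predict_next_spring <- function(N, harvest, days, weights, specs, params,
                                clim) {
  z <- days_z(days, clim)
  preds <- vapply(specs, function(sp) transition(N, harvest, z, params, sp),
                  numeric(1))
  sum(unclass(weights) * preds)
}

#' Emergency-closure check for a standing block quota
#'
#' Fires when the model-averaged expected next-spring population under the
#' standing (positive) block quota falls below the closure threshold. A zero
#' quota can never trigger a closure.
#'
#' @param N Current spring abundance, thousands.
#' @param days Current DAYS value.
#' @param weights An `ahm_weights` vector.
#' @param block_quota Standing quota, thousands.
#' @param specs Model set.
#' @param params An [parameter_set()].
#' @param clim An [climatology()].
#' @param threshold Closure threshold, thousands (default 60, the target).
#' @return Logical flag.
#' @export
emergency_closure_check <- function(N, days, weights, block_quota, specs,
                                    params, clim, threshold = 60) {
  if (block_quota <= 0) return(FALSE)
  predict_next_spring(N, block_quota, days, weights, specs, params, clim) <
    threshold
}

#' Run the annual assessment and produce a harvest decision
#'
#' Orchestrates one pass of the annual cycle at the June decision point: the
#' model weights are updated from the observed spring count (when last year's
#' state is supplied), the quota is set under the configured strategy mode,
#' the emergency-closure rule is applied in THREE_YEAR mode, and the total is
#' allocated between the hunting countries.
#'
#' @param record One year's [monitoring_record()]; the spring count and DAYS
#'   must be present.
#' @param weights Current `ahm_weights` (prior to this year's update).
#' @param specs Model set.
#' @param params An [parameter_set()].
#' @param cfg An [strategy_config()].
#' @param utility_cfg An [utility_config()].
#' @param grids An [default_grids()] object.
#' @param clim An [climatology()].
#' @param block_quota Standing block quota in thousands (required in
#'   THREE_YEAR mode).
#' @param prev Optional list with last year's decision state: `N` (observed
#'   spring abundance, thousands), `days`, and `harvest` (realized, thousands).
#'   When supplied, the weights are updated from this year's spring count
#'   against each model's prediction from that state.
#' @param discount Discount factor for the ONE_YEAR policy optimization.
#' @param kernels Optional precomputed [build_model_kernels()] (speeds up
#'   repeated ONE_YEAR assessments).
#' @param V0 Optional warm-start value vector for the ONE_YEAR policy
#'   optimization (e.g. `value_function` of last year's decision).
#' @return An object of class `ahm_decision`. In ONE_YEAR mode the decision
#'   carries the converged `value_function`, reusable as next year's `V0`.
#' @export
annual_assessment <- function(record, weights, specs, params, cfg,
                              utility_cfg = utility_config(),
                              grids = default_grids(),
                              clim = climatology(),
                              block_quota = NULL, prev = NULL,
                              discount = 0.95, kernels = NULL, V0 = NULL) {
  if (is.na(record$spring_count)) {
    stop("spring count is missing: no decision can be made")
  }
  N <- record$spring_count / 1000
  days <- record$days
  if (!is.null(prev)) {
    z_prev <- days_z(prev$days, clim)
    preds <- vapply(specs, function(sp) {
      transition(prev$N, prev$harvest, z_prev, params, sp)
    }, numeric(1))
    weights <- update_weights(weights, preds, N, params$obs_cv)
  }
  closure <- FALSE
  value_function <- NULL
  if (cfg$mode == "ONE_YEAR") {
    policy <- optimize_policy(specs, params, weights, grids, utility_cfg,
                              clim, discount = discount, kernels = kernels,
                              V0 = V0)
    quota_k <- lookup_quota(policy, N, days)
    value_function <- policy$value
  } else {
    if (is.null(block_quota)) {
      stop("THREE_YEAR mode requires a standing block quota")
    }
    closure <- emergency_closure_check(N, days, weights, block_quota, specs,
                                       params, clim,
                                       threshold = cfg$closure_threshold)
    quota_k <- if (closure) 0 else block_quota
  }
  total <- round(quota_k * 1000 / cfg$rounding) * cfg$rounding
  allocation <- allocate_quota(total, cfg$shares, cfg$rounding)
  predicted <- predict_next_spring(N, quota_k, days, weights, specs, params,
                                   clim)
  structure(
    list(year = record$year, total_quota = total, allocation = allocation,
         closure = closure, strategy_mode = cfg$mode, weights = weights,
         quota_thousands = quota_k, predicted_next_spring = predicted,
         value_function = value_function),
    class = "ahm_decision"
  )
}

#' @exportS3Method base::print
print.ahm_decision <- function(x, ...) {
  cat(sprintf("<ahm_decision> year %s [%s]%s\n", x$year, x$strategy_mode,
              if (x$closure) " EMERGENCY CLOSURE" else ""))
  cat(sprintf("  total quota: %d individuals (%s)\n", x$total_quota,
              paste(sprintf("%s %d", names(x$allocation), x$allocation),
                    collapse = ", ")))
  cat(sprintf("  predicted next spring: %.1f thousand\n",
              x$predicted_next_spring))
  invisible(x)
}

#' Append a decision to an append-only decision log
#'
#' Decisions already issued are never rewritten: revised counts enter only the
#' next cycle, so the log grows strictly by appending one row per decision.
#'
#' @param decision An `ahm_decision`.
#' @param path Log file path (tab-separated; header written on creation).
#' @return `path`, invisibly.
#' @export
append_decision <- function(decision, path) {
  row <- data.frame(
    year = decision$year, mode = decision$strategy_mode,
    total_quota = decision$total_quota,
    t(decision$allocation),
    closure = decision$closure,
    predicted_next_spring = round(decision$predicted_next_spring, 3)
  )
  new_file <- !file.exists(path)
  suppressWarnings(
    utils::write.table(row, path, sep = "\t", row.names = FALSE,
                       col.names = new_file, quote = FALSE,
                       append = !new_file)
  )
  invisible(path)
}

#' Chapman mark-resight abundance estimate
#'
#' Bias-corrected Lincoln-Petersen estimator from the number of marked
#' (neck-banded) birds alive, a resighting sample size, and the number of
#' marked birds in the sample. Finite even when no marked birds are resighted.
#'
#' @param marked_alive Number of marked individuals alive (M).
#' @param resight_sample Size of the scanned sample (n).
#' @param marked_in_sample Marked individuals within the sample (m), with
#'   `m <= min(M, n)`.
#' @return List with `estimate` and `se`.
#' @examples
#' cmr_estimate(100, 50, 10)
#' @export
cmr_estimate <- function(marked_alive, resight_sample, marked_in_sample) {
  M <- marked_alive; n <- resight_sample; m <- marked_in_sample
  stopifnot(M >= 0, n >= 0, m >= 0)
  if (m > n || m > M) stop("marked_in_sample cannot exceed the sample or the marked total")
  est <- (M + 1) * (n + 1) / (m + 1) - 1
  v <- (M + 1) * (n + 1) * (M - m) * (n - m) / ((m + 1)^2 * (m + 2))
  list(estimate = est, se = sqrt(v))
}
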