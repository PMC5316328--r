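#' Create a valid model-weight vector
#'
#' Model weights are Bayesian probabilities expressing the relative ability of
#' each of the nine models to predict observed population change. Weights
#' below `floor` are zeroed to avoid underflow in long sequential updates; the
#' vector is then renormalized.
#'
#' @param w Numeric vector of length 9, non-negative; names are taken as model
#'   ids if present, else assigned 1..9.
#' @param floor Weights strictly below this value are set to 0 (default 1e-12).
#' @return A named numeric vector of class `ahm_weights` summing to 1.
#' @export
weight_vector <- function(w, floor = 1e-12) {
  stopifnot(length(w) == 9L, all(is.finite(w)), all(w >= 0), sum(w) > 0)
  w[w < floor] <- 0
  w <- w / sum(w)
  names(w) <- if (is.null(names(w))) as.character(1:9) else names(w)
  structure(w, class = "ahm_weights")
}

#' Uniform prior over the nine models
#' @return An `ahm_weights` vector with weight 1/9 on each model.
#' @export
uniform_weights <- function() weight_vector(rep(1, 9) / 9)

#' Point-mass weights on a single model
#' @param id Model id receiving all weight.
#' @return An `ahm_weights` vector.
#' @export
point_weights <- function(id) {
  w <- rep(0, 9)
  w[id] <- 1
  weight_vector(w)
}

#' @exportS3Method base::print
print.ahm_weights <- function(x, ...) {
  cat("<ahm_weights>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Predictive density of an observed count given a model's prediction
#'
#' The observation model is lognormal: counts are positive and survey error is
#' multiplicative. The density of the observed spring count is evaluated at
#' log-mean `log(predicted_mean)` with log-SD `obs_cv`.
#'
#' @param observed_count Observed count, thousands (> 0).
#' @param predicted_mean Model-predicted mean count, thousands (> 0).
#' @param obs_cv Observation CV (> 0), used as the lognormal log-SD.
#' @return Strictly positive density value.
#' @export
predictive_density <- function(observed_count, predicted_mean, obs_cv) {
  if (any(observed_count <= 0) || any(predicted_mean <= 0) || obs_cv <= 0) {
    stop("observed count, predicted mean and obs_cv must all be positive")
  }
  stats::dlnorm(observed_count, meanlog = log(predicted_mean), sdlog = obs_cv)
}

#' Bayesian update of model weights from one year's observed count
#'
#' Each model's posterior weight is proportional to its prior weight times the
#' predictive density of the observed spring count under that model's
#' prediction.
#'
#' @param prior An `ahm_weights` vector ([weight_vector()]).
#' @param per_model_predictions Numeric vector of length 9: each model's
#'   predicted mean count (thousands), in model-id order.
#' @param observed_count Observed count, thousands.
#' @param obs_cv Observation CV.
#' @return Posterior `ahm_weights`.
#' @export
update_weights <- function(prior, per_model_predictions, observed_count,
                           obs_cv) {
  stopifnot(inherits(prior, "ahm_weights"),
            length(per_model_predictions) == 9L,
            all(per_model_predictions > 0))
  lik <- predictive_density(observed_count, per_model_predictions, obs_cv)
  post <- unclass(prior) * lik
  if (sum(post) <= 0 || !all(is.finite(post))) {
    stop("degenerate weight update: all model likelihoods are zero")
  }
  weight_vector(post)
}

#' Aggregate weight on a structural feature of the model set
#'
#' Sums the weight over models that include a given feature: density-dependent
#' survival, density-dependent reproduction, or any DAYS (spring temperature)
#' effect in either process.
#'
#' @param weights An `ahm_weights` vector.
#' @param feature One of `"DD_SURVIVAL"`, `"DD_REPRODUCTION"`, `"DAYS_ANY"`.
#' @param specs Model set, default [enumerate_models()].
#' @return Probability in `[0, 1]`.
#' @export
aggregate_weight <- function(weights, feature, specs = enumerate_models()) {
  stopifnot(inherits(weights, "ahm_weights"))
  feature <- match.arg(feature, c("DD_SURVIVAL", "DD_REPRODUCTION", "DAYS_ANY"))
  sel <- vapply(specs, function(sp) {
    switch(feature,
      DD_SURVIVAL = form_has_density(sp$survival_form),
      DD_REPRODUCTION = form_has_density(sp$reproduction_form),
      DAYS_ANY = form_has_days(sp$survival_form) ||
        form_has_days(sp$reproduction_form)
    )
  }, logical(1))
  sum(unclass(weights)[sel])
}

#' Write a weight trajectory as delimited text
#'
#' One row per year: the nine model weights plus the three aggregate
#' probabilities (density-dependent survival, density-dependent reproduction,
#' any DAYS effect).
#'
#' @param years Integer vector of years.
#' @param weight_list List of `ahm_weights`, same length as `years`.
#' @param path Output file path (tab-separated).
#' @return The written data frame, invisibly.
#' @export
write_weight_log <- function(years, weight_list, path) {
  stopifnot(length(years) == length(weight_list))
  rows <- lapply(seq_along(years), function(i) {
    w <- weight_list[[i]]
    data.frame(year = years[i], t(unclass(w)),
               agg_dd_survival = aggregate_weight(w, "DD_SURVIVAL"),
               agg_dd_reproduction = aggregate_weight(w, "DD_REPRODUCTION"),
               agg_days_any = aggregate_weight(w, "DAYS_ANY"))
  })
  out <- do.call(rbind, rows)
  names(out)[2:10] <- paste0("w", 1:9)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
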