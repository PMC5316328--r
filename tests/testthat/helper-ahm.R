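# Shared fixtures: calibrate the default parameter set once per test run.
default_params <- local({
  cache <- NULL
  function(...) {
    if (length(list(...)) > 0) return(calibrate_defaults(...))
    if (is.null(cache)) cache <<- calibrate_defaults()
    cache
  }
})

the_specs <- enumerate_models()
the_clim <- climatology()
null_spec <- the_specs[[1]]

# Independent lognormal density oracle (plain formula, no stats::dlnorm).
lnorm_density_oracle <- function(x, meanlog, sdlog) {
  1 / (x * sdlog * sqrt(2 * pi)) * exp(-(log(x) - meanlog)^2 / (2 * sdlog^2))
}

# Brute-force MDP oracle: enumerate every stationary policy, evaluate each
# exactly by solving the linear system, and return the best value vector.
enumerate_mdp_oracle <- function(P, R, discount) {
  S <- dim(P)[1]; A <- dim(P)[2]
  combos <- as.matrix(expand.grid(rep(list(seq_len(A)), S)))
  best_V <- rep(-Inf, S)
  for (i in seq_len(nrow(combos))) {
    pol <- combos[i, ]
    Ppol <- t(vapply(seq_len(S), function(s) P[s, pol[s], ], numeric(S)))
    Rpol <- vapply(seq_len(S), function(s) R[s, pol[s]], numeric(1))
    V <- solve(diag(S) - discount * Ppol, Rpol)
    # the optimal value dominates every stationary policy componentwise
    best_V <- pmax(best_V, V)
  }
  best_V
}

# Evaluate a fixed policy exactly.
evaluate_policy_exact <- function(P, R, discount, pol) {
  S <- dim(P)[1]
  Ppol <- t(vapply(seq_len(S), function(s) P[s, pol[s], ], numeric(S)))
  Rpol <- vapply(seq_len(S), function(s) R[s, pol[s]], numeric(1))
  solve(diag(S) - discount * Ppol, Rpol)
}

# Random small MDP with valid transition rows.
random_mdp <- function(S, A, seed) {
  set.seed(seed)
  P <- array(stats::runif(S * A * S), dim = c(S, A, S))
  for (s in seq_len(S)) for (a in seq_len(A)) {
    P[s, a, ] <- P[s, a, ] / sum(P[s, a, ])
  }
  R <- matrix(stats::runif(S * A), S, A)
  list(P = P, R = R)
}
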