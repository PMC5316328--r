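#' Utility configuration for the population target
#'
#' Management preference over spring population sizes: utility peaks at the
#' agreed target (60 thousand) and falls to 0.5 at the edges of the acceptance
#' band (50 and 70 thousand). The Gaussian shape SD is derived from the band
#' so that the half-utility points sit exactly on the band edges:
#' `shape_sd = (band_high - target) / sqrt(2 log 2)`.
#'
#' @param target Target population, thousands (default 60).
#' @param band_low,band_high Acceptance band, thousands (defaults 50, 70).
#' @return An object of class `ahm_utility`.
#' @export
utility_config <- function(target = 60, band_low = 50, band_high = 70) {
  stopifnot(band_low < target, target < band_high)
  shape_sd <- (band_high - target) / sqrt(2 * log(2))
  structure(
    list(target = target, band_low = band_low, band_high = band_high,
         shape_sd = shape_sd),
    class = "ahm_utility"
  )
}

#' Utility of a population size
#'
#' @param N Abundance, thousands (vectorized, >= 0).
#' @param cfg An [utility_config()].
#' @return Utility in `[0, 1]`; 1 at the target, 0.5 at the band edges.
#' @export
utility <- function(N, cfg = utility_config()) {
  exp(-(N - cfg$target)^2 / (2 * cfg$shape_sd^2))
}

#' Discretization grids for the harvest optimization
#'
#' @param N_grid Abundance nodes, thousands (default 0 to 150 by 2.5).
#' @param days_grid DAYS nodes (default 0 to 20 by 4).
#' @param action_grid Quota nodes, thousands (default 0 to 30 by 2.5, i.e.
#'   quotas to the nearest 2.5 thousand).
#' @return An object of class `ahm_grids`.
#' @export
default_grids <- function(N_grid = seq(0, 150, by = 2.5),
                          days_grid = seq(0, 20, by = 4),
                          action_grid = seq(0, 30, by = 2.5)) {
  stopifnot(all(diff(N_grid) > 0), all(diff(days_grid) > 0),
            all(diff(action_grid) > 0))
  structure(list(N_grid = N_grid, days_grid = days_grid,
                 action_grid = action_grid),
            class = "ahm_grids")
}

#' Generic value iteration for a finite Markov decision process
#'
#' Solves `V(s) = max_a R(s, a) + discount * sum_s' P(s, a, s') V(s')` by
#' successive approximation, with ties in the argmax broken toward the
#' lowest-indexed action.
#'
#' @param P Transition array of dimension `S x A x S`; each `P[s, a, ]` must
#'   be a probability vector.
#' @param R Reward matrix `S x A`.
#' @param discount Discount factor in (0, 1).
#' @param tol Convergence tolerance on the sup-norm value change.
#' @param max_iter Maximum number of iterations; exceeding it is an error.
#' @param V0 Optional starting value vector (default zeros).
#' @return List with `V` (values), `policy` (action index per state),
#'   `iterations`, `gap`.
#' @export
value_iteration <- function(P, R, discount, tol = 1e-6, max_iter = 1000L,
                            V0 = NULL) {
  stopifnot(discount > 0, discount < 1)
  S <- dim(P)[1]; A <- dim(P)[2]
  stopifnot(dim(P)[3] == S, nrow(R) == S, ncol(R) == A)
  # flatten to (S*A) x S for fast matrix products
  Pm <- matrix(aperm(P, c(1, 2, 3)), nrow = S * A, ncol = S)
  vi_core(
    R_sa = as.vector(R),
    cont_fun = function(V) as.vector(Pm %*% V),
    S = S, A = A, discount = discount, tol = tol,
    max_iter = max_iter, V0 = V0
  )
}

# Shared value-iteration engine. R_sa is the reward stacked action-major
# (element (a-1)*S + s); cont_fun maps a value vector of length S to the
# expected next-state value for every (s, a) pair in the same stacking.
vi_core <- function(R_sa, cont_fun, S, A, discount, tol, max_iter, V0 = NULL) {
  V <- if (is.null(V0)) numeric(S) else V0
  gap <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Q <- matrix(R_sa + discount * cont_fun(V), nrow = S, ncol = A)
    V_new <- do.call(pmax, as.data.frame(Q))
    gap <- max(abs(V_new - V))
    V <- V_new
    if (gap < tol) {
      # argmax with ties (to numerical precision) broken toward the lowest action
      pol <- apply(Q, 1L, function(q) which.max(q >= max(q) - 1e-12))
      return(list(V = V, policy = pol, iterations = iter, gap = gap))
    }
  }
  stop(sprintf("value iteration did not converge in %d iterations (gap %.3g)",
               max_iter, gap))
}

# Discretize mean-corrected lognormal process error into equal-weight
# midpoint-quantile nodes; a single unit node when process_sd is 0.
noise_nodes <- function(process_sd, n_nodes = 5L) {
  if (process_sd <= 0) return(list(q = 1, p = 1))
  pr <- (seq_len(n_nodes) - 0.5) / n_nodes
  list(q = stats::qlnorm(pr, meanlog = -process_sd^2 / 2, sdlog = process_sd),
       p = rep(1 / n_nodes, n_nodes))
}

# Aggregate climatology mass onto the policy DAYS grid (nearest node).
days_grid_probs <- function(grids, clim) {
  nd <- length(grids$days_grid)
  p <- numeric(nd)
  for (k in seq_along(clim$support)) {
    j <- which.min(abs(grids$days_grid - clim$support[k]))
    p[j] <- p[j] + clim$probs[k]
  }
  p / sum(p)
}

#' Precompute per-model transition and reward kernels on the decision grids
#'
#' For each model, builds the expected-utility reward and the projection of
#' next-year abundance onto the abundance grid (linear interpolation), with
#' process error integrated over discrete lognormal nodes. The kernels do not
#' depend on the model weights, so they can be built once and reused across
#' annual re-optimizations as the weights evolve.
#'
#' @param specs Model set ([enumerate_models()]).
#' @param params An [parameter_set()].
#' @param grids An [default_grids()] object.
#' @param clim An [climatology()].
#' @param utility_cfg An [utility_config()].
#' @param n_noise Number of process-error nodes (default 5).
#' @return An object of class `ahm_kernels` for [optimize_policy()].
#' @export
build_model_kernels <- function(specs, params, grids, clim,
                                utility_cfg = utility_config(),
                                n_noise = 5L) {
  nN <- length(grids$N_grid); nD <- length(grids$days_grid)
  A <- length(grids$action_grid)
  S <- nN * nD
  z_grid <- days_z(grids$days_grid, clim)
  # expanded state-action vectors, stacking s = (j-1)*nN + i, then actions
  N_vec <- rep(rep(grids$N_grid, times = nD), times = A)
  z_vec <- rep(rep(z_grid, each = nN), times = A)
  h_vec <- rep(grids$action_grid, each = S)
  nodes <- noise_nodes(params$process_sd, n_noise)
  rows <- seq_len(S * A)
  D_list <- vector("list", length(specs))
  R_list <- vector("list", length(specs))
  for (m in seq_along(specs)) {
    sp <- specs[[m]]
    r <- reproduction_rate(N_vec, z_vec, params, sp)
    s_rate <- survival_rate(N_vec, z_vec, params, sp)
    post <- N_vec * (1 + r)
    core <- (post - pmin(h_vec, post)) * s_rate
    Rm <- numeric(S * A)
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    for (k in seq_along(nodes$q)) {
      Np <- core * nodes$q[k]
      Rm <- Rm + nodes$p[k] * utility(Np, utility_cfg)
      Npc <- pmin(pmax(Np, grids$N_grid[1]), grids$N_grid[nN])
      ilo <- findInterval(Npc, grids$N_grid, all.inside = TRUE)
      whi <- (Npc - grids$N_grid[ilo]) /
        (grids$N_grid[ilo + 1L] - grids$N_grid[ilo])
      trip_i <- c(trip_i, rows, rows)
      trip_j <- c(trip_j, ilo, ilo + 1L)
      trip_x <- c(trip_x, nodes$p[k] * (1 - whi), nodes$p[k] * whi)
    }
    D_list[[m]] <- as.matrix(Matrix::sparseMatrix(
      i = trip_i, j = trip_j, x = trip_x, dims = c(S * A, nN)))
    R_list[[m]] <- Rm
  }
  structure(
    list(D = D_list, R = R_list, S = S, A = A, nN = nN, nD = nD,
         p_days = days_grid_probs(grids, clim), grids = grids,
         utility_cfg = utility_cfg),
    class = "ahm_kernels"
  )
}

#' Optimize the state-dependent harvest policy by stochastic dynamic programming
#'
#' Value iteration on the model-averaged transition kernel: the expectation is
#' taken over the current model weights, lognormal process error and next-year
#' DAYS drawn from the climatology. The per-step reward is the expected
#' utility of the post-transition population, so the optimal policy maximizes
#' expected discounted utility of future population sizes. The returned policy
#' prescribes a quota (a member of the action grid) for every abundance x DAYS
#' state node.
#'
#' @param specs Model set ([enumerate_models()]).
#' @param params An [parameter_set()].
#' @param weights An `ahm_weights` vector.
#' @param grids An [default_grids()] object.
#' @param utility_cfg An [utility_config()].
#' @param clim An [climatology()].
#' @param discount Discount factor in (0, 1), default 0.95.
#' @param tol Sup-norm convergence tolerance, default 1e-6.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @param kernels Optional precomputed [build_model_kernels()] result.
#' @param V0 Optional warm-start value vector (e.g. from last year's policy).
#' @return An object of class `ahm_policy`: quota matrix over (N, DAYS) nodes
#'   plus value function and convergence metadata.
#' @export
optimize_policy <- function(specs, params, weights,
                            grids = default_grids(),
                            utility_cfg = utility_config(),
                            clim = climatology(),
                            discount = 0.95, tol = 1e-6, max_iter = 1000L,
                            kernels = NULL, V0 = NULL) {
  stopifnot(inherits(weights, "ahm_weights"), discount > 0, discount < 1)
  if (is.null(kernels)) {
    kernels <- build_model_kernels(specs, params, grids, clim, utility_cfg)
  }
  w <- unclass(weights)
  active <- which(w > 0)
  D <- kernels$D[[active[1]]] * w[active[1]]
  R_sa <- kernels$R[[active[1]]] * w[active[1]]
  for (m in active[-1]) {
    D <- D + kernels$D[[m]] * w[m]
    R_sa <- R_sa + kernels$R[[m]] * w[m]
  }
  S <- kernels$S; nN <- kernels$nN; nD <- kernels$nD
  p_days <- kernels$p_days
  cont_fun <- function(V) {
    W <- as.vector(matrix(V, nN, nD) %*% p_days)
    as.vector(D %*% W)
  }
  sol <- vi_core(R_sa, cont_fun, S = S, A = kernels$A, discount = discount,
                 tol = tol, max_iter = max_iter, V0 = V0)
  quota <- matrix(kernels$grids$action_grid[sol$policy], nN, nD,
                  dimnames = list(kernels$grids$N_grid,
                                  kernels$grids$days_grid))
  structure(
    list(quota = quota, value = sol$V,
         N_grid = kernels$grids$N_grid, days_grid = kernels$grids$days_grid,
         action_grid = kernels$grids$action_grid,
         weights = weights, discount = discount,
         iterations = sol$iterations, gap = sol$gap),
    class = "ahm_policy"
  )
}

#' @exportS3Method base::print
print.ahm_policy <- function(x, ...) {
  cat(sprintf(
    "<ahm_policy> %d abundance x %d DAYS nodes | %d actions | %d iterations (gap %.2g)\n",
    length(x$N_grid), length(x$days_grid), length(x$action_grid),
    x$iterations, x$gap))
  mid <- ceiling(length(x$days_grid) / 2)
  show <- x$quota[seq(1, length(x$N_grid), by = 8), mid, drop = FALSE]
  cat(sprintf("quota at DAYS = %s (thousands):\n", x$days_grid[mid]))
  print(show)
  invisible(x)
}

#' Look up the quota prescribed for a population state
#'
#' States off the grid are clamped to the hull and matched to the nearest
#' node, with ties broken toward the lower node.
#'
#' @param policy An `ahm_policy` from [optimize_policy()].
#' @param N Spring abundance, thousands.
#' @param days Current DAYS value.
#' @return Quota in thousands (a member of the action grid).
#' @export
lookup_quota <- function(policy, N, days) {
  i <- which.min(abs(policy$N_grid - N))
  j <- which.min(abs(policy$days_grid - days))
  unname(policy$quota[i, j])
}

#' Write a policy table as delimited text
#'
#' @param policy An `ahm_policy`.
#' @param path Output path (tab-separated columns N, days, quota).
#' @return The written data frame, invisibly.
#' @export
write_policy <- function(policy, path) {
  out <- data.frame(
    N = rep(policy$N_grid, times = length(policy$days_grid)),
    days = rep(policy$days_grid, each = length(policy$N_grid)),
    quota = as.vector(policy$quota)
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
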