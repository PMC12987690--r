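#' Simulation scenario configuration
#'
#' Generative constants for the two benchmark scenarios.  Initial states are
#' multivariate normal with variance `sigma_diag` on the diagonal,
#' covariance `sigma_12` between the two reward-relevant features, and a
#' band covariance `sigma_band` between adjacent noise features.  States
#' evolve through an exponentially weighted moving average
#' `Xtilde_t = ewma_old * Xtilde_{t-1} + ewma_new * X_t` with Gaussian
#' innovations of standard deviation `innovation_sd`.  Actions under the
#' behavior policy are `+1`/`-1` with equal probability `behavior_prob`.
#'
#' Scenario 1 has a nonlinear (softplus) reward with a `tanh` interaction in
#' the state dynamics; Scenario 2 has a linear reward.  In both, the reward
#' of stage `t` is realized through the stage-`t+1` state, so the process is
#' deliberately non-Markovian in the returned features.
#'
#' @param scenario 1 or 2.
#' @param n number of subjects.
#' @param T number of stages.
#' @param d number of features (`>= 2`); defaults to 50.
#' @param seed integer seed.
#' @param sigma_diag,sigma_12,sigma_band initial-state covariance entries.
#' @param innovation_sd innovation standard deviation.
#' @param ewma_old,ewma_new EWMA weights.
#' @param behavior_prob behavior-policy probability of each action.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario, n, T, d = 50L, seed = 1L,
                            sigma_diag = 4, sigma_12 = 1, sigma_band = 0.2,
                            innovation_sd = 0.4, ewma_old = 0.2,
                            ewma_new = 0.8, behavior_prob = 0.5) {
  if (!scenario %in% c(1L, 2L)) stop("scenario must be 1 or 2")
  if (d < 2L) stop("d must be >= 2")
  cfg <- structure(list(scenario = as.integer(scenario), n = as.integer(n),
                        T = as.integer(T), d = as.integer(d),
                        seed = as.integer(seed),
                        sigma_diag = sigma_diag, sigma_12 = sigma_12,
                        sigma_band = sigma_band,
                        innovation_sd = innovation_sd,
                        ewma_old = ewma_old, ewma_new = ewma_new,
                        behavior_prob = behavior_prob),
                   class = "scenario_config")
  chol(scenario_sigma(cfg))  # errors if not positive definite
  cfg
}

scenario_sigma <- function(cfg) {
  d <- cfg$d
  S <- diag(cfg$sigma_diag, d)
  S[1L, 2L] <- S[2L, 1L] <- cfg$sigma_12
  if (d >= 3L)
    for (j in 3:d) S[j - 1L, j] <- S[j, j - 1L] <- cfg$sigma_band
  S
}

#' Simulate trajectories from a benchmark scenario
#'
#' Draws `n` independent trajectories: `X_1 ~ N(0, Sigma)`,
#' `Xtilde_1 = X_1`; at each stage the action comes from the behavior
#' policy (equal probabilities) or from a supplied policy (with the policy's
#' own probability recorded as `behavior_prob`); the next state follows the
#' scenario dynamics driven by the EWMA state, and the stage-`t` reward is
#' computed from the stage-`t+1` state and the stage-`t` action.  Internally
#' the state sequence runs to `T + 1`; the returned dataset has `T` stages.
#'
#' @param cfg a [scenario_config()].
#' @param policy `"behavior"` or a [policy_params()] to generate actions
#'   from.
#' @return a [trajectory_dataset()].
#' @export
simulate_trajectories <- function(cfg, policy = "behavior") {
  local_seed(cfg$seed, simulate_impl(cfg, policy))
}

simulate_impl <- function(cfg, policy) {
  n <- cfg$n; T_ <- cfg$T; d <- cfg$d
  L <- chol(scenario_sigma(cfg))
  X <- matrix(stats::rnorm(n * d), n, d) %*% L
  Xt <- X                                  # EWMA state
  feats <- array(NA_real_, dim = c(n, T_, d))
  actions <- rewards <- bprob <- matrix(NA_real_, n, T_)
  for (t in seq_len(T_)) {
    feats[, t, ] <- X
    if (identical(policy, "behavior")) {
      A <- ifelse(stats::runif(n) < cfg$behavior_prob, 1, -1)
      bp <- rep(cfg$behavior_prob, n)
    } else {
      p1 <- stats::plogis(decision_score_mat(policy, X) / policy$tau)
      A <- ifelse(stats::runif(n) < p1, 1, -1)
      bp <- ifelse(A == 1, p1, 1 - p1)
    }
    eps <- matrix(stats::rnorm(n * d, sd = cfg$innovation_sd), n, d)
    Xn <- matrix(NA_real_, n, d)
    if (cfg$scenario == 1L) {
      Xn[, 1L] <- 0.8 * Xt[, 1L] + 0.3 * A * Xt[, 1L] + 0.2 * Xt[, 2L] +
        eps[, 1L]
      Xn[, 2L] <- 0.8 * Xt[, 2L] - 0.3 * A * Xt[, 2L] +
        A * tanh((Xt[, 1L] - Xt[, 2L]) / 2) + eps[, 2L]
    } else {
      Xn[, 1L] <- 0.8 * Xt[, 1L] + 0.3 * A * Xt[, 1L] + 0.1 * Xt[, 2L] +
        eps[, 1L]
      Xn[, 2L] <- 0.8 * Xt[, 1L] + 0.2 * A * Xt[, 2L] + 0.2 * Xt[, 2L] +
        eps[, 2L]
    }
    if (d >= 3L)
      Xn[, 3:d] <- 0.9 * Xt[, 3:d, drop = FALSE] + eps[, 3:d, drop = FALSE]
    R <- if (cfg$scenario == 1L)
      log1p(exp(Xn[, 1L] + Xn[, 2L])) - 0.5 * A
    else
      Xn[, 1L] + Xn[, 2L] - 0.6 * A
    actions[, t] <- A
    rewards[, t] <- R
    bprob[, t] <- bp
    Xt <- cfg$ewma_old * Xt + cfg$ewma_new * Xn
    X <- Xn
  }
  trajectory_dataset(feats, actions, rewards, bprob, p0 = 1e-12)
}

#' On-policy Monte Carlo policy evaluation
#'
#' Simulates `n_eval` fresh trajectories with actions drawn from the policy
#' and reports the mean per-stage (average) reward `Vbar = V / T` with its
#' Monte Carlo standard error (subject-level SD over `sqrt(n_eval)`).
#'
#' @param cfg a [scenario_config()]; its `n` is replaced by `n_eval`.
#' @param policy a [policy_params()] or `"behavior"`.
#' @param n_eval evaluation sample size (the reference protocol uses
#'   200,000; tests scale this down).
#' @param seed optional seed overriding `cfg$seed`.
#' @return a list with `mean_average_reward`, `se`, `n_eval`.
#' @export
evaluate_on_policy <- function(cfg, policy, n_eval = 200000L,
                               seed = cfg$seed) {
  cfg$n <- as.integer(n_eval)
  cfg$seed <- as.integer(seed)
  ds <- simulate_trajectories(cfg, policy)
  avg <- rowMeans(ds$rewards)
  list(mean_average_reward = mean(avg),
       se = stats::sd(avg) / sqrt(length(avg)),
       n_eval = as.integer(n_eval))
}

#' Normalized-IPW policy value on held-out data
#'
#' Off-policy estimate of the average reward of `policy` from behavior-policy
#' data: `(1/T) sum_t mean_i [ (rho_{i,1:t} / omega_{1:t}) R_{i,t} ]` with
#' weighted-importance-sampling normalization; the standard error comes from
#' the per-subject contributions.
#'
#' @param ds_test a [trajectory_dataset()] collected under the behavior
#'   policy.
#' @param policy a [policy_params()].
#' @return a list with `mean_average_reward`, `se`, `n_eval`.
#' @export
ipw_value <- function(ds_test, policy) {
  rho <- stepwise_weights(policy, ds_test)
  nw <- normalized_weights(rho)$normalized
  contrib <- rowSums(nw[, -1L, drop = FALSE] * ds_test$rewards) / ds_test$T
  list(mean_average_reward = mean(contrib),
       se = stats::sd(contrib) / sqrt(ds_test$n),
       n_eval = ds_test$n)
}

#' Locate the optimal policy parameter by grid search on the sphere
#'
#' Evaluates the on-policy Monte Carlo value over a grid of unit-norm
#' parameter vectors supported on a declared active set of coordinates
#' (default: intercept plus the two reward-relevant features; the remaining
#' coordinates are irrelevant to the reward by construction) and returns the
#' maximizer.  For `T = 1` the search uses common random numbers and exact
#' enumeration over both actions, which removes action-sampling noise from
#' the comparison; for `T > 1` each grid point is evaluated by independent
#' on-policy simulation.
#'
#' @param cfg a [scenario_config()].
#' @param grid_resolution angular resolution (radians) of the sphere grid.
#' @param n_eval Monte Carlo size per evaluation.
#' @param active integer coordinates (0-based, 0 = intercept) allowed to be
#'   nonzero; must have length 3 and include the intercept.
#' @param tau policy scaling parameter for the candidate policies.
#' @return a [policy_params()] for the best grid point, with attributes
#'   `value` (its estimated value) and `table` (values of the best 20 grid
#'   points).
#' @export
grid_search_theta_star <- function(cfg, grid_resolution = 0.05,
                                   n_eval = 10000L, active = c(0L, 1L, 2L),
                                   tau = 0.2) {
  if (length(active) != 3L)
    stop("the sphere grid is parameterized for exactly 3 active coordinates")
  ph1 <- seq(0, pi, by = grid_resolution)
  ph2 <- seq(0, 2 * pi - grid_resolution / 2, by = grid_resolution)
  grid <- cbind(cos(rep(ph1, each = length(ph2))),
                sin(rep(ph1, each = length(ph2))) * cos(ph2),
                sin(rep(ph1, each = length(ph2))) * sin(ph2))
  # poles duplicate across ph2; deduplicate
  grid <- unique(round(grid, 10))
  if (nrow(grid) == 0L) stop("empty grid")
  vals <- if (cfg$T == 1L)
    grid_values_t1(cfg, grid, n_eval, active, tau)
  else
    vapply(seq_len(nrow(grid)), function(g) {
      th <- numeric(cfg$d + 1L)
      th[active + 1L] <- grid[g, ]
      evaluate_on_policy(cfg, policy_params(th, tau), n_eval,
                         seed = cfg$seed)$mean_average_reward
    }, numeric(1L))
  best <- which.max(vals)
  th <- numeric(cfg$d + 1L)
  th[active + 1L] <- grid[best, ]
  ord <- order(vals, decreasing = TRUE)[seq_len(min(20L, length(vals)))]
  structure(policy_params(th, tau),
            value = vals[best],
            table = data.frame(theta0 = grid[ord, 1L],
                               theta_a = grid[ord, 2L],
                               theta_b = grid[ord, 3L],
                               value = vals[ord]))
}

# T = 1 fast path: one shared draw of initial states and innovations; the
# value of each grid point is the exact expectation over the binary action
# given those draws (Rao-Blackwellized on-policy Monte Carlo).
grid_values_t1 <- function(cfg, grid, n_eval, active, tau) {
  sim <- local_seed(cfg$seed, {
    L <- chol(scenario_sigma(cfg))
    X <- matrix(stats::rnorm(n_eval * cfg$d), n_eval, cfg$d) %*% L
    eps <- matrix(stats::rnorm(n_eval * 2L, sd = cfg$innovation_sd),
                  n_eval, 2L)
    list(X = X, eps = eps)
  })
  X <- sim$X; eps <- sim$eps
  r_given_a <- function(A) {
    if (cfg$scenario == 1L) {
      x1 <- 0.8 * X[, 1L] + 0.3 * A * X[, 1L] + 0.2 * X[, 2L] + eps[, 1L]
      x2 <- 0.8 * X[, 2L] - 0.3 * A * X[, 2L] +
        A * tanh((X[, 1L] - X[, 2L]) / 2) + eps[, 2L]
      log1p(exp(x1 + x2)) - 0.5 * A
    } else {
      x1 <- 0.8 * X[, 1L] + 0.3 * A * X[, 1L] + 0.1 * X[, 2L] + eps[, 1L]
      x2 <- 0.8 * X[, 1L] + 0.2 * A * X[, 2L] + 0.2 * X[, 2L] + eps[, 2L]
      x1 + x2 - 0.6 * A
    }
  }
  Rp <- r_given_a(1)
  Rm <- r_given_a(-1)
  # features entering the decision score for the active coordinates
  Z <- cbind(if (0L %in% active) 1, X[, setdiff(active, 0L), drop = FALSE])
  vals <- numeric(nrow(grid))
  block <- 500L
  for (s in seq(1L, nrow(grid), by = block)) {
    e <- min(s + block - 1L, nrow(grid))
    G <- Z %*% t(grid[s:e, , drop = FALSE])
    P1 <- stats::plogis(G / tau)
    vals[s:e] <- colMeans(P1 * Rp + (1 - P1) * Rm)
  }
  vals
}
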