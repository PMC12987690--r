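#' Stochastic sigmoid policy parameters
#'
#' The policy class assigns action `a` in `{-1, +1}` with probability
#' `exp(a g(x, theta)/tau) / (1 + exp(a g(x, theta)/tau))`, where
#' `g(x, theta) = theta_0 + sum_j x_j theta_j` is a linear decision score and
#' `tau > 0` is a fixed scaling constant: small `tau` approaches a
#' deterministic rule `sign(g)`.  The parameter vector is constrained to the
#' L2 unit ball; final sparse estimates lie on the unit sphere.
#'
#' @param theta numeric vector of length `d + 1`; `theta[1]` is the intercept
#'   `theta_0`, the remainder are feature coefficients `theta_1..theta_d`.
#' @param tau positive scaling parameter (default 0.2, the value used
#'   throughout the package's simulations).
#' @return an object of class `policy_params`.
#' @export
policy_params <- function(theta, tau = 0.2) {
  theta <- as.numeric(theta)
  if (anyNA(theta) || any(!is.finite(theta)))
    stop("`theta` must be finite")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be a positive scalar")
  nrm <- sqrt(sum(theta^2))
  if (nrm > 1 + 1e-8)
    stop(sprintf("||theta||_2 = %g exceeds the unit-ball constraint", nrm))
  structure(list(theta = theta, tau = tau), class = "policy_params")
}

#' @export
print.policy_params <- function(x, ...) {
  cat(sprintf("<policy_params> d = %d, tau = %g, ||theta||_2 = %.6f\n",
              length(x$theta) - 1L, x$tau, sqrt(sum(x$theta^2))))
  print(stats::setNames(x$theta, c("(intercept)",
                                   paste0("theta", seq_len(length(x$theta) - 1L)))))
  invisible(x)
}

#' Linear decision score
#'
#' Computes `g(x, theta) = theta_0 + sum_j x_j theta_j`.
#'
#' @param policy a [policy_params()].
#' @param x numeric feature vector of length `d`, or an `m x d` matrix for
#'   vectorized evaluation.
#' @return a numeric scalar (or length-`m` vector).
#' @export
decision_score <- function(policy, x) {
  theta <- policy$theta
  d <- length(theta) - 1L
  if (is.matrix(x)) {
    if (ncol(x) != d) stop("feature length mismatch")
    return(as.numeric(theta[1L] + x %*% theta[-1L]))
  }
  if (length(x) != d) stop("feature length mismatch")
  theta[1L] + sum(x * theta[-1L])
}

#' Policy action probability
#'
#' `pi_theta(a | x) = plogis(a g(x, theta) / tau)`, strictly inside (0, 1).
#'
#' @inheritParams decision_score
#' @param a action, `-1` or `+1` (scalar or vector conformable with `x`).
#' @return probability of taking action `a` at feature `x`.
#' @export
action_prob <- function(policy, x, a) {
  if (!all(a == -1 | a == 1)) stop("`a` must be -1 or +1")
  g <- decision_score(policy, x)
  stats::plogis(a * g / policy$tau)
}

#' Sample an action from the policy
#'
#' Draws `+1` with probability `action_prob(policy, x, +1)`, else `-1`,
#' using the current RNG state (seed with `set.seed()` for reproducibility).
#'
#' @inheritParams decision_score
#' @return an action in `{-1, +1}` (vectorized over matrix `x`).
#' @export
sample_action <- function(policy, x) {
  p1 <- action_prob(policy, x, 1)
  ifelse(stats::runif(length(p1)) < p1, 1, -1)
}

#' Step-wise importance sampling weights
#'
#' For each subject `i` and stage `t`, the cumulative product over stages
#' `k = 1..t` of `pi_theta(A_{i,k} | X_{i,k}) / mu_k(A_{i,k} | H_{i,k})` --
#' the step-wise importance weight of the target policy against the behavior
#' policy.  Column `t = 0` is the empty product, identically 1.  Products are
#' accumulated in log space to survive long horizons.
#'
#' @param policy a [policy_params()].
#' @param ds a [trajectory_dataset()].
#' @param cap optional positive cap applied to each cumulative weight
#'   (default `Inf`: no truncation; stabilization is normally done via
#'   [normalized_weights()], not truncation).
#' @return an `n x (T + 1)` matrix; column `t + 1` holds `rho_{i,1:t}`.
#' @export
stepwise_weights <- function(policy, ds, cap = Inf) {
  validate_trajectories(ds)
  if (any(ds$behavior_prob <= 0)) stop("behavior_prob must be positive")
  n <- ds$n; T_ <- ds$T
  G <- score_matrix(policy, ds)
  logpi <- stats::plogis(ds$actions * G / policy$tau, log.p = TRUE)
  logstep <- logpi - log(ds$behavior_prob)
  logrho <- logstep
  if (T_ > 1L)
    for (t in 2:T_) logrho[, t] <- logrho[, t - 1L] + logstep[, t]
  rho <- cbind(1, exp(logrho))
  if (is.finite(cap)) rho <- pmin(rho, cap)
  colnames(rho) <- paste0("t", 0:T_)
  rho
}

# n x T matrix of decision scores g(X_{i,t}, theta).
score_matrix <- function(policy, ds) {
  theta <- policy$theta
  if (length(theta) != ds$d + 1L) stop("feature length mismatch")
  Xcat <- matrix(ds$features, nrow = ds$n * ds$T, ncol = ds$d)
  matrix(theta[1L] + Xcat %*% theta[-1L], ds$n, ds$T)
}

#' Weighted importance sampling normalization
#'
#' Divides each step-wise weight by its cross-subject average
#' `omega_{1:t} = mean_i rho_{i,1:t}`, so that the normalized weights average
#' exactly to 1 at every stage.  This is the weighted-importance-sampling
#' stabilization used throughout the estimators.
#'
#' @param rho an `n x (T + 1)` weight matrix from [stepwise_weights()]
#'   (column 1 is the `t = 0` convention column).
#' @return a list with `omega` (length `T + 1`, `omega[1] = 1`) and
#'   `normalized` (same shape as `rho`).
#' @export
normalized_weights <- function(rho) {
  if (any(rho < 0)) stop("weights must be nonnegative")
  omega <- colMeans(rho)
  if (any(omega <= 0)) stop("degenerate all-zero weight column")
  normalized <- sweep(rho, 2L, omega, "/")
  list(omega = omega, normalized = normalized)
}
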