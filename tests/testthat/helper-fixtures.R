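# Shared fixtures and independent oracles for the test suite.  Everything is
# generated in code under fixed seeds; no stored data files.

# Small random MRT-like dataset with constant behavior probability mu.
make_toy_ds <- function(n, T_, d, seed = 1, mu = 0.5, reward_sd = 1) {
  set.seed(seed)
  feats <- array(stats::rnorm(n * T_ * d), c(n, T_, d))
  acts <- matrix(sample(c(-1, 1), n * T_, replace = TRUE), n, T_)
  rews <- matrix(stats::rnorm(n * T_, sd = reward_sd), n, T_)
  bp <- matrix(mu, n, T_)
  trajectory_dataset(feats, acts, rews, bp)
}

# Nuisance model with random coefficients (still a valid model: the AIPW
# loss must be unbiased for ANY Q).
make_random_nuisance <- function(ds, theta_check, seed = 1, sd = 0.5,
                                 method = 1L) {
  set.seed(seed)
  basis <- basis_spec(ds$d)
  betas <- replicate(ds$T, stats::rnorm(2L * basis$d_prime, sd = sd),
                     simplify = FALSE)
  mstpolicy:::new_nuisance(method, betas, basis, theta_check)
}

# Analytic gradient and Hessian of the UNNORMALIZED, zero-augmentation loss
#   l(theta) = -(1/n) sum_i sum_t rho_{i,1:t} R_{i,t},
# derived by hand from d log pi / d theta_j = (a xt_j / tau)(1 - pi) and
# d^2 log pi = -(xt xt' / tau^2) pi (1 - pi).  Independent of the package's
# difference-quotient code path.
analytic_m0_derivs <- function(ds, theta, tau) {
  p <- ds$d + 1L
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  for (i in seq_len(ds$n)) {
    S <- numeric(p)
    M2 <- matrix(0, p, p)
    logrho <- 0
    for (t in seq_len(ds$T)) {
      xt <- c(1, ds$features[i, t, ])
      a <- ds$actions[i, t]
      g <- sum(xt * theta)
      pi_k <- stats::plogis(a * g / tau)
      logrho <- logrho + log(pi_k) - log(ds$behavior_prob[i, t])
      S <- S + (a / tau) * (1 - pi_k) * xt
      M2 <- M2 - (pi_k * (1 - pi_k) / tau^2) * tcrossprod(xt)
      rho <- exp(logrho)
      grad <- grad - (1 / ds$n) * rho * ds$rewards[i, t] * S
      hess <- hess - (1 / ds$n) * rho * ds$rewards[i, t] * (tcrossprod(S) + M2)
    }
  }
  list(grad = grad, hess = hess)
}

# Brute-force unnormalized m = 0 loss: explicit product-and-sum, no
# log-space tricks.
brute_force_m0_loss <- function(ds, theta, tau) {
  per <- numeric(ds$n)
  for (i in seq_len(ds$n)) {
    acc <- 0
    rho <- 1
    for (t in seq_len(ds$T)) {
      g <- theta[1] + sum(ds$features[i, t, ] * theta[-1])
      pi_t <- exp(ds$actions[i, t] * g / tau) /
        (1 + exp(ds$actions[i, t] * g / tau))
      rho <- rho * pi_t / ds$behavior_prob[i, t]
      acc <- acc + rho * ds$rewards[i, t]
    }
    per[i] <- -acc
  }
  list(per_subject = per, loss = mean(per))
}

# Random symmetric positive-definite matrix.
random_spd <- function(p, seed, ridge = 0.1) {
  set.seed(seed)
  M <- crossprod(matrix(stats::rnorm(p * p), p)) / p
  M + diag(ridge, p)
}

# Lightweight fit configuration for tests.
test_cfg <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_lambda = 6L, n_starts = 3L, max_iter = 30L,
                   cv_folds = 3L, seed = seed)
  defaults[names(args)] <- args
  do.call(fit_config, defaults)
}
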