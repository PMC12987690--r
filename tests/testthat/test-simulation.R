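test_that("initial states match the declared covariance structure", {
  sc <- scenario_config(1, n = 10000, T = 1, d = 5, seed = 110)
  ds <- simulate_trajectories(sc)
  X1 <- ds$features[, 1, ]
  # sample variance of a N(0, 4) variable: sd(s^2) ~ sqrt(2) * 4 / sqrt(n)
  se_var <- sqrt(2) * 4 / sqrt(10000)
  for (j in 1:5)
    expect_lt(abs(stats::var(X1[, j]) - 4), 3 * se_var)
  se_cov <- sqrt((4 * 4 + 1^2) / 10000)
  expect_lt(abs(stats::cov(X1[, 1], X1[, 2]) - 1), 3 * se_cov)
  se_cov2 <- sqrt((4 * 4 + 0.2^2) / 10000)
  expect_lt(abs(stats::cov(X1[, 3], X1[, 4]) - 0.2), 3 * se_cov2)
  expect_lt(abs(stats::cov(X1[, 1], X1[, 4])), 3 * sqrt(16 / 10000))
  expect_error(scenario_config(3, 10, 1), "scenario")
  expect_error(scenario_config(1, 10, 1, d = 1), "d must be")
})

test_that("the generator reproduces a hand-rolled two-stage trace", {
  # independently re-derive the whole trajectory from the same RNG stream:
  # EWMA state, dynamics, and the reward alignment R_t = f(X_{t+1}) - c A_t
  for (scenario in 1:2) {
    sc <- scenario_config(scenario, n = 4, T = 2, d = 3, seed = 120)
    ds <- simulate_trajectories(sc)
    set.seed(120)
    n <- 4; d <- 3
    L <- chol(mstpolicy:::scenario_sigma(sc))
    X <- matrix(stats::rnorm(n * d), n, d) %*% L
    Xt <- X                                      # EWMA state at t = 1 is X_1
    for (t in 1:2) {
      expect_equal(ds$features[, t, ], unname(X))
      A <- ifelse(stats::runif(n) < 0.5, 1, -1)
      expect_true(all(ds$actions[, t] == A))
      eps <- matrix(stats::rnorm(n * d, sd = 0.4), n, d)
      Xn <- matrix(0, n, d)
      if (scenario == 1) {
        Xn[, 1] <- 0.8 * Xt[, 1] + 0.3 * A * Xt[, 1] + 0.2 * Xt[, 2] + eps[, 1]
        Xn[, 2] <- 0.8 * Xt[, 2] - 0.3 * A * Xt[, 2] +
          A * tanh((Xt[, 1] - Xt[, 2]) / 2) + eps[, 2]
        R <- log(1 + exp(Xn[, 1] + Xn[, 2])) - 0.5 * A
      } else {
        Xn[, 1] <- 0.8 * Xt[, 1] + 0.3 * A * Xt[, 1] + 0.1 * Xt[, 2] + eps[, 1]
        Xn[, 2] <- 0.8 * Xt[, 1] + 0.2 * A * Xt[, 2] + 0.2 * Xt[, 2] + eps[, 2]
        R <- Xn[, 1] + Xn[, 2] - 0.6 * A
      }
      Xn[, 3] <- 0.9 * Xt[, 3] + eps[, 3]
      expect_equal(ds$rewards[, t], R)
      expect_equal(ds$behavior_prob[, t], rep(0.5, n))
      Xt <- 0.2 * Xt + 0.8 * Xn
      X <- Xn
    }
  }
})

test_that("noise coordinates evolve independently of the actions", {
  sc <- scenario_config(2, n = 8000, T = 2, d = 5, seed = 130)
  ds <- simulate_trajectories(sc)
  # X_{t=2, j>=3} is driven only by its own lag: no correlation with A_1
  for (j in 3:5) {
    r <- stats::cor(ds$features[, 2, j], ds$actions[, 1])
    expect_lt(abs(r), 3 / sqrt(8000))
  }
  # behavior data satisfy positivity at p0 = 0.5
  expect_silent(validate_trajectories(ds, p0 = 0.5))
})

test_that("rewards depend on past states beyond the current ones", {
  # the stated Markov violation: R_2 correlates with stage-1 features even
  # after regressing out the stage-2 features
  sc <- scenario_config(2, n = 6000, T = 2, d = 3, seed = 131)
  ds <- simulate_trajectories(sc)
  res <- stats::residuals(stats::lm(ds$rewards[, 2] ~ ds$features[, 2, ] +
                                      ds$actions[, 2]))
  r <- stats::cor(res, ds$features[, 1, 1])
  expect_gt(abs(r), 3 / sqrt(6000))
})

test_that("on-policy evaluation is consistent across seeds and centered for
           the behavior policy", {
  sc <- scenario_config(2, n = 1, T = 1, d = 4, seed = 140)
  zero <- policy_params(numeric(5), tau = 0.2)   # behaves like the behavior policy
  e1 <- evaluate_on_policy(sc, zero, n_eval = 20000, seed = 141)
  e2 <- evaluate_on_policy(sc, zero, n_eval = 20000, seed = 142)
  expect_lt(abs(e1$mean_average_reward - e2$mean_average_reward),
            3 * sqrt(e1$se^2 + e2$se^2))
  # Scenario 2, T = 1, random actions: E[R] = E[1.6 X1 + 0.3 X2] + 0 = 0
  expect_lt(abs(e1$mean_average_reward), 3 * e1$se)
  expect_gt(e1$se, 0)
})

test_that("normalized IPW agrees with on-policy Monte Carlo", {
  sc <- scenario_config(2, n = 20000, T = 2, d = 4, seed = 150)
  ds <- simulate_trajectories(sc)
  th <- c(-0.5, 0.6, 0.3, 0, 0)
  pol <- policy_params(th / sqrt(sum(th^2)), tau = 0.2)
  est_ipw <- ipw_value(ds, pol)
  est_mc <- evaluate_on_policy(sc, pol, n_eval = 50000, seed = 151)
  expect_lt(abs(est_ipw$mean_average_reward - est_mc$mean_average_reward),
            3 * sqrt(est_ipw$se^2 + est_mc$se^2))
  # policy = behavior (theta = 0): weights are 1, estimate is the plain mean
  zero <- policy_params(numeric(5), tau = 0.2)
  expect_equal(ipw_value(ds, zero)$mean_average_reward,
               mean(rowMeans(ds$rewards)), tolerance = 1e-12)
  # a single subject: that subject's average reward
  ds1 <- mstpolicy:::subset_subjects(ds, 7L)
  expect_equal(ipw_value(ds1, pol)$mean_average_reward,
               mean(ds1$rewards), tolerance = 1e-12)
})

test_that("grid search maximizes the on-policy value over the sphere grid", {
  sc <- scenario_config(2, n = 1, T = 1, d = 4, seed = 160)
  # a one-point grid returns that point
  g1 <- grid_search_theta_star(sc, grid_resolution = 4, n_eval = 500)
  expect_equal(g1$theta[1:3], c(1, 0, 0))
  # the optimum beats the behavior policy, and refining the (nested) grid
  # never lowers the best value under common random numbers
  coarse <- grid_search_theta_star(sc, grid_resolution = 0.4, n_eval = 4000)
  fine <- grid_search_theta_star(sc, grid_resolution = 0.2, n_eval = 4000)
  expect_gte(attr(fine, "value"), attr(coarse, "value") - 1e-12)
  zero_val <- evaluate_on_policy(sc, policy_params(numeric(5), 0.2),
                                 n_eval = 20000, seed = 161)
  expect_gt(attr(fine, "value") + 3 * zero_val$se,
            zero_val$mean_average_reward)
  # the optimal rule's signs: negative intercept, positive slopes
  expect_lt(fine$theta[1], 0)
  expect_gt(fine$theta[2], 0)
})
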