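test_that("basis features concatenate main effects and action interactions", {
  b <- basis_spec(2)
  expect_equal(b$d_prime, 3L)
  expect_equal(basis_features(b, c(3, 4), 1), c(1, 3, 4, 1, 3, 4))
  expect_equal(basis_features(b, c(3, 4), -1), c(1, 3, 4, -1, -3, -4))
  # action blocks cancel over the two actions
  s <- basis_features(b, c(3, 4), 1) + basis_features(b, c(3, 4), -1)
  expect_equal(s[4:6], c(0, 0, 0))
  expect_error(basis_features(b, c(3, 4), 0), "-1 or \\+1")
  expect_error(basis_features(b, c(3, 4, 5), 1), "mismatch")
})

test_that("zero-augmentation model kills the augmentation exactly", {
  ds <- make_toy_ds(6, 2, 3, seed = 20)
  m0 <- fit_q_zero(ds)
  expect_equal(m0$method, 0L)
  expect_equal(predict_q(m0, ds$features[1, 1, ], 1, 2), 0)
  pol <- policy_params(c(0.2, 0.3, -0.1, 0.4), tau = 0.2)
  expect_equal(predict_u(m0, pol, ds$features[2, 2, ], 1), 0)
  # loss with m = 0 equals the plain (unaugmented) IPW loss
  ctx0 <- loss_context(ds, m0, use_normalized_weights = FALSE)
  rho <- stepwise_weights(pol, ds)
  ipw <- -mean(rowSums(rho[, -1] * ds$rewards))
  expect_equal(loss(ctx0, pol), ipw, tolerance = 1e-12)
})

test_that("backward fitting recovers a linear reward model at T = 1", {
  set.seed(21)
  n <- 2000; d <- 4
  basis <- basis_spec(d)
  beta_star <- c(1, 0.8, 0, -0.5, 0, 0.6, 0.9, 0, 0, 0)   # sparse truth
  feats <- array(stats::rnorm(n * d), c(n, 1, d))
  acts <- matrix(sample(c(-1, 1), n, replace = TRUE), n, 1)
  Phi <- mstpolicy:::phi_matrix(basis, feats[, 1, ], acts[, 1])
  rews <- matrix(Phi %*% beta_star + stats::rnorm(n, sd = 0.5), n, 1)
  ds <- trajectory_dataset(feats, acts, rews, matrix(0.5, n, 1))
  pol <- policy_params(numeric(d + 1), tau = 0.2)
  nm <- fit_q_backward(ds, basis, pol, seed = 22)
  expect_equal(nm$method, 1L)
  # oracle: OLS on the true support gives coefficient SEs
  fit <- stats::lm(rews[, 1] ~ Phi[, which(beta_star != 0)] - 1)
  ses <- summary(fit)$coefficients[, 2]
  est_on_support <- nm$betas[[1]][which(beta_star != 0)]
  expect_true(all(abs(est_on_support - beta_star[beta_star != 0]) < 3 * ses))

  # zero rewards -> zero coefficients
  ds0 <- ds; ds0$rewards[] <- 0
  nm0 <- fit_q_backward(ds0, basis, pol, seed = 23)
  expect_equal(nm0$betas[[1]], numeric(2 * basis$d_prime))
})

test_that("backward fitting propagates the continuation value across stages", {
  # with lambda fixed to ~0 and n large, beta_t should solve the stage-t
  # least squares of R_t + E_pi[Q_{t+1}] computed by hand
  set.seed(24)
  n <- 400; d <- 2; T_ <- 2
  ds <- make_toy_ds(n, T_, d, seed = 24)
  basis <- basis_spec(d)
  pol <- policy_params(c(0.1, 0.5, -0.2), tau = 0.2)
  lam <- c(1e-8, 1e-8)
  nm <- fit_q_backward(ds, basis, pol, seed = 25, lambdas = lam)
  # stage 2 by hand: OLS of R_2 on Phi(X_2, A_2)
  Phi2 <- mstpolicy:::phi_matrix(basis, ds$features[, 2, ], ds$actions[, 2])
  b2 <- stats::coef(stats::lm(ds$rewards[, 2] ~ Phi2 - 1))
  expect_equal(unname(nm$betas[[2]]), unname(b2), tolerance = 1e-4)
  # stage 1 by hand: pseudo-response uses pi-weighted stage-2 prediction
  p1 <- stats::plogis(decision_score(pol, ds$features[, 2, ]) / pol$tau)
  qp <- mstpolicy:::phi_matrix(basis, ds$features[, 2, ], rep(1, n)) %*% nm$betas[[2]]
  qm <- mstpolicy:::phi_matrix(basis, ds$features[, 2, ], rep(-1, n)) %*% nm$betas[[2]]
  q1 <- ds$rewards[, 1] + p1 * qp + (1 - p1) * qm
  Phi1 <- mstpolicy:::phi_matrix(basis, ds$features[, 1, ], ds$actions[, 1])
  b1 <- stats::coef(stats::lm(q1 ~ Phi1 - 1))
  expect_equal(unname(nm$betas[[1]]), unname(b1), tolerance = 1e-4)
})

test_that("variance-minimizing fit uses the documented contrast design", {
  ds <- make_toy_ds(3, 1, 2, seed = 26)
  basis <- basis_spec(2)
  pol <- policy_params(numeric(3), tau = 0.2)   # pi = mu = 0.5 -> rho = 1
  lam <- 0.05
  nm <- fit_q_varmin(ds, basis, pol, seed = 27, lambdas = lam)
  # hand-built design: rho-tilde = 1, so design = Phi(obs) - mean_a Phi(a)
  X <- ds$features[, 1, ]
  Phi_obs <- mstpolicy:::phi_matrix(basis, X, ds$actions[, 1])
  Phi_avg <- (mstpolicy:::phi_matrix(basis, X, rep(1, 3)) +
              mstpolicy:::phi_matrix(basis, X, rep(-1, 3))) / 2
  design <- Phi_obs - Phi_avg
  oracle <- mstpolicy:::lasso_refit(design, ds$rewards[, 1],
                                    foldid = 1:3, lambda = lam)
  expect_equal(nm$betas[[1]], oracle$beta, tolerance = 1e-10)

  # zero rewards -> zero fit
  ds0 <- ds; ds0$rewards[] <- 0
  nm0 <- fit_q_varmin(ds0, basis, pol, seed = 28, lambdas = lam)
  expect_equal(nm0$betas[[1]], numeric(2 * basis$d_prime))
})

test_that("predictions follow the linear model and the exact U identity", {
  b <- basis_spec(2)
  beta <- c(1, 0, 0, 0, 0, 0)                 # unit intercept coordinate
  nm <- mstpolicy:::new_nuisance(1L, list(beta), b, NULL)
  expect_equal(predict_q(nm, c(9, -9), 1, 1), 1)
  expect_equal(predict_q(nm, c(9, -9), -1, 1), 1)
  expect_error(predict_q(nm, c(1, 2), 1, 2), "out of range")

  beta2 <- c(0.5, 2, -1, 0.3, 1, -2)
  nm2 <- mstpolicy:::new_nuisance(1L, list(beta2), b, NULL)
  x <- c(1.5, -0.5)
  expect_equal(predict_q(nm2, x, -1, 1),
               sum(c(1, x, -1, -x) * beta2))

  # theta = 0 -> U is the plain average of the two Q values
  zero <- policy_params(numeric(3), tau = 0.2)
  expect_equal(predict_u(nm2, zero, x, 1),
               (predict_q(nm2, x, 1, 1) + predict_q(nm2, x, -1, 1)) / 2)

  # U is the exact pi-expectation of Q for random models and policies
  set.seed(29)
  for (k in 1:10) {
    th <- stats::rnorm(3); th <- th / sqrt(sum(th^2)) * stats::runif(1)
    p <- policy_params(th, tau = 0.2)
    bet <- stats::rnorm(6)
    nmk <- mstpolicy:::new_nuisance(1L, list(bet), b, NULL)
    xk <- stats::rnorm(2)
    manual <- action_prob(p, xk, 1) * predict_q(nmk, xk, 1, 1) +
      action_prob(p, xk, -1) * predict_q(nmk, xk, -1, 1)
    expect_equal(predict_u(nmk, p, xk, 1), manual, tolerance = 1e-12)
    # constant-in-a Q: U = that constant for any theta
    bconst <- c(stats::rnorm(3), 0, 0, 0)
    nmc <- mstpolicy:::new_nuisance(1L, list(bconst), b, NULL)
    expect_equal(predict_u(nmc, p, xk, 1), predict_q(nmc, xk, 1, 1))
  }
})

test_that("support refitting never increases in-sample squared loss", {
  set.seed(30)
  n <- 80
  X <- cbind(1, matrix(stats::rnorm(n * 5), n))
  y <- X %*% c(1, 0.5, 0, 0, -0.3, 0) + stats::rnorm(n)
  lam <- 0.1
  gfit <- glmnet::glmnet(X, y, intercept = FALSE, standardize = FALSE,
                         lambda = lam)
  b_pen <- as.numeric(stats::coef(gfit, s = lam))[-1]
  refit <- mstpolicy:::lasso_refit(X, as.numeric(y), foldid = rep(1:4, 20),
                                   lambda = lam)
  expect_lte(sum((y - X %*% refit$beta)^2), sum((y - X %*% b_pen)^2) + 1e-10)
  # refit support includes the intercept column always
  expect_true(refit$beta[1] != 0 || all(refit$beta == 0))
})

test_that("nuisance models serialize to JSON and back", {
  ds <- make_toy_ds(10, 2, 3, seed = 31)
  pol <- policy_params(c(0.1, 0.2, -0.3, 0), tau = 0.2)
  nm <- fit_q_backward(ds, basis_spec(3), pol, seed = 32)
  path <- withr::local_tempfile(fileext = ".json")
  nuisance_to_json(nm, path)
  nm2 <- nuisance_from_json(path)
  expect_equal(nm2$method, nm$method)
  expect_equal(nm2$betas, nm$betas, tolerance = 1e-12)
  expect_equal(nm2$basis$d_prime, nm$basis$d_prime)
  expect_equal(nm2$theta_check$theta, nm$theta_check$theta)
})
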