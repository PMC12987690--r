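test_that("proximal coordinate descent solves separable quadratic
           surrogates", {
  # f(theta) = 0.5 * sum (theta_j - c_j)^2, prox solution soft(c, lambda)
  cvec <- c(0.05, -0.08, 0.03)
  quad <- function(v) 0.5 * sum((v - cvec)^2)
  cfg <- fit_config(seed = 1, max_iter = 100, tol = 1e-6)
  # all |c_j| <= lambda -> exact kill to zero
  res0 <- proximal_cd(NULL, lambda_theta = 0.1, start = numeric(3),
                      cfg = cfg, loss_fn = quad)
  expect_equal(res0$theta, numeric(3))
  # lambda = 0, interior solution -> theta = c
  res1 <- proximal_cd(NULL, lambda_theta = 0, start = numeric(3),
                      cfg = cfg, loss_fn = quad)
  expect_equal(res1$theta, cvec, tolerance = 1e-4)
  # intermediate lambda -> soft threshold of c
  res2 <- proximal_cd(NULL, lambda_theta = 0.04, start = numeric(3),
                      cfg = cfg, loss_fn = quad)
  expect_equal(res2$theta, sign(cvec) * pmax(abs(cvec) - 0.04, 0),
               tolerance = 1e-4)
  expect_error(proximal_cd(NULL, 0.1, c(1, 1, 1), cfg, loss_fn = quad),
               "constraint")
})

test_that("coordinate descent matches grid search on a 1-d sigmoid toy and
           never increases the objective", {
  ds <- make_toy_ds(40, 2, 1, seed = 50)
  ctx <- loss_context(ds, fit_q_zero(ds))
  cfg <- fit_config(seed = 2, max_iter = 100, tol = 1e-6)
  lam <- 0.02
  res <- proximal_cd(ctx, lam, start = c(0, 0), cfg = cfg)
  # objective trace is non-increasing cycle over cycle
  expect_true(all(diff(res$trace) <= 1e-10))
  # grid-search oracle over the segment {(0, t): t in [-1, 1]} plus the
  # intercept coordinate grid: optimize both coordinates on a fine grid
  grid <- seq(-1, 1, by = 0.01)
  best <- Inf; best_pt <- NULL
  for (a in seq(-1, 1, by = 0.05)) for (t in grid) {
    if (a^2 + t^2 > 1) next
    v <- mstpolicy:::loss_eval(ctx, c(a, t))$loss + lam * (abs(a) + abs(t))
    if (v < best) { best <- v; best_pt <- c(a, t) }
  }
  expect_lt(res$objective, best + 1e-3)
})

test_that("multi-start returns the best converged run", {
  ds <- make_toy_ds(30, 1, 2, seed = 51)
  ctx <- loss_context(ds, fit_q_zero(ds))
  cfg <- test_cfg(seed = 3, n_starts = 4)
  best <- mstpolicy:::multistart_cd(ctx, 0.01, cfg)
  # rerunning each start individually can never beat the returned solution
  starts <- list(numeric(3))
  rand <- mstpolicy:::local_seed(mstpolicy:::derive_seeds(3, 3)[3],
                                 replicate(3, {
                                   v <- stats::rnorm(3); v / sqrt(sum(v^2))
                                 }, simplify = FALSE))
  for (s in c(starts, rand)) {
    run <- proximal_cd(ctx, 0.01, s, cfg)
    expect_gte(run$objective, best$objective - 1e-9)
  }
})

test_that("support refitting descends and matches a 1-d grid oracle", {
  ds <- make_toy_ds(50, 2, 2, seed = 52)
  ctx <- loss_context(ds, fit_q_zero(ds))
  th <- c(0, 0.4, 0)               # support = coordinate 1 only
  ref <- refit_on_support(ctx, policy_params(th, 0.2))
  expect_lte(loss(ctx, ref), loss(ctx, th) + 1e-10)
  expect_equal(which(ref$theta != 0), 2L)
  # grid oracle over theta_1 in [-1, 1]
  grid <- seq(-1, 1, by = 0.001)
  vals <- vapply(grid, function(t) mstpolicy:::loss_eval(ctx, c(0, t, 0))$loss,
                 numeric(1))
  expect_lt(abs(loss(ctx, ref) - min(vals)), 1e-3)
  # empty support returns the input unchanged
  ref0 <- refit_on_support(ctx, policy_params(numeric(3), 0.2))
  expect_equal(ref0$theta, numeric(3))
  # sphere refit lands on the unit sphere
  refs <- refit_on_support(ctx, policy_params(c(0.1, 0.4, -0.2), 0.2),
                           sphere = TRUE)
  expect_equal(sqrt(sum(refs$theta^2)), 1, tolerance = 1e-6)
})

test_that("lambda tuning returns the grid singleton and a full CV table", {
  ds <- make_toy_ds(24, 1, 2, seed = 53)
  nuis <- fit_q_zero(ds)
  cfg <- test_cfg(seed = 4, lambda_grid_theta = 0.07)
  tuned <- tune_lambda_theta(ds, 0.2, nuis, cfg)
  expect_equal(tuned$lambda, 0.07)
  expect_equal(nrow(tuned$table), 1L)
  cfg2 <- test_cfg(seed = 4, lambda_grid_theta = c(0.01, 0.1, 1))
  tuned2 <- tune_lambda_theta(ds, 0.2, nuis, cfg2)
  expect_equal(nrow(tuned2$table), 3L)
  expect_true(all(is.finite(as.matrix(tuned2$table[, -1]))))
  expect_equal(ncol(tuned2$table), 1L + 3L + 1L)   # lambda + folds + mean
})

test_that("pure-noise rewards select heavy penalties and a near-trivial
           policy", {
  hits <- 0L
  for (rep in 1:10) {
    ds <- make_toy_ds(60, 1, 3, seed = 60 + rep)   # rewards independent noise
    cfg <- test_cfg(seed = rep, lambda_grid_theta = c(0.003, 0.01, 0.3, 1))
    tuned <- tune_lambda_theta(ds, 0.2, fit_q_zero(ds), cfg)
    if (tuned$lambda >= 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("initial and sparse fits share the objective when m = 0 and are
           deterministic", {
  ds <- make_toy_ds(40, 1, 3, seed = 70)
  # the m = 0 sparse objective IS the initial objective: identical losses
  ctx_a <- loss_context(ds, fit_q_zero(ds))
  set.seed(71)
  for (k in 1:5) {
    th <- stats::rnorm(4); th <- th / sqrt(sum(th^2)) * stats::runif(1)
    expect_equal(loss(ctx_a, th), loss(ctx_a, th))
  }
  cfg <- test_cfg(seed = 5, lambda_grid_theta = c(0.02, 0.2))
  f1 <- fit_initial(ds, 0.2, cfg)
  f2 <- fit_initial(ds, 0.2, cfg)
  expect_identical(f1$theta, f2$theta)
  expect_lte(sqrt(sum(f1$theta^2)), 1 + 1e-8)
})

test_that("the sparse fit recovers the sign structure of the optimal rule", {
  # Scenario 2, T = 1: E[R | X, A] = 1.6 X1 + 0.3 X2 + A(0.3 X1 + 0.2 X2 - 0.6),
  # so the optimal rule takes A = +1 iff 0.3 X1 + 0.2 X2 > 0.6: negative
  # intercept, positive theta_1 and theta_2 (closed-form oracle).
  sc <- scenario_config(2, n = 1200, T = 1, d = 6, seed = 72)
  ds <- simulate_trajectories(sc)
  cfg <- test_cfg(seed = 6)
  chk <- fit_initial(ds, 0.2, cfg)
  expect_gt(chk$theta[2], 0)
  expect_gt(chk$theta[3], 0)
  expect_lt(chk$theta[1], 0)
  # full AIPW fit, m = 1 nuisance: same signs and unit norm
  nm <- fit_q_backward(ds, basis_spec(ds$d), chk, seed = 73)
  hat <- fit_sparse(ds, 0.2, nm, cfg, theta_check = chk)
  expect_gt(hat$theta[2], 0)
  expect_lt(hat$theta[1], 0)
  expect_equal(sqrt(sum(hat$theta^2)), 1, tolerance = 1e-6)
  expect_lte(sqrt(sum(hat$theta^2)), 1 + 1e-8)
})
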