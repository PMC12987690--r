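#' Optimizer configuration
#'
#' @param lambda_grid_theta optional positive penalty grid for the policy
#'   L1 penalty; when `NULL`, a data-driven log-spaced grid is built from the
#'   gradient of the loss at zero.
#' @param n_lambda grid size when the grid is data-driven.
#' @param n_starts number of multi-start points (zero vector, the warm start
#'   when available, plus seeded random unit vectors).
#' @param max_iter maximum full coordinate-descent cycles.
#' @param tol convergence tolerance on the maximum coordinate change
#'   (must be `< 1e-2`).
#' @param cv_folds subject-level cross-validation folds.
#' @param cv_n_starts multi-start count used inside cross-validation fits
#'   (kept small; CV only ranks penalty levels).
#' @param seed master seed; all randomness (starts, folds, bootstrap)
#'   derives from it through named substreams.
#' @param curvature_floor lower bound on the coordinate-wise curvature used
#'   in the proximal step, preventing runaway steps in flat regions.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(lambda_grid_theta = NULL, n_lambda = 8L,
                       n_starts = 5L, max_iter = 50L, tol = 1e-4,
                       cv_folds = 5L, cv_n_starts = 1L, seed = 1L,
                       curvature_floor = 1e-2) {
  stopifnot(n_starts >= 1L, max_iter >= 1L, tol > 0, tol < 1e-2,
            cv_folds >= 2L, curvature_floor > 0)
  if (!is.null(lambda_grid_theta)) stopifnot(all(lambda_grid_theta > 0))
  structure(list(lambda_grid_theta = lambda_grid_theta, n_lambda = n_lambda,
                 n_starts = n_starts, max_iter = max_iter, tol = tol,
                 cv_folds = cv_folds, cv_n_starts = cv_n_starts,
                 seed = as.integer(seed), curvature_floor = curvature_floor),
            class = "fit_config")
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Proximal coordinate descent on the unit ball
#'
#' Cycles over coordinates `j = 0..d`; each update builds a local quadratic
#' model of the loss from symmetric-difference first and second quotients at
#' the current point and applies a soft-thresholding (proximal) step, with
#' curvature floored at `cfg$curvature_floor` and geometric curvature
#' backtracking so that the penalized objective never increases.  After each
#' full cycle the iterate is projected onto the unit ball (divided by its L2
#' norm when the norm exceeds one); a projection that would increase the
#' objective terminates the descent at the previous feasible iterate.
#' Terminates when the maximum coordinate change falls below `cfg$tol` or
#' after `cfg$max_iter` cycles.
#'
#' @param ctx a [loss_context()] (or any object whose `loss` can be
#'   evaluated through [loss()]).
#' @param lambda_theta nonnegative L1 penalty.
#' @param start numeric start vector (length `d + 1`) with
#'   `||start||_2 <= 1`.
#' @param cfg a [fit_config()].
#' @param loss_fn optional plain function `theta -> loss` overriding the
#'   context loss (used by tests with synthetic surrogates).
#' @return a list with `theta`, `objective` (final penalized value),
#'   `trace` (penalized objective after each cycle), `converged`,
#'   `iterations`.
#' @export
proximal_cd <- function(ctx, lambda_theta, start, cfg = fit_config(),
                        loss_fn = NULL) {
  f <- if (is.null(loss_fn)) function(th) loss_eval(ctx, th)$loss else loss_fn
  h <- if (is.null(loss_fn)) ctx$diff_step else 1e-4
  th <- as_theta(start)
  if (sqrt(sum(th^2)) > 1 + 1e-8) stop("start violates the unit-ball constraint")
  p <- length(th)
  f0 <- f(th)
  if (!is.finite(f0)) stop("non-finite loss at start")
  obj <- f0 + lambda_theta * sum(abs(th))
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (cycle in seq_len(cfg$max_iter)) {
    it <- cycle
    th_prev <- th
    obj_prev <- obj
    for (j in seq_len(p)) {
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      fp <- f(tp); fm <- f(tm)
      grad <- (fp - fm) / (2 * h)
      curv <- max((fp - 2 * f0 + fm) / h^2, cfg$curvature_floor)
      # curvature backtracking: enlarge curv (shrink the step) until the
      # penalized objective does not increase
      old_j <- th[j]
      accepted <- FALSE
      for (bt in 0:6) {
        cand <- soft_threshold(old_j - grad / curv, lambda_theta / curv)
        th[j] <- cand
        f_new <- f(th)
        obj_new <- f_new + lambda_theta * sum(abs(th))
        if (obj_new <= obj + 1e-12) { accepted <- TRUE; break }
        curv <- curv * 4
      }
      if (accepted) { f0 <- f_new; obj <- obj_new } else th[j] <- old_j
    }
    nrm <- sqrt(sum(th^2))
    if (nrm > 1) {
      th_proj <- th / nrm
      f_proj <- f(th_proj)
      obj_proj <- f_proj + lambda_theta * sum(abs(th_proj))
      if (obj_proj > obj_prev + 1e-12) {
        # projection would undo the cycle's progress: stop at the last
        # feasible iterate
        th <- th_prev
        obj <- obj_prev
        f0 <- f(th)
        converged <- TRUE
        trace <- c(trace, obj)
        break
      }
      th <- th_proj; f0 <- f_proj; obj <- obj_proj
    }
    trace <- c(trace, obj)
    if (max(abs(th - th_prev)) < cfg$tol) { converged <- TRUE; break }
  }
  list(theta = th, objective = obj, trace = trace, converged = converged,
       iterations = it)
}

# Multi-start wrapper: zero vector, optional warm starts, and seeded random
# unit vectors.  Ties broken by smaller L1 norm, then start index.
multistart_cd <- function(ctx, lambda_theta, cfg, warm = NULL, seed = NULL) {
  p <- ctx$d + 1L
  starts <- list(numeric(p))
  for (w in warm) starts[[length(starts) + 1L]] <- as_theta(w)
  n_random <- max(0L, cfg$n_starts - length(starts))
  if (n_random > 0L) {
    if (is.null(seed)) seed <- cfg$seed
    rand <- local_seed(seed, replicate(n_random, {
      v <- stats::rnorm(p); v / sqrt(sum(v^2))
    }, simplify = FALSE))
    starts <- c(starts, rand)
  }
  starts <- starts[seq_len(min(length(starts), max(cfg$n_starts, length(starts))))]
  best <- NULL
  for (s in seq_along(starts)) {
    res <- proximal_cd(ctx, lambda_theta, starts[[s]], cfg)
    better <- is.null(best) ||
      res$objective < best$objective - 1e-12 ||
      (abs(res$objective - best$objective) <= 1e-12 &&
         sum(abs(res$theta)) < sum(abs(best$theta)) - 1e-12)
    if (better) best <- res
  }
  best
}

#' Tune the policy L1 penalty by cross-validation
#'
#' K-fold cross-validation with folds split at the subject (trajectory)
#' level.  For each candidate penalty, the policy is fit on the training
#' folds and scored by the held-out unpenalized normalized loss (i.e. the
#' negated weighted-importance-sampling value estimate on held-out
#' subjects).  The selected penalty is the largest one whose mean held-out
#' loss is within one standard error of the minimum (the usual
#' one-standard-error rule): with no exploitable signal all candidates tie
#' statistically and the heaviest penalty -- the sparsest policy -- wins.
#'
#' @param ds a [trajectory_dataset()].
#' @param tau policy scaling parameter.
#' @param nuisance a `nuisance_model` (zero model for the initial
#'   estimator's tuning).
#' @param cfg a [fit_config()].
#' @return a list with `lambda` (the selected penalty) and `table` (a data
#'   frame with one row per candidate: the penalty, per-fold held-out
#'   losses, and their mean).
#' @export
tune_lambda_theta <- function(ds, tau, nuisance, cfg = fit_config()) {
  grid <- cfg$lambda_grid_theta
  ctx_full <- loss_context(ds, nuisance, tau = tau)
  if (is.null(grid)) {
    g0 <- numeric_gradient(ctx_full, numeric(ds$d + 1L))
    lmax <- max(abs(g0), 1e-3)
    grid <- lmax * 10^seq(0, -2.5, length.out = cfg$n_lambda)
  }
  if (length(grid) == 0L) stop("empty penalty grid")
  seeds <- derive_seeds(cfg$seed, 2L)
  folds <- subject_folds(ds$n, cfg$cv_folds, seeds[1L])
  K <- max(folds)
  cv_cfg <- cfg
  cv_cfg$n_starts <- cfg$cv_n_starts
  scores <- matrix(NA_real_, length(grid), K)
  for (k in seq_len(K)) {
    tr <- which(folds != k); te <- which(folds == k)
    ds_tr <- subset_subjects(ds, tr)
    ds_te <- subset_subjects(ds, te)
    nu_tr <- restrict_nuisance(nuisance)
    ctx_tr <- loss_context(ds_tr, nu_tr, tau = tau)
    ctx_te <- loss_context(ds_te, nu_tr, tau = tau)
    for (g in seq_along(grid)) {
      fit <- multistart_cd(ctx_tr, grid[g], cv_cfg, seed = seeds[2L])
      scores[g, k] <- loss_eval(ctx_te, fit$theta)$loss
    }
  }
  mean_score <- rowMeans(scores)
  best <- which.min(mean_score)
  se_best <- stats::sd(scores[best, ]) / sqrt(K)
  chosen <- max(grid[mean_score <= mean_score[best] + se_best])
  table <- data.frame(lambda = grid, scores,
                      mean = mean_score,
                      check.names = FALSE)
  names(table)[1L + seq_len(K)] <- paste0("fold", seq_len(K))
  list(lambda = chosen, table = table)
}

# The nuisance coefficients are fixed functions of (x, a); reusing them on a
# subject subset requires no refitting.
restrict_nuisance <- function(nuisance) nuisance

#' Initial sparse policy estimator (no augmentation)
#'
#' Minimizes the normalized-weight, augmentation-free penalized loss (IPW
#' only, `Q = 0`) over the unit ball, with the penalty chosen by
#' subject-level cross-validation, multi-start proximal coordinate descent,
#' and an unpenalized refit on the selected support.  This estimator is
#' consistent without any nuisance model and seeds the augmentation fits.
#'
#' @param ds a [trajectory_dataset()].
#' @param tau policy scaling parameter.
#' @param cfg a [fit_config()].
#' @param lambda optional fixed penalty (skips tuning; used in bootstrap
#'   replicates where tuning parameters are frozen).
#' @param warm optional list of additional start vectors (e.g. a full-data
#'   estimate when refitting on a bootstrap resample).
#' @return a [policy_params()] with attributes `lambda`, `support`,
#'   `converged`, `objective`.
#' @export
fit_initial <- function(ds, tau = 0.2, cfg = fit_config(), lambda = NULL,
                        warm = NULL) {
  nuis <- fit_q_zero(ds)
  fit_policy(ds, tau, nuis, cfg, lambda = lambda, warm = warm,
             sphere = FALSE)
}

#' Final sparse policy estimator (with augmentation)
#'
#' Same machinery as [fit_initial()] but on the full AIPW objective with the
#' supplied nuisance model; the unpenalized refit is performed on the unit
#' sphere, so the returned estimate has `||theta||_2 = 1` (the scale that
#' approximates a deterministic rule).
#'
#' @inheritParams fit_initial
#' @param nuisance a fitted `nuisance_model`.
#' @param theta_check optional initial estimate used as an extra start.
#' @return a [policy_params()] with attributes `lambda`, `support`,
#'   `converged`, `objective`.
#' @export
fit_sparse <- function(ds, tau = 0.2, nuisance, cfg = fit_config(),
                       theta_check = NULL, lambda = NULL, warm = NULL) {
  if (!is.null(theta_check)) warm <- c(list(theta_check), warm)
  fit_policy(ds, tau, nuisance, cfg, lambda = lambda, warm = warm,
             sphere = TRUE)
}

fit_policy <- function(ds, tau, nuisance, cfg, lambda, warm, sphere) {
  if (is.null(lambda)) {
    tuned <- tune_lambda_theta(ds, tau, nuisance, cfg)
    lambda <- tuned$lambda
  }
  ctx <- loss_context(ds, nuisance, tau = tau)
  seeds <- derive_seeds(cfg$seed, 3L)
  best <- multistart_cd(ctx, lambda, cfg, warm = warm, seed = seeds[3L])
  pol <- policy_params(best$theta, tau = tau)
  refit <- refit_on_support(ctx, pol, sphere = sphere)
  structure(refit,
            lambda = lambda,
            support = which(as_theta(refit) != 0) - 1L,
            converged = best$converged,
            objective = loss_eval(ctx, as_theta(refit))$loss)
}

#' Refit a sparse estimate on its support without the penalty
#'
#' Minimizes the unpenalized loss over the vectors supported on the nonzero
#' coordinates of `theta`, subject to the unit-ball constraint (or
#' restricted to the unit sphere with `sphere = TRUE`), using a smooth
#' quasi-Newton optimizer started at `theta`.  An empty support returns the
#' input unchanged; an optimizer failure returns the input with a warning.
#'
#' @param ctx a [loss_context()].
#' @param theta a [policy_params()] or coefficient vector.
#' @param sphere logical; constrain to `||theta||_2 = 1` rather than
#'   `||theta||_2 <= 1`.
#' @return a [policy_params()].
#' @export
refit_on_support <- function(ctx, theta, sphere = FALSE) {
  tau <- if (inherits(theta, "policy_params")) theta$tau else ctx$tau
  th <- as_theta(theta)
  support <- which(th != 0)
  if (length(support) == 0L) return(policy_params(th, tau))
  embed <- function(u) {
    full <- numeric(length(th))
    nrm <- sqrt(sum(u^2))
    full[support] <- if (sphere) u / nrm else if (nrm > 1) u / nrm else u
    full
  }
  # the tiny radial term keeps the (scale-invariant) sphere parameterization
  # well conditioned for BFGS; it does not affect the reported direction
  objfn <- function(u) {
    nrm <- sqrt(sum(u^2))
    if (nrm < 1e-10) return(loss_eval(ctx, numeric(length(th)))$loss + 1)
    loss_eval(ctx, embed(u))$loss + 1e-8 * (nrm - 1)^2
  }
  u0 <- th[support]
  if (sphere && sqrt(sum(u0^2)) < 1e-8) u0 <- rep(1 / sqrt(length(support)),
                                                  length(support))
  res <- tryCatch(
    stats::optim(u0, objfn, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$par))) {
    warning("support refit failed; returning the penalized estimate")
    return(policy_params(th, tau))
  }
  cand <- embed(res$par)
  if (loss_eval(ctx, cand)$loss <= loss_eval(ctx, th)$loss || sphere)
    policy_params(cand, tau)
  else
    policy_params(th, tau)
}
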