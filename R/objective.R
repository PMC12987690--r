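#' Loss evaluation context
#'
#' Packages a dataset with a fitted nuisance model and all precomputable
#' pieces of the AIPW value loss, so that repeated evaluations at different
#' policy parameters (as in coordinate descent and difference quotients)
#' cost a single `n T x d` matrix product plus elementwise work.
#'
#' The loss is the negative AIPW value estimate
#' `l_i(theta) = -sum_t { rho_{i,1:t} [R_{i,t} - Q_t(X_{i,t}, A_{i,t})]
#'                        + rho_{i,1:(t-1)} U_t(X_{i,t}) }`,
#' averaged over subjects; with `use_normalized_weights = TRUE` each weight
#' is divided by its cross-subject mean `omega` (weighted importance
#' sampling), and `omega` is recomputed at every evaluated `theta`.
#'
#' @param ds a [trajectory_dataset()].
#' @param nuisance a `nuisance_model` (use [fit_q_zero()] for the
#'   augmentation-free loss).
#' @param tau policy scaling parameter.
#' @param use_normalized_weights logical; divide weights by their stage means.
#' @param diff_step base step `h` for symmetric difference quotients
#'   (must lie in `(0, 0.1]`); the effective step is
#'   `h * max(1, ||theta||_2)`.
#' @param weight_cap optional hard cap on individual cumulative weights
#'   (default `Inf`, i.e. off).
#' @return an object of class `loss_context`.
#' @export
loss_context <- function(ds, nuisance, tau = 0.2,
                         use_normalized_weights = TRUE, diff_step = 1e-4,
                         weight_cap = Inf) {
  validate_trajectories(ds)
  if (!(diff_step > 0 && diff_step <= 0.1))
    stop("`diff_step` must lie in (0, 0.1]")
  n <- ds$n; T_ <- ds$T; d <- ds$d
  basis <- nuisance$basis
  Qobs <- Qplus <- Qminus <- matrix(0, n, T_)
  if (nuisance$method != 0L) {
    for (t in seq_len(T_)) {
      X <- ds$features[, t, , drop = TRUE]
      if (is.null(dim(X))) X <- matrix(X, nrow = n)
      b <- nuisance$betas[[t]]
      Qobs[, t] <- phi_matrix(basis, X, ds$actions[, t]) %*% b
      Qplus[, t] <- phi_matrix(basis, X, rep(1, n)) %*% b
      Qminus[, t] <- phi_matrix(basis, X, rep(-1, n)) %*% b
    }
  }
  structure(list(
    ds = ds, nuisance = nuisance, tau = tau,
    use_normalized_weights = use_normalized_weights,
    diff_step = diff_step, weight_cap = weight_cap,
    Xcat = matrix(ds$features, nrow = n * T_, ncol = d),
    A = ds$actions, R = ds$rewards, logmu = log(ds$behavior_prob),
    Qobs = Qobs, Qplus = Qplus, Qminus = Qminus,
    n = n, T = T_, d = d), class = "loss_context")
}

# Core evaluator.  Returns per-subject losses, their mean, and the omega
# vector actually used.  `fixed_omega` (length T + 1) freezes the
# normalization constants instead of recomputing them at `theta`.
loss_eval <- function(ctx, theta, fixed_omega = NULL) {
  n <- ctx$n; T_ <- ctx$T
  G <- matrix(theta[1L] + ctx$Xcat %*% theta[-1L], n, T_)
  z <- G / ctx$tau
  logpi_obs <- stats::plogis(ctx$A * z, log.p = TRUE)
  logstep <- logpi_obs - ctx$logmu
  logrho <- logstep
  if (T_ > 1L)
    for (t in 2:T_) logrho[, t] <- logrho[, t - 1L] + logstep[, t]
  rho <- exp(logrho)
  if (is.finite(ctx$weight_cap)) rho <- pmin(rho, ctx$weight_cap)
  rho_all <- cbind(1, rho)                       # columns t = 0..T
  if (ctx$use_normalized_weights) {
    omega <- if (is.null(fixed_omega)) colMeans(rho_all) else fixed_omega
    rho_all <- sweep(rho_all, 2L, omega, "/")
  } else {
    omega <- rep(1, T_ + 1L)
  }
  contrib <- rho_all[, -1L, drop = FALSE] * (ctx$R - ctx$Qobs)
  if (ctx$nuisance$method != 0L) {
    p1 <- stats::plogis(z)
    U <- p1 * ctx$Qplus + (1 - p1) * ctx$Qminus
    contrib <- contrib + rho_all[, -(T_ + 1L), drop = FALSE] * U
  }
  per_subject <- -rowSums(contrib)
  list(per_subject = per_subject, loss = mean(per_subject), omega = omega)
}

as_theta <- function(theta) {
  if (inherits(theta, "policy_params")) theta$theta else as.numeric(theta)
}

#' Per-trajectory AIPW loss
#'
#' The contribution `l_i(theta)` of subject `i` to the loss.  When
#' normalization is on, the shared `omega` is computed from the full dataset,
#' so per-trajectory values are coupled across subjects by design.
#'
#' @param ctx a [loss_context()].
#' @param theta a [policy_params()] or bare coefficient vector.
#' @param i subject index.
#' @return a finite numeric scalar.
#' @export
trajectory_loss <- function(ctx, theta, i) {
  if (i < 1L || i > ctx$n) stop("invalid subject index")
  loss_eval(ctx, as_theta(theta))$per_subject[i]
}

#' AIPW value loss
#'
#' `loss(ctx, theta) = mean_i l_i(theta)`, which equals minus the (possibly
#' weight-normalized) AIPW estimate of the value function at `theta`.
#'
#' @inheritParams trajectory_loss
#' @return a numeric scalar.
#' @export
loss <- function(ctx, theta) {
  loss_eval(ctx, as_theta(theta))$loss
}

#' L1-penalized AIPW loss
#'
#' @inheritParams trajectory_loss
#' @param lambda_theta nonnegative L1 penalty level; the penalty covers all
#'   coordinates including the intercept.
#' @return `loss(ctx, theta) + lambda_theta * sum(|theta_j|)`.
#' @export
penalized_loss <- function(ctx, theta, lambda_theta) {
  th <- as_theta(theta)
  if (sqrt(sum(th^2)) > 1 + 1e-8) stop("unit-ball constraint violated")
  if (lambda_theta < 0) stop("lambda_theta must be nonnegative")
  loss(ctx, th) + lambda_theta * sum(abs(th))
}

# Evaluate the loss at a perturbed point, renormalizing to the sphere when
# the perturbation leaves the unit ball.  Returns the point actually used.
project_ball <- function(theta) {
  nrm <- sqrt(sum(theta^2))
  if (nrm > 1) theta / nrm else theta
}

#' Numeric gradient of the loss by symmetric difference quotients
#'
#' Coordinate `j` gets `[l(theta + h e_j) - l(theta - h e_j)] / (2h)` with
#' `h = diff_step * max(1, ||theta||)`.  The loss itself is well defined for
#' any `theta` (the unit ball constrains the estimator, not the loss), so
#' perturbed points are evaluated in the ambient coordinate even when they
#' leave the ball -- this keeps the quotient an estimate of the ambient
#' derivative that the inference theory needs.  If an evaluation is
#' non-finite, the one-sided Newton quotient toward the finite side is used.
#'
#' @inheritParams trajectory_loss
#' @return numeric vector of length `d + 1`.
#' @export
numeric_gradient <- function(ctx, theta) {
  th <- as_theta(theta)
  h <- ctx$diff_step * max(1, sqrt(sum(th^2)))
  fd_gradient(function(v) loss_eval(ctx, v)$loss, th, h)
}

# Symmetric-difference gradient of a scalar function, with a one-sided
# Newton fallback if an evaluation comes back non-finite.
fd_gradient <- function(f, x, h) {
  p <- length(x)
  f0 <- NULL
  g <- numeric(p)
  for (j in seq_len(p)) {
    tp <- x; tp[j] <- tp[j] + h
    tm <- x; tm[j] <- tm[j] - h
    fp <- f(tp); fm <- f(tm)
    if (is.finite(fp) && is.finite(fm)) {
      g[j] <- (fp - fm) / (2 * h)
    } else {
      if (is.null(f0)) f0 <- f(x)
      g[j] <- if (is.finite(fm)) (f0 - fm) / h else (fp - f0) / h
    }
  }
  g
}

# Central-stencil Hessian of a scalar function (three-point diagonal,
# four-point cross terms), symmetric by construction.
fd_hessian <- function(f, x, h) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (j in seq_len(p)) {
    tp <- x; tp[j] <- tp[j] + h
    tm <- x; tm[j] <- tm[j] - h
    H[j, j] <- (f(tp) - 2 * f0 + f(tm)) / h^2
  }
  if (p > 1L) {
    for (j in seq_len(p - 1L)) {
      for (k in (j + 1L):p) {
        tpp <- x; tpp[j] <- tpp[j] + h; tpp[k] <- tpp[k] + h
        tpm <- x; tpm[j] <- tpm[j] + h; tpm[k] <- tpm[k] - h
        tmp <- x; tmp[j] <- tmp[j] - h; tmp[k] <- tmp[k] + h
        tmm <- x; tmm[j] <- tmm[j] - h; tmm[k] <- tmm[k] - h
        H[j, k] <- H[k, j] <- (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h^2)
      }
    }
  }
  H
}

#' Numeric Hessian of the loss by central difference stencils
#'
#' Diagonal entries use the three-point stencil
#' `[l(theta + h e_j) - 2 l(theta) + l(theta - h e_j)] / h^2`; off-diagonal
#' entries use the four-point cross stencil.  The result is symmetrized by
#' averaging with its transpose.  As for [numeric_gradient()], perturbed
#' points are evaluated in the ambient coordinate.
#'
#' @inheritParams trajectory_loss
#' @return a symmetric `(d+1) x (d+1)` numeric matrix.
#' @export
numeric_hessian <- function(ctx, theta) {
  per_subject_hessian(ctx, theta, reduce = TRUE)
}

# Shared stencil machinery: with reduce = TRUE returns the (d+1)x(d+1)
# Hessian of the mean loss; with reduce = FALSE returns an n x (d+1)^2
# matrix of per-subject Hessian entries (omega frozen at `theta` so the
# per-subject decomposition is exact).
per_subject_hessian <- function(ctx, theta, reduce = TRUE,
                                fixed_omega = NULL) {
  th <- as_theta(theta)
  h <- ctx$diff_step * max(1, sqrt(sum(th^2)))
  p <- length(th)
  ev <- function(x) {
    r <- loss_eval(ctx, x, fixed_omega = fixed_omega)
    if (reduce) r$loss else r$per_subject
  }
  f0 <- ev(th)
  H <- if (reduce) matrix(0, p, p) else
    array(0, dim = c(ctx$n, p, p))
  fp <- fm <- vector("list", p)
  for (j in seq_len(p)) {
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    fp[[j]] <- ev(tp); fm[[j]] <- ev(tm)
    val <- (fp[[j]] - 2 * f0 + fm[[j]]) / h^2
    if (reduce) H[j, j] <- val else H[, j, j] <- val
  }
  if (p > 1L) {
    for (j in seq_len(p - 1L)) {
      for (k in (j + 1L):p) {
        tpp <- th; tpp[j] <- tpp[j] + h; tpp[k] <- tpp[k] + h
        tpm <- th; tpm[j] <- tpm[j] + h; tpm[k] <- tpm[k] - h
        tmp <- th; tmp[j] <- tmp[j] - h; tmp[k] <- tmp[k] + h
        tmm <- th; tmm[j] <- tmm[j] - h; tmm[k] <- tmm[k] - h
        val <- (ev(tpp) - ev(tpm) - ev(tmp) + ev(tmm)) / (4 * h^2)
        if (reduce) { H[j, k] <- val; H[k, j] <- val }
        else { H[, j, k] <- val; H[, k, j] <- val }
      }
    }
  }
  H
}

#' Per-subject loss gradients
#'
#' Row `i` is the symmetric-difference gradient of `l_i` at `theta`.  When
#' normalization is on, the `omega` constants are frozen at their full-data
#' values at the unperturbed `theta`, so the rows are an exact decomposition
#' of a fixed-omega gradient and their sample covariance estimates the score
#' covariance `Sigma`.
#'
#' @inheritParams trajectory_loss
#' @return an `n x (d+1)` numeric matrix.
#' @export
per_subject_gradients <- function(ctx, theta) {
  th <- as_theta(theta)
  h <- ctx$diff_step * max(1, sqrt(sum(th^2)))
  p <- length(th)
  omega0 <- loss_eval(ctx, th)$omega
  Gm <- matrix(0, ctx$n, p)
  for (j in seq_len(p)) {
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    Gm[, j] <- (loss_eval(ctx, tp, fixed_omega = omega0)$per_subject -
                loss_eval(ctx, tm, fixed_omega = omega0)$per_subject) /
      (2 * h)
  }
  Gm
}

# ---- sphere-profiled (xi) parameterization --------------------------------
#
# On the unit sphere the intercept is determined by the feature
# coefficients: theta_0 = s * sqrt(1 - ||xi||^2) with xi = theta_{1:d} and
# s the sign of the intercept.  Inference for the feature coefficients is
# carried out in this d-dimensional parameterization, where the sparse
# estimate is an interior stationary point and the decorrelated-score
# theory applies.  The sqrt is clamped at zero, which realizes the
# one-sided (Newton) quotient in the boundary case theta_0 = 0.

xi_eval_fn <- function(ctx, sign0, fixed_omega = NULL, reduce = TRUE) {
  force(sign0)
  function(xi) {
    th0 <- sign0 * sqrt(max(1 - sum(xi^2), 0))
    r <- loss_eval(ctx, c(th0, xi), fixed_omega = fixed_omega)
    if (reduce) r$loss else r$per_subject
  }
}

intercept_sign <- function(theta) if (theta[1L] < 0) -1 else 1

#' Gradient of the loss in the sphere-profiled parameterization
#'
#' Derivatives of `l(theta_0(xi), xi)` with respect to the feature
#' coefficients `xi = theta_{1:d}`, where the intercept is profiled out by
#' the unit-sphere constraint, `theta_0 = sign(theta_0) sqrt(1 - ||xi||^2)`.
#' These are the score components the decorrelated one-step inference uses;
#' `theta` must lie (numerically) on the unit sphere.
#'
#' @inheritParams trajectory_loss
#' @return numeric vector of length `d`.
#' @export
sphere_gradient <- function(ctx, theta) {
  th <- as_theta(theta)
  fd_gradient(xi_eval_fn(ctx, intercept_sign(th)), th[-1L], ctx$diff_step)
}

#' Hessian of the loss in the sphere-profiled parameterization
#'
#' Central-stencil second derivatives of `l(theta_0(xi), xi)` with respect
#' to `xi`; see [sphere_gradient()].  Symmetrized by averaging with the
#' transpose.
#'
#' @inheritParams trajectory_loss
#' @return a symmetric `d x d` numeric matrix.
#' @export
sphere_hessian <- function(ctx, theta) {
  th <- as_theta(theta)
  H <- fd_hessian(xi_eval_fn(ctx, intercept_sign(th)), th[-1L],
                  ctx$diff_step)
  (H + t(H)) / 2
}

# Per-subject xi-gradients (omega frozen at the evaluation point), the rows
# whose sample covariance estimates the score covariance Sigma.
per_subject_sphere_gradients <- function(ctx, theta) {
  th <- as_theta(theta)
  omega0 <- loss_eval(ctx, th)$omega
  f <- xi_eval_fn(ctx, intercept_sign(th), fixed_omega = omega0,
                  reduce = FALSE)
  xi <- th[-1L]
  h <- ctx$diff_step
  Gm <- matrix(0, ctx$n, length(xi))
  for (j in seq_along(xi)) {
    tp <- xi; tp[j] <- tp[j] + h
    tm <- xi; tm[j] <- tm[j] - h
    Gm[, j] <- (f(tp) - f(tm)) / (2 * h)
  }
  Gm
}

# Per-subject xi-Hessians as an n x d x d array (omega frozen); used by the
# cross-validated choice of the Dantzig tolerance.
per_subject_sphere_hessians <- function(ctx, theta) {
  th <- as_theta(theta)
  omega0 <- loss_eval(ctx, th)$omega
  f <- xi_eval_fn(ctx, intercept_sign(th), fixed_omega = omega0,
                  reduce = FALSE)
  xi <- th[-1L]
  h <- ctx$diff_step
  p <- length(xi)
  H <- array(0, dim = c(ctx$n, p, p))
  f0 <- f(xi)
  for (j in seq_len(p)) {
    tp <- xi; tp[j] <- tp[j] + h
    tm <- xi; tm[j] <- tm[j] - h
    H[, j, j] <- (f(tp) - 2 * f0 + f(tm)) / h^2
  }
  if (p > 1L) {
    for (j in seq_len(p - 1L)) {
      for (k in (j + 1L):p) {
        tpp <- xi; tpp[j] <- tpp[j] + h; tpp[k] <- tpp[k] + h
        tpm <- xi; tpm[j] <- tpm[j] + h; tpm[k] <- tpm[k] - h
        tmp <- xi; tmp[j] <- tmp[j] - h; tmp[k] <- tmp[k] + h
        tmm <- xi; tmm[j] <- tmm[j] - h; tmm[k] <- tmm[k] - h
        val <- (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h^2)
        H[, j, k] <- H[, k, j] <- val
      }
    }
  }
  H
}
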