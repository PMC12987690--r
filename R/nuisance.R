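#' Basis specification for the augmentation models
#'
#' The stage-wise augmentation (Q) models are linear in the expanded design
#' `Phi(x, a) = (phi(x), a * phi(x))`, where `phi` is a feature basis that
#' always includes an intercept.  Only the linear basis
#' `phi(x) = (1, x_1, ..., x_d)` is currently provided, giving
#' `d' = d + 1` and a design of dimension `2 d'`.
#'
#' @param d number of raw features.
#' @param kind basis family; only `"linear"` is implemented.
#' @return an object of class `basis_spec` with fields `kind`,
#'   `includes_intercept`, `d`, `d_prime`.
#' @export
basis_spec <- function(d, kind = "linear") {
  kind <- match.arg(kind)
  if (d < 1L) stop("d must be >= 1")
  structure(list(kind = kind, includes_intercept = TRUE,
                 d = as.integer(d), d_prime = as.integer(d) + 1L),
            class = "basis_spec")
}

#' Expanded design vector Phi(x, a)
#'
#' Returns the concatenation `(phi(x), a * phi(x))` with
#' `phi(x) = (1, x_1, ..., x_d)`: a main-effect block and an
#' action-interaction block, of total length `2 d'`.
#'
#' @param basis a [basis_spec()].
#' @param x numeric feature vector of length `d`.
#' @param a action, `-1` or `+1`.
#' @return numeric vector of length `2 * basis$d_prime`.
#' @export
basis_features <- function(basis, x, a) {
  if (!(length(a) == 1L && (a == -1 || a == 1))) stop("`a` must be -1 or +1")
  if (length(x) != basis$d) stop("feature length mismatch")
  phi <- c(1, x)
  c(phi, a * phi)
}

# Vectorized design matrix for one stage: rows Phi(X[i, ], A[i]).
phi_matrix <- function(basis, X, A) {
  phi <- cbind(1, X)
  cbind(phi, phi * A)
}

#' Zero augmentation (naive method, m = 0)
#'
#' Sets every stage's Q model to zero, so the AIPW loss reduces to the
#' (normalized) inverse-probability-weighted loss without augmentation.
#'
#' @param ds a [trajectory_dataset()].
#' @param basis a [basis_spec()]; defaults to the linear basis for `ds`.
#' @return a `nuisance_model` with `method = 0` and all-zero coefficients.
#' @export
fit_q_zero <- function(ds, basis = basis_spec(ds$d)) {
  betas <- replicate(ds$T, numeric(2L * basis$d_prime), simplify = FALSE)
  new_nuisance(0L, betas, basis, theta_check = NULL)
}

new_nuisance <- function(method, betas, basis, theta_check,
                         lambdas = rep(NA_real_, length(betas))) {
  stopifnot(all(vapply(betas, function(b) all(is.finite(b)), logical(1L))))
  structure(list(method = as.integer(method), betas = betas, basis = basis,
                 theta_check = theta_check, lambdas = lambdas),
            class = "nuisance_model")
}

#' @export
print.nuisance_model <- function(x, ...) {
  nz <- vapply(x$betas, function(b) sum(b != 0), integer(1L))
  cat(sprintf("<nuisance_model> method m = %d, T = %d stages, 2d' = %d, nonzero per stage: %s\n",
              x$method, length(x$betas), 2L * x$basis$d_prime,
              paste(nz, collapse = " ")))
  invisible(x)
}

# L1-penalized least squares with subject-level CV followed by an OLS refit
# on the selected support (intercept column always kept).  Returns the
# refitted coefficient vector and the chosen penalty.
lasso_refit <- function(X, y, foldid, lambda = NULL, nlambda = 50L) {
  p <- ncol(X)
  if (stats::var(y) < 1e-300 || nrow(X) < 2L) {
    # degenerate: constant response (or a single row) -> intercept-only fit
    beta <- numeric(p)
    beta[1L] <- mean(y)
    return(list(beta = beta, lambda = if (is.null(lambda)) Inf else lambda))
  }
  if (is.null(lambda)) {
    nf <- max(min(max(foldid), 10L), 3L)
    cv <- glmnet::cv.glmnet(X, y, foldid = refold(foldid, nf),
                            intercept = FALSE, standardize = FALSE,
                            nlambda = nlambda)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(X, y, intercept = FALSE, standardize = FALSE,
                          lambda = lambda)
  }
  b <- as.numeric(stats::coef(fit, s = lambda))[-1L]  # drop glmnet's intercept
  support <- union(1L, which(b != 0))
  list(beta = ols_on_support(X, y, support), lambda = lambda)
}

# Unpenalized least-squares refit on a coordinate support; rank-deficient
# columns get coefficient 0.
ols_on_support <- function(X, y, support) {
  beta <- numeric(ncol(X))
  Xs <- X[, support, drop = FALSE]
  fit <- stats::lm.fit(Xs, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  beta[support] <- coefs
  beta
}

# Collapse subject ids into `nf` CV folds, keeping subjects intact.
refold <- function(subject_fold, nf) {
  ((subject_fold - 1L) %% nf) + 1L
}

# Subject-level fold assignment (1..nfolds), deterministic given seed.
subject_folds <- function(n, nfolds, seed) {
  nfolds <- min(nfolds, n)
  local_seed(seed, sample(rep_len(seq_len(nfolds), n)))
}

#' Backward Q-function estimation (method m = 1)
#'
#' Fits the stage-wise Q models backward from `t = T` to `t = 1` by
#' L1-penalized least squares of the pseudo-response
#' `q_{i,t} = R_{i,t} + sum_a pi_thetacheck(a | X_{i,t+1}) Phi(X_{i,t+1}, a)' beta_{t+1}`
#' on `Phi(X_{i,t}, A_{i,t})`, with `beta_{T+1} = 0`.  The penalty level for
#' each stage is chosen by subject-level cross-validation (or fixed via
#' `lambdas`), and each fit is refit by ordinary least squares on its
#' selected support.
#'
#' @param ds a [trajectory_dataset()].
#' @param basis a [basis_spec()].
#' @param theta_check initial [policy_params()] used inside the
#'   continuation term.
#' @param cv_folds number of cross-validation folds (subject-level).
#' @param seed integer seed controlling fold assignment.
#' @param lambdas optional numeric vector of length `T` of fixed penalty
#'   levels (used during bootstrap, where tuning parameters are frozen).
#' @param nlambda number of log-spaced candidate penalties.
#' @return a `nuisance_model` with `method = 1`.
#' @export
fit_q_backward <- function(ds, basis = basis_spec(ds$d), theta_check,
                           cv_folds = 5L, seed = 1L, lambdas = NULL,
                           nlambda = 50L) {
  validate_trajectories(ds)
  T_ <- ds$T
  betas <- vector("list", T_)
  chosen <- numeric(T_)
  foldid <- subject_folds(ds$n, cv_folds, seed)
  beta_next <- numeric(2L * basis$d_prime)
  for (t in rev(seq_len(T_))) {
    q <- ds$rewards[, t]
    if (t < T_) {
      Xn <- ds$features[, t + 1L, , drop = TRUE]
      if (is.null(dim(Xn))) Xn <- matrix(Xn, nrow = ds$n)
      p1 <- stats::plogis(decision_score_mat(theta_check, Xn) / theta_check$tau)
      qp <- phi_matrix(basis, Xn, rep(1, ds$n)) %*% beta_next
      qm <- phi_matrix(basis, Xn, rep(-1, ds$n)) %*% beta_next
      q <- q + p1 * as.numeric(qp) + (1 - p1) * as.numeric(qm)
    }
    X <- ds$features[, t, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = ds$n)
    Phi <- phi_matrix(basis, X, ds$actions[, t])
    fit <- lasso_refit(Phi, q, foldid, lambda = lambdas[t], nlambda = nlambda)
    betas[[t]] <- fit$beta
    chosen[t] <- fit$lambda
    beta_next <- fit$beta
  }
  new_nuisance(1L, betas, basis, theta_check, chosen)
}

decision_score_mat <- function(policy, X) {
  as.numeric(policy$theta[1L] + X %*% policy$theta[-1L])
}

#' Variance-minimizing augmentation (method m = 2)
#'
#' A heuristic that targets the finite-sample variance of the stage-wise
#' value estimator directly: each stage `t` is fit independently by
#' L1-penalized least squares of the normalized-weighted reward
#' `rhotilde_{i,1:t} R_{i,t}` on the contrast design
#' `rhotilde_{i,1:t} Phi(X_{i,t}, A_{i,t}) -
#'  rhotilde_{i,1:(t-1)} sum_a pi_thetacheck(a | X_{i,t}) Phi(X_{i,t}, a)`,
#' where `rhotilde` are the omega-normalized importance weights under the
#' initial policy estimate.  Penalties are CV-chosen per stage and fits are
#' refit by OLS on their support.
#'
#' @inheritParams fit_q_backward
#' @return a `nuisance_model` with `method = 2`.
#' @export
fit_q_varmin <- function(ds, basis = basis_spec(ds$d), theta_check,
                         cv_folds = 5L, seed = 1L, lambdas = NULL,
                         nlambda = 50L) {
  validate_trajectories(ds)
  T_ <- ds$T
  rho <- stepwise_weights(theta_check, ds)
  rt <- normalized_weights(rho)$normalized
  betas <- vector("list", T_)
  chosen <- numeric(T_)
  foldid <- subject_folds(ds$n, cv_folds, seed)
  for (t in seq_len(T_)) {
    X <- ds$features[, t, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = ds$n)
    p1 <- stats::plogis(decision_score_mat(theta_check, X) / theta_check$tau)
    Phi_obs <- phi_matrix(basis, X, ds$actions[, t])
    Phi_p <- phi_matrix(basis, X, rep(1, ds$n))
    Phi_m <- phi_matrix(basis, X, rep(-1, ds$n))
    design <- rt[, t + 1L] * Phi_obs -
      rt[, t] * (p1 * Phi_p + (1 - p1) * Phi_m)
    y <- rt[, t + 1L] * ds$rewards[, t]
    fit <- lasso_refit(design, y, foldid, lambda = lambdas[t],
                       nlambda = nlambda)
    betas[[t]] <- fit$beta
    chosen[t] <- fit$lambda
  }
  new_nuisance(2L, betas, basis, theta_check, chosen)
}

#' Predict the augmentation term Q_t(x, a)
#'
#' @param model a `nuisance_model`.
#' @param x feature vector of length `d`.
#' @param a action, `-1` or `+1`.
#' @param t stage index in `1..T`.
#' @return `Phi(x, a)' beta_t`.
#' @export
predict_q <- function(model, x, a, t) {
  if (t < 1L || t > length(model$betas)) stop("stage index out of range")
  sum(basis_features(model$basis, x, a) * model$betas[[t]])
}

#' Predict U_t(x), the policy expectation of Q_t
#'
#' `U_t(x) = pi_theta(+1 | x) Q_t(x, +1) + pi_theta(-1 | x) Q_t(x, -1)`,
#' evaluated exactly by enumerating both actions, which is what makes the
#' augmentation mean-zero for any Q model.
#'
#' @param model a `nuisance_model`.
#' @param policy the evaluation [policy_params()] (the `theta` being
#'   optimized, not the `theta_check` the model was built from).
#' @param x feature vector of length `d`.
#' @param t stage index in `1..T`.
#' @return a numeric scalar.
#' @export
predict_u <- function(model, policy, x, t) {
  p1 <- action_prob(policy, x, 1)
  p1 * predict_q(model, x, 1, t) + (1 - p1) * predict_q(model, x, -1, t)
}

#' Serialize a nuisance model to JSON
#' @param model a `nuisance_model`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
nuisance_to_json <- function(model, path = NULL) {
  obj <- list(method = model$method,
              basis = list(kind = model$basis$kind, d = model$basis$d,
                           d_prime = model$basis$d_prime),
              betas = model$betas,
              lambdas = model$lambdas,
              theta_check = if (!is.null(model$theta_check))
                list(theta = model$theta_check$theta,
                     tau = model$theta_check$tau))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a nuisance model from JSON
#' @param path file path or JSON string produced by [nuisance_to_json()].
#' @return a `nuisance_model`.
#' @export
nuisance_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  basis <- basis_spec(obj$basis$d, obj$basis$kind)
  betas <- lapply(seq_len(nrow(obj$betas)), function(i) obj$betas[i, ])
  if (is.list(obj$betas)) betas <- obj$betas
  tc <- if (!is.null(obj$theta_check))
    policy_params(obj$theta_check$theta, obj$theta_check$tau)
  new_nuisance(obj$method, betas, basis, tc, obj$lambdas)
}
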