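#' Dantzig decorrelation vector
#'
#' Solves, for row `j` of a symmetric Hessian-type matrix `H`, the linear
#' program
#' `minimize ||w||_1  subject to  ||H[j, -j] - w' H[-j, -j]||_inf <= lambda`:
#' the minimum-L1 sparse linear combination of the remaining coordinates'
#' scores that approximates the score of coordinate `j` with infeasibility
#' at most `lambda`.  For policy inference `H` is the sphere-profiled
#' Hessian from [sphere_hessian()] and `j` indexes a feature coefficient
#' (`1..d`).  Solved exactly as a linear program after splitting `w` into
#' positive and negative parts.
#'
#' @param hess symmetric `p x p` matrix.
#' @param j coordinate of interest (row index, `1..p`).
#' @param lambda_wj nonnegative infeasibility tolerance; any
#'   `lambda_wj >= max|H[j, -j]|` admits `w = 0`.
#' @return numeric vector `w_j` of length `p - 1`.
#' @export
dantzig_w <- function(hess, j, lambda_wj) {
  p <- nrow(hess)
  if (j < 1L || j > p) stop("coordinate index out of range")
  if (lambda_wj < 0) stop("lambda_wj must be nonnegative")
  b <- hess[j, -j]
  A <- hess[-j, -j, drop = FALSE]
  d <- length(b)
  # constraints:  A w - b <= lambda,  b - A w <= lambda, w = w+ - w-
  G <- rbind(cbind(A, -A), cbind(-A, A))
  h <- c(lambda_wj + b, lambda_wj - b)
  res <- solve_lp(rep(1, 2L * d), G, h)
  if (res$status != 0L)
    stop(sprintf("Dantzig LP failed (%s); j = %d, lambda = %g, ||b||_inf = %g",
                 res$message, j, lambda_wj, max(abs(b))))
  w <- res$x[seq_len(d)] - res$x[d + seq_len(d)]
  # snap numerically-zero entries so supports are exact
  w[abs(w) < 1e-10] <- 0
  w
}

#' Decorrelated score
#'
#' `S_j = grad_j - w_j' grad_{-j}`: the score of coordinate `j` minus its
#' sparse projection onto the remaining coordinates' scores.
#'
#' @param grad gradient vector (length `p`; for policy inference the
#'   sphere-profiled gradient of length `d`).
#' @param w_hat_j decorrelation vector for coordinate `j` (length `p - 1`).
#' @param j coordinate, `1..p`.
#' @return a numeric scalar.
#' @export
decorrelated_score <- function(grad, w_hat_j, j) {
  if (length(w_hat_j) != length(grad) - 1L) stop("shape mismatch")
  grad[j] - sum(w_hat_j * grad[-j])
}

#' Decorrelated information
#'
#' `I_{j|nu} = H[j, j] - w_j' H[-j, j]`, the effective information for
#' coordinate `j` after decorrelation.  A near-singular value (below 1e-8 in
#' magnitude) triggers a warning.
#'
#' @inheritParams dantzig_w
#' @param w_hat_j decorrelation vector (length `p - 1`).
#' @return a numeric scalar.
#' @export
information_contrast <- function(hess, w_hat_j, j) {
  val <- hess[j, j] - sum(w_hat_j * hess[-j, j])
  if (abs(val) < 1e-8)
    warning(sprintf("near-singular decorrelated information for j = %d", j))
  val
}

#' One-step estimator for a single coordinate
#'
#' A single Newton-type correction of the sparse estimate using the
#' decorrelated score: `theta_tilde_j = theta_hat_j - S_j / I_{j|nu}`, the
#' root of the linearized score equation.
#'
#' @param theta_hat coefficient vector of the block under analysis (for
#'   policy inference the feature block `theta_{1:d}`; a [policy_params()]
#'   is accepted and its intercept dropped).
#' @param s_hat_j decorrelated score at `theta_hat`.
#' @param info_j decorrelated information (must be nonzero).
#' @param j coordinate, `1..p`.
#' @return a numeric scalar.
#' @export
one_step <- function(theta_hat, s_hat_j, info_j, j) {
  if (info_j == 0) stop("singular information")
  xi <- if (inherits(theta_hat, "policy_params")) theta_hat$theta[-1L]
        else as.numeric(theta_hat)
  xi[j] - s_hat_j / info_j
}

#' Plug-in variance of the decorrelated score
#'
#' `sigma_j = v_j' Sigma v_j` with `v_j = (1, -w_j')'` arranged in coordinate
#' order and `Sigma` the sample covariance of the per-subject gradient rows.
#'
#' @param per_subject_grads `n x p` matrix of per-subject score rows (for
#'   policy inference the sphere-profiled per-subject gradients).
#' @param w_hat_j decorrelation vector (length `p - 1`).
#' @param j coordinate, `1..p`.
#' @return a nonnegative numeric scalar.
#' @export
plugin_variance <- function(per_subject_grads, w_hat_j, j) {
  if (nrow(per_subject_grads) < 2L) stop("need at least 2 subjects")
  v <- numeric(ncol(per_subject_grads))
  v[j] <- 1
  v[-j] <- -w_hat_j
  contrib <- as.numeric(per_subject_grads %*% v)
  stats::var(contrib)
}

# Tune the Dantzig tolerance for coordinate j by K-fold subject-level CV:
# fit w on the in-fold Hessian, score by out-of-fold infeasibility
# ||H_out[j,-j] - w' H_out[-j,-j]||_inf with a small L1 tiebreak.
tune_lambda_w <- function(ps_hess, j, folds, grid = NULL, tiebreak = 1e-3) {
  H_full <- apply(ps_hess, c(2L, 3L), mean)
  bmax <- max(abs(H_full[j, -j]))
  if (is.null(grid))
    grid <- pmax(bmax, 1e-6) * 10^seq(-0.5, -2.5, length.out = 6L)
  K <- max(folds)
  score <- matrix(NA_real_, length(grid), K)
  for (k in seq_len(K)) {
    H_in <- apply(ps_hess[folds != k, , , drop = FALSE], c(2L, 3L), mean)
    H_out <- apply(ps_hess[folds == k, , , drop = FALSE], c(2L, 3L), mean)
    for (g in seq_along(grid)) {
      w <- tryCatch(dantzig_w(H_in, j, grid[g]), error = function(e) NULL)
      if (is.null(w)) { score[g, k] <- Inf; next }
      infeas <- max(abs(H_out[j, -j] - as.numeric(w %*% H_out[-j, -j])))
      score[g, k] <- infeas + tiebreak * sum(abs(w))
    }
  }
  grid[which.min(rowMeans(score))]
}

#' Decorrelated one-step inference with trajectory-bootstrap CIs
#'
#' Runs the full pipeline on the data: initial estimator, nuisance model of
#' the requested method, sparse AIPW estimator, Dantzig decorrelation
#' vectors, and one-step estimates for the requested feature coefficients,
#' with every tuning parameter selected once on the full data.  Then draws
#' `B` trajectory-level bootstrap resamples and recomputes the whole
#' pipeline on each with the frozen tuning parameters; the headline
#' confidence interval for each coordinate is the empirical `alpha/2` and
#' `1 - alpha/2` quantile of the bootstrap one-step replicates.  The
#' asymptotic-normal plug-in interval
#' `theta_tilde_j +/- z * sqrt(sigma_j) / (sqrt(n) |I_{j|nu}|)` is reported
#' as a secondary output.
#'
#' Inference is carried out in the sphere-profiled parameterization (the
#' intercept is determined by the feature coefficients on the unit sphere),
#' so coordinates are the feature indices `1..d`; the intercept is reported
#' through the sparse estimate only.
#'
#' Bootstrap replicates that fail are logged and skipped; more than 20%
#' failures abort the run rather than silently corrupting the quantiles.
#'
#' @param ds a [trajectory_dataset()].
#' @param tau policy scaling parameter.
#' @param method_m augmentation method: 0 (none), 1 (backward Q-learning),
#'   or 2 (variance-minimizing).
#' @param cfg a [fit_config()]; `cfg$seed` drives every substream.
#' @param B number of bootstrap resamples (`>= 2`).
#' @param alpha miscoverage level in (0, 1) for the `1 - alpha` intervals.
#' @param coords integer vector of feature coordinates (`1..d`) to infer;
#'   defaults to all.
#' @return an object of class `inference_result`: list with `theta_hat`,
#'   `theta_tilde`, `ci_lower`, `ci_upper`, `plugin_se`, `plugin_lower`,
#'   `plugin_upper`, `w_hat` (list), `info`, `sigma_hat`, `bootstrap_draws`
#'   (`B x length(coords)`), `n_failed`, `B`, `alpha`, `coords`, `lambdas`.
#' @export
infer <- function(ds, tau = 0.2, method_m = 1L, cfg = fit_config(), B = 100L,
                  alpha = 0.05, coords = seq_len(ds$d)) {
  stopifnot(B >= 2L, alpha > 0, alpha < 1, method_m %in% 0:2)
  if (any(coords < 1L | coords > ds$d))
    stop("`coords` must index feature coefficients 1..d")
  seeds <- derive_seeds(cfg$seed, 4L + B)
  full <- fit_pipeline(ds, tau, method_m, cfg,
                       seed_nuis = seeds[1L], lambdas = NULL)
  ctx <- loss_context(ds, full$nuisance, tau = tau)
  th_hat <- as_theta(full$theta_hat)
  grad <- sphere_gradient(ctx, th_hat)
  hess <- sphere_hessian(ctx, th_hat)
  psg <- per_subject_sphere_gradients(ctx, th_hat)
  psh <- per_subject_sphere_hessians(ctx, th_hat)
  wfolds <- subject_folds(ds$n, cfg$cv_folds, seeds[2L])
  nc <- length(coords)
  lambda_w <- numeric(nc)
  w_hat <- vector("list", nc)
  s_hat <- info <- sigma_hat <- theta_tilde <- numeric(nc)
  for (ci in seq_len(nc)) {
    j <- coords[ci]
    lambda_w[ci] <- tune_lambda_w(psh, j, wfolds)
    w_hat[[ci]] <- dantzig_w(hess, j, lambda_w[ci])
    s_hat[ci] <- decorrelated_score(grad, w_hat[[ci]], j)
    info[ci] <- information_contrast(hess, w_hat[[ci]], j)
    sigma_hat[ci] <- plugin_variance(psg, w_hat[[ci]], j)
    theta_tilde[ci] <- one_step(th_hat[-1L], s_hat[ci], info[ci], j)
  }
  lambdas <- list(theta_check = attr(full$theta_check, "lambda"),
                  beta = full$nuisance$lambdas,
                  theta = attr(full$theta_hat, "lambda"),
                  w = lambda_w)
  draws <- matrix(NA_real_, B, nc)
  n_failed <- 0L
  for (b in seq_len(B)) {
    db <- bootstrap_resample(ds, seeds[4L + b])
    rep_b <- tryCatch(
      bootstrap_replicate(db, tau, method_m, cfg, lambdas, coords,
                          seed_nuis = seeds[4L + b],
                          warm = list(theta_check = as_theta(full$theta_check),
                                      theta_hat = th_hat)),
      error = function(e) NULL)
    if (is.null(rep_b)) n_failed <- n_failed + 1L else draws[b, ] <- rep_b
  }
  if (n_failed > 0.2 * B)
    stop(sprintf("%d of %d bootstrap replicates failed", n_failed, B))
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), type = 1L)
  z <- stats::qnorm(1 - alpha / 2)
  plugin_se <- sqrt(sigma_hat) / (sqrt(ds$n) * abs(info))
  structure(list(
    theta_hat = full$theta_hat, theta_check = full$theta_check,
    nuisance = full$nuisance,
    theta_tilde = stats::setNames(theta_tilde, paste0("theta", coords)),
    ci_lower = qs[1L, ], ci_upper = qs[2L, ],
    plugin_se = plugin_se,
    plugin_lower = theta_tilde - z * plugin_se,
    plugin_upper = theta_tilde + z * plugin_se,
    w_hat = w_hat, s_hat = s_hat, info = info, sigma_hat = sigma_hat,
    bootstrap_draws = draws, n_failed = n_failed,
    B = B, alpha = alpha, coords = coords, lambdas = lambdas,
    seed = cfg$seed), class = "inference_result")
}

# Full-data pipeline: initial fit -> nuisance -> sparse fit.  `lambdas`
# freezes tuning parameters (bootstrap); NULL tunes everything.
fit_pipeline <- function(ds, tau, method_m, cfg, seed_nuis, lambdas = NULL,
                         warm = NULL) {
  th_check <- fit_initial(ds, tau, cfg, lambda = lambdas$theta_check,
                          warm = if (!is.null(warm$theta_check))
                            list(warm$theta_check))
  nuis <- switch(as.character(method_m),
    "0" = fit_q_zero(ds),
    "1" = fit_q_backward(ds, basis_spec(ds$d), th_check,
                         cv_folds = cfg$cv_folds, seed = seed_nuis,
                         lambdas = lambdas$beta),
    "2" = fit_q_varmin(ds, basis_spec(ds$d), th_check,
                       cv_folds = cfg$cv_folds, seed = seed_nuis,
                       lambdas = lambdas$beta))
  th_hat <- fit_sparse(ds, tau, nuis, cfg, theta_check = th_check,
                       lambda = lambdas$theta,
                       warm = if (!is.null(warm$theta_hat))
                         list(warm$theta_hat))
  list(theta_check = th_check, nuisance = nuis, theta_hat = th_hat)
}

bootstrap_replicate <- function(db, tau, method_m, cfg, lambdas, coords,
                                seed_nuis, warm = NULL) {
  # bootstrap replicates warm-start at the full-data estimates and skip the
  # extra random starts; tuning parameters arrive frozen in `lambdas`
  cfg$n_starts <- 1L
  fit <- fit_pipeline(db, tau, method_m, cfg, seed_nuis, lambdas = lambdas,
                      warm = warm)
  ctx <- loss_context(db, fit$nuisance, tau = tau)
  th <- as_theta(fit$theta_hat)
  grad <- sphere_gradient(ctx, th)
  hess <- sphere_hessian(ctx, th)
  vapply(seq_along(coords), function(ci) {
    j <- coords[ci]
    w <- dantzig_w(hess, j, lambdas$w[ci])
    s <- decorrelated_score(grad, w, j)
    i <- information_contrast(hess, w, j)
    one_step(th[-1L], s, i, j)
  }, numeric(1L))
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("<inference_result> B = %d (failed %d), alpha = %g\n",
              x$B, x$n_failed, x$alpha))
  df <- data.frame(j = x$coords,
                   theta_hat = as_theta(x$theta_hat)[x$coords + 1L],
                   theta_tilde = x$theta_tilde,
                   ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                   plugin_se = x$plugin_se)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize an inference result to a JSON report
#'
#' Per-coordinate record mirroring a coefficient table: sparse estimate,
#' one-step estimate, bootstrap CI, plug-in standard error, and whether the
#' coordinate was selected (nonzero in the sparse estimate).  The intercept
#' appears with its sparse estimate only (no one-step correction exists for
#' it under the sphere profile).
#'
#' @param x an `inference_result`.
#' @param path optional output path.
#' @return JSON string (invisibly if written to `path`).
#' @export
inference_to_json <- function(x, path = NULL) {
  th <- as_theta(x$theta_hat)
  rows <- lapply(seq_along(x$coords), function(ci) {
    j <- x$coords[ci]
    list(j = j, theta_hat = th[j + 1L], theta_tilde = x$theta_tilde[[ci]],
         ci_lower = x$ci_lower[[ci]], ci_upper = x$ci_upper[[ci]],
         plugin_se = x$plugin_se[[ci]], selected = th[j + 1L] != 0)
  })
  obj <- list(B = x$B, alpha = x$alpha, n_failed = x$n_failed,
              seed = x$seed, intercept_hat = th[1L],
              coefficients = rows)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
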