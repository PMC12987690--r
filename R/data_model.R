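#' Trajectory datasets from micro-randomized trials
#'
#' A `trajectory_dataset` holds the complete observed trajectories of `n`
#' subjects over a common horizon of `T` stages: a `d`-dimensional feature
#' vector, a binary action coded `-1`/`+1`, a real-valued reward, and the
#' known behavior-policy probability of the action actually taken, for every
#' subject-stage pair.  All estimators in the package consume this container.
#'
#' @param features numeric array of dimension `c(n, T, d)`; `features[i, t, ]`
#'   is the feature vector of subject `i` at stage `t`.
#' @param actions integer or numeric matrix `n x T` with entries in `{-1, 1}`.
#' @param rewards numeric matrix `n x T`.
#' @param behavior_prob numeric matrix `n x T`; entry `(i, t)` is the
#'   behavior-policy probability of the action subject `i` actually received
#'   at stage `t`.  Must lie in `[p0, 1]` (positivity).
#' @param p0 positivity lower bound for `behavior_prob` (must be `> 0`).
#' @param feature_names optional character vector of length `d`; defaults to
#'   `x1 ... xd`.
#'
#' @return An object of class `trajectory_dataset`: a list with elements
#'   `features`, `actions`, `rewards`, `behavior_prob`, `n`, `T`, `d`,
#'   `feature_names`.
#' @export
trajectory_dataset <- function(features, actions, rewards, behavior_prob,
                               p0 = 1e-6, feature_names = NULL) {
  if (length(dim(features)) != 3L)
    stop("`features` must be an n x T x d array")
  n <- dim(features)[1L]
  T_ <- dim(features)[2L]
  d <- dim(features)[3L]
  actions <- as.matrix(actions)
  rewards <- as.matrix(rewards)
  behavior_prob <- as.matrix(behavior_prob)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(d))
  ds <- structure(
    list(features = features, actions = actions, rewards = rewards,
         behavior_prob = behavior_prob, n = n, T = T_, d = d,
         feature_names = feature_names),
    class = "trajectory_dataset")
  validate_trajectories(ds, p0 = p0)
  ds
}

#' Validate a trajectory dataset
#'
#' Checks shape consistency, completeness, the action coding, and positivity
#' of the behavior-policy probabilities.  Validation is idempotent and has no
#' side effects; it either returns the dataset invisibly or throws.
#'
#' @param ds a `trajectory_dataset`.
#' @param p0 positivity lower bound (Assumption: behavior probabilities are
#'   bounded away from zero); must satisfy `p0 > 0`.
#' @return `ds`, invisibly.
#' @export
validate_trajectories <- function(ds, p0 = 1e-6) {
  stopifnot(inherits(ds, "trajectory_dataset"))
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0)
    stop("`p0` must be a single positive number")
  n <- ds$n; T_ <- ds$T; d <- ds$d
  if (!(n >= 1L && T_ >= 1L && d >= 1L))
    stop("n, T, d must be positive")
  if (!identical(dim(ds$features), c(n, T_, d)))
    stop("`features` has inconsistent dimensions")
  for (nm in c("actions", "rewards", "behavior_prob")) {
    m <- ds[[nm]]
    if (!identical(dim(m), c(n, T_)))
      stop(sprintf("`%s` must be an n x T matrix", nm))
    if (anyNA(m) || any(!is.finite(m)))
      stop(sprintf("`%s` contains missing or non-finite values", nm))
  }
  if (anyNA(ds$features) || any(!is.finite(ds$features)))
    stop("`features` contains missing or non-finite values")
  bad_a <- which(!(ds$actions == -1 | ds$actions == 1), arr.ind = TRUE)
  if (nrow(bad_a) > 0L)
    stop(sprintf("action at subject %d, stage %d is %s; actions must be -1 or +1",
                 bad_a[1L, 1L], bad_a[1L, 2L],
                 format(ds$actions[bad_a[1L, , drop = FALSE]])))
  bad_p <- which(ds$behavior_prob < p0 | ds$behavior_prob > 1, arr.ind = TRUE)
  if (nrow(bad_p) > 0L)
    stop(sprintf(
      "behavior_prob at subject %d, stage %d is %g; must lie in [%g, 1]",
      bad_p[1L, 1L], bad_p[1L, 2L], ds$behavior_prob[bad_p[1L, , drop = FALSE]],
      p0))
  if (length(ds$feature_names) != d)
    stop("`feature_names` must have length d")
  invisible(ds)
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf("<trajectory_dataset> n = %d subjects, T = %d stages, d = %d features\n",
              x$n, x$T, x$d))
  invisible(x)
}

default_schema <- function(d) {
  list(subject_id = "subject_id", stage = "stage",
       features = paste0("x", seq_len(d)),
       action = "action", reward = "reward", behavior_prob = "behavior_prob")
}

#' Read trajectories from a long-format CSV file
#'
#' The file must contain one row per (subject, stage) with stages contiguous
#' `1..T` within subject and a common `T` across subjects.  Subjects are
#' ordered by first appearance; stage order within subject is preserved.
#'
#' @param path CSV file path.
#' @param schema optional named list remapping column names; recognized
#'   entries are `subject_id`, `stage`, `features` (character vector),
#'   `action`, `reward`, `behavior_prob`.  Feature columns default to every
#'   column named `x1, x2, ...` present in the file.
#' @param p0 positivity bound passed to [validate_trajectories()].
#' @return a [trajectory_dataset()].
#' @export
read_trajectories <- function(path, schema = NULL, p0 = 1e-6) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(schema)) {
    feat_cols <- grep("^x[0-9]+$", names(df), value = TRUE)
    feat_cols <- feat_cols[order(as.integer(sub("^x", "", feat_cols)))]
    schema <- default_schema(length(feat_cols))
    schema$features <- feat_cols
  }
  needed <- c(schema$subject_id, schema$stage, schema$features,
              schema$action, schema$reward, schema$behavior_prob)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("schema error: column(s) %s not found in %s",
                 paste(missing_cols, collapse = ", "), path))
  subj <- df[[schema$subject_id]]
  subj_levels <- unique(subj)
  n <- length(subj_levels)
  T_ <- nrow(df) / n
  if (T_ != as.integer(T_))
    stop("subjects do not share a common number of stages")
  T_ <- as.integer(T_)
  d <- length(schema$features)
  # reorder rows: subject by first appearance, stage ascending
  ord <- order(match(subj, subj_levels), df[[schema$stage]])
  df <- df[ord, , drop = FALSE]
  stages <- matrix(df[[schema$stage]], nrow = T_)
  if (!all(stages == seq_len(T_)))
    stop("stages must be contiguous 1..T within every subject, with common T")
  a <- df[[schema$action]]
  bad <- which(!(a %in% c(-1, 1)))
  if (length(bad) > 0L)
    stop(sprintf("validation error: row %d has action %s (must be -1 or +1)",
                 bad[1L], format(a[bad[1L]])))
  p <- df[[schema$behavior_prob]]
  badp <- which(!(p > 0 & p <= 1))
  if (length(badp) > 0L)
    stop(sprintf("validation error: row %d has behavior_prob %g (must be in (0,1])",
                 badp[1L], p[badp[1L]]))
  feats <- array(NA_real_, dim = c(n, T_, d))
  for (j in seq_len(d))
    feats[, , j] <- matrix(df[[schema$features[j]]], nrow = n, ncol = T_,
                           byrow = TRUE)
  to_mat <- function(v) matrix(v, nrow = n, ncol = T_, byrow = TRUE)
  trajectory_dataset(feats, to_mat(a), to_mat(df[[schema$reward]]),
                     to_mat(p), p0 = p0, feature_names = schema$features)
}

#' Write trajectories to a long-format CSV file
#'
#' Inverse of [read_trajectories()]: one row per (subject, stage), columns
#' `subject_id, stage, x1..xd, action, reward, behavior_prob` (or the
#' supplied schema names, in that order), numeric fields at full precision.
#'
#' @param ds a `trajectory_dataset`.
#' @param path output file path.
#' @param schema optional column-name mapping as in [read_trajectories()].
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ds, path, schema = NULL) {
  validate_trajectories(ds)
  if (is.null(schema)) {
    schema <- default_schema(ds$d)
    schema$features <- ds$feature_names
  }
  n <- ds$n; T_ <- ds$T; d <- ds$d
  # %.17g round-trips doubles exactly through text
  num <- function(v) formatC(v, format = "g", digits = 17)
  df <- data.frame(rep(seq_len(n), each = T_), rep(seq_len(T_), times = n))
  names(df) <- c(schema$subject_id, schema$stage)
  for (j in seq_len(d))
    df[[schema$features[j]]] <- num(as.vector(t(ds$features[, , j])))
  df[[schema$action]] <- as.integer(as.vector(t(ds$actions)))
  df[[schema$reward]] <- num(as.vector(t(ds$rewards)))
  df[[schema$behavior_prob]] <- num(as.vector(t(ds$behavior_prob)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample whole trajectories with replacement
#'
#' Draws `n` subjects with replacement at the trajectory level (never
#' stage-wise), as required by the trajectory bootstrap.  Deterministic given
#' `seed`.
#'
#' @param ds a `trajectory_dataset`.
#' @param seed integer seed for the resample.
#' @return a `trajectory_dataset` of the same dimensions whose subject `i` is
#'   a complete copy of some original subject's trajectory.
#' @export
bootstrap_resample <- function(ds, seed) {
  validate_trajectories(ds)
  idx <- local_seed(seed, sample.int(ds$n, ds$n, replace = TRUE))
  subset_subjects(ds, idx)
}

# Subset/reorder subjects (indices may repeat).
subset_subjects <- function(ds, idx) {
  structure(
    list(features = ds$features[idx, , , drop = FALSE],
         actions = ds$actions[idx, , drop = FALSE],
         rewards = ds$rewards[idx, , drop = FALSE],
         behavior_prob = ds$behavior_prob[idx, , drop = FALSE],
         n = length(idx), T = ds$T, d = ds$d,
         feature_names = ds$feature_names),
    class = "trajectory_dataset")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive k reproducible sub-seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, k) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
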