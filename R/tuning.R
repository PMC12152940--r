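#' Hyperparameter search space
#'
#' Default grids for random-search cross-validation. `min_samples_split`
#' values are fractions of the training set (e.g. with 500 training points
#' the candidate counts are 5, 13, 25 and 50).
#'
#' @param max_features Candidate per-split feature fractions.
#' @param min_samples_split Candidate split-size fractions.
#' @param alpha Candidate quality-weight strengths.
#' @param beta Candidate mean smearing variances.
#' @param epsilon Candidate SVR tube half-widths.
#' @param n_iterations Random-search draws (capped at the grid size).
#' @param cv_folds Cross-validation folds.
#' @return Object of class `search_space`.
#' @export
search_space <- function(max_features = c(0.1, 0.33, 0.5, 1.0),
                         min_samples_split = c(0.01, 0.025, 0.05, 0.10),
                         alpha = c(0, 0.33, 1, 2),
                         beta = c(0.25, 1, 1.5, 2.5),
                         epsilon = c(0.05, 0.1, 0.2, 0.5),
                         n_iterations = 20, cv_folds = 5) {
  structure(list(max_features = max_features,
                 min_samples_split = min_samples_split, alpha = alpha,
                 beta = beta, epsilon = epsilon,
                 n_iterations = as.integer(n_iterations),
                 cv_folds = as.integer(cv_folds)),
            class = "search_space")
}

# full hyperparameter grid for one family, one row per combination
family_grid <- function(family, space) {
  g <- switch(family,
    RF = expand.grid(max_features = space$max_features,
                     min_samples_split = space$min_samples_split),
    PB_RF = ,
    W_RF = expand.grid(max_features = space$max_features,
                       min_samples_split = space$min_samples_split,
                       alpha = space$alpha),
    OS_RF = expand.grid(min_samples_split = space$min_samples_split,
                        beta = space$beta),
    VOS_RF = expand.grid(min_samples_split = space$min_samples_split,
                         beta = space$beta, alpha = space$alpha),
    SVR = expand.grid(epsilon = space$epsilon),
    WSVR = expand.grid(epsilon = space$epsilon, alpha = space$alpha),
    stop("unknown family: ", family))
  g
}

grid_row_to_spec <- function(family, row, n_trees, seed) {
  model_spec(family,
             max_features = if ("max_features" %in% names(row))
               row$max_features else 1.0,
             min_samples_split = if ("min_samples_split" %in% names(row))
               row$min_samples_split else 0.01,
             alpha = if ("alpha" %in% names(row)) row$alpha else NULL,
             beta = if ("beta" %in% names(row)) row$beta else NULL,
             epsilon = if ("epsilon" %in% names(row)) row$epsilon else NULL,
             n_trees = n_trees, seed = seed)
}

#' Split molecules into training and test sets
#'
#' The split is at the molecule level: every measurement of a molecule ends
#' up on the same side. Typical fractions are 0.75 for uniform-quality
#' (PubChem-like) data and 0.5 for large heteroscedastic (BASF-like) data.
#'
#' @param sets Named-or-not list of [dose_response_set()] objects.
#' @param train_fraction In (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with `train` and `test` (lists of sets).
#' @export
split_dataset <- function(sets, train_fraction, seed = 1L) {
  if (length(sets) < 2L) stop("need at least 2 molecules to split")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("'train_fraction' must be in (0, 1)")
  n <- length(sets)
  n_train <- min(max(round(train_fraction * n), 1L), n - 1L)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  idx <- sample(n, n_train)
  list(train = sets[sort(idx)], test = sets[sort(setdiff(seq_len(n), idx))])
}

cv_fold_ids <- function(n, k) {
  # balanced fold labels in a fixed order relative to the shuffled rows
  rep_len(seq_len(k), n)
}

#' Random-search cross-validation over a family's hyperparameter grid
#'
#' Samples `n_iterations` distinct parameter combinations uniformly without
#' replacement from the family's grid (exhaustive when the grid is
#' smaller), scores each by k-fold cross-validated mean squared error on
#' the LogEC50 targets, and returns the winning [model_spec()]. Ties go to
#' the earliest-sampled combination.
#'
#' @param table A [quality_table()] of training molecules.
#' @param family Model family code (see [model_spec()]).
#' @param space A [search_space()].
#' @param seed Integer seed driving both the combination sampling and the
#'   fold assignment; fits use seeds derived from it.
#' @param n_trees Trees per forest during the search and in the returned
#'   spec.
#' @return The selected `model_spec`, with attributes `cv_mse` (per
#'   candidate) and `candidates` (the sampled grid rows).
#' @export
random_search <- function(table, family, space = search_space(), seed = 1L,
                          n_trees = 250) {
  grid <- family_grid(family, space)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  n <- length(table$target)
  k <- space$cv_folds
  if (n < k) stop("table has fewer rows than cv_folds")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  take <- min(space$n_iterations, nrow(grid))
  cand <- grid[sample(nrow(grid), take), , drop = FALSE]
  perm <- sample(n)
  fold <- cv_fold_ids(n, k)
  mse <- numeric(take)
  for (ci in seq_len(take)) {
    spec <- grid_row_to_spec(family, cand[ci, , drop = FALSE], n_trees,
                             seed = seed + ci)
    err2 <- 0
    for (f in seq_len(k)) {
      test_rows <- perm[fold == f]
      train_rows <- perm[fold != f]
      m <- fit_model(qt_subset(table, train_rows), spec)
      pred <- predict(m, table$features[test_rows, , drop = FALSE])
      err2 <- err2 + sum((pred - table$target[test_rows])^2)
    }
    mse[ci] <- err2 / n
  }
  best <- which.min(mse)
  spec <- grid_row_to_spec(family, cand[best, , drop = FALSE], n_trees,
                           seed = seed)
  attr(spec, "cv_mse") <- mse
  attr(spec, "candidates") <- cand
  spec
}
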