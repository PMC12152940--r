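#' Quality-metric weight transform
#'
#' Converts per-molecule fit-quality metrics `z` (larger = worse fit) into
#' bootstrap selection probabilities `p_i = exp(-alpha * z_i) / sum_j
#' exp(-alpha * z_j)`. `alpha >= 0` controls how strongly quality is used:
#' `alpha = 0` gives the uniform distribution (quality ignored) and larger
#' `alpha` concentrates mass on well-fit molecules.
#'
#' By default `z` is first divided by its mean (`scaling = "mean"`), so a
#' fixed `alpha` grid is comparable across datasets whose raw quality
#' metrics differ by orders of magnitude; `scaling = "raw"` uses `z` as is.
#'
#' @param z Nonnegative, finite quality metrics.
#' @param alpha Nonnegative scalar.
#' @param scaling `"mean"` (default) or `"raw"`.
#' @return Object of class `weight_vector`: list with `p` (sums to 1),
#'   `alpha`, `z_scaling`.
#' @examples
#' quality_weights(c(0, 1), alpha = 1, scaling = "raw")$p
#' @export
quality_weights <- function(z, alpha, scaling = c("mean", "raw")) {
  scaling <- match.arg(scaling)
  if (any(!is.finite(z)) || any(z < 0)) stop("'z' must be finite and >= 0")
  if (!is.finite(alpha) || alpha < 0) stop("'alpha' must be >= 0")
  zs <- if (scaling == "mean" && mean(z) > 0) z / mean(z) else z
  lw <- -alpha * zs
  p <- exp(lw - max(lw))
  p <- p / sum(p)
  structure(list(p = p, alpha = alpha, z_scaling = scaling),
            class = "weight_vector")
}

#' Specify a model family and its hyperparameters
#'
#' Families: `"RF"` (standard random forest), `"PB_RF"` (parametric
#' bootstrap: bootstrap probabilities from [quality_weights()]), `"W_RF"`
#' (weighted variance-reduction splits with weights `n * p_i`), `"OS_RF"`
#' (output smearing: per-tree Gaussian target noise with variance `beta`,
#' random feature selection disabled), `"VOS_RF"` (variable output
#' smearing: per-point noise variance increasing with `z`, mean variance
#' `beta`), `"SVR"` (epsilon-insensitive RBF support vector regression) and
#' `"WSVR"` (SVR with per-sample cost `n * p_i`).
#'
#' Fractional hyperparameters follow the usual conventions:
#' `max_features` is the fraction of features considered per split and
#' `min_samples_split` the fraction of training points a node needs to be
#' split (converted to a count by round-half-up with floor 2).
#'
#' @param family One of the seven family codes.
#' @param max_features Fraction of features per split (forests without
#'   output smearing).
#' @param min_samples_split Fraction of training points (forests).
#' @param alpha Quality-weight strength (quality-aware families).
#' @param beta Mean smearing variance (OS_RF, VOS_RF).
#' @param epsilon Insensitivity tube half-width (SVR, WSVR).
#' @param n_trees Trees per forest, fixed across compared models
#'   (default 250).
#' @param seed Integer seed for the stochastic fits.
#' @param vos_literal Use the literal `beta * p_i` smearing variance instead
#'   of the default quality-consistent rule (see vignette).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("RF", "PB_RF", "W_RF", "OS_RF", "VOS_RF",
                                  "SVR", "WSVR"),
                       max_features = 1.0, min_samples_split = 0.01,
                       alpha = NULL, beta = NULL, epsilon = NULL,
                       n_trees = 250, seed = 1L, vos_literal = FALSE) {
  family <- match.arg(family)
  needs_alpha <- family %in% c("PB_RF", "W_RF", "VOS_RF", "WSVR")
  needs_beta <- family %in% c("OS_RF", "VOS_RF")
  needs_eps <- family %in% c("SVR", "WSVR")
  if (needs_alpha) {
    if (is.null(alpha)) stop(family, " requires 'alpha'")
    if (alpha < 0) stop("'alpha' must be >= 0")
  } else alpha <- NULL
  if (needs_beta) {
    if (is.null(beta)) stop(family, " requires 'beta'")
    if (beta < 0) stop("'beta' must be >= 0")
  } else beta <- NULL
  if (needs_eps) {
    if (is.null(epsilon)) stop(family, " requires 'epsilon'")
    if (epsilon <= 0) stop("'epsilon' must be > 0")
  } else epsilon <- NULL
  structure(list(family = family, max_features = max_features,
                 min_samples_split = min_samples_split, alpha = alpha,
                 beta = beta, epsilon = epsilon, n_trees = as.integer(n_trees),
                 seed = as.integer(seed), vos_literal = isTRUE(vos_literal)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- c(max_features = x$max_features,
          min_samples_split = x$min_samples_split, alpha = x$alpha,
          beta = x$beta, epsilon = x$epsilon)
  cat("<model_spec>", x$family, "-",
      paste(names(hp), unlist(hp), sep = "=", collapse = ", "),
      sprintf("(n_trees=%d, seed=%d)\n", x$n_trees, x$seed))
  invisible(x)
}

# fraction -> per-split feature count (floor, at least 1)
mtry_from_fraction <- function(frac, p) max(1L, as.integer(floor(frac * p)))

# fraction -> min samples to split a node (round half up, floor 2)
min_split_from_fraction <- function(frac, n) max(2L, as.integer(floor(frac * n + 0.5)))

fit_forest_engine <- function(table, spec, prob = NULL, casew = NULL,
                              smear_sd = NULL, mtry = NULL,
                              keep_inbag = FALSE) {
  X <- table$features
  n <- nrow(X)
  if (n == 0L) stop("cannot fit a model on an empty table")
  if (is.null(prob)) prob <- rep(1 / n, n)
  if (is.null(casew)) casew <- rep(1, n)
  if (is.null(smear_sd)) smear_sd <- numeric(0)
  if (is.null(mtry)) mtry <- mtry_from_fraction(spec$max_features, ncol(X))
  ms <- min_split_from_fraction(spec$min_samples_split, n)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  eng <- .grow_forest_cpp(X, table$target, prob, casew, smear_sd,
                          spec$n_trees, mtry, ms, keep_inbag)
  structure(list(spec = spec, trees = eng$trees,
                 inbag = if (keep_inbag) eng$inbag else NULL,
                 n_train = n, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = c("drq_forest", "drq_model"))
}

#' Fit a standard random forest
#'
#' Baseline regression forest: uniform bootstrap, random feature selection,
#' variance-reduction splits, predictions averaged over trees.
#'
#' @param table A [quality_table()].
#' @param spec A [model_spec()] with `family = "RF"`.
#' @param keep_inbag Record per-tree bootstrap counts (diagnostics).
#' @return A trained model (class `drq_forest`).
#' @export
fit_standard_rf <- function(table, spec, keep_inbag = FALSE) {
  stopifnot(spec$family == "RF")
  fit_forest_engine(table, spec, keep_inbag = keep_inbag)
}

#' Fit a random forest with parametric bootstrap
#'
#' Replaces the uniform bootstrap: each tree's training sample draws the
#' `n` points with replacement with probabilities `p_i` from
#' [quality_weights()], so well-fit molecules are selected more often
#' without discarding poorly fit ones. `alpha = 0` reproduces the standard
#' forest exactly (same seed, same trees).
#'
#' @inheritParams fit_standard_rf
#' @param spec A [model_spec()] with `family = "PB_RF"` and `alpha`.
#' @export
fit_pb_rf <- function(table, spec, keep_inbag = FALSE) {
  stopifnot(spec$family == "PB_RF")
  w <- quality_weights(table$quality, spec$alpha)
  fit_forest_engine(table, spec, prob = w$p, keep_inbag = keep_inbag)
}

#' Fit a weighted random forest
#'
#' Standard bootstrap and feature selection, but splits maximize the
#' weighted variance reduction with per-sample weights `n * p_i` and leaves
#' predict weighted means. The criterion is scale-invariant in the weights;
#' `alpha = 0` reproduces the standard forest exactly.
#'
#' @inheritParams fit_standard_rf
#' @param spec A [model_spec()] with `family = "W_RF"` and `alpha`.
#' @export
fit_weighted_rf <- function(table, spec, keep_inbag = FALSE) {
  stopifnot(spec$family == "W_RF")
  w <- quality_weights(table$quality, spec$alpha)
  n <- length(w$p)
  fit_forest_engine(table, spec, casew = n * w$p, keep_inbag = keep_inbag)
}

#' Fit an output-smearing random forest
#'
#' Per-tree randomness comes from Gaussian noise added to the targets
#' (variance `beta`, fresh per tree) instead of random feature selection:
#' every split considers all features.
#'
#' @inheritParams fit_standard_rf
#' @param spec A [model_spec()] with `family = "OS_RF"` and `beta`.
#' @export
fit_os_rf <- function(table, spec, keep_inbag = FALSE) {
  stopifnot(spec$family == "OS_RF")
  n <- nrow(table$features)
  fit_forest_engine(table, spec, smear_sd = rep(sqrt(spec$beta), n),
                    mtry = ncol(table$features), keep_inbag = keep_inbag)
}

# per-point smearing variances for VOS; mean over points is exactly beta
vos_variances <- function(z, alpha, beta, literal = FALSE) {
  if (literal) {
    w <- quality_weights(z, alpha)
    return(beta * w$p)
  }
  zs <- if (mean(z) > 0) z / mean(z) else z
  e <- exp(alpha * zs - max(alpha * zs))
  beta * e / mean(e)
}

#' Fit a variable-output-smearing random forest
#'
#' As [fit_os_rf()], but the per-point noise variance depends on the
#' quality metric so that poorly fit molecules are smeared more:
#' `variance_i = beta * exp(alpha * z'_i) / mean_j exp(alpha * z'_j)`,
#' whose mean over points is exactly `beta` and which reduces to uniform
#' smearing at `alpha = 0`. `vos_literal = TRUE` in the spec switches to
#' the raw `beta * p_i` rule (which smears well-fit points more; see the
#' methods vignette for why it is not the default).
#'
#' @inheritParams fit_standard_rf
#' @param spec A [model_spec()] with `family = "VOS_RF"`, `alpha`, `beta`.
#' @export
fit_vos_rf <- function(table, spec, keep_inbag = FALSE) {
  stopifnot(spec$family == "VOS_RF")
  v <- vos_variances(table$quality, spec$alpha, spec$beta, spec$vos_literal)
  fit_forest_engine(table, spec, smear_sd = sqrt(v),
                    mtry = ncol(table$features), keep_inbag = keep_inbag)
}

fit_svr_engine <- function(table, spec, sample_cost) {
  X <- table$features
  n <- nrow(X)
  if (n == 0L) stop("cannot fit a model on an empty table")
  gamma <- 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
  K <- .rbf_kernel_cpp(X, X, gamma)
  sol <- .svr_smo_cpp(K, table$target, sample_cost, spec$epsilon,
                      tol = 1e-3, max_iter = 2000000L)
  if (!sol$converged)
    warning("SVR solver hit its iteration cap before reaching tolerance")
  structure(list(spec = spec, beta = sol$beta, b = sol$b, gamma = gamma,
                 X = X, n_train = n, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = c("drq_svr", "drq_model"))
}

#' Fit an epsilon-insensitive support vector regressor (RBF kernel)
#'
#' Kernel width follows the common `1 / (n_features * var(X))` default and
#' the box constraint is `C = 1`; only `epsilon` is tuned.
#'
#' @inheritParams fit_standard_rf
#' @param spec A [model_spec()] with `family = "SVR"` and `epsilon`.
#' @export
fit_svr <- function(table, spec) {
  stopifnot(spec$family == "SVR")
  fit_svr_engine(table, spec, rep(1, nrow(table$features)))
}

#' Fit a weighted support vector regressor
#'
#' Each sample's loss penalty (box constraint) is scaled by `n * p_i` from
#' [quality_weights()], so the fit may ignore the tube violations of poorly
#' fit molecules more cheaply. `alpha = 0` reproduces [fit_svr()] exactly.
#'
#' @inheritParams fit_standard_rf
#' @param spec A [model_spec()] with `family = "WSVR"`, `epsilon`, `alpha`.
#' @export
fit_wsvr <- function(table, spec) {
  stopifnot(spec$family == "WSVR")
  w <- quality_weights(table$quality, spec$alpha)
  n <- length(w$p)
  fit_svr_engine(table, spec, n * w$p)
}

#' Fit any model family from its spec
#'
#' Dispatches to the family-specific `fit_*` function.
#'
#' @inheritParams fit_standard_rf
#' @param spec A [model_spec()].
#' @export
fit_model <- function(table, spec) {
  switch(spec$family,
         RF = fit_standard_rf(table, spec),
         PB_RF = fit_pb_rf(table, spec),
         W_RF = fit_weighted_rf(table, spec),
         OS_RF = fit_os_rf(table, spec),
         VOS_RF = fit_vos_rf(table, spec),
         SVR = fit_svr(table, spec),
         WSVR = fit_wsvr(table, spec))
}

check_feature_dim <- function(object, features) {
  features <- as.matrix(features)
  if (ncol(features) != object$n_features)
    stop("feature dimension mismatch: model trained on ", object$n_features,
         " features, got ", ncol(features))
  features
}

#' Predict LogEC50s for new molecules
#'
#' @param object A trained model.
#' @param features 0/1 feature matrix (same width as at training).
#' @param all_trees Return the per-tree prediction matrix instead of the
#'   forest mean (forests only).
#' @param ... Unused.
#' @return Numeric vector of predicted LogEC50s (or a matrix if
#'   `all_trees = TRUE`).
#' @export
predict.drq_forest <- function(object, features, all_trees = FALSE, ...) {
  features <- check_feature_dim(object, features)
  m <- .predict_forest_cpp(object$trees, features)
  if (all_trees) return(m)
  out <- rowMeans(m)
  names(out) <- rownames(features)
  out
}

#' @rdname predict.drq_forest
#' @export
predict.drq_svr <- function(object, features, ...) {
  features <- check_feature_dim(object, features)
  sv <- which(object$beta != 0)
  out <- if (length(sv) == 0) rep(object$b, nrow(features)) else
    as.vector(.rbf_kernel_cpp(features, object$X[sv, , drop = FALSE],
                              object$gamma) %*% object$beta[sv]) + object$b
  names(out) <- rownames(features)
  out
}

#' @export
print.drq_model <- function(x, ...) {
  cat("<trained model>", x$spec$family, "- trained on", x$n_train,
      "molecules x", x$n_features, "features\n")
  invisible(x)
}

#' Save / load a trained model
#'
#' Single-file on-disk serialization (RDS) of the spec plus fitted state.
#'
#' @param model A trained model.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "drq_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "drq_model")) stop("not a saved drqual model: ", path)
  model
}
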