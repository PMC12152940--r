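#' Assemble the machine-learning training payload
#'
#' Aligns per-molecule EC50 targets and fit-quality metrics with a binary
#' feature matrix into a single table, the payload consumed by every model
#' family. Rows are ordered deterministically by molecule id.
#'
#' @param fits List of per-molecule summaries: [hill_fit()] objects
#'   (regression analysis) or `bayes_summary` objects (Bayesian analysis);
#'   each carries `molecule_id`, a target and a `quality` value.
#' @param features Numeric 0/1 matrix with one row per molecule; rownames
#'   are molecule ids.
#' @return An object of class `quality_table` with elements `molecule_id`,
#'   `features`, `target` (LogEC50) and `quality` (z).
#' @export
quality_table <- function(fits, features) {
  features <- as.matrix(features)
  ids <- unname(vapply(fits, `[[`, character(1), "molecule_id"))
  if (anyDuplicated(ids)) stop("duplicate molecule ids in 'fits'")
  if (length(ids) == 0L && nrow(features) == 0L)
    return(structure(list(molecule_id = character(0), features = features,
                          target = numeric(0), quality = numeric(0)),
                     class = "quality_table"))
  if (is.null(rownames(features)))
    stop("'features' must have molecule ids as rownames")
  fid <- rownames(features)
  if (!setequal(ids, fid)) {
    only_fits <- setdiff(ids, fid)
    only_feat <- setdiff(fid, ids)
    stop("molecule sets differ between fits and features; ",
         "missing features for: ",
         paste(utils::head(only_fits, 10), collapse = ", "),
         if (length(only_fits) == 0) "(none)", "; missing fits for: ",
         paste(utils::head(only_feat, 10), collapse = ", "),
         if (length(only_feat) == 0) "(none)")
  }
  ord <- order(ids, method = "radix") # locale-independent
  ids <- ids[ord]
  fits <- fits[ord]
  target <- unname(vapply(fits, function(f)
    if (!is.null(f$log_ec50)) f$log_ec50 else f$target, numeric(1)))
  quality <- unname(vapply(fits, `[[`, numeric(1), "quality"))
  structure(list(molecule_id = ids,
                 features = features[ids, , drop = FALSE],
                 target = target, quality = quality),
            class = "quality_table")
}

#' @export
print.quality_table <- function(x, ...) {
  cat("<quality_table>", length(x$molecule_id), "molecules,",
      ncol(x$features), "features; target LogEC50 range [",
      sprintf("%.3f, %.3f", min(x$target), max(x$target)),
      "], mean quality", sprintf("%.4g", mean(x$quality)), "\n")
  invisible(x)
}

#' @export
as.data.frame.quality_table <- function(x, ...) {
  data.frame(molecule_id = x$molecule_id, target = x$target,
              quality = x$quality, stringsAsFactors = FALSE)
}

# subset a quality table by row index (used by cross-validation)
qt_subset <- function(table, idx) {
  structure(list(molecule_id = table$molecule_id[idx],
                 features = table$features[idx, , drop = FALSE],
                 target = table$target[idx], quality = table$quality[idx]),
            class = "quality_table")
}

#' Convert dose-response sets into a training table (regression analysis)
#'
#' Runs [fit_hill_regression()] on every molecule and aligns the fitted
#' LogEC50s and mean-squared-residual quality metrics with the feature
#' matrix.
#'
#' @param sets List of [dose_response_set()] objects.
#' @param features 0/1 feature matrix with molecule ids as rownames.
#' @return A [quality_table()].
#' @export
analyze_regression <- function(sets, features) {
  quality_table(lapply(sets, fit_hill_regression), features)
}

#' Convert dose-response sets into a training table (Bayesian analysis)
#'
#' Estimates the measurement-noise variance by pooling replicated
#' (molecule, concentration) groups, evaluates the discretized posterior
#' over Hill parameters for each molecule, and summarizes posterior draws
#' of LogEC50 into a target (mean) and quality metric (variance).
#'
#' @param sets List of [dose_response_set()] objects.
#' @param features 0/1 feature matrix with molecule ids as rownames.
#' @param fallback_sigma2 Noise variance used when no replicated groups
#'   exist (response units squared).
#' @param n_ec50,n_slope Posterior grid resolution (default 100 x 10).
#' @param n_draws Posterior sample size per molecule (default 1000).
#' @param seed Integer seed for the posterior draws.
#' @return A [quality_table()].
#' @export
analyze_bayesian <- function(sets, features, fallback_sigma2 = NULL,
                             n_ec50 = 100, n_slope = 10, n_draws = 1000,
                             seed = 1L) {
  noise <- pooled_variance(sets, fallback = fallback_sigma2)
  seeds <- seed + seq_along(sets) - 1L
  fits <- lapply(seq_along(sets), function(i) {
    g <- posterior_grid(sets[[i]], noise, n_ec50 = n_ec50, n_slope = n_slope)
    s <- posterior_summary(g, n_draws = n_draws, seed = seeds[i])
    s$molecule_id <- sets[[i]]$molecule_id
    s
  })
  quality_table(fits, features)
}
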