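#' Pooled measurement-noise variance across replicated groups
#'
#' Assumes experimental noise is Gaussian and estimates its variance by
#' pooling the unbiased within-group variances of every
#' (molecule, concentration) group with at least two measurements:
#' `sigma2 = sum_g (n_g - 1) s2_g / sum_g (n_g - 1)`. When no group
#' qualifies (or the pooled estimate is exactly zero, which would make the
#' likelihood degenerate) the configured fallback variance is used instead,
#' mirroring the convention of borrowing a noise level from comparable
#' assays.
#'
#' @param sets List of [dose_response_set()] objects.
#' @param fallback Fallback variance (> 0) or `NULL` (error if needed).
#' @return An object of class `noise_model` with `sigma2` and
#'   `source` (`"pooled"` or `"fallback"`).
#' @export
pooled_variance <- function(sets, fallback = NULL) {
  if (inherits(sets, "dose_response_set")) sets <- list(sets)
  num <- 0; den <- 0
  for (s in sets) {
    m <- s$measurements
    for (v in split(m$response, m$concentration)) {
      n <- length(v)
      if (n >= 2L) {
        num <- num + (n - 1) * stats::var(v)
        den <- den + (n - 1)
      }
    }
  }
  if (den > 0 && num / den > 0) {
    structure(list(sigma2 = num / den, source = "pooled"),
              class = "noise_model")
  } else {
    if (is.null(fallback))
      stop("no replicated (molecule, concentration) groups with positive ",
           "variance and no fallback variance configured")
    if (!is.finite(fallback) || fallback <= 0)
      stop("'fallback' variance must be > 0")
    structure(list(sigma2 = fallback, source = "fallback"),
              class = "noise_model")
  }
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> sigma2 = %.4g (%s)\n", x$sigma2, x$source))
  invisible(x)
}

#' Discretized posterior over Hill parameters for one molecule
#'
#' Evaluates the posterior probability of every pair on a grid of LogEC50
#' and HillSlope values under a Gaussian likelihood with known noise
#' variance and uniform priors: LogEC50 spans one decade beyond the tested
#' concentration range (uniform on the log10 scale, matching the Hill
#' parameterization) and HillSlope is uniform on `[0.1, 10]`. Responses are
#' clipped to `[0, 100]` first. The likelihood is accumulated in log space
#' and normalized with the max-subtraction trick, so molecules with many
#' measurements cannot underflow the grid.
#'
#' @param set A [dose_response_set()].
#' @param noise A `noise_model` from [pooled_variance()], or a positive
#'   number taken as the variance.
#' @param n_ec50,n_slope Grid sizes (defaults 100 and 10).
#' @param log_ec50_range Optional length-2 override of the LogEC50 prior
#'   range.
#' @param slope_range HillSlope prior range (default `c(0.1, 10)`).
#' @return An object of class `posterior_grid` with `log_ec50_values`,
#'   `slope_values` and the `n_ec50 x n_slope` matrix `probabilities`
#'   summing to 1.
#' @export
posterior_grid <- function(set, noise, n_ec50 = 100, n_slope = 10,
                           log_ec50_range = NULL, slope_range = c(0.1, 10)) {
  stopifnot(inherits(set, "dose_response_set"))
  if (inherits(noise, "noise_model")) noise <- noise$sigma2
  if (!is.finite(noise) || noise <= 0) stop("noise variance must be > 0")
  if (n_ec50 < 1 || n_slope < 1) stop("empty posterior grid configuration")
  set <- clip_responses(set)
  X <- log10(set$measurements$concentration)
  resp <- set$measurements$response
  if (is.null(log_ec50_range))
    log_ec50_range <- log_ec50_bounds(set$measurements$concentration)
  les <- if (n_ec50 == 1) mean(log_ec50_range) else
    seq(log_ec50_range[1], log_ec50_range[2], length.out = n_ec50)
  hss <- if (n_slope == 1) mean(slope_range) else
    seq(slope_range[1], slope_range[2], length.out = n_slope)

  loglik <- matrix(0, n_ec50, n_slope)
  sd <- sqrt(noise)
  for (j in seq_len(n_slope)) {
    # model responses: n_ec50 x n_meas for this slope
    mu <- vapply(X, function(x) hill_response(x, les, hss[j], set$direction),
                 numeric(n_ec50))
    mu <- matrix(mu, nrow = n_ec50)
    loglik[, j] <- rowSums(stats::dnorm(matrix(resp, n_ec50, length(resp),
                                               byrow = TRUE),
                                        mean = mu, sd = sd, log = TRUE))
  }
  prob <- exp(loglik - max(loglik))
  prob <- prob / sum(prob)
  structure(list(log_ec50_values = les, slope_values = hss,
                 probabilities = prob),
            class = "posterior_grid")
}

#' Summarize a posterior grid into an EC50 target and quality metric
#'
#' Draws `n_draws` grid cells with replacement according to their posterior
#' probabilities and reports the mean of the drawn LogEC50 values as the
#' machine-learning target and their variance as the quality metric
#' (larger variance = less certain EC50). `exact = TRUE` replaces sampling
#' with the exact grid moments, useful for deterministic checks.
#'
#' @param grid A [posterior_grid()].
#' @param n_draws Number of posterior draws (default 1000).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param exact Use exact grid moments instead of sampling.
#' @return An object of class `bayes_summary` with `target`, `quality` and
#'   `n_draws`.
#' @export
posterior_summary <- function(grid, n_draws = 1000, seed = NULL,
                              exact = FALSE) {
  stopifnot(inherits(grid, "posterior_grid"))
  p <- grid$probabilities
  le_cell <- matrix(grid$log_ec50_values, nrow(p), ncol(p))
  if (exact) {
    mu <- sum(p * le_cell)
    v <- sum(p * (le_cell - mu)^2)
    return(structure(list(target = mu, quality = v, n_draws = 0L),
                     class = "bayes_summary"))
  }
  if (n_draws < 1) stop("'n_draws' must be >= 1")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  draws <- sample(length(p), n_draws, replace = TRUE, prob = as.vector(p))
  le <- as.vector(le_cell)[draws]
  structure(list(target = mean(le),
                 quality = if (n_draws == 1) 0 else stats::var(le),
                 n_draws = as.integer(n_draws)),
            class = "bayes_summary")
}

#' @export
print.bayes_summary <- function(x, ...) {
  cat(sprintf("<bayes_summary> target LogEC50 = %.4f, quality = %.4g (%d draws)\n",
              x$target, x$quality, x$n_draws))
  invisible(x)
}

# save/restore .Random.seed so seeded helpers do not disturb callers
get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
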