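#' Configuration for the synthetic dose-response generator
#'
#' Describes a simulated assay with known ground truth. Molecular features
#' are independent Bernoulli(0.1) bits (sparse fingerprint-like vectors)
#' and the true LogEC50 is a sparse linear map of the features, rescaled so
#' that a chosen fraction of molecules falls inside the tested
#' concentration span -- the rest land outside it, deliberately recreating
#' the very-low / very-high-activity molecules whose curve fits are
#' unreliable.
#'
#' @param n_molecules Number of molecules (>= 2).
#' @param feature_dim Number of binary features (default 256).
#' @param n_active Number of features carrying true signal (default 20,
#'   capped at `feature_dim`).
#' @param log_conc_range Log10 span of the shared concentration grid
#'   (default `c(-2, 2)`).
#' @param n_concentrations Grid points (default 8, log-spaced).
#' @param replicates Either a single integer (every molecule is measured
#'   that many times at every grid concentration -- the uniform-quality
#'   design) or a length-2 range `c(lo, hi)` (each molecule's total
#'   measurement count is uniform on `lo:hi`, with concentrations drawn
#'   from the grid with replacement -- the heterogeneous design).
#' @param noise_sigma Either a single response-unit standard deviation
#'   (homoscedastic) or a range `c(lo, hi)` sampled log-uniformly per
#'   molecule (heteroscedastic).
#' @param slope_range True Hill slopes are log-uniform over this range
#'   (default `c(0.5, 2)`, realistic assay steepness around 1).
#' @param frac_in_range Target fraction of true LogEC50s inside the tested
#'   span (default 0.8).
#' @param direction Assay direction for all molecules.
#' @param seed Integer seed; the dataset is a pure function of
#'   (config, seed).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_molecules, feature_dim = 256, n_active = 20,
                       log_conc_range = c(-2, 2), n_concentrations = 8,
                       replicates = 1, noise_sigma = 10,
                       slope_range = c(0.5, 2), frac_in_range = 0.8,
                       direction = c("efficacy", "inhibition"), seed = 1L) {
  direction <- match.arg(direction)
  n_active <- min(n_active, feature_dim)
  stopifnot(n_molecules >= 2, feature_dim >= 1, n_active >= 1,
            n_concentrations >= 2, length(log_conc_range) == 2,
            log_conc_range[1] < log_conc_range[2],
            length(replicates) %in% 1:2, all(replicates >= 1),
            length(noise_sigma) %in% 1:2, all(noise_sigma >= 0),
            frac_in_range > 0, frac_in_range <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 feature_dim = as.integer(feature_dim),
                 n_active = as.integer(n_active),
                 log_conc_range = log_conc_range,
                 n_concentrations = as.integer(n_concentrations),
                 replicates = as.integer(replicates),
                 noise_sigma = noise_sigma, slope_range = slope_range,
                 frac_in_range = frac_in_range, direction = direction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic dose-response dataset with known ground truth
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_dataset`: `sets` (named list of
#'   [dose_response_set()], responses stored unclipped), `features` (0/1
#'   matrix), `truth` (data frame with molecule_id, log_ec50, hill_slope,
#'   sigma), `config`.
#' @examples
#' d <- generate_dataset(sim_config(25, seed = 7))
#' d$truth[1:3, ]
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  n <- config$n_molecules
  d <- config$feature_dim
  ids <- sprintf("M%05d", seq_len(n))
  features <- matrix(stats::rbinom(n * d, 1, 0.1), n, d,
                     dimnames = list(ids, sprintf("f%04d", seq_len(d))))

  w <- numeric(d)
  w[sample.int(d, config$n_active)] <- stats::rnorm(config$n_active)
  score <- as.vector(features %*% w)
  mid <- mean(config$log_conc_range)
  half <- diff(config$log_conc_range) / 2
  if (stats::sd(score) > 0) {
    z <- (score - mean(score)) / stats::sd(score)
    if (config$frac_in_range >= 1) {
      # map the empirical score range just inside the tested span
      log_ec50 <- mid + z / max(abs(z)) * 0.9 * half
    } else {
      q <- stats::qnorm(0.5 + config$frac_in_range / 2)
      log_ec50 <- mid + z * half / q
    }
  } else log_ec50 <- rep(mid, n)

  slopes <- 10^stats::runif(n, log10(config$slope_range[1]),
                            log10(config$slope_range[2]))
  sigma <- if (length(config$noise_sigma) == 1)
    rep(config$noise_sigma, n)
  else 10^stats::runif(n, log10(config$noise_sigma[1]),
                       log10(config$noise_sigma[2]))

  grid_logc <- seq(config$log_conc_range[1], config$log_conc_range[2],
                   length.out = config$n_concentrations)
  sets <- vector("list", n)
  names(sets) <- ids
  for (i in seq_len(n)) {
    logc <- if (length(config$replicates) == 1) {
      rep(grid_logc, times = config$replicates)
    } else {
      nm <- sample(config$replicates[1]:config$replicates[2], 1)
      grid_logc[sample.int(length(grid_logc), nm, replace = TRUE)]
    }
    mu <- hill_response(logc, log_ec50[i], slopes[i], config$direction)
    resp <- mu + stats::rnorm(length(logc), 0, sigma[i])
    sets[[i]] <- dose_response_set(ids[i], 10^logc, resp,
                                   direction = config$direction)
  }
  structure(list(sets = sets, features = features,
                 truth = data.frame(molecule_id = ids, log_ec50 = log_ec50,
                                    hill_slope = slopes, sigma = sigma,
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  nm <- vapply(x$sets, function(s) nrow(s$measurements), integer(1))
  cat("<synthetic_dataset>", length(x$sets), "molecules,",
      sum(nm), "measurements (", min(nm), "-", max(nm), "per molecule ),",
      ncol(x$features), "features\n")
  invisible(x)
}

#' Preset: uniform-quality assay (PubChem-like)
#'
#' Every molecule is measured once at the same 8-point log-spaced
#' concentration grid with a shared noise level (sigma = 10 response
#' units), so curve-fit quality varies little between molecules.
#'
#' @param n Number of molecules (>= 20).
#' @param seed Integer seed.
#' @return A `synthetic_dataset`.
#' @export
pubchem_like <- function(n, seed = 1L) {
  stopifnot(n >= 20)
  generate_dataset(sim_config(n, replicates = 1, noise_sigma = 10,
                              seed = seed))
}

#' Preset: heteroscedastic assay (BASF-like)
#'
#' Per-molecule measurement counts are uniform over 4..100 (drawn from the
#' shared grid with replacement) and per-molecule noise levels are
#' log-uniform over a 10x range (sigma in [5, 50]), so curve-fit quality
#' varies by orders of magnitude across molecules.
#'
#' @inheritParams pubchem_like
#' @export
basf_like <- function(n, seed = 1L) {
  stopifnot(n >= 20)
  generate_dataset(sim_config(n, replicates = c(4, 100),
                              noise_sigma = c(5, 50), seed = seed))
}
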