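#' Construct a dose-response set for one molecule
#'
#' Bundles all (concentration, response) measurements recorded for a single
#' molecule together with the assay direction. Responses are percent effect,
#' nominally 0-100 but stored as recorded (possibly out of range);
#' concentrations must be strictly positive and share one unit per dataset.
#'
#' @param molecule_id Identifier (coerced to character).
#' @param concentration Numeric vector of positive assay concentrations.
#' @param response Numeric vector of percent-effect responses (same length).
#' @param direction `"efficacy"` (response rises with concentration, EC50) or
#'   `"inhibition"` (response falls, IC50).
#' @param replicate_id Optional per-measurement label.
#' @return An object of class `dose_response_set`.
#' @examples
#' drs <- dose_response_set("mol1", 10^seq(-2, 2, length.out = 8),
#'                          c(2, 5, 11, 28, 55, 78, 91, 97))
#' print(drs)
#' @export
dose_response_set <- function(molecule_id, concentration, response,
                              direction = c("efficacy", "inhibition"),
                              replicate_id = NULL) {
  direction <- match.arg(direction)
  if (length(molecule_id) != 1L) stop("'molecule_id' must be a single value")
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) == 0L)
    stop("dose_response_set requires at least one measurement (molecule ",
         molecule_id, ")")
  if (length(response) != length(concentration))
    stop("'concentration' and 'response' lengths differ")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("all concentrations must be finite and > 0 (molecule ",
         molecule_id, ")")
  if (any(!is.finite(response)))
    stop("all responses must be finite (molecule ", molecule_id, ")")
  m <- data.frame(concentration = concentration, response = response)
  if (!is.null(replicate_id)) m$replicate_id <- as.character(replicate_id)
  structure(list(molecule_id = as.character(molecule_id),
                 measurements = m, direction = direction),
            class = "dose_response_set")
}

#' @export
print.dose_response_set <- function(x, ...) {
  cat("<dose_response_set> molecule", x$molecule_id, "-",
      nrow(x$measurements), "measurements,",
      length(unique(x$measurements$concentration)),
      "distinct concentrations,", x$direction, "\n")
  invisible(x)
}

#' Two-parameter Hill equation
#'
#' Evaluates the sigmoidal dose-response curve with asymptotes fixed at 0 and
#' 100. For efficacy data the response at log10 concentration `X` is
#' `100 / (1 + 10^((LogEC50 - X) * HillSlope))`, strictly increasing in `X`
#' and equal to 50 at `X = LogEC50` for every slope. Inhibition uses the
#' mirrored (strictly decreasing) curve with the same midpoint.
#'
#' @param log_concentration Log10 of concentration (the `X` axis); any finite
#'   numeric vector.
#' @param log_ec50 Midpoint parameter, log10 of the EC50/IC50 concentration.
#' @param hill_slope Positive steepness parameter (default 1).
#' @param direction `"efficacy"` or `"inhibition"`.
#' @return Responses in (0, 100), same length as the broadcast inputs.
#' @examples
#' hill_response(0, log_ec50 = 0)            # 50 at the midpoint
#' hill_response(1, log_ec50 = 0)            # 100/1.1
#' hill_response(1, 0, direction = "inhibition")
#' @export
hill_response <- function(log_concentration, log_ec50, hill_slope = 1,
                          direction = c("efficacy", "inhibition")) {
  direction <- match.arg(direction)
  if (any(!is.finite(log_concentration)) || any(!is.finite(log_ec50)))
    stop("non-finite log-concentration or LogEC50")
  if (any(!is.finite(hill_slope)) || any(hill_slope <= 0))
    stop("'hill_slope' must be finite and > 0")
  d <- if (direction == "efficacy") (log_ec50 - log_concentration)
       else (log_concentration - log_ec50)
  100 / (1 + 10^(d * hill_slope))
}

#' Clip responses into the modelable range
#'
#' Out-of-range percent effects are snapped to the Hill curve's asymptotes:
#' values below 0 become 0 and values above 100 become 100, so every
#' measurement is representable by the two-parameter model. In-range values,
#' ordering and counts are untouched; the operation is idempotent.
#'
#' @param x A numeric vector, a `dose_response_set`, or a list of sets.
#' @return Same shape as the input with responses in `[0, 100]`.
#' @export
clip_responses <- function(x) UseMethod("clip_responses")

#' @export
clip_responses.numeric <- function(x) pmin(pmax(x, 0), 100)

#' @export
clip_responses.dose_response_set <- function(x) {
  x$measurements$response <- pmin(pmax(x$measurements$response, 0), 100)
  x
}

#' @export
clip_responses.list <- function(x) lapply(x, clip_responses)

# Bounds for LogEC50 shared by the regression fit and the Bayesian prior:
# one decade below the lowest and above the highest tested concentration.
log_ec50_bounds <- function(concentration) {
  c(log10(0.1 * min(concentration)), log10(10 * max(concentration)))
}

#' Fit the Hill equation to one molecule by least squares
#'
#' Clips responses to `[0, 100]`, then minimizes the summed squared error of
#' the two-parameter Hill curve over `(LogEC50, HillSlope)` within bounds
#' (`LogEC50` one decade beyond the tested concentration range, `HillSlope`
#' in `[0.1, 10]`), starting from the midpoint of the log-concentration range
#' with slope 1. On optimizer failure or a suspect local optimum the fit is
#' restarted from a 5-point LogEC50 grid and the lowest-SSE result kept.
#' When fewer than 3 distinct concentrations are available there are not
#' enough points to estimate a slope, so `HillSlope` is fixed at 1 and only
#' `LogEC50` is optimized.
#'
#' The returned `quality` is the average squared residual per measurement
#' (`SSE / n`), the fit-quality metric `z`: larger means a less reliable
#' EC50.
#'
#' @param set A [dose_response_set()].
#' @return An object of class `hill_fit` with elements `log_ec50`,
#'   `hill_slope`, `direction`, `quality`, `slope_fixed`, `n_measurements`,
#'   `molecule_id`.
#' @examples
#' conc <- 10^seq(-2, 2, length.out = 8)
#' resp <- hill_response(log10(conc), log_ec50 = 0.5)
#' fit_hill_regression(dose_response_set("m", conc, resp))
#' @export
fit_hill_regression <- function(set) {
  stopifnot(inherits(set, "dose_response_set"))
  set <- clip_responses(set)
  conc <- set$measurements$concentration
  resp <- set$measurements$response
  X <- log10(conc)
  n <- length(resp)
  lb <- log_ec50_bounds(conc)
  sse <- function(le, hs) {
    sum((resp - hill_response(X, le, hs, set$direction))^2)
  }
  slope_fixed <- length(unique(conc)) < 3L
  if (slope_fixed) {
    opt <- stats::optimize(function(le) sse(le, 1), interval = lb)
    le <- opt$minimum; hs <- 1; best <- opt$objective
    # optimize() can miss a boundary optimum on flat data; check the edges
    for (cand in lb) if (sse(cand, 1) < best) { best <- sse(cand, 1); le <- cand }
  } else {
    starts <- cbind(log_ec50 = mean(lb), hill_slope = 1)
    fit1 <- try(stats::optim(starts[1L, ], function(p) sse(p[1], p[2]),
                             method = "L-BFGS-B",
                             lower = c(lb[1], 0.1), upper = c(lb[2], 10)),
                silent = TRUE)
    ok <- !inherits(fit1, "try-error") && fit1$convergence == 0
    if (!ok) {
      # restart from a 5-point LogEC50 grid, keep the lowest SSE
      grid <- seq(lb[1], lb[2], length.out = 5)
      fits <- list(if (ok) fit1 else NULL)
      for (g in grid) {
        f <- try(stats::optim(c(g, 1), function(p) sse(p[1], p[2]),
                              method = "L-BFGS-B",
                              lower = c(lb[1], 0.1), upper = c(lb[2], 10)),
                 silent = TRUE)
        if (!inherits(f, "try-error")) fits <- c(fits, list(f))
      }
      fits <- Filter(Negate(is.null), fits)
      if (length(fits) == 0L)
        stop("Hill fit failed for molecule ", set$molecule_id)
      fit1 <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    }
    le <- unname(fit1$par[1]); hs <- unname(fit1$par[2]); best <- fit1$value
  }
  structure(list(log_ec50 = le, hill_slope = hs, direction = set$direction,
                 quality = best / n, slope_fixed = slope_fixed,
                 n_measurements = n, molecule_id = set$molecule_id),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> %s: LogEC50 = %.4f, HillSlope = %.3f%s, z = %.4g (n = %d)\n",
    x$molecule_id, x$log_ec50, x$hill_slope,
    if (x$slope_fixed) " (fixed)" else "", x$quality, x$n_measurements))
  invisible(x)
}
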