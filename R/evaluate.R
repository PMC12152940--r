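#' Evaluate a model by predicting raw dose-response outcomes
#'
#' The dose-response-level test protocol: no EC50 is ever fitted for test
#' molecules. For each held-out measurement the model's predicted LogEC50
#' (from molecular features alone) is pushed through the Hill curve with
#' slope fixed at 1 -- the default slope, since the slope itself is not
#' modeled -- at that measurement's log10 concentration, and compared with
#' the observed response (clipped to `[0, 100]`). The score is the RMSE
#' over all available measurements, so molecules with more experiments
#' weigh more, and molecules whose EC50 could never be fitted reliably
#' still contribute a meaningful test signal.
#'
#' @param model A trained model.
#' @param test_sets List of [dose_response_set()] objects.
#' @param features 0/1 feature matrix containing every test molecule
#'   (rownames are molecule ids).
#' @return Object of class `evaluation_report`: `pairs` (data frame with
#'   molecule_id, concentration, observed, predicted), `rmse`, `n_pairs`,
#'   `model_family`.
#' @export
evaluate_on_dose_response <- function(model, test_sets, features) {
  features <- as.matrix(features)
  ids <- vapply(test_sets, `[[`, character(1), "molecule_id")
  missing <- setdiff(ids, rownames(features))
  if (length(missing) > 0)
    stop("missing features for test molecules: ",
         paste(utils::head(missing, 10), collapse = ", "))
  pred_le <- predict(model, features[ids, , drop = FALSE])
  pairs <- do.call(rbind, lapply(seq_along(test_sets), function(i) {
    s <- clip_responses(test_sets[[i]])
    m <- s$measurements
    data.frame(molecule_id = s$molecule_id,
               concentration = m$concentration,
               observed = m$response,
               predicted = hill_response(log10(m$concentration),
                                         pred_le[i], 1, s$direction),
               stringsAsFactors = FALSE)
  }))
  structure(list(pairs = pairs,
                 rmse = sqrt(mean((pairs$observed - pairs$predicted)^2)),
                 n_pairs = nrow(pairs),
                 model_family = model$spec$family),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: RMSE = %.4f over %d dose-response pairs (%d molecules)\n",
              x$model_family, x$rmse, x$n_pairs,
              length(unique(x$pairs$molecule_id))))
  invisible(x)
}

#' Bootstrap standard deviation of a report's RMSE
#'
#' Resamples the (observed, predicted) pairs -- the unit over which the
#' RMSE is defined -- with replacement `n_boot` times and returns the
#' standard deviation of the resampled RMSEs.
#'
#' @param report An [evaluate_on_dose_response()] report.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Nonnegative scalar.
#' @export
bootstrap_rmse_sd <- function(report, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(report, "evaluation_report"), n_boot >= 2)
  e2 <- (report$pairs$observed - report$pairs$predicted)^2
  n <- length(e2)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  rmses <- vapply(seq_len(n_boot), function(b)
    sqrt(mean(e2[sample.int(n, n, replace = TRUE)])), numeric(1))
  stats::sd(rmses)
}

#' Paired Wilcoxon signed-rank comparison of two reports
#'
#' Tests whether model A's per-measurement squared errors are
#' systematically smaller than model B's on the identical test
#' measurements (one-sided signed-rank test on the paired differences;
#' zero differences dropped). Significance is flagged at the 0.1% level, a
#' deliberately low threshold to limit type-I errors across many
#' comparisons. The exact null distribution is used for 25 or fewer
#' non-zero pairs, the normal approximation above.
#'
#' @param report_a,report_b Reports over the identical measurements in
#'   identical order.
#' @param level Significance level (default 0.001).
#' @return List with `p_value` (one-sided, A better than B), `direction`
#'   (`"a_better"`, `"b_better"` or `"tie"`), `significant`, `n_pairs`
#'   (non-zero pairs used).
#' @export
wilcoxon_compare <- function(report_a, report_b, level = 0.001) {
  pa <- report_a$pairs; pb <- report_b$pairs
  if (nrow(pa) != nrow(pb) ||
      !identical(pa$molecule_id, pb$molecule_id) ||
      !isTRUE(all.equal(pa$concentration, pb$concentration)) ||
      !isTRUE(all.equal(pa$observed, pb$observed)))
    stop("reports do not cover the identical test measurements")
  d <- (pa$observed - pa$predicted)^2 - (pb$observed - pb$predicted)^2
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p_value = 1, direction = "tie", significant = FALSE,
                n_pairs = 0L))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "less",
                       exact = n <= 25, correct = TRUE))
  r <- rank(abs(d))
  direction <- if (sum(r[d < 0]) > sum(r[d > 0])) "a_better" else
    if (sum(r[d < 0]) < sum(r[d > 0])) "b_better" else "tie"
  list(p_value = unname(wt$p.value), direction = direction,
       significant = unname(wt$p.value) < level, n_pairs = n)
}
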