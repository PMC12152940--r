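# shared fixture builders (all data generated in code)

# exact Hill-curve measurements for one molecule
hill_set <- function(log_ec50 = 0.5, slope = 1, id = "m1",
                     log_conc = seq(-2, 2, length.out = 8),
                     direction = "efficacy", noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  resp <- hill_response(log_conc, log_ec50, slope, direction)
  if (noise_sd > 0) resp <- resp + rnorm(length(log_conc), 0, noise_sd)
  dose_response_set(id, 10^log_conc, resp, direction = direction)
}

# tiny quality table with explicit fields (features optionally continuous)
toy_table <- function(features, target, quality,
                      ids = sprintf("m%03d", seq_along(target))) {
  features <- as.matrix(features)
  rownames(features) <- ids
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%02d", seq_len(ncol(features)))
  structure(list(molecule_id = ids, features = features,
                 target = as.numeric(target), quality = as.numeric(quality)),
            class = "quality_table")
}

# minimal evaluation report from raw (observed, predicted) vectors
toy_report <- function(observed, predicted,
                       ids = sprintf("m%03d", seq_along(observed))) {
  pairs <- data.frame(molecule_id = ids, concentration = 1,
                      observed = observed, predicted = predicted,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 rmse = sqrt(mean((observed - predicted)^2)),
                 n_pairs = nrow(pairs), model_family = "toy"),
            class = "evaluation_report")
}

# one-sided exact signed-rank p-value by full sign enumeration (n <= 15)
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 15)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0]) # statistic for alternative "less"
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(w_all <= w_obs)
}
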