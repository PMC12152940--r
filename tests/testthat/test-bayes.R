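test_that("pooled variance matches hand-computed and brute-force values", {
  # two (molecule, concentration) groups, each {40, 60}: s2 = 200 in both
  s1 <- dose_response_set("a", c(1, 1), c(40, 60))
  s2 <- dose_response_set("b", c(5, 5), c(40, 60))
  nm <- pooled_variance(list(s1, s2))
  expect_equal(nm$sigma2, 200)
  expect_equal(nm$source, "pooled")

  # brute force over random small instances
  set.seed(7)
  for (i in 1:100) {
    n_mol <- sample(2:5, 1)
    sets <- lapply(seq_len(n_mol), function(j) {
      conc <- sample(c(1, 3, 10), sample(2:6, 1), replace = TRUE)
      dose_response_set(paste0("m", j), conc, rnorm(length(conc), 50, 12))
    })
    num <- 0; den <- 0
    for (s in sets) {
      m <- s$measurements
      for (cc in unique(m$concentration)) {
        v <- m$response[m$concentration == cc]
        if (length(v) >= 2) {
          num <- num + (length(v) - 1) * var(v)
          den <- den + (length(v) - 1)
        }
      }
    }
    if (den > 0 && num / den > 0)
      expect_equal(pooled_variance(sets)$sigma2, num / den, tolerance = 1e-10)
  }
})

test_that("degenerate or absent replication routes to the fallback", {
  # zero within-group variance is rejected (degenerate likelihood)
  s <- dose_response_set("a", c(1, 1, 1), c(50, 50, 50))
  expect_error(pooled_variance(list(s)), "fallback")
  nm <- pooled_variance(list(s), fallback = 150)
  expect_equal(nm$sigma2, 150)
  expect_equal(nm$source, "fallback")
  # no repeated measurements anywhere
  s2 <- dose_response_set("b", c(1, 10, 100), c(10, 50, 90))
  nm2 <- pooled_variance(list(s2), fallback = 150)
  expect_equal(nm2$sigma2, 150)
  expect_equal(nm2$source, "fallback")
  expect_error(pooled_variance(list(s2), fallback = -3), "> 0")
})

test_that("posterior grid normalizes, concentrates on the truth, and is scale-invariant", {
  set <- hill_set(0, 1)
  g <- posterior_grid(set, noise = 25)
  expect_equal(dim(g$probabilities), c(100L, 10L))
  expect_equal(sum(g$probabilities), 1, tolerance = 1e-12)
  expect_true(all(g$probabilities >= 0))
  expect_equal(length(g$log_ec50_values), 100L)
  expect_equal(range(g$slope_values), c(0.1, 10))
  # prior range: one decade beyond the tested concentrations
  expect_equal(range(g$log_ec50_values), c(-3, 3))

  # data generated exactly at a grid cell + tiny noise variance:
  # mass >= 0.99 lands on that cell
  le_star <- g$log_ec50_values[37]
  hs_star <- g$slope_values[4]
  lc <- seq(-2, 2, length.out = 8)
  set_star <- dose_response_set("m", 10^lc,
                                hill_response(lc, le_star, hs_star))
  g2 <- posterior_grid(set_star, noise = 1e-4)
  expect_gte(g2$probabilities[37, 4], 0.99)

  # flat likelihood when noise dominates
  flat <- dose_response_set("m", 10^lc, rep(50, 8))
  g3 <- posterior_grid(flat, noise = 1e8)
  expect_lt(max(g3$probabilities) / min(g3$probabilities), 1 + 1e-3)

  # many measurements must not underflow (log-space evaluation)
  big <- dose_response_set("m", rep(10^lc, 50),
                           rep(hill_response(lc, 0.3, 1), 50) +
                             rnorm(400, 0, 1))
  g4 <- posterior_grid(big, noise = 1)
  expect_equal(sum(g4$probabilities), 1, tolerance = 1e-12)
  expect_false(any(is.nan(g4$probabilities)))
})

test_that("posterior summary has the right moments and is seed-deterministic", {
  # degenerate posterior: all mass on one cell
  g <- structure(list(log_ec50_values = c(-1, 0, 1, 2),
                      slope_values = 1,
                      probabilities = matrix(c(0, 1, 0, 0), 4, 1)),
                 class = "posterior_grid")
  s <- posterior_summary(g, n_draws = 500, seed = 1)
  expect_equal(s$target, 0)
  expect_equal(s$quality, 0)

  # two cells at LogEC50 {0, 1} with mass 0.5/0.5: Bernoulli moments
  g2 <- structure(list(log_ec50_values = c(0, 1), slope_values = 1,
                       probabilities = matrix(c(0.5, 0.5), 2, 1)),
                  class = "posterior_grid")
  s2 <- posterior_summary(g2, n_draws = 2e5, seed = 2)
  expect_equal(s2$target, 0.5, tolerance = 0.01)
  expect_equal(s2$quality, 0.25, tolerance = 0.01)
  ex <- posterior_summary(g2, exact = TRUE)
  expect_equal(ex$target, 0.5)
  expect_equal(ex$quality, 0.25)

  # determinism
  expect_identical(posterior_summary(g2, 1000, seed = 99),
                   posterior_summary(g2, 1000, seed = 99))
})

test_that("posterior variance shrinks as replication grows", {
  # same molecule measured with increasing replication; average posterior
  # quality over seeds must be non-increasing
  lc <- seq(-2, 2, length.out = 8)
  reps <- c(1, 4, 16)
  qual <- matrix(NA_real_, 20, length(reps))
  for (seed in 1:20) {
    set.seed(seed)
    for (k in seq_along(reps)) {
      lck <- rep(lc, reps[k])
      resp <- hill_response(lck, 0.4, 1.2) + rnorm(length(lck), 0, 10)
      s <- dose_response_set("m", 10^lck, resp)
      g <- posterior_grid(s, noise = 100)
      qual[seed, k] <- posterior_summary(g, n_draws = 2000,
                                         seed = seed)$quality
    }
  }
  avg <- colMeans(qual)
  expect_true(all(diff(avg) <= 0))
})

test_that("bayesian and regression targets agree in the low-noise limit", {
  s <- hill_set(0.6, 1.1, noise_sd = 0.5, seed = 3)
  reg <- fit_hill_regression(s)
  g <- posterior_grid(s, noise = 0.25)
  bay <- posterior_summary(g, exact = TRUE)
  cell_width <- diff(g$log_ec50_values[1:2])
  expect_lt(abs(bay$target - reg$log_ec50), cell_width)
})
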