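# Single-exponential exchange-decay fitting.

test_that("noiseless decays are recovered to at least 6 significant digits", {
  t <- seq(0, 300, by = 30)
  cv <- decay_curve(t, 100 * exp(-0.0103 * t) + 50)
  fit <- fit_single_exponential(cv)
  expect_equal(fit$k_obs, 0.0103, tolerance = 1e-7)
  expect_equal(fit$amplitude, 100, tolerance = 1e-7)
  expect_equal(fit$plateau, 50, tolerance = 1e-7)
  expect_true(fit$converged)
})

test_that("rate estimates are unbiased at 5% multiplicative noise", {
  k_true <- 7.10e-2
  t_half <- log(2) / k_true
  times <- seq(0, 3 * t_half, length.out = 12)
  ks <- sapply(seq_len(40), function(i) {
    tab <- gen_decay_table(c(r = k_true), times = times,
                           plateau_fraction = 0.10, noise_sigma = 0.05,
                           replicates = 1, seed = 500 + i)
    fit_single_exponential(decay_curve(tab$time_min, tab$volume))$k_obs
  })
  sem <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - k_true), 2 * sem + 1e-12)
})

test_that("degenerate curves are rejected with a fit-failure condition", {
  t <- seq(0, 300, by = 30)
  expect_error(fit_single_exponential(decay_curve(t, rep(100, length(t)))),
               class = "hdx_fit_failure")
  expect_error(decay_curve(c(0, 10, 5, 20), c(4, 3, 2, 1)),
               class = "hdx_invalid_parameters")
  expect_error(decay_curve(c(0, 10, 20), c(3, 2, 1)),
               class = "hdx_invalid_parameters")
})

test_that("shifting the time origin rescales amplitude but not the rate", {
  t <- seq(0, 200, by = 20)
  y <- 80 * exp(-0.02 * t) + 10
  f0 <- fit_single_exponential(decay_curve(t, y))
  f1 <- fit_single_exponential(decay_curve(t + 37, y))
  expect_equal(f1$k_obs, f0$k_obs, tolerance = 1e-6)
  expect_equal(f1$amplitude, f0$amplitude * exp(0.02 * 37),
               tolerance = 1e-5)
})

test_that("replicate aggregation uses the SEM, with a single-fit fallback", {
  mk <- function(k, se = 0.001) {
    structure(list(k_obs = k,
                   standard_errors = c(amplitude = NA, k_obs = se,
                                       plateau = NA)),
              class = "exponential_fit")
  }
  a <- aggregate_replicates(list(mk(1), mk(1), mk(1)))
  expect_equal(a$mean_k_obs, 1)
  expect_equal(a$se, 0)
  b <- aggregate_replicates(list(mk(0.009), mk(0.010), mk(0.011)))
  expect_equal(b$mean_k_obs, 0.010)
  expect_equal(b$se, 0.058e-2, tolerance = 1e-3)
  s <- aggregate_replicates(mk(0.5, se = 0.042))
  expect_equal(s$se, 0.042)
  expect_error(aggregate_replicates(list()), class = "hdx_no_data")
})

test_that("plateau diagnostics flag residual-protonation inconsistency", {
  mk <- function(amp, plat) {
    structure(list(amplitude = amp, plateau = plat),
              class = "exponential_fit")
  }
  expect_true(check_plateau(mk(90, 10), 0.10)$ok)
  expect_false(check_plateau(mk(100, 0), 0.10, tolerance = 0.05)$ok)
  neg <- check_plateau(mk(100, -5), 0.10)
  expect_false(neg$ok)
  expect_match(neg$message, "negative")
})

test_that("the long-format table fitter averages replicates per residue", {
  tab <- gen_decay_table(c(L18 = 1.03e-2, G30 = 7.10e-2),
                         noise_sigma = 0, replicates = 3, seed = 7)
  res <- fit_decay_table(tab)
  expect_equal(nrow(res), 2)
  expect_equal(res$k_obs[res$residue == "L18"], 1.03e-2, tolerance = 1e-6)
  expect_equal(res$k_obs[res$residue == "G30"], 7.10e-2, tolerance = 1e-6)
  expect_equal(res$n_replicates, c(3L, 3L))
})
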