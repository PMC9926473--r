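# Reference rate law, calibration fit and sequence-specific intrinsic rates.

test_that("pD is the electrode reading plus the fixed offset", {
  expect_equal(pd_from_ph_star(3.4), 3.8)
  expect_equal(pd_from_ph_star(0.0), 0.4)
  expect_equal(pd_from_ph_star(3.3), 3.7)
  expect_error(pd_from_ph_star(NaN), class = "hdx_invalid_conditions")
})

test_that("rate law reduces to the water term and scales with acid limb", {
  p <- catalysis_params(0, 0, 0.05)
  expect_equal(k_ref(c(1, 3.8, 7), p), rep(0.05, 3))
  # acid limb: doubling A doubles k_ref where the acid channel dominates
  p1 <- catalysis_params(1e8, 1e3, 0)
  p2 <- catalysis_params(2e8, 1e3, 0)
  expect_equal(k_ref(2, p2) / k_ref(2, p1), 2, tolerance = 1e-9)
})

test_that("V minimum matches the closed form and a grid-search oracle", {
  p <- catalysis_params(1e8, 1e10, 0)
  pKw <- 15.24
  pd_star <- (pKw + log10(p$A / p$B)) / 2
  expect_equal(k_ref_minimum_pd(p, pKw), pd_star)
  # independent oracle: dense grid minimization of the rate law
  grid <- seq(1, 14, by = 1e-4)
  kv <- k_ref(grid, p, pKw)
  expect_equal(grid[which.min(kv)], pd_star, tolerance = 1e-3)
  expect_equal(min(kv), 2 * sqrt(p$A * p$B * 10^(-pKw)), tolerance = 1e-6)
})

test_that("log k_ref approaches slope -1 and +1 on the limbs", {
  p <- catalysis_params(1e2, 1e10, 1e-3)
  lk <- function(pd) log10(k_ref(pd, p))
  expect_equal(lk(0.5) - lk(1.5), 1, tolerance = 1e-3)    # acid: slope -1
  expect_equal(lk(14.5) - lk(13.5), 1, tolerance = 1e-3)  # base: slope +1
})

test_that("catalysis fit recovers exact parameters from noiseless data", {
  truth <- catalysis_params(30, 9e9, 0.02)
  d <- gen_pdla_series(truth, noise_sigma = 0)
  fit <- fit_catalysis_params(d$pD, d$k_ref)
  expect_equal(fit$A, truth$A, tolerance = 1e-6)
  expect_equal(fit$B, truth$B, tolerance = 1e-6)
  expect_equal(fit$C, truth$C, tolerance = 1e-6)
  expect_false(attr(fit, "ill_conditioned"))
})

test_that("catalysis fit is accurate under 5% lognormal noise", {
  truth <- catalysis_params(30, 9e9, 0.02)
  rel_err <- sapply(seq_len(20), function(i) {
    d <- gen_pdla_series(truth, noise_sigma = 0.05, seed = 100 + i)
    fit <- fit_catalysis_params(d$pD, d$k_ref)
    c(A = abs(fit$A - truth$A) / truth$A,
      C = abs(fit$C - truth$C) / truth$C)
  })
  expect_lt(median(rel_err["A", ]), 0.15)
  expect_lt(median(rel_err["C", ]), 0.15)
})

test_that("degenerate calibration inputs are flagged", {
  # flat limit: pure water catalysis
  fit <- fit_catalysis_params(seq(1.5, 4.5, 0.5), rep(0.07, 7))
  expect_equal(fit$C, 0.07)
  expect_equal(fit$A, 0)
  expect_equal(fit$B, 0)
  expect_true(attr(fit, "ill_conditioned"))
  # one limb only: V minimum outside sampled range
  p <- catalysis_params(30, 9e9, 1e-4)
  d <- gen_pdla_series(p, pD_grid = seq(1.0, 2.0, 0.2), noise_sigma = 0)
  expect_warning(fit1 <- fit_catalysis_params(d$pD, d$k_ref),
                 "one limb")
  expect_true(attr(fit1, "ill_conditioned"))
  expect_error(fit_catalysis_params(c(1, 2), c(0.1, 0.2)),
               class = "hdx_ill_conditioned_fit")
})

test_that("interior polyalanine NH reproduces the reference rate", {
  p <- pdla_catalysis_defaults()
  for (pd in c(2.0, 3.8, 5.0)) {
    cond <- exchange_conditions(pD = pd)
    k <- k_int_for_residue("AAAAAA", 3, cond, p)
    expect_equal(as.numeric(k), k_ref(pd, p, cond$pKw), tolerance = 1e-12)
  }
})

test_that("k_int depends on the flanking residues but not beyond", {
  cond <- exchange_conditions(pH_star = 3.4)
  p <- pdla_catalysis_defaults()
  # swapping unequal neighbours changes the rate
  k1 <- k_int_for_residue("AGVAA", 3, cond, p)   # V's NH, left neighbour G
  k2 <- k_int_for_residue("AVGAA", 3, cond, p)   # G's NH, left neighbour V
  expect_false(isTRUE(all.equal(as.numeric(k1), as.numeric(k2))))
  # content more than one residue away is irrelevant
  k3 <- k_int_for_residue("WGVKY", 3, cond, p)
  expect_equal(as.numeric(k1), as.numeric(k3), tolerance = 1e-12)
})

test_that("non-exchanging positions and unknown codes are rejected", {
  cond <- exchange_conditions(pH_star = 3.4)
  expect_error(k_int_for_residue("APAA", 2, cond),
               class = "hdx_no_exchangeable_nh")
  expect_error(k_int_for_residue("AAAA", 1, cond),
               class = "hdx_no_exchangeable_nh")
  expect_error(k_int_for_residue("AZAA", 2, cond),
               class = "hdx_unknown_residue")
})

test_that("proline isomer blending is the population-weighted mean", {
  expect_equal(k_int_after_proline(10, 20, 0.8), 18)
  expect_equal(k_int_after_proline(7, 7, 0.33), 7)
  expect_equal(k_int_after_proline(10, 20, 0), 10)
  expect_error(k_int_after_proline(1, 2, 1.2),
               class = "hdx_invalid_parameters")
})

test_that("reference correction rescales only the base/water channels", {
  p <- pdla_catalysis_defaults()
  # identity at factor 1
  cond <- exchange_conditions(pH_star = 3.4)
  k <- k_int_for_residue("AALAA", 3, cond, p)
  expect_equal(as.numeric(apply_reference_correction(k, 1)),
               as.numeric(k))
  # base-dominated pD: whole rate (hence P) scales by the factor
  cond_b <- exchange_conditions(pD = 7)
  kb <- k_int_for_residue("AALAA", 3, cond_b, p)
  expect_equal(as.numeric(apply_reference_correction(kb, 1.35)) /
                 as.numeric(kb), 1.35, tolerance = 1e-4)
  # acid-dominated pD: nearly unchanged
  cond_a <- exchange_conditions(pD = 0.5)
  ka <- k_int_for_residue("AALAA", 3, cond_a, p)
  expect_equal(as.numeric(apply_reference_correction(ka, 1.35)) /
                 as.numeric(ka), 1, tolerance = 0.01)
  expect_error(apply_reference_correction(k, 0),
               class = "hdx_invalid_parameters")
})

test_that("every standard residue has positive factors; Ala factors are 1", {
  f <- sidechain_factors(3.8)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (aa in aas) {
    code <- if (aa == "P") "P_trans" else aa
    expect_true(all(unlist(f[code, ]) > 0))
  }
  expect_equal(unname(unlist(f["A", ])), rep(1, 4))
  expect_equal(unname(unlist(f["G", "AL"])), 10^-0.22)
})
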