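# EX2 protection factors, H-bond fractions and class tallies.

fx <- bdpa_fixture()
meas <- is.finite(fx$table$kobs_e2) & is.finite(fx$table$kint_e2)

test_that("published protection factors are recovered from the rate ratio", {
  tab <- fx$table[meas, ]
  P <- protection_factor(tab$kint_e2, tab$kobs_e2)
  expect_true(all(abs(P - tab$P) <= 0.1))
  one_dec <- function(res) round(P[tab$residue == res], 1)
  expect_equal(one_dec("A49"), 5.2)
  expect_equal(one_dec("L18"), 1.0)
  expect_equal(one_dec("G30"), 1.6)
})

test_that("protection factor propagates the k_obs relative error", {
  P <- protection_factor(15.30e-2, 2.93e-2, k_obs_se = 0.16e-2)
  expect_equal(round(as.numeric(P), 1), 5.2)
  expect_equal(attr(P, "se"), as.numeric(P) * 0.16 / 2.93,
               tolerance = 1e-12)
  expect_error(protection_factor(1, 0), class = "hdx_invalid_rate")
  expect_error(protection_factor(-1, 1), class = "hdx_invalid_rate")
})

test_that("EX2 H-bond fraction and breakage free energy behave analytically", {
  expect_equal(f_hbond(2.0), 0.50)
  expect_equal(round(f_hbond(5.2), 2), 0.81)
  expect_equal(f_hbond(1), 0)
  expect_true(is.na(f_hbond(0.8)))
  expect_equal(dG_breakage(2.0, 288.15), 0)
  expect_equal(dG_breakage(2.0, 310), 0)
  expect_equal(round(dG_breakage(5.2, 288.15), 2), 0.82)
  expect_equal(dG_breakage(1.5, 288.15), 1.987e-3 * 288.15 * log(0.5))
  expect_equal(round(dG_breakage(1.5, 288.15), 1), -0.4)
  expect_true(is.na(dG_breakage(1.0)))
})

test_that("round trip through P is exact and conversions are monotone", {
  set.seed(11)
  for (i in 1:25) {
    k <- runif(1, 1e-4, 1)
    P <- runif(1, 1, 20)
    expect_equal(f_hbond(protection_factor(k * P, k)), 1 - 1 / P,
                 tolerance = 1e-12)
  }
  Ps <- seq(1.01, 30, length.out = 200)
  expect_true(all(diff(f_hbond(Ps)) > 0))
  expect_true(all(diff(dG_breakage(Ps)) > 0))
})

test_that("classification thresholds follow the one-decimal rounding rule", {
  expect_equal(as.character(classify_protection(5.2)), "high")
  expect_equal(as.character(classify_protection(2.0)), "significant")
  expect_equal(as.character(classify_protection(1.9)), "unprotected")
  # borderline: 1.95 rounds to 2.0, hence significant
  expect_equal(as.character(classify_protection(3.63 / 1.86)),
               "significant")
  expect_equal(as.character(classify_protection(4.0)), "high")
  expect_equal(as.character(classify_protection(3.96)), "high")
})

test_that("class tallies reproduce the published counts", {
  tly <- tally_classes(fx$table$P)
  expect_equal(tly$followed, 29)
  expect_equal(tly$high, 4)
  expect_equal(tly$significant, 17)
  expect_equal(tly$protected, 21)
  empty <- tally_classes(numeric(0))
  expect_equal(empty$followed, 0)
  expect_equal(empty$high, 0)
  one <- tally_classes(10)
  expect_equal(one$followed, 1)
  expect_equal(one$high, 1)
})

test_that("the C-terminal helix is the most protected region", {
  rs <- region_summary(fx$table$position, fx$table$P, fx$regions)
  expect_equal(rs$name[rs$rank == 1], "H3")
  expect_false(any(rs$tied))
  # identical P everywhere ties all regions
  tied <- region_summary(c(12, 30, 45), rep(3, 3), fx$regions)
  expect_true(all(tied$tied))
  # single-residue region reports that residue's P
  single <- region_summary(12, 2.5,
                           data.frame(name = "X", first = 12, last = 12))
  expect_equal(single$mean_P, 2.5)
  expect_equal(single$n, 1)
  # a region without measured residues is absent, not zero
  none <- region_summary(12, 2.5, helix_regions())
  expect_false("H3" %in% none$name)
})

test_that("the assembled protection table joins rates and derives classes", {
  tab <- fx$table[meas, ]
  pt <- protection_table(
    data.frame(position = tab$position, k_obs = tab$kobs_e2 * 1e-2,
               se = tab$kobs_se_e2 * 1e-2),
    data.frame(position = fx$table$position, residue = fx$table$residue,
               kint = fx$table$kint_e2 * 1e-2))
  expect_equal(nrow(pt), nrow(fx$table))
  a49 <- pt[pt$residue == "A49", ]
  expect_equal(round(a49$P, 1), 5.2)
  expect_equal(as.character(a49$class), "high")
  expect_equal(a49$region, "H3")
  expect_equal(round(a49$dG_breakage, 2), 0.82)
  expect_true(all(is.na(pt$P[!meas])))
})
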