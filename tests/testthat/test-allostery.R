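test_that("the partition ratio reproduces the two-site binding gain", {
  # toy: unbound weight 1, bound weight c_ref/Kd for each receptor state
  wI <- list(bound = 150 / 23, unbound = 1)
  wA <- list(bound = 150 / 850, unbound = 1)
  pr <- partition_ratio(wI, wA, conc = c(0, 150), c_ref = 150)
  gain <- (1 + 150 / 23) / (1 + 150 / 850)
  expect_equal(pr$rho[pr$conc_mM == 150], gain, tolerance = 1e-12)
  expect_equal(gain, 6.394, tolerance = 1e-3)
  expect_equal(pr$rho[pr$conc_mM == 0], 1)
})

test_that("rho is exactly 1 at zero sodium and monotone for tighter sites", {
  wI <- list(bound = 5, unbound = 1)
  wA <- list(bound = 0.2, unbound = 1)
  pr <- partition_ratio(wI, wA, conc = c(0, 10, 50, 250, 1000))
  expect_equal(pr$rho[1], 1)
  expect_true(all(diff(pr$rho) > 0))
  # constant ratio when neither binds: rho = 1 everywhere
  w0 <- list(bound = 1e-12, unbound = 1)
  pr0 <- partition_ratio(w0, w0, conc = c(0, 100, 1000))
  expect_equal(pr0$rho, rep(1, 3), tolerance = 1e-9)
})

test_that("rho_of_sodium normalizes by the zero-concentration reference", {
  d <- tibble::tibble(conc_mM = c(0, 100), ratio = c(2, 6))
  out <- rho_of_sodium(d)
  expect_equal(out$rho, c(1, 3))
  expect_error(rho_of_sodium(tibble::tibble(conc_mM = 100, ratio = 6)),
               "reference")
})

test_that("L50 covers antagonist, agonist and saturating regimes", {
  expect_equal(ligand_l50(4, 2, 2), 4)                # antagonist
  expect_equal(ligand_l50(4, 9, 0), 40)               # full agonist
  expect_lt(ligand_l50(4, 1, 1e9), 1e-6)              # tau_b -> infinity
  expect_error(ligand_l50(-1, 1, 1), "K_star")
})

test_that("bound fraction is the simple binding isotherm", {
  expect_equal(bound_fraction(40, 40), 0.5)
  expect_equal(bound_fraction(1, 40), 1 / 41)
  expect_equal(bound_fraction(1e9, 40), 1, tolerance = 1e-6)
  expect_error(bound_fraction(0, 0), "both")
})

test_that("the percent-change curve follows (1 - rho)/(x + rho)", {
  expect_equal(percent_change_curve(1, x = 0.25)$pct_change, 0)
  expect_equal(percent_change_curve(2, x = 0.25)$pct_change, -4 / 9,
               tolerance = 1e-12)
  expect_equal(round(percent_change_curve(2, x = 0.25)$pct_change, 4),
               -0.4444)
  # bounds: for rho >= 1 the change lies in (-1, 0]
  rho <- c(1, 1.5, 5, 50, 5000)
  pc <- percent_change_curve(rho, x = 0.25)$pct_change
  expect_true(all(pc <= 0 & pc > -1))
  expect_error(percent_change_curve(2, x = 0), "x must")
})

test_that("antagonists are invariant: tau_u = tau_b means no change", {
  # equal equilibrium constants at every concentration: L50 constant,
  # rho = 1, percent change identically zero
  l50s <- vapply(c(0, 10, 100, 1000), function(cc) ligand_l50(4, 3, 3),
                 numeric(1))
  rho <- l50s / l50s[1]
  expect_equal(percent_change_curve(rho, x = 0.25)$pct_change, rep(0, 4))
})

test_that("the sodium IC50 solves the percent-change equation", {
  conc <- exp(seq(log(5), log(2000), length.out = 400))
  curve <- tibble::tibble(conc_mM = conc, rho = 1 + conc / 100)
  out <- sodium_ic50(curve, level = 0.5, x = 0.25)
  # (1 - rho)/(0.25 + rho) = -1/2  =>  rho = 2.25  =>  c = 125 mM
  expect_true(out$reached)
  expect_equal(out$ic50_mM, 125, tolerance = 0.5)
  # a flat curve never reaches the level
  flat <- tibble::tibble(conc_mM = conc, rho = rep(1, length(conc)))
  out2 <- sodium_ic50(flat, level = 0.5)
  expect_false(out2$reached)
  expect_true(is.na(out2$ic50_mM))
})

test_that("bootstrap curves yield a quartile interval", {
  conc <- exp(seq(log(5), log(2000), length.out = 100))
  mk <- function(c0, s) tibble::tibble(sample = s, conc_mM = conc,
                                       rho = 1 + conc / c0)
  curves <- dplyr::bind_rows(mk(80, 1), mk(100, 2), mk(120, 3))
  out <- sodium_ic50(curves, level = 0.5, x = 0.25)
  expect_equal(out$ic50_mM, 125, tolerance = 1)
  expect_lt(out$q1, out$ic50_mM)
  expect_gt(out$q3, out$ic50_mM)
})

test_that("the two-state receptor object summarizes the prediction", {
  conc <- exp(seq(log(5), log(2000), length.out = 100))
  curve <- percent_change_curve(
    tibble::tibble(conc_mM = conc, rho = 1 + conc / 100), x = 0.25)
  tsr <- two_state_receptor(curve, K_star = 4, L = 1)
  expect_s3_class(tsr, "two_state_receptor")
  expect_equal(glance(tsr)$ic50_mM, 125, tolerance = 0.5)
  expect_equal(tsr$x, 0.25)
})
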