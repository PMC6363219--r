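test_that("identical seeds reproduce trajectories bit-identically", {
  ls <- landscape_preset("two_well")
  sp <- umbrella_ladder(0, 0, k_bias = 0.5)[1, ]
  t1 <- simulate_trajectory(ls, sp, 5000, seed = 99)
  t2 <- simulate_trajectory(ls, sp, 5000, seed = 99)
  expect_identical(t1$frames$z, t2$frames$z)
  expect_identical(t1$frames$c, t2$frames$c)
  t3 <- simulate_trajectory(ls, sp, 5000, seed = 100)
  expect_false(identical(t1$frames$z, t3$frames$z))
})

test_that("free diffusion has the expected mean squared displacement", {
  ls <- flat_landscape(z_range = c(-5000, 5000))
  tr <- simulate_trajectory(ls, unbiased_spec(), 2e5, seed = 42, z_init = 0)
  z <- tr$frames$z
  lagf <- 10
  msd <- mean(diff(z, lag = lagf)^2)
  expected <- 2 * ls$D_z * tr$dt * lagf
  # displacement^2 has variance 2*expected^2 per (correlated) sample
  se <- sqrt(2) * expected / sqrt(length(z) / lagf)
  expect_lt(abs(msd - expected), 3 * se)
})

test_that("umbrella sampling reproduces the harmonic Boltzmann variance", {
  ls <- flat_landscape(z_range = c(-50, 50))
  sp <- umbrella_ladder(0, 0, k_bias = 10)[1, ]
  # small dt keeps the integrator's O(dt) variance inflation below the
  # statistical resolution of the test
  tr <- simulate_trajectory(ls, sp, 8e5, dt = 2e-5, stride = 20, seed = 3,
                            burn_in = 1e4)
  v <- var(tr$frames$z)
  expect_equal(v, ls$kBT / 10, tolerance = 0.05)
})

test_that("window ladder covers the umbrella range at the stated spacing", {
  lad <- umbrella_ladder(-35, 40, spacing = 0.5)
  expect_equal(nrow(lad), 151)
  expect_true(all(lad$k_bias == 10))
  expect_equal(diff(lad$z0)[1], 0.5)
  expect_error(umbrella_ladder(0, 1, spacing = 0), "spacing")
})

test_that("long unbiased runs converge to the Boltzmann distribution", {
  # fast-mixing single-well landscape; decorrelated subsamples feed a
  # chi-square test against the analytic bin probabilities
  ls <- build_landscape(
    tibble::tibble(amp = -2, z0 = 0, sz = 1.5, c0 = 0, sc = 1e6),
    kappa_c = 1, z_range = c(-6, 6))
  tr <- simulate_trajectory(ls, unbiased_spec(), 2e7, dt = 2e-4, stride = 10,
                            seed = 11, z_init = 0)
  z <- tr$frames$z
  expect_gte(length(z), 1e5)
  idx <- seq(1000, length(z), by = 500)   # ~1 ns apart: independent
  edges <- seq(-6, 6, length.out = 16)
  obs <- table(cut(z[idx], edges))
  prof <- ground_truth_profile(ls, bins = 600)
  w <- exp(-prof$G / ls$kBT)
  p <- vapply(seq_len(15), function(b) {
    sum(w[prof$z >= edges[b] & prof$z < edges[b + 1]])
  }, numeric(1))
  p <- p / sum(p)
  keep <- p > 1e-4
  ct <- suppressWarnings(
    stats::chisq.test(as.vector(obs)[keep], p = p[keep] / sum(p[keep])))
  expect_gt(ct$p.value, 0.01)
})

test_that("window means sit at the biased-Boltzmann mean within 3 SE", {
  ls <- landscape_preset("two_well")
  for (z0 in c(-10, 3)) {
    sp <- umbrella_ladder(z0, z0, k_bias = 0.5)[1, ]
    tr <- simulate_trajectory(ls, sp, 4e5, seed = 5 + z0, burn_in = 2e4)
    z <- tr$frames$z
    prof <- ground_truth_profile(ls, bins = 2000)
    wt <- exp(-(prof$G + 0.5 * 0.5 * (prof$z - z0)^2) / ls$kBT)
    m_an <- sum(wt * prof$z) / sum(wt)
    blocks <- split(z, ceiling(seq_along(z) / 4000))
    bm <- vapply(blocks, mean, numeric(1))
    se <- sd(bm) / sqrt(length(bm))
    expect_lt(abs(mean(z) - m_an), 3 * se)
  }
})

test_that("unstable step sizes are rejected", {
  ls <- landscape_preset("two_well")
  expect_error(
    simulate_trajectory(ls, unbiased_spec(), 100, dt = 0.05),
    "unstable step size")
  expect_error(simulate_trajectory(ls, unbiased_spec(), -5), "negative")
})

test_that("feature emission is seeded, noisy, and keeps the slow mode", {
  ls <- landscape_preset("receptor")
  tr <- simulate_ensembles(ls, umbrella_ladder(-10, 10, spacing = 5,
                                               k_bias = 0.5),
                           n_steps = 5000, seed = 1, burn_in = 1000)
  expect_error(emit_features(tr, n_features = 1), "n_features")
  expect_error(emit_features(tr, snr = 0), "snr")
  fa <- emit_features(tr, n_features = 6, snr = 10, seed = 2)
  fb <- emit_features(tr, n_features = 6, snr = 10, seed = 2)
  expect_identical(fa$frames$feat_3, fb$frames$feat_3)
  # infinite snr: first feature is exactly the conformational coordinate
  fi <- emit_features(tr, n_features = 4, snr = Inf, seed = 2)
  expect_identical(fi$frames$feat_1, fi$frames$c)
  expect_equal(nrow(fa$sensors), 6)
})

test_that("trajectory sets round-trip through flat files", {
  ls <- landscape_preset("two_well")
  tr <- simulate_ensembles(ls, umbrella_ladder(-5, 5, spacing = 5,
                                               k_bias = 0.5),
                           n_steps = 2000, unbiased_steps = 2000, seed = 4,
                           burn_in = 500)
  tr <- emit_features(tr, n_features = 3, snr = 5, seed = 1)
  dir <- tempfile("trajio")
  write_trajectories(tr, dir)
  tr2 <- read_trajectories(dir)
  expect_equal(tr2$dt, tr$dt)
  expect_equal(as.data.frame(tr2$frames), as.data.frame(tr$frames),
               tolerance = 1e-12)
  expect_equal(tr2$sensors$z_sensor, tr$sensors$z_sensor)
  unlink(dir, recursive = TRUE)
})
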