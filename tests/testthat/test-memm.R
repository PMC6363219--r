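# build a dtraj_set directly from a discrete state series
dtrajs_from_series <- function(series_list, n_states, dt = 0.002) {
  map <- microstate_map(c(0, n_states), n_zbins = n_states)
  fr <- purrr::imap_dfr(series_list, function(s, i) {
    tibble::tibble(traj_id = paste0("t", i), ensemble_id = "unbiased",
                   microstate = as.integer(s - 1))
  })
  structure(list(frames = fr, map = map, specs = unbiased_spec(), dt = dt,
                 n_dropped = 0L),
            class = "dtraj_set")
}

test_that("symmetric two-state counts give the uniform distribution", {
  # 50/50 self and cross counts via an alternating + repeating series
  s <- rep(c(1, 1, 2, 2), 500)
  mm <- estimate_tram(dtrajs_from_series(list(s), 2), lag = 1, tol = 1e-14)
  expect_equal(mm$pi, c(0.5, 0.5), tolerance = 1e-3)
})

test_that("single-ensemble TRAM equals the reversible MSM estimator", {
  T0 <- matrix(c(0.90, 0.10, 0.00,
                 0.05, 0.90, 0.05,
                 0.00, 0.10, 0.90), 3, 3, byrow = TRUE)
  s <- simulate_chain(T0, 3e4, seed = 8)
  d <- dtrajs_from_series(list(s), 3)
  mm <- estimate_tram(d, lag = 1, tol = 1e-15, max_iter = 2e5)
  C <- matrix(0, 3, 3)
  for (t in seq_len(length(s) - 1)) C[s[t], s[t + 1]] <- C[s[t], s[t + 1]] + 1
  oracle <- rev_mle(C)
  expect_lt(max(abs(mm$T - oracle$T)), 1e-8)
  expect_lt(max(abs(mm$pi - oracle$pi)), 1e-8)
})

test_that("a sampled reversible chain's stationary law is recovered", {
  pi0 <- c(0.5, 0.3, 0.2)
  T0 <- matrix(c(0.8, 0.12, 0.08,
                 0.2, 0.7, 0.1,
                 0.2, 0.15, 0.65), 3, 3, byrow = TRUE)
  # symmetrize the flux so T0 is exactly reversible wrt pi0
  X <- (pi0 * T0 + t(pi0 * T0)) / 2
  T0 <- X / rowSums(X); pi0 <- rowSums(X) / sum(X)
  n <- 5e4
  s <- simulate_chain(T0, n, seed = 3)
  mm <- estimate_tram(dtrajs_from_series(list(s), 3), lag = 1, tol = 1e-13)
  t2 <- implied_timescales(T0, lag_ns = 1, n = 1)$timescale_ns
  n_eff <- n / (2 * t2)
  se <- sqrt(pi0 * (1 - pi0) / n_eff)
  expect_true(all(abs(mm$pi - pi0) < 3 * se))
})

test_that("TRAM log-likelihood is non-decreasing once feasible", {
  s <- simulate_chain(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
                      5e3, seed = 5)
  mm <- estimate_tram(dtrajs_from_series(list(s), 2), lag = 1)
  ll <- mm$loglik
  burn <- min(20, length(ll) - 1)
  expect_true(all(diff(ll[-seq_len(burn)]) > -1e-8))
})

test_that("implied timescales follow the closed form", {
  T <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)   # eigenvalue 0.8
  its <- implied_timescales(T, lag_ns = 0.4, n = 1)
  expect_equal(its$timescale_ns, -0.4 / log(0.8), tolerance = 1e-12)
  expect_equal(its$timescale_ns, 1.7926, tolerance = 1e-4)
  # eigenvalue at 1: infinite timescale
  Tb <- diag(2)
  expect_true(is.infinite(implied_timescales(Tb, 0.4, 1)$timescale_ns))
  # non-reversible input with complex spectrum errors
  Tc <- matrix(c(0.1, 0.9, 0, 0, 0.1, 0.9, 0.9, 0, 0.1), 3, 3, byrow = TRUE)
  expect_error(implied_timescales(Tc, 0.4), "reversible")
})

test_that("the implied-timescale ladder includes the chosen lag", {
  T0 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  s <- simulate_chain(T0, 2e4, seed = 12)
  d <- dtrajs_from_series(list(s), 2)
  lad <- implied_timescales_ladder(d, lags = c(1, 2, 5), n = 1)
  expect_equal(sort(unique(lad$lag_frames)), c(1L, 2L, 5L))
  expect_true(all(is.finite(lad$timescale_ns)))
})

test_that("the z profile integrates out clusters by log-sum-exp", {
  kBT <- 0.616
  # two clusters, both at G = 0: the combined bin is lower by kBT ln 2
  cl <- list(centers = matrix(c(-1, 1), 2, 1))
  class(cl) <- "tic_clusters"
  map <- microstate_map(c(0, 3), n_zbins = 3, clusters = cl)
  base <- make_fake_memm(rep(0, 3))
  m <- base
  m$map <- map
  m$G <- c(0, 0, 1, Inf, 2, Inf)   # bins: (0,0), (1,empty), (2,empty)
  m$pi <- exp(-m$G / kBT); m$pi[is.infinite(m$G)] <- 0
  m$pi <- m$pi / sum(m$pi)
  prof <- free_energy_profile(m)
  # bin 1 before anchoring: -kBT ln(2); bins 2,3 keep their single values
  expect_equal(prof$G[2] - prof$G[1], 1 + kBT * log(2), tolerance = 1e-10)
  expect_equal(prof$G[3] - prof$G[2], 1, tolerance = 1e-10)
  # invariance under a constant shift of all state energies
  m2 <- m
  m2$G <- m$G + 3.7
  expect_equal(free_energy_profile(m2)$G, prof$G, tolerance = 1e-10)
})

test_that("bootstrap resampling keeps umbrella data and hits the fraction", {
  ls <- landscape_preset("two_well")
  tr <- simulate_ensembles(ls, umbrella_ladder(-10, 10, spacing = 10,
                                               k_bias = 0.5),
                           n_steps = 3000, unbiased_steps = 3000, seed = 2,
                           burn_in = 500)
  bs <- bootstrap_resample(tr, n_samples = 3, frac = 0.9, seed = 7)
  expect_length(bs, 3)
  n_umb <- sum(tr$frames$ensemble_id != "unbiased")
  n_unb <- sum(tr$frames$ensemble_id == "unbiased")
  for (b in bs) {
    expect_equal(sum(b$frames$ensemble_id != "unbiased"), n_umb)
    expect_gte(sum(b$frames$ensemble_id == "unbiased"), 0.9 * n_unb)
  }
  # a single unbiased trajectory at frac 1 reproduces the full set
  one <- tr
  one$frames <- one$frames[one$frames$traj_id %in%
                             c(one$frames$traj_id[1],
                               "ub_from_win_1"), ]
  b1 <- bootstrap_resample(one, n_samples = 1, frac = 1, seed = 1)[[1]]
  expect_equal(sum(b1$frames$ensemble_id == "unbiased"),
               sum(one$frames$ensemble_id == "unbiased"))
  expect_error(bootstrap_resample(tr, frac = 1.5), "frac")
})

test_that("quartile summaries follow order statistics", {
  q <- quartile_summary(1:13)
  expect_equal(q$median, 7)
  expect_equal(q$q1, 4)
  expect_equal(q$q3, 10)
  expect_equal(q$err_lo, 3)
  expect_equal(q$err_hi, 3)
})
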