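make_frames <- function(X, dt = 0.002) {
  colnames(X) <- paste0("feat_", seq_len(ncol(X)))
  fr <- tibble::tibble(traj_id = "t1", ensemble_id = "unbiased",
                       time = (seq_len(nrow(X)) - 1) * dt)
  as_traj_set(dplyr::bind_cols(fr, tibble::as_tibble(X)), unbiased_spec(),
              dt = dt)
}

test_that("white-noise features have near-zero tICA eigenvalues", {
  set.seed(1)
  tr <- make_frames(matrix(rnorm(1e5 * 4), ncol = 4))
  m <- estimate_tica(tr, lag = 0.1, n_components = 4)
  expect_lt(max(abs(m$eigenvalues)), 0.05)
})

test_that("a telegraph process gives eigenvalue exp(-lag/t_r)", {
  # two-state jump process, switch rate k each way: relaxation time
  # t_r = 1/(2k); analytic autocorrelation exp(-t/t_r)
  set.seed(7)
  n <- 2e5; dt <- 0.002; k <- 5
  flips <- rbinom(n, 1, k * dt)
  s <- cumsum(flips) %% 2
  X <- cbind(s + rnorm(n, sd = 0.01), rnorm(n))
  m <- estimate_tica(make_frames(X, dt), lag = 0.1, n_components = 2)
  t_r <- 1 / (2 * k)
  lam_an <- exp(-0.1 / t_r)
  n_eff <- n * dt / (2 * t_r)
  se <- (1 - lam_an^2) / sqrt(n_eff)
  expect_lt(abs(m$eigenvalues[1] - lam_an), 3 * se)
})

test_that("tICA eigenvalues are invariant under affine feature rescaling", {
  set.seed(3)
  n <- 5e4
  s <- cumsum(rbinom(n, 1, 0.01)) %% 2
  X <- cbind(s + rnorm(n, sd = 0.05), rnorm(n), 0.5 * s + rnorm(n, sd = 0.2))
  m1 <- estimate_tica(make_frames(X), lag = 0.1)
  X2 <- sweep(sweep(X, 2, c(3, 0.25, 10), "*"), 2, c(-2, 5, 100), "+")
  m2 <- estimate_tica(make_frames(X2), lag = 0.1)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-8)
})

test_that("projections of the training data are whitened", {
  set.seed(5)
  n <- 4e4
  s <- cumsum(rbinom(n, 1, 0.02)) %% 2
  X <- cbind(s + rnorm(n, sd = 0.1), rnorm(n))
  tr <- make_frames(X)
  m <- estimate_tica(tr, lag = 0.1, n_components = 2)
  pr <- project_tica(tr, m)
  expect_equal(var(pr$frames$tic_1), 1, tolerance = 0.05)
  expect_equal(var(pr$frames$tic_2), 1, tolerance = 0.05)
})

test_that("the dominant tIC recovers the slow conformational mode", {
  ls <- landscape_preset("receptor")
  tr <- simulate_ensembles(ls, umbrella_ladder(-30, 35, spacing = 5,
                                               k_bias = 0.5),
                           n_steps = 30000, unbiased_steps = 30000,
                           seed = 9)
  tr <- emit_features(tr, n_features = 12, snr = 10, seed = 10)
  m <- estimate_tica(tr, lag = 0.1, n_components = 2)
  pr <- project_tica(tr, m)
  expect_gt(abs(cor(pr$frames$tic_1, pr$frames$c)), 0.9)
})

test_that("feature-tIC correlation selects by the |r| threshold", {
  set.seed(11)
  n <- 1e4
  s <- cumsum(rbinom(n, 1, 0.02)) %% 2
  X <- cbind(s + rnorm(n, sd = 0.05), rnorm(n), rnorm(n))
  tr <- make_frames(X)
  m <- estimate_tica(tr, lag = 0.1, n_components = 1)
  pr <- project_tica(tr, m)
  # a copy of tIC0 itself must have |r| = 1 and be selected
  pr$frames$feat_4 <- pr$frames$tic_1
  m2 <- estimate_tica(pr, lag = 0.1, n_components = 1)
  sel <- correlate_features_to_tics(pr, m2, threshold = 0.6)
  expect_equal(unname(sel$max_abs_r[sel$feature == "feat_4"]), 1,
               tolerance = 1e-8)
  expect_true(sel$selected[sel$feature == "feat_4"])
  # pure-noise features stay below the null bound and are not selected
  expect_lt(sel$max_abs_r[sel$feature == "feat_2"], 0.1)
  expect_false(sel$selected[sel$feature == "feat_2"])
})

test_that("entities are ranked by selected pair participation", {
  sel <- tibble::tibble(feature = c("f1", "f2", "f3"),
                        max_abs_r = c(0.9, 0.8, 0.1),
                        selected = c(TRUE, TRUE, FALSE))
  pairs <- tibble::tibble(feature = c("f1", "f2", "f3"),
                          entity_a = c("Y336", "Y336", "A113"),
                          entity_b = c("F343", "N332", "D114"))
  rk <- rank_entities(sel, pairs)
  expect_equal(rk$entity[1], "Y336")
  expect_equal(rk$n_pairs[1], 2)
  expect_false("A113" %in% rk$entity)
})

test_that("density-proximity feature selection applies cutoff and factor", {
  g <- build_density_grid(matrix(c(0.1), 1, 1), extent = 20, spacing = 2,
                          origin = -10,
                          bulk_region = array(rep(TRUE, 10), 10))
  # hot voxel at the origin: make one voxel 10x bulk
  g$normalized <- array(c(rep(1, 4), 10, rep(1, 5)), 10)
  sensors <- tibble::tibble(feature = c("near", "far"),
                            z_sensor = c(-1 + 4.0, -1 + 5.0))
  sel <- select_features_near_density(g, sensors, cutoff = 4.4, factor = 7)
  expect_identical(sel, "near")
  expect_identical(
    select_features_near_density(g, sensors, cutoff = 4.4, factor = 20),
    character(0))
  expect_error(select_features_near_density(g, sensors, cutoff = -1),
               "cutoff")
})
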