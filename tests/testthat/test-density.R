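test_that("the density grid has the right geometry and point count", {
  set.seed(1)
  S <- cbind(runif(5000, -15, 15), runif(5000, -15, 15),
             runif(5000, -35, 35))
  g <- build_density_grid(S, extent = c(30, 30, 70), spacing = 1.25)
  expect_equal(g$dims, c(24L, 24L, 56L))
  expect_equal(prod(g$dims), 32256)
  expect_error(build_density_grid(S, extent = c(30, 30, 70), spacing = 1.3),
               "divide")
})

test_that("uniform samples give unit normalized density everywhere", {
  set.seed(2)
  n <- 2e5
  S <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 10))
  g <- build_density_grid(S, extent = c(10, 10, 10), spacing = 2.5,
                          origin = c(0, 0, 0))
  per_vox <- n / prod(g$dims)
  se <- sqrt(per_vox) / per_vox
  expect_lt(max(abs(g$normalized - 1)), 4 * se)
  expect_equal(mean(g$normalized[g$bulk_region & g$values > 0]), 1)
})

test_that("a point mass lands in one voxel with density weight/volume", {
  S <- matrix(c(1.1, 1.1, 1.1), 1, 3)
  g <- build_density_grid(S, extent = c(10, 10, 10), spacing = 2.5,
                          origin = c(0, 0, 0), weights = 3,
                          bulk_region = array(TRUE, c(4, 4, 4)))
  vol_nm3 <- 2.5^3 * 1e-3
  expect_equal(max(g$values), 3 / vol_nm3)
  expect_equal(sum(g$values > 0), 1)
})

test_that("WHAM reduces to the histogram for one unbiased ensemble", {
  h <- matrix(c(5, 10, 25, 10), 1)
  b <- matrix(0, 1, 4)
  w <- wham_weights(h, b)
  expect_equal(w$p, h[1, ] / sum(h), tolerance = 1e-10)
  expect_true(w$converged)
})

test_that("WHAM recovers a flat profile from overlapping harmonic windows", {
  # analytic sampling: on a flat landscape a harmonic window yields exact
  # Gaussian z samples - no dynamics involved, pure estimator check
  set.seed(4)
  kBT <- kBT()
  k_b <- 0.5
  centers <- seq(-4, 4, by = 2)
  n <- 4000
  z <- unlist(lapply(centers, function(z0) rnorm(n, z0, sqrt(kBT / k_b))))
  ens <- rep(seq_along(centers), each = n)
  edges <- seq(-8, 8, length.out = 33)
  bin <- findInterval(z, edges, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= 32
  H <- matrix(0, length(centers), 32)
  for (k in seq_along(centers)) {
    H[k, ] <- tabulate(bin[ok & ens == k], 32)
  }
  zc <- (edges[-1] + edges[-33]) / 2
  B <- 0.5 * k_b * outer(centers, zc, function(a, b) (b - a)^2) / kBT
  w <- wham_weights(H, B)
  G <- -kBT * log(w$p[w$p > 0])
  inner <- which(zc > -4 & zc < 4)
  g_in <- -kBT * log(w$p[inner])
  se <- kBT / sqrt(min(colSums(H)[inner]))
  expect_lt(diff(range(g_in)), 6 * se)
  # log-likelihood never decreases once past the infeasible start
  expect_true(all(diff(w$loglik)[-1] > -1e-8))
})

test_that("disconnected histogram support is reported", {
  H <- rbind(c(10, 5, 0, 0), c(0, 0, 4, 9))
  B <- matrix(0, 2, 4)
  expect_error(wham_weights(H, B), "disconnected")
})

test_that("OpenDX export round-trips and writes the stated header", {
  g0 <- build_density_grid(matrix(1, 1, 3), extent = c(5, 5, 5),
                           spacing = 2.5, origin = c(0, 0, 0),
                           bulk_region = array(TRUE, c(2, 2, 2)))
  path <- tempfile(fileext = ".dx")
  write_dx_grid(g0, path)
  txt <- readLines(path)
  expect_true(any(grepl("object 1 class gridpositions counts 2 2 2", txt)))
  rt <- read_dx_grid(path)
  expect_equal(rt$dims, g0$dims)
  expect_equal(rt$values, g0$normalized, tolerance = 1e-6)

  set.seed(9)
  S <- cbind(runif(3000, -15, 15), runif(3000, -15, 15),
             runif(3000, -35, 35))
  g <- build_density_grid(S, extent = c(30, 30, 70), spacing = 1.25)
  p2 <- tempfile(fileext = ".dx")
  write_dx_grid(g, p2)
  hdr <- grep("gridpositions", readLines(p2), value = TRUE)
  expect_match(hdr, "24 24 56")
  rt2 <- read_dx_grid(p2)
  expect_equal(max(abs(rt2$values - g$normalized) /
                     pmax(abs(g$normalized), 1e-10)), 0, tolerance = 1e-5)
  unlink(c(path, p2))
})

test_that("1D grids export a z profile with free energies", {
  set.seed(10)
  z <- c(rnorm(5000, -2, 1), runif(5000, -10, 10))
  g <- build_density_grid(matrix(z, ncol = 1), extent = 20, spacing = 1,
                          origin = -10)
  prof <- density_profile(g)
  expect_equal(nrow(prof), 20)
  expect_true(all(is.finite(prof$G[prof$normalized > 0])))
  expect_lt(prof$G[which.min(abs(prof$z + 2))], prof$G[which.min(abs(prof$z - 8))])
})
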