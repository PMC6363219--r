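random_reversible <- function(m, seed) {
  set.seed(seed)
  X <- matrix(runif(m * m), m, m)
  X <- X + t(X)
  list(T = X / rowSums(X), pi = rowSums(X) / sum(X))
}

test_that("PCCA+ returns exact indicators for block-diagonal chains", {
  B1 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  T <- rbind(cbind(B1, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), B1))
  pi <- rep(0.25, 4)
  chi <- pcca_macrostates(T, 2, pi = pi)
  crisp <- attr(chi, "crisp")
  expect_equal(crisp[1], crisp[2])
  expect_equal(crisp[3], crisp[4])
  expect_false(crisp[1] == crisp[3])
  expect_equal(as.vector(chi[chi > 0.5]), rep(1, 4), tolerance = 1e-8)
})

test_that("PCCA+ crisp states match the sign structure of the slow mode", {
  # nearly decomposable 4-state chain: two lumps weakly coupled
  T <- matrix(c(0.89, 0.10, 0.01, 0.00,
                0.10, 0.89, 0.01, 0.00,
                0.00, 0.01, 0.89, 0.10,
                0.00, 0.01, 0.10, 0.89), 4, 4, byrow = TRUE)
  T <- T / rowSums(T)
  pi <- memmkin:::stationary_of(T)
  chi <- pcca_macrostates(T, 2, pi = pi)
  crisp <- attr(chi, "crisp")
  s <- sqrt(pi)
  S <- (T * outer(s, 1 / s) + t(T * outer(s, 1 / s))) / 2
  v2 <- eigen(S, symmetric = TRUE)$vectors[, 2] / s
  expect_equal(crisp == crisp[1], sign(v2) == sign(v2)[1])
})

test_that("Hummer-Szabo projection is exact in the degenerate cases", {
  rr <- random_reversible(5, 31)
  # identity memberships: the chain itself
  That <- coarse_grain_hs(rr$T, rr$pi, diag(5))
  expect_equal(unclass(That), rr$T, tolerance = 1e-10, ignore_attr = TRUE)
  # exactly lumpable chain: block-constant rows
  B <- matrix(c(0.85, 0.15, 0.05, 0.95), 2, 2, byrow = TRUE)
  Tl <- rbind(cbind(matrix(0.85 / 2, 2, 2), matrix(0.15 / 2, 2, 2)),
              cbind(matrix(0.05 / 2, 2, 2), matrix(0.95 / 2, 2, 2)))
  pil <- memmkin:::stationary_of(Tl)
  chi <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  Tc <- coarse_grain_hs(Tl, pil, chi)
  expect_equal(unclass(Tc), B, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("coarse-graining preserves stationary weights on random chains", {
  for (seed in c(1, 2, 3)) {
    rr <- random_reversible(8, seed)
    chi <- pcca_macrostates(rr$T, 3, pi = rr$pi)
    That <- coarse_grain_hs(rr$T, rr$pi, chi)
    pi_hat <- attr(That, "pi")
    expect_equal(as.vector(crossprod(chi, rr$pi)), pi_hat, tolerance = 1e-10)
    expect_equal(as.vector(pi_hat %*% That), pi_hat, tolerance = 1e-10)
    expect_equal(rowSums(That), rep(1, 3), tolerance = 1e-10)
  }
})

test_that("macrostates are labeled by the 90 percent z-range rule", {
  map <- microstate_map(c(-35, 40), n_zbins = 100)
  # one macrostate fully at bin 95, one with 80% weight in the bound range
  crisp <- c(1, 2, 2)
  active <- c(microstate_id(map, 95),
              microstate_id(map, 45), microstate_id(map, 75))
  pi <- c(0.2, 0.64, 0.16)   # macro 2: 0.8 bound / 0.2 outside
  lab <- label_macrostates(crisp, map, pi, active = active)
  expect_equal(lab$label, c("extracellular", "unassigned"))
  lab2 <- label_macrostates(crisp, map, c(0.2, 0.76, 0.04), active = active)
  expect_equal(lab2$label[2], "bound")
})

test_that("MFPT solves match closed forms and simulation", {
  # two-state chain, cross probability 0.2 at lag 0.4 ns: MFPT = tau/p = 2 ns
  T <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  model <- list(T = T, pi = c(0.5, 0.5), lag_ns = 0.4)
  expect_equal(mean_first_passage(model, 1, 2), 2)
  expect_equal(mean_first_passage(model, 1, 1), 0)

  # 5-state linear chain: linear solve vs direct stochastic simulation
  m <- 5
  Tl <- matrix(0, m, m)
  for (i in 1:(m - 1)) { Tl[i, i + 1] <- 0.15; Tl[i + 1, i] <- 0.1 }
  diag(Tl) <- 1 - rowSums(Tl)
  pil <- memmkin:::stationary_of(Tl)
  t_solve <- mean_first_passage(list(T = Tl, pi = pil, lag_ns = 1),
                                1, 5)
  set.seed(17)
  hits <- replicate(400, {
    s <- 1; t <- 0
    while (s != 5) { s <- sample.int(m, 1, prob = Tl[s, ]); t <- t + 1 }
    t
  })
  se <- sd(hits) / sqrt(length(hits))
  expect_lt(abs(t_solve - mean(hits)), 3 * se)

  # unreachable target reports Inf
  Tu <- diag(2)
  expect_true(is.infinite(
    mean_first_passage(list(T = Tu, pi = c(0.5, 0.5), lag_ns = 1), 1, 2)))
})

test_that("the all-pairs table mirrors unreachability with Inf", {
  T <- matrix(c(0.9, 0.1, 0, 0, 0.9, 0.1, 0, 0, 1), 3, 3, byrow = TRUE)
  model <- structure(list(
    chi = diag(3), crisp = 1:3, T_coarse = T, pi_coarse = c(0.4, 0.3, 0.3),
    labels = tibble::tibble(macrostate = 1:3,
                            label = c("extracellular", "bound",
                                      "cytoplasmic"),
                            weight = 1, pi = c(0.4, 0.3, 0.3)),
    lag_ns = 0.4), class = "macro_model")
  tab <- mfpt_table(model)
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$mfpt_ns[tab$from == tab$to] == 0))
  expect_true(is.infinite(tab$mfpt_ns[tab$from == 3 & tab$to == 1]))
  expect_true(is.finite(tab$mfpt_ns[tab$from == 1 & tab$to == 3]))
})
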