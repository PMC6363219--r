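# Independent oracles and small fixtures used across the suite.

# Reversible Markov-chain MLE by the classic symmetric-flux fixed point:
# x_ij = (c_ij + c_ji) / (c_i/x_i + c_j/x_j). Independent of the dTRAM code
# path; used to cross-check the single-ensemble reduction.
rev_mle <- function(C, tol = 1e-14, max_iter = 1e5) {
  C <- as.matrix(C)
  ci <- rowSums(C)
  X <- C + t(C)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    Xn <- (C + t(C)) / outer(ci / xi, ci / xi, "+")
    if (max(abs(Xn - X)) < tol) { X <- Xn; break }
    X <- Xn
  }
  list(T = X / rowSums(X), pi = rowSums(X) / sum(X))
}

# Brute-force realization of a discrete Markov chain.
simulate_chain <- function(T, n, seed = 1, start = 1) {
  set.seed(seed)
  m <- nrow(T)
  s <- integer(n)
  s[1] <- start
  for (t in 2:n) s[t] <- sample.int(m, 1, prob = T[s[t - 1], ])
  s
}

# Empty (flat) landscape on a given domain.
flat_landscape <- function(z_range = c(-35, 40), ...) {
  build_landscape(tibble::tibble(amp = numeric(0), z0 = numeric(0),
                                 sz = numeric(0), c0 = numeric(0),
                                 sc = numeric(0)),
                  kappa_c = 1, z_range = z_range, ...)
}

# Wrap a plain frames tibble as a traj_set (for constructed fixtures).
as_traj_set <- function(frames, specs, dt = 0.002, seed = 1) {
  memmkin:::new_traj_set(frames, specs, dt, seed)
}

# A hand-built MEMM over an N = 1 map: Boltzmann weights of the supplied
# per-bin free energies and a Metropolis chain that is reversible w.r.t.
# them (detailed balance exact by construction).
make_fake_memm <- function(G, z_range = c(0, length(G)), kBT = 0.616) {
  M <- length(G)
  map <- microstate_map(z_range, n_zbins = M)
  p <- exp(-(G - min(G)) / kBT)
  p <- p / sum(p)
  T <- matrix(0, M, M)
  hop <- 0.2
  for (i in seq_len(M - 1)) {
    T[i, i + 1] <- hop * min(1, p[i + 1] / p[i])
    T[i + 1, i] <- hop * min(1, p[i] / p[i + 1])
  }
  diag(T) <- 1 - rowSums(T)
  structure(list(pi = p, G = G - min(G), T = T,
                 active = 0:(M - 1), kin = 0:(M - 1), pi_kin = p,
                 w_tram = p, map = map, lag_frames = 200L, lag_ns = 0.4,
                 dt = 0.002, kBT = kBT, loglik = 0, iterations = 1L,
                 converged = TRUE,
                 specs = unbiased_spec()),
            class = "memm")
}

# Boltzmann-averaged analytic reference profile on the map's bins.
oracle_profile <- function(ls, map, bins = 2000) {
  bin_average_profile(ground_truth_profile(ls, bins = bins), map$edges,
                      ls$kBT)
}
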