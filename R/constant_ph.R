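#' Combine charged/neutral models into a constant-pH kinetic model
#'
#' Builds the product-space (microstate x protonation) kinetic model of a
#' titratable coordinating residue from the MEMMs of its charged (alpha) and
#' neutral (beta) variants. The protonation free-energy shift at the given pH
#' is \eqn{\Delta G_0 = k_BT \ln 10 (pK_a - pH)}; microstate energies are put
#' on a common scale by anchoring each variant's extracellular-bulk weight
#' (where protonation is ion-independent) and shifting the charged variant by
#' \eqn{\Delta G_0}.
#'
#' Within-protonation rates come from each MEMM's transition matrix
#' (\eqn{K = (T - I)/\tau}); protonation switching is local in (z, i):
#' deprotonation (beta to alpha) at the constant rate `k_off`, reprotonation
#' at \eqn{k_{off} \exp(\Delta G(z,i)/k_BT)} with
#' \eqn{\Delta G = \epsilon_\alpha - \epsilon_\beta}, so the product chain
#' satisfies detailed balance against the Boltzmann distribution of the
#' combined energies exactly.
#'
#' @param memm_charged,memm_neutral Fitted `memm` objects sharing the
#'   microstate map.
#' @param pKa Acid constant of the coordinating residue (default 9).
#' @param pH Solution pH (default 7).
#' @param k_off Deprotonation rate in 1/s (default 1e6).
#' @param bulk_bins 1-based z-bin range used as the common bulk anchor.
#' @return A `protonation_mix`.
#' @export
mix_protonation_states <- function(memm_charged, memm_neutral,
                                   pKa = 9, pH = 7, k_off = 1e6,
                                   bulk_bins = c(90, 100)) {
  stopifnot(inherits(memm_charged, "memm"), inherits(memm_neutral, "memm"))
  if (k_off <= 0) abort("k_off must be positive")
  mA <- memm_charged; mB <- memm_neutral
  if (mA$map$M != mB$map$M || mA$map$n_clusters != mB$map$n_clusters) {
    abort("mismatched microstate maps")
  }
  kBT <- mA$kBT
  dG0 <- kBT * log(10) * (pKa - pH)
  if (is.null(mA$T) || is.null(mB$T)) abort("both memms need transition matrices")
  shared <- intersect(mA$kin, mB$kin)           # 0-based
  if (!length(shared)) abort("no shared active microstates")
  m <- length(shared)
  iA <- match(shared, mA$kin); iB <- match(shared, mB$kin)

  anchor <- function(memm) {
    g <- memm$G[shared + 1L]
    zb <- microstate_zbin(memm$map, shared)
    in_bulk <- zb >= bulk_bins[1] & zb <= bulk_bins[2]
    if (!any(in_bulk)) abort("no shared states in the bulk anchor range")
    g + kBT * logsumexp(-g[in_bulk] / kBT)
  }
  e_alpha <- anchor(mA)
  e_beta <- anchor(mB)
  eps_alpha <- e_alpha + dG0
  eps_beta <- e_beta

  tau <- mA$lag_ns
  koff_ns <- k_off * 1e-9                      # 1/s -> 1/ns
  rate_of <- function(memm, idx) {
    K <- (memm$T[idx, idx, drop = FALSE] - diag(length(idx))) / memm$lag_ns
    K <- pmax(K, 0) * (1 - diag(length(idx)))  # off-diagonal rates
    diag(K) <- -rowSums(K)
    K
  }
  KA <- rate_of(mA, iA)
  KB <- rate_of(mB, iB)

  # product space: rows 1..m alpha layer, m+1..2m beta layer
  Q <- matrix(0, 2 * m, 2 * m)
  Q[seq_len(m), seq_len(m)] <- KA
  Q[m + seq_len(m), m + seq_len(m)] <- KB
  dG <- eps_alpha - eps_beta
  k_deprot <- rep(koff_ns, m)                  # beta -> alpha
  k_reprot <- koff_ns * exp(pmin(dG / kBT, 50))  # alpha -> beta
  Q[cbind(m + seq_len(m), seq_len(m))] <- k_deprot
  Q[cbind(seq_len(m), m + seq_len(m))] <- k_reprot
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)

  eps <- c(eps_alpha, eps_beta)
  pi_mix <- exp(-(eps - min(eps)) / kBT)
  pi_mix <- pi_mix / sum(pi_mix)

  # charged probability vs z (Eq-4 analog, aggregated over clusters)
  map <- mA$map
  zb <- microstate_zbin(map, shared)
  zc <- (map$edges[-1] + map$edges[-length(map$edges)]) / 2
  p_alpha <- purrr::map_dfr(sort(unique(zb)), function(b) {
    at <- zb == b
    wa <- sum(exp(-(eps_alpha[at] - min(eps[c(at, at)])) / kBT))
    wb <- sum(exp(-(eps_beta[at] - min(eps[c(at, at)])) / kBT))
    tibble(z_bin = b, z = zc[b], p_alpha = wa / (wa + wb))
  })

  structure(list(Q = Q, pi = pi_mix, eps = eps, eps_alpha = eps_alpha,
                 eps_beta = eps_beta, active = shared, map = map,
                 p_alpha = p_alpha, dG0 = dG0, k_off = k_off, kBT = kBT,
                 lag_ns = tau),
            class = "protonation_mix")
}

#' @export
print.protonation_mix <- function(x, ...) {
  cat("<protonation_mix>", length(x$active), "shared microstates x 2",
      "protonation states; dG0 =", signif(x$dG0, 4), "kcal/mol\n")
  invisible(x)
}

#' @export
free_energy_profile.protonation_mix <- function(memm) {
  x <- memm
  map <- x$map
  zc <- (map$edges[-1] + map$edges[-length(map$edges)]) / 2
  zb <- microstate_zbin(map, x$active)
  kBT <- x$kBT
  G <- vapply(seq_len(map$n_zbins), function(b) {
    at <- which(zb == b)
    if (!length(at)) return(Inf)
    -kBT * logsumexp(-c(x$eps_alpha[at], x$eps_beta[at]) / kBT)
  }, numeric(1))
  new_fe_profile(tibble(z_bin = seq_len(map$n_zbins), z = zc,
                        G = G - min(G[is.finite(G)])))
}
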