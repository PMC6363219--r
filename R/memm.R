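#' Count microstate transitions at a lag
#'
#' Sliding-window transition counts per ensemble, never across segment
#' boundaries.
#'
#' @param dtrajs A `dtraj_set`.
#' @param lag Lag in frames (>= 1).
#' @return Named list (per ensemble) of tibbles `from`, `to`, `n`
#'   (0-based microstate ids).
#' @export
count_transitions <- function(dtrajs, lag) {
  stopifnot(inherits(dtrajs, "dtraj_set"))
  lag <- as.integer(lag)
  if (lag < 1) abort("lag must be >= 1 frame")
  fr <- dtrajs$frames
  M <- dtrajs$map$M
  out <- list()
  for (ens in dtrajs$specs$ensemble_id) {
    sub <- fr[fr$ensemble_id == ens, ]
    froms <- integer(0); tos <- integer(0)
    for (id in unique(sub$traj_id)) {
      s <- sub$microstate[sub$traj_id == id]
      if (length(s) > lag) {
        froms <- c(froms, s[seq_len(length(s) - lag)])
        tos <- c(tos, s[-seq_len(lag)])
      }
    }
    if (length(froms)) {
      key <- as.numeric(froms) * M + tos
      tab <- table(key)
      k <- as.numeric(names(tab))
      out[[ens]] <- tibble(from = as.integer(k %/% M), to = as.integer(k %% M),
                           n = as.numeric(tab))
    } else {
      out[[ens]] <- tibble(from = integer(0), to = integer(0), n = numeric(0))
    }
  }
  out
}

largest_component <- function(edges_i, edges_j, M) {
  parent <- seq_len(M)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_along(edges_i)) {
    parent[find(edges_i[e])] <- find(edges_j[e])
  }
  roots <- vapply(seq_len(M), find, integer(1))
  touched <- unique(c(edges_i, edges_j))
  tab <- table(roots[touched])
  as.integer(touched[roots[touched] == as.integer(names(tab)[which.max(tab)])])
}

#' Estimate a multi-ensemble Markov model by discrete TRAM
#'
#' Joint maximum-likelihood estimation over all ensembles of the unbiased
#' microstate stationary distribution and the reversible unbiased transition
#' matrix, from transition counts at a lag and per-(ensemble, microstate)
#' bias energies. The self-consistent dTRAM fixed point alternates the
#' row-normalization update of the Lagrange multipliers with the
#' likelihood-gradient update of the unbiased weights; iteration stops when
#' the log-likelihood increment falls below `tol`.
#'
#' The estimate is restricted to the largest microstate set connected by
#' transitions in any ensemble; microstates outside it are reported with
#' `pi = 0`, `G = Inf`. The returned transition matrix is built from the
#' unbiased-ensemble counts at the fixed point and flux-symmetrized, so it
#' satisfies detailed balance exactly with respect to its stationary vector.
#'
#' The state-level bias of each (ensemble, z-bin) pair is the Boltzmann
#' average of the continuous bias over the bin. With `refine_bias = TRUE`
#' (default) a second pass recomputes these averages weighting the interior
#' of each bin by the first pass's interpolated free-energy profile, which
#' corrects the misweighting a uniform within-bin reference causes on steep
#' landscape slopes.
#'
#' @param dtrajs A `dtraj_set`.
#' @param lag Lag in frames (default 200).
#' @param tol Log-likelihood increment tolerance.
#' @param max_iter Iteration cap (warning flag on non-convergence).
#' @param kBT Thermal energy (kcal/mol) for free energies.
#' @param refine_bias Run the within-bin reweighting second pass.
#' @return A `memm`: `pi`, `G` (length-M, kcal/mol, min-anchored), `T`
#'   (active x active), `active` (0-based ids), `map`, `lag_frames`,
#'   `lag_ns`, `loglik`, `converged`.
#' @export
estimate_tram <- function(dtrajs, lag = 200, tol = 1e-10, max_iter = 50000,
                          kBT = KBT_310, refine_bias = TRUE) {
  fit <- tram_pass(dtrajs, lag, tol, max_iter, kBT, bias = NULL)
  if (refine_bias && any(dtrajs$specs$kind == "umbrella")) {
    prof <- free_energy_profile(fit)
    bias2 <- refined_bias_matrix(dtrajs$map, dtrajs$specs, prof, kBT)
    fit <- tram_pass(dtrajs, lag, tol, max_iter, kBT, bias = bias2)
  }
  fit
}

# Boltzmann-averaged state bias with within-bin reference weights taken from
# an interpolated bin-level profile
refined_bias_matrix <- function(map, specs, profile, kBT) {
  m_sub <- 25
  lo <- map$edges[-length(map$edges)]
  wdt <- diff(map$edges)
  sub <- outer(lo, rep(1, m_sub)) +
    outer(wdt, (seq_len(m_sub) - 0.5) / m_sub)          # nb x m_sub
  g <- profile$G
  ok <- is.finite(g)
  g_sub <- matrix(stats::approx(profile$z[ok], g[ok], xout = as.vector(sub),
                                rule = 2)$y, nrow(sub), m_sub)
  lw <- -g_sub / kBT
  lw <- lw - apply(lw, 1, max)
  wts <- exp(lw)
  wts <- wts / rowSums(wts)
  B <- matrix(0, nrow(specs), map$n_zbins * map$n_clusters,
              dimnames = list(specs$ensemble_id, NULL))
  for (k in seq_len(nrow(specs))) {
    if (specs$kind[k] == "umbrella") {
      bs <- 0.5 * specs$k_bias[k] * (sub - specs$z0[k])^2 / kBT
      bmin <- apply(bs, 1, min)
      beff <- bmin - log(rowSums(wts * exp(-(bs - bmin))))
      B[k, ] <- rep(beff, each = map$n_clusters)
    }
  }
  B
}

tram_pass <- function(dtrajs, lag, tol, max_iter, kBT, bias = NULL) {
  counts <- count_transitions(dtrajs, lag)
  specs <- dtrajs$specs
  M <- dtrajs$map$M
  all_i <- unlist(lapply(counts, `[[`, "from")) + 1L
  all_j <- unlist(lapply(counts, `[[`, "to")) + 1L
  if (!length(all_i)) abort("no transitions at this lag")
  active <- sort(largest_component(all_i, all_j, M))   # 1-based
  if (length(active) < M) {
    n_frag <- length(unique(c(all_i, all_j))) - length(active)
    if (n_frag > 0) {
      warn(sprintf("%d visited microstate(s) outside the largest connected set",
                   n_frag))
    }
  }
  relab <- rep(NA_integer_, M)
  relab[active] <- seq_along(active)
  Ma <- length(active)

  K <- nrow(specs)
  bias_full <- if (is.null(bias)) {
    compute_bias_energies(dtrajs$map, specs, kBT = kBT)
  } else bias
  logbias <- bias_full[, active, drop = FALSE]

  pair_i <- pair_j <- pair_s <- vector("list", K)
  diagc <- inc <- rowc <- matrix(0, K, Ma)
  for (k in seq_len(K)) {
    cc <- counts[[specs$ensemble_id[k]]]
    f <- relab[cc$from + 1L]; t_ <- relab[cc$to + 1L]
    keep <- !is.na(f) & !is.na(t_)
    f <- f[keep]; t_ <- t_[keep]; n <- cc$n[keep]
    dg <- f == t_
    for (ii in which(dg)) diagc[k, f[ii]] <- diagc[k, f[ii]] + n[ii]
    fo <- f[!dg]; to <- t_[!dg]; no <- n[!dg]
    if (length(fo)) {
      lo <- pmin(fo, to); hi <- pmax(fo, to)
      key <- lo * (Ma + 1) + hi
      agg <- rowsum(no, key)
      kk <- as.numeric(rownames(agg))
      pair_i[[k]] <- as.integer(kk %/% (Ma + 1)) - 1L   # 0-based
      pair_j[[k]] <- as.integer(kk %% (Ma + 1)) - 1L
      pair_s[[k]] <- as.numeric(agg)
      inc_k <- rowsum(no, to)
      inc[k, as.integer(rownames(inc_k))] <- as.numeric(inc_k)
      out_k <- rowsum(no, fo)
      rowc[k, as.integer(rownames(out_k))] <- as.numeric(out_k)
    } else {
      pair_i[[k]] <- integer(0); pair_j[[k]] <- integer(0)
      pair_s[[k]] <- numeric(0)
    }
    rowc[k, ] <- rowc[k, ] + diagc[k, ]
  }

  fit <- dtram_cpp(pair_i, pair_j, pair_s, diagc, inc, rowc,
                   logbias, Ma, tol, as.integer(max_iter))
  if (!fit$converged) warn("TRAM did not converge within max_iter")
  w <- fit$w

  # unbiased transition matrix at the fixed point, restricted to the largest
  # component connected by unbiased transitions (states seen only under bias
  # carry thermodynamic but no kinetic information)
  k0 <- which(specs$kind == "unbiased")
  Tmat <- NULL; pi_kin <- NULL; kin <- integer(0)
  pi_est <- w / sum(w)
  if (length(k0) >= 1) {
    k0 <- k0[1]
    gam <- exp(-(logbias[k0, ] - min(logbias[k0, ])))
    Traw <- dtram_transition_cpp(pair_i[[k0]], pair_j[[k0]], pair_s[[k0]],
                                 fit$nu[k0, ], gam, w)
    X <- w * Traw
    X <- (X + t(X)) / 2
    if (length(pair_i[[k0]])) {
      comp <- largest_component(pair_i[[k0]] + 1L, pair_j[[k0]] + 1L, Ma)
      kin_local <- sort(comp)
    } else kin_local <- integer(0)
    if (length(kin_local) >= 2) {
      Xk <- X[kin_local, kin_local, drop = FALSE]
      pi_T <- rowSums(Xk)
      Tmat <- Xk / pi_T
      pi_kin <- pi_T / sum(pi_T)
      kin <- active[kin_local] - 1L               # 0-based original ids
    } else {
      warn("unbiased counts too sparse for a transition matrix")
    }
  } else {
    warn("no unbiased ensemble: stationary estimate only, no transition matrix")
  }

  pi_full <- rep(0, M); pi_full[active] <- pi_est
  G_full <- rep(Inf, M)
  G_full[active] <- -kBT * log(pi_est)
  G_full <- G_full - min(G_full)

  structure(list(pi = pi_full, G = G_full, T = Tmat, active = active - 1L,
                 kin = kin, pi_kin = pi_kin,
                 w_tram = w, map = dtrajs$map, lag_frames = as.integer(lag),
                 lag_ns = lag * dtrajs$dt, dt = dtrajs$dt, kBT = kBT,
                 loglik = fit$loglik, iterations = fit$iterations,
                 converged = fit$converged, specs = specs),
            class = "memm")
}

#' @export
print.memm <- function(x, ...) {
  cat("<memm>", length(x$active), "active /", x$map$M, "microstates, lag =",
      x$lag_ns, "ns,", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iterations\n")
  invisible(x)
}

#' Implied relaxation timescales of a transition matrix
#'
#' \eqn{t_i = -\tau / \ln \lambda_i} for the largest non-unit eigenvalues.
#' Eigenvalues within numerical tolerance of 1 give `Inf`.
#'
#' @param T Row-stochastic matrix, or a `memm`.
#' @param lag_ns Lag time in ns (taken from the `memm` if given).
#' @param n Number of timescales.
#' @return Tibble `index`, `eigenvalue`, `timescale_ns`.
#' @export
implied_timescales <- function(T, lag_ns = NULL, n = 10) {
  if (inherits(T, "memm")) { lag_ns <- T$lag_ns; T <- T$T }
  if (is.null(lag_ns)) abort("lag_ns required")
  ev <- eigen(T, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-8) {
    abort("complex eigenvalues beyond tolerance: input not reversible")
  }
  ev <- sort(Re(ev), decreasing = TRUE)
  ev <- ev[-1]                                 # drop the unit eigenvalue
  ev <- ev[seq_len(min(n, length(ev)))]
  ts <- ifelse(ev >= 1 - 1e-12, Inf,
               ifelse(ev <= 0, NaN, -lag_ns / log(ev)))
  tibble(index = seq_along(ev), eigenvalue = ev, timescale_ns = ts)
}

#' Implied-timescale convergence ladder
#'
#' Re-estimates the model across a ladder of lag times and reports the
#' leading implied timescales, the standard convergence diagnostic for
#' choosing the Markov-model lag.
#'
#' @param dtrajs A `dtraj_set`.
#' @param lags Integer vector of lags (frames).
#' @param n Number of timescales per lag.
#' @param ... Passed to [estimate_tram()].
#' @return Tibble `lag_frames`, `lag_ns`, `index`, `timescale_ns`.
#' @export
implied_timescales_ladder <- function(dtrajs, lags, n = 10, ...) {
  purrr::map_dfr(lags, function(l) {
    m <- suppressWarnings(estimate_tram(dtrajs, lag = l, ...))
    if (is.null(m$T)) return(tibble())
    its <- implied_timescales(m$T, m$lag_ns, n = n)
    mutate(its, lag_frames = as.integer(l), lag_ns = m$lag_ns,
           .before = 1)
  })
}

#' One-dimensional free-energy profile of a MEMM
#'
#' Integrates out the conformational clusters:
#' \eqn{G(z) = -k_BT \ln \sum_i \exp(-\bar G(z,i)/k_BT)}, min-anchored.
#' z bins with no populated cluster report `Inf`.
#'
#' @param memm A `memm` (or a `protonation_mix`, which dispatches to the
#'   constant-pH combined profile).
#' @return An `fe_profile` tibble: `z_bin` (1-based), `z` (center), `G`.
#' @export
free_energy_profile <- function(memm) UseMethod("free_energy_profile")

#' @export
free_energy_profile.memm <- function(memm) {
  map <- memm$map
  zc <- (map$edges[-1] + map$edges[-length(map$edges)]) / 2
  kBT <- memm$kBT
  G <- vapply(seq_len(map$n_zbins), function(b) {
    ids <- microstate_id(map, b, seq_len(map$n_clusters)) + 1L
    g <- memm$G[ids]
    g <- g[is.finite(g)]
    if (!length(g)) return(Inf)
    -kBT * logsumexp(-g / kBT)
  }, numeric(1))
  if (!any(is.finite(G))) abort("all-empty profile")
  new_fe_profile(tibble(z_bin = seq_len(map$n_zbins), z = zc,
                        G = G - min(G[is.finite(G)])))
}

#' Bootstrap resampling of the unbiased trajectories
#'
#' Each bootstrap sample draws unbiased trajectories with replacement (whole
#' trajectories) until the cumulative frame count reaches `frac` of the full
#' unbiased sample, and keeps the complete umbrella set unchanged. Downstream
#' summaries take the median over the samples plus the full estimate, with
#' 1st/3rd-quartile errors (see [quartile_summary()]).
#'
#' @param trajs A `traj_set` containing at least one unbiased trajectory.
#' @param n_samples Number of bootstrap samples (default 12).
#' @param frac Target frame fraction in (0, 1] (default 0.9).
#' @param seed Integer seed.
#' @return List of `traj_set` objects.
#' @export
bootstrap_resample <- function(trajs, n_samples = 12, frac = 0.9, seed = 1) {
  stopifnot(inherits(trajs, "traj_set"))
  if (frac <= 0 || frac > 1) abort("frac must be in (0, 1]")
  fr <- trajs$frames
  ub_kinds <- trajs$specs$ensemble_id[trajs$specs$kind == "unbiased"]
  ub <- fr[fr$ensemble_id %in% ub_kinds, ]
  if (nrow(ub) == 0) abort("no unbiased trajectories to resample")
  other <- fr[!fr$ensemble_id %in% ub_kinds, ]
  ids <- unique(ub$traj_id)
  sizes <- vapply(ids, function(i) sum(ub$traj_id == i), numeric(1))
  target <- frac * nrow(ub)
  with_local_seed(seed, {
    lapply(seq_len(n_samples), function(s) {
      tot <- 0; picked <- integer(0)
      while (tot < target) {
        p <- sample.int(length(ids), 1)
        picked <- c(picked, p)
        tot <- tot + sizes[p]
      }
      res <- purrr::map_dfr(seq_along(picked), function(r) {
        d <- ub[ub$traj_id == ids[picked[r]], ]
        d$traj_id <- paste0("bs", s, "_r", r, "_", d$traj_id)
        d
      })
      out <- trajs
      out$frames <- bind_rows(other, res)
      out
    })
  })
}

#' Median and quartile errors of bootstrap estimates
#'
#' @param x Numeric vector (bootstrap values plus the full-sample value).
#' @return One-row tibble `median`, `q1`, `q3`, `err_lo = median - q1`,
#'   `err_hi = q3 - median`.
#' @export
quartile_summary <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  tibble(median = q[2], q1 = q[1], q3 = q[3],
         err_lo = q[2] - q[1], err_hi = q[3] - q[2])
}
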