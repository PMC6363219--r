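#' PCCA+ fuzzy macrostate memberships
#'
#' Perron-cluster cluster analysis of a reversible transition matrix using
#' the inner-simplex construction: the dominant right eigenvectors span a
#' simplex whose vertices are identified by successive orthogonal deflation;
#' memberships are the barycentric coordinates, clipped to `[0, 1]` and
#' row-normalized.
#'
#' @param T Reversible row-stochastic matrix (or a `memm`).
#' @param n_macro Number of macrostates (2 <= n_macro <= nstates).
#' @param pi Stationary distribution (computed from `T` if omitted).
#' @return Membership matrix (nstates x n_macro), rows summing to 1, with the
#'   crisp argmax assignment as attribute `"crisp"`.
#' @export
pcca_macrostates <- function(T, n_macro, pi = NULL) {
  if (inherits(T, "memm")) { pi <- stationary_of(T$T); T <- T$T }
  M <- nrow(T)
  if (n_macro < 2 || n_macro > M) abort("need 2 <= n_macro <= nstates")
  if (is.null(pi)) pi <- stationary_of(T)
  # symmetrized spectral problem for real eigenvectors
  s <- sqrt(pi)
  S <- T * outer(s, 1 / s)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  lam <- es$values
  if (abs(lam[n_macro] - lam[min(n_macro + 1, M)]) < 1e-10 && n_macro < M) {
    warn("eigenvalue degeneracy at the spectral gap; tie broken by index")
  }
  X <- es$vectors[, seq_len(n_macro), drop = FALSE] / s
  X[, 1] <- 1                                   # constant eigenvector
  # inner simplex algorithm: find n_macro rows spanning the largest simplex
  idx <- integer(n_macro)
  ortho <- X
  idx[1] <- which.max(rowSums(ortho^2))
  ortho <- sweep(ortho, 2, ortho[idx[1], ])
  for (j in seq_len(n_macro - 1)) {
    d <- sqrt(rowSums(ortho^2))
    idx[j + 1] <- which.max(d)
    v <- ortho[idx[j + 1], ] / d[idx[j + 1]]
    ortho <- ortho - (ortho %*% v) %*% t(v)
  }
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  attr(chi, "crisp") <- max.col(chi, ties.method = "first")
  chi
}

stationary_of <- function(T) {
  e <- eigen(t(T))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- abs(v)
  v / sum(v)
}

#' Hummer-Szabo optimal coarse-graining
#'
#' Projects a Markov chain onto macrostates so that the stationary weights
#' and the zero-frequency (mean-first-passage) structure are preserved. With
#' fundamental matrix \eqn{Z = (I - T + 1\pi^T)^{-1}} and memberships
#' \eqn{\chi}, the reduced chain is
#' \eqn{\hat T = I + 1\hat\pi^T - \hat Z^{-1}} where
#' \eqn{\hat Z = \hat D^{-1}\chi^T \Pi Z \chi}. Identity memberships return
#' `T` itself; crisp lumping of an exactly lumpable chain returns the lumped
#' chain.
#'
#' @param T Row-stochastic transition matrix.
#' @param pi Stationary distribution of `T`.
#' @param chi Membership matrix (states x macrostates), rows summing to 1.
#' @return The coarse transition matrix with attribute `"pi"` (macrostate
#'   stationary weights).
#' @export
coarse_grain_hs <- function(T, pi, chi) {
  chi <- as.matrix(chi)
  M <- nrow(T); n <- ncol(chi)
  pi_hat <- as.vector(crossprod(chi, pi))
  Z <- solve(diag(M) - T + outer(rep(1, M), pi))
  Zhat <- crossprod(chi, pi * Z %*% chi) / pi_hat
  Zi <- tryCatch(solve(Zhat),
                 error = function(e) abort("singular membership overlap matrix"))
  That <- diag(n) + outer(rep(1, n), pi_hat) - Zi
  attr(That, "pi") <- pi_hat
  That
}

#' Assemble, coarse-grain and label macrostates of a MEMM
#'
#' Runs PCCA+ on the unbiased transition matrix, projects it onto the
#' macrostates with the Hummer-Szabo method, and labels each macrostate by
#' ion region (see [label_macrostates()]).
#'
#' @param memm A `memm` with a transition matrix.
#' @param n_macro Number of metastable states.
#' @param groups Named list of 1-based z-bin ranges per group.
#' @param frac Labeling fraction threshold (default 0.9).
#' @param weighting `"pi"` (default) or `"count"` microstate weighting.
#' @return A `macro_model`: memberships, crisp assignment, coarse `T`,
#'   macrostate weights, labels, lag.
#' @export
macrostates <- function(memm, n_macro,
                        groups = list(cytoplasmic = c(1, 10),
                                      bound = c(30, 60),
                                      extracellular = c(90, 100)),
                        frac = 0.9, weighting = c("pi", "count")) {
  stopifnot(inherits(memm, "memm"))
  if (is.null(memm$T)) abort("memm has no transition matrix")
  weighting <- match.arg(weighting)
  pi_a <- memm$pi_kin
  chi <- pcca_macrostates(memm$T, n_macro, pi = pi_a)
  crisp <- attr(chi, "crisp")
  That <- coarse_grain_hs(memm$T, pi_a, chi)
  labels <- label_macrostates(crisp, memm$map, pi_a, active = memm$kin,
                              groups = groups, frac = frac,
                              weighting = weighting)
  structure(list(chi = chi, crisp = crisp, T_coarse = That,
                 pi_coarse = attr(That, "pi"), labels = labels,
                 lag_ns = memm$lag_ns, map = memm$map, active = memm$kin,
                 memm = memm, groups = groups),
            class = "macro_model")
}

#' @export
print.macro_model <- function(x, ...) {
  cat("<macro_model>", ncol(x$chi), "macrostates:",
      paste(sprintf("%s(%.3f)", x$labels$label, x$labels$weight),
            collapse = ", "), "\n")
  invisible(x)
}

#' Label macrostates by ion region
#'
#' A macrostate is assigned to a group (cytoplasmic, bound, extracellular)
#' when at least `frac` (default 90%) of its microstates — weighted by the
#' stationary distribution, or counted crisply — fall in that group's z-bin
#' range; otherwise it stays `"unassigned"` and acts as an explicit
#' intermediate in the kinetic network.
#'
#' @param crisp Crisp macrostate assignment per active microstate.
#' @param map A `microstate_map`.
#' @param pi Stationary weights of the active microstates.
#' @param active 0-based ids of the active microstates.
#' @param groups Named list of 1-based inclusive z-bin ranges.
#' @param frac Threshold fraction.
#' @param weighting `"pi"` or `"count"`.
#' @return Tibble `macrostate`, `label`, `weight` (winning group fraction),
#'   `pi`.
#' @export
label_macrostates <- function(crisp, map, pi, active = NULL,
                              groups = list(cytoplasmic = c(1, 10),
                                            bound = c(30, 60),
                                            extracellular = c(90, 100)),
                              frac = 0.9, weighting = c("pi", "count")) {
  weighting <- match.arg(weighting)
  if (is.null(active)) active <- seq_along(crisp) - 1L
  zbin <- microstate_zbin(map, active)
  w <- if (weighting == "pi") pi else rep(1, length(crisp))
  n_macro <- max(crisp)
  purrr::map_dfr(seq_len(n_macro), function(a) {
    in_a <- crisp == a
    tot <- sum(w[in_a])
    fracs <- vapply(groups, function(g) {
      sum(w[in_a & zbin >= g[1] & zbin <= g[2]]) / tot
    }, numeric(1))
    best <- which.max(fracs)
    tibble(macrostate = a,
           label = if (fracs[best] >= frac) names(groups)[best] else "unassigned",
           weight = fracs[best], pi = sum(pi[in_a]))
  })
}

resolve_states <- function(model, which) {
  if (is.character(which)) {
    if (!inherits(model, "macro_model")) abort("labels need a macro_model")
    out <- model$labels$macrostate[model$labels$label %in% which]
    if (!length(out)) abort(paste("no macrostate labeled", which))
    out
  } else as.integer(which)
}

#' Mean first passage time between state sets
#'
#' Linear-solve MFPT with the target set absorbing. For a discrete-time
#' chain at lag `tau` the system is \eqn{(I - T_{QQ}) t = \tau 1}; for a
#' continuous-time generator it is \eqn{-Q_{QQ} t = 1}. The source average is
#' weighted by the stationary distribution restricted to the source set. An
#' unreachable target reports `Inf`.
#'
#' @param model A `macro_model`, or a list with `T` and `lag_ns`, or a
#'   generator matrix with attribute `"pi"` and `rate = TRUE`.
#' @param source,target Macrostate indices or group labels.
#' @param rate If `TRUE`, `model` is a continuous-time generator (1/ns).
#' @return MFPT in ns.
#' @export
mean_first_passage <- function(model, source, target, rate = FALSE) {
  if (inherits(model, "macro_model")) {
    T <- model$T_coarse; pi <- model$pi_coarse; tau <- model$lag_ns
  } else if (is.matrix(model)) {
    T <- model; pi <- attr(model, "pi"); tau <- attr(model, "lag_ns")
    if (is.null(pi)) pi <- rep(1, nrow(T))
  } else {
    T <- model$T; pi <- model$pi; tau <- model$lag_ns
  }
  src <- resolve_states(model, source)
  tgt <- resolve_states(model, target)
  if (!length(src) || !length(tgt)) abort("empty source or target set")
  if (all(src %in% tgt)) return(0)
  n <- nrow(T)
  keep <- setdiff(seq_len(n), tgt)
  A <- if (rate) -T[keep, keep, drop = FALSE]
       else diag(length(keep)) - T[keep, keep, drop = FALSE]
  b <- if (rate) rep(1, length(keep)) else rep(tau, length(keep))
  t_keep <- tryCatch(solve(A, b), error = function(e) rep(Inf, length(keep)))
  if (any(t_keep < -1e-6)) t_keep <- rep(Inf, length(keep))
  t_all <- rep(0, n)
  t_all[keep] <- t_keep
  ws <- pi[src] / sum(pi[src])
  sum(t_all[src] * ws)
}

#' All-pairs macrostate transition time table
#'
#' @param model A `macro_model`.
#' @return Tibble `from`, `to`, `label_from`, `label_to`, `mfpt_ns` (`Inf`
#'   marks the absence of transitions).
#' @export
mfpt_table <- function(model) {
  n <- ncol(model$chi)
  grid <- tidyr::expand_grid(from = seq_len(n), to = seq_len(n))
  grid |>
    mutate(
      label_from = model$labels$label[.data$from],
      label_to = model$labels$label[.data$to],
      mfpt_ns = purrr::map2_dbl(.data$from, .data$to, function(a, b) {
        if (a == b) 0 else mean_first_passage(model, a, b)
      }))
}
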