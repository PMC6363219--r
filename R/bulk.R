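#' State groups and rate matrix of a kinetic model
#'
#' Internal generics that let bulk coupling work uniformly on a
#' `macro_model` (coarse chain with labeled macrostates), a `memm`
#' (microstate chain, grouped by z-bin ranges), or a `protonation_mix`
#' (product-space generator, grouped by z-bin ranges across both protonation
#' layers).
#'
#' @param model A supported model object.
#' @param groups Named list of 1-based z-bin ranges (used for `memm` /
#'   `protonation_mix`).
#' @return `kinetic_parts()`: list with `K` (generator, 1/ns), `pi`,
#'   and index vectors `ec`, `bound`, `cyt`.
#' @keywords internal
kinetic_parts <- function(model,
                          groups = list(cytoplasmic = c(1, 10),
                                        bound = c(30, 60),
                                        extracellular = c(90, 100))) {
  if (inherits(model, "macro_model")) {
    n <- ncol(model$chi)
    K <- (model$T_coarse - diag(n)) / model$lag_ns
    K[K < 0 & !diag(n)] <- 0
    diag(K) <- 0; diag(K) <- -rowSums(K)
    lab <- model$labels$label
    # when the 90% rule leaves a group unlabeled, fall back to the
    # macrostate carrying the most weight in that group's z range
    zb <- microstate_zbin(model$map, model$active)
    pi_micro <- model$memm$pi_kin
    pick <- function(name, rng) {
      hit <- which(lab == name)
      if (length(hit)) return(hit)
      frac <- vapply(seq_len(n), function(a) {
        at <- model$crisp == a
        sum(pi_micro[at & zb >= rng[1] & zb <= rng[2]])
      }, numeric(1))
      if (max(frac) > 0) which.max(frac) else integer(0)
    }
    list(K = K, pi = model$pi_coarse,
         ec = pick("extracellular", groups$extracellular),
         bound = pick("bound", groups$bound),
         cyt = pick("cytoplasmic", groups$cytoplasmic))
  } else if (inherits(model, "protonation_mix")) {
    zb <- rep(microstate_zbin(model$map, model$active), 2)
    list(K = model$Q, pi = model$pi,
         ec = which(zb >= groups$extracellular[1] & zb <= groups$extracellular[2]),
         bound = which(zb >= groups$bound[1] & zb <= groups$bound[2]),
         cyt = which(zb >= groups$cytoplasmic[1] & zb <= groups$cytoplasmic[2]))
  } else if (inherits(model, "memm")) {
    if (is.null(model$T)) abort("memm has no transition matrix")
    n <- length(model$kin)
    K <- (model$T - diag(n)) / model$lag_ns
    K[K < 0 & !diag(n)] <- 0
    diag(K) <- 0; diag(K) <- -rowSums(K)
    zb <- microstate_zbin(model$map, model$kin)
    list(K = K, pi = model$pi_kin,
         ec = which(zb >= groups$extracellular[1] & zb <= groups$extracellular[2]),
         bound = which(zb >= groups$bound[1] & zb <= groups$bound[2]),
         cyt = which(zb >= groups$cytoplasmic[1] & zb <= groups$cytoplasmic[2]))
  } else if (is.list(model) && !is.null(model$K)) {
    model  # pre-assembled parts (toy fixtures)
  } else abort("unsupported model type")
}

#' Smoluchowski encounter-formation rate
#'
#' \eqn{k^+ = 4\pi D r [Na^+]} with the concentration converted to
#' particles/nm^3.
#'
#' @param D Ion diffusion constant (nm^2/us), default 20.
#' @param r Encounter radius (nm), default 1.5.
#' @param conc_mM Bulk concentration (mM).
#' @return Rate in 1/us.
#' @export
smoluchowski_rate <- function(conc_mM, D = 20, r = 1.5) {
  4 * pi * D * r * mM_to_nm3(conc_mM)
}

#' Couple a kinetic model to extracellular/intracellular bulk states
#'
#' Augments the model's generator with an extracellular bulk state feeding
#' the extracellular (encounter) states at the Smoluchowski rate
#' \eqn{k^+_{EC} = 4\pi D_{Na} r_{EC} [Na^+]_{EC}}, escape rates from the
#' encounter states fixed by the capture probability \eqn{\gamma_{EC}}, and
#' an absorbing intracellular bulk receiving flux from the cytoplasmic
#' states (no ion binding from the intracellular side). With the default
#' `gamma_form = "flux"`, \eqn{\gamma = \sum_j k_{ij} / (k^-_{EC} +
#' \sum_j k_{ij})}; `"printed"` uses the inverted convention
#' \eqn{\gamma = k^-_{EC}/(k^-_{EC} + \sum_j k_{ij})}.
#'
#' @param model A `macro_model`, `memm`, `protonation_mix`, or a list of
#'   pre-assembled `kinetic_parts`.
#' @param conc_EC Extracellular sodium concentration (mM).
#' @param conc_IC Intracellular concentration (mM); retained as metadata (no
#'   intracellular binding flux).
#' @param D Ion diffusion constant (nm^2/us), default 20.
#' @param r_EC Encounter radius (nm), default 1.5.
#' @param gamma Capture probabilities `c(gamma_EC, gamma_IC)` in (0, 1), or a
#'   single value used for both; see [estimate_gamma()].
#' @param gamma_form `"flux"` (default) or `"printed"`.
#' @param groups z-bin group ranges (for microstate-level models).
#' @return A `bulk_model`: generator `Q` (1/ns; state 1 = EC bulk, last =
#'   IC bulk), `pi` (model-state weights), group index list, parameters.
#' @export
couple_to_bulk <- function(model, conc_EC, conc_IC = 0, D = 20, r_EC = 1.5,
                           gamma = 0.5, gamma_form = c("flux", "printed"),
                           groups = list(cytoplasmic = c(1, 10),
                                         bound = c(30, 60),
                                         extracellular = c(90, 100))) {
  gamma_form <- match.arg(gamma_form)
  gamma <- rep_len(gamma, 2)
  if (any(gamma <= 0 | gamma >= 1)) abort("gamma must lie strictly in (0, 1)")
  if (conc_EC < 0 || conc_IC < 0 || D <= 0 || r_EC <= 0) {
    abort("concentrations must be >= 0 and D, r_EC > 0")
  }
  parts <- kinetic_parts(model, groups)
  if (!length(parts$ec)) abort("no extracellular boundary states found")
  n <- nrow(parts$K)
  Q <- matrix(0, n + 2, n + 2)
  Q[1 + seq_len(n), 1 + seq_len(n)] <- parts$K
  diag(Q) <- 0

  k_on <- smoluchowski_rate(conc_EC, D, r_EC) * 1e-3   # 1/us -> 1/ns
  w_ec <- parts$pi[parts$ec] / sum(parts$pi[parts$ec])
  Q[1, 1 + parts$ec] <- k_on * w_ec

  interior <- setdiff(seq_len(n), parts$ec)
  for (s in parts$ec) {
    fwd <- sum(parts$K[s, interior])
    esc <- if (gamma_form == "flux") fwd * (1 - gamma[1]) / gamma[1]
           else fwd * gamma[1] / (1 - gamma[1])
    Q[1 + s, 1] <- esc
  }
  if (length(parts$cyt)) {
    non_cyt <- setdiff(seq_len(n), parts$cyt)
    for (s in parts$cyt) {
      bwd <- sum(parts$K[s, non_cyt])
      esc <- if (gamma_form == "flux") bwd * (1 - gamma[2]) / gamma[2]
             else bwd * gamma[2] / (1 - gamma[2])
      Q[1 + s, n + 2] <- esc
    }
  }
  # IC bulk absorbing: no binding from the intracellular side
  Q[n + 2, ] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, pi = parts$pi, n_model = n,
                 ec = 1 + parts$ec, bound = 1 + parts$bound,
                 cyt = 1 + parts$cyt, ec_bulk = 1L, ic_bulk = n + 2L,
                 conc_EC = conc_EC, conc_IC = conc_IC, D = D, r_EC = r_EC,
                 gamma = gamma, gamma_form = gamma_form, k_on_ns = k_on),
            class = "bulk_model")
}

# MFPT on a generator with optional removed (reflected-out) states
generator_mfpt <- function(Q, source, target, weights = NULL, drop = integer(0)) {
  n <- nrow(Q)
  keep <- setdiff(seq_len(n), union(target, drop))
  Qk <- Q[keep, keep, drop = FALSE]
  diag(Qk) <- 0
  # keep only flux among retained + into targets: recompute diagonal so rows
  # balance over retained states plus absorption into the target
  into_tgt <- rowSums(Q[keep, target, drop = FALSE])
  diag(Qk) <- -(rowSums(Qk) + into_tgt)
  t_keep <- tryCatch(solve(Qk, rep(-1, length(keep))),
                     error = function(e) rep(Inf, length(keep)))
  if (any(t_keep < -1e-9)) t_keep <- rep(Inf, length(keep))
  t_all <- rep(0, n)
  t_all[keep] <- t_keep
  src <- setdiff(source, target)
  if (!length(src)) return(0)
  w <- if (is.null(weights)) rep(1, length(src)) else weights
  sum(t_all[src] * w / sum(w))
}

#' Concentration-dependent binding, dissociation and egress kinetics
#'
#' For each concentration in `conc_grid`, assembles the bulk-coupled model
#' and computes mean first passage times for binding (EC bulk to bound
#' states), dissociation (bound to EC bulk; intracellular leak excluded) and
#' egress (bound to IC bulk), together with the equilibrium bound fraction of
#' the reversible extracellular subnetwork. The binding affinity is the
#' concentration at 50% occupancy, located by root finding on the (monotone)
#' occupancy curve.
#'
#' @param model See [couple_to_bulk()].
#' @param conc_grid Concentrations (mM), all > 0.
#' @param ... Passed to [couple_to_bulk()].
#' @return A `conc_kinetics` tibble: `conc_mM`, `t_binding_ns`,
#'   `t_dissociation_ns`, `t_egress_ns`, `occupancy`; attribute
#'   `affinity_mM`.
#' @export
concentration_kinetics <- function(model, conc_grid, ...) {
  if (any(conc_grid <= 0)) abort("concentrations must be positive for binding")
  rows <- purrr::map_dfr(conc_grid, function(cc) {
    bm <- couple_to_bulk(model, conc_EC = cc, ...)
    tibble(conc_mM = cc,
           t_binding_ns = generator_mfpt(
             bm$Q, bm$ec_bulk, bm$bound, drop = bm$ic_bulk),
           t_dissociation_ns = generator_mfpt(
             bm$Q, bm$bound, bm$ec_bulk, weights = bm$pi[bm$bound - 1],
             drop = bm$ic_bulk),
           t_egress_ns = generator_mfpt(
             bm$Q, bm$bound, bm$ic_bulk, weights = bm$pi[bm$bound - 1],
             drop = bm$ec_bulk),
           occupancy = bound_occupancy(bm))
  })
  aff <- NA_real_
  if (all(diff(rows$occupancy) >= -1e-12)) {
    f <- function(cc) bound_occupancy(couple_to_bulk(model, conc_EC = cc, ...)) - 0.5
    lo <- min(conc_grid); hi <- max(conc_grid)
    grow <- 0
    while (f(hi) < 0 && grow < 20) { hi <- hi * 2; grow <- grow + 1 }
    while (f(lo) > 0 && grow < 40) { lo <- lo / 2; grow <- grow + 1 }
    if (f(lo) <= 0 && f(hi) >= 0) {
      aff <- uniroot(f, c(lo, hi), tol = 1e-4)$root
    }
  } else {
    warn("non-monotone occupancy curve; no affinity reported")
  }
  structure(rows, affinity_mM = aff, class = c("conc_kinetics", class(rows)))
}

# equilibrium bound fraction of the reversible EC subnetwork (IC leak cut)
bound_occupancy <- function(bm) {
  keep <- setdiff(seq_len(nrow(bm$Q)), bm$ic_bulk)
  Q <- bm$Q[keep, keep, drop = FALSE]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # stationary distribution: left null vector
  p <- stationary_generator(Q)
  sum(p[match(bm$bound, keep)]) / sum(p)
}

stationary_generator <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  qr.solve(A, b)
}

#' Estimate the capture probability from unbiased trajectories
#'
#' Counts, over all unbiased trajectories, entries into the encounter region
#' from the bulk side, and the fraction of those entries that reach the bound
#' region before escaping back to the bulk side.
#'
#' @param trajs A `traj_set`.
#' @param enter_range z interval of the encounter (extracellular) region
#'   (angstrom).
#' @param bound_range z interval of the bound region (angstrom).
#' @return One-row tibble: `gamma`, `n_entries`, `n_captures`.
#' @export
estimate_gamma <- function(trajs, enter_range, bound_range) {
  fr <- trajs$frames
  ub <- trajs$specs$ensemble_id[trajs$specs$kind == "unbiased"]
  fr <- fr[fr$ensemble_id %in% ub, ]
  entries <- 0L; captures <- 0L
  hi <- max(enter_range)
  for (id in unique(fr$traj_id)) {
    z <- fr$z[fr$traj_id == id]
    # out (bulk side) / in (encounter region) / deep (past it)
    state <- if (z[1] > hi) "out" else if (z[1] <= max(bound_range)) "deep" else "in"
    for (t in seq_along(z)[-1]) {
      if (state == "out" && z[t] <= hi && z[t] >= min(enter_range)) {
        state <- "in"; entries <- entries + 1L
      } else if (state == "in") {
        if (z[t] <= max(bound_range)) { captures <- captures + 1L; state <- "deep" }
        else if (z[t] > hi) state <- "out"
      } else if (state == "deep" && z[t] > hi) state <- "out"
    }
  }
  tibble(gamma = if (entries > 0) captures / entries else NA_real_,
         n_entries = entries, n_captures = captures)
}
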