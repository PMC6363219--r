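#' Sodium-bound and unbound state weights of a model
#'
#' Boltzmann weights of the sodium-bound states versus all other states,
#' used in the grand-canonical partition functions of the two-state receptor
#' model. For a `macro_model` the bound set is the bound-labeled macrostates;
#' for a `memm` or `protonation_mix` it is the bound z-bin range.
#'
#' @param model A `macro_model`, `memm` or `protonation_mix`.
#' @param groups z-bin group ranges (microstate-level models).
#' @return List with `bound` and `unbound` total weights (normalized).
#' @export
state_weights <- function(model,
                          groups = list(cytoplasmic = c(1, 10),
                                        bound = c(30, 60),
                                        extracellular = c(90, 100))) {
  if (inherits(model, "macro_model")) {
    # bound set = microstates of the bound-labeled macrostates; weights from
    # the full TRAM stationary distribution (microstates outside the kinetic
    # set still carry thermodynamic weight, assigned by z range)
    memm <- model$memm
    pi_full <- memm$pi[memm$active + 1L]
    pi_full <- pi_full / sum(pi_full)
    bound_macros <- model$labels$macrostate[model$labels$label == "bound"]
    if (!length(bound_macros)) abort("empty sodium-bound state set")
    bound_ids <- model$active[model$crisp %in% bound_macros]
    extra <- setdiff(memm$active, model$active)
    zb_extra <- microstate_zbin(memm$map, extra)
    bound_ids <- c(bound_ids,
                   extra[zb_extra >= model$groups$bound[1] &
                           zb_extra <= model$groups$bound[2]])
    in_b <- memm$active %in% bound_ids
    b <- sum(pi_full[in_b])
  } else if (inherits(model, "memm")) {
    pi_full <- model$pi[model$active + 1L]
    pi_full <- pi_full / sum(pi_full)
    zb <- microstate_zbin(model$map, model$active)
    in_b <- zb >= groups$bound[1] & zb <= groups$bound[2]
    if (!any(in_b)) abort("empty sodium-bound state set")
    b <- sum(pi_full[in_b])
  } else {
    parts <- kinetic_parts(model, groups)
    if (!length(parts$bound)) abort("empty sodium-bound state set")
    pi_full <- parts$pi
    b <- sum(parts$pi[parts$bound])
  }
  list(bound = b, unbound = sum(pi_full) - b)
}

#' Partition-function ratio of inactive to active receptor vs sodium
#'
#' Grand-canonical weighting: each model's partition function is
#' \eqn{Z(c) = W_{unbound} + (c/c_{ref}) W_{bound}}, with `c_ref` the
#' simulated reference concentration, so the sodium-bound statistical weight
#' scales linearly with bulk concentration. The ratio
#' \eqn{Z_{Ina}(c)/Z_{Act}(c)} drives the allosteric stabilization of the
#' inactive state; its normalization cancels in \eqn{\rho}.
#'
#' @param model_inactive,model_active Models exposing bound/unbound weights
#'   (see [state_weights()]); alternatively lists `list(bound=, unbound=)`.
#' @param conc Concentration grid (mM), >= 0.
#' @param c_ref Reference concentration (mM), default 150.
#' @param groups Passed to [state_weights()].
#' @return Tibble `conc_mM`, `ratio`, `rho` (ratio normalized to its
#'   zero-sodium value); attribute `ratio0`.
#' @export
partition_ratio <- function(model_inactive, model_active, conc,
                            c_ref = 150,
                            groups = list(cytoplasmic = c(1, 10),
                                          bound = c(30, 60),
                                          extracellular = c(90, 100))) {
  wI <- if (is.list(model_inactive) && !is.null(model_inactive$bound))
    model_inactive else state_weights(model_inactive, groups)
  wA <- if (is.list(model_active) && !is.null(model_active$bound))
    model_active else state_weights(model_active, groups)
  z <- function(w, cc) w$unbound + (cc / c_ref) * w$bound
  ratio0 <- z(wI, 0) / z(wA, 0)
  out <- tibble(conc_mM = as.numeric(conc),
                ratio = z(wI, .data$conc_mM) / z(wA, .data$conc_mM))
  out$rho <- out$ratio / ratio0
  attr(out, "ratio0") <- ratio0
  out
}

#' Normalized stabilization ratio rho
#'
#' \eqn{\rho(c) = ratio(c)/ratio(0)}; \eqn{\rho(0) = 1} exactly.
#'
#' @param ratios Tibble with `conc_mM` and `ratio` (e.g. from
#'   [partition_ratio()]); the zero-concentration reference is taken from the
#'   `ratio0` attribute or a `conc_mM == 0` row.
#' @return The tibble with a `rho` column (re)computed.
#' @export
rho_of_sodium <- function(ratios) {
  r0 <- attr(ratios, "ratio0")
  if (is.null(r0)) {
    i0 <- which(ratios$conc_mM == 0)
    if (!length(i0)) abort("no zero-concentration reference available")
    r0 <- ratios$ratio[i0[1]]
  }
  if (!is.finite(r0) || r0 == 0) abort("zero reference ratio")
  mutate(ratios, rho = .data$ratio / r0)
}

#' Half-maximal ligand concentration of the two-state receptor
#'
#' \eqn{L_{50} = K^\star (1 + \tau_u)/(1 + \tau_b)} with \eqn{\tau_u,
#' \tau_b} the inactive/active equilibrium constants of the ligand-free and
#' ligand-bound receptor and \eqn{K^\star} the ligand affinity for the active
#' state. For antagonists (\eqn{\tau_u \sim \tau_b}) this reduces to
#' \eqn{K^\star}; for full agonists (\eqn{\tau_b \ll \tau_u}) to
#' \eqn{K^\star (1 + \tau_u)}.
#'
#' @param K_star Ligand affinity at the active state (nM), > 0.
#' @param tau_u,tau_b Equilibrium constants (>= 0).
#' @return L50 in nM.
#' @export
ligand_l50 <- function(K_star, tau_u, tau_b) {
  if (K_star <= 0 || tau_u < 0 || tau_b < 0) {
    abort("K_star must be > 0 and tau_u, tau_b >= 0")
  }
  K_star * (1 + tau_u) / (1 + tau_b)
}

#' Fraction of ligand-bound receptors
#'
#' \eqn{f_b = L / (L_{50} + L)}.
#'
#' @param L Ligand concentration (nM).
#' @param L50 Half-maximal concentration (nM).
#' @return Bound fraction in `[0, 1]`.
#' @export
bound_fraction <- function(L, L50) {
  if (any(L < 0) || any(L50 < 0)) abort("concentrations must be >= 0")
  if (any(L == 0 & L50 == 0)) abort("L and L50 cannot both be zero")
  L / (L50 + L)
}

#' Percent change of agonist binding vs sodium concentration
#'
#' \eqn{\Delta f_b/f_b = (1 - \rho)/(x + \rho)} with
#' \eqn{x = [L]/L_{50}(0)} the reduced ligand concentration and \eqn{\rho}
#' the sodium-dependent stabilization ratio. For \eqn{\rho \ge 1} the change
#' lies in \eqn{(-1, 0]}; antagonists (\eqn{\rho \equiv 1}) are unaffected.
#'
#' @param rho Tibble with `conc_mM` and `rho` (see [rho_of_sodium()]), or a
#'   numeric vector of rho values.
#' @param x Reduced ligand concentration, > 0 (default 1 nM / 4 nM = 0.25).
#' @return Tibble `conc_mM` (if available), `rho`, `pct_change`.
#' @export
percent_change_curve <- function(rho, x = 0.25) {
  if (x <= 0) abort("x must be positive")
  if (is.data.frame(rho)) {
    if (any(rho$rho <= 0)) abort("rho must be positive")
    mutate(rho, pct_change = (1 - .data$rho) / (x + .data$rho))
  } else {
    if (any(rho <= 0)) abort("rho must be positive")
    tibble(rho = rho, pct_change = (1 - rho) / (x + rho))
  }
}

#' Sodium concentration producing a given reduction of agonist binding
#'
#' Solves \eqn{\Delta f_b/f_b = -level} on the monotone percent-change curve
#' by bisection on log-concentration (tolerance 0.1 mM), interpolating
#' \eqn{\rho} log-linearly between grid points. When bootstrap curves are
#' supplied (a `sample` column), the median and 1st/3rd-quartile interval
#' over samples is reported.
#'
#' @param curve Tibble with `conc_mM`, `rho` (and optionally `pct_change`,
#'   `sample`).
#' @param level Target fractional reduction (default 0.5).
#' @param x Reduced ligand concentration (default 0.25).
#' @return One-row tibble: `ic50_mM` (NA if not reached), `reached`, and
#'   quartile columns when bootstrap samples are present.
#' @export
sodium_ic50 <- function(curve, level = 0.5, x = 0.25) {
  solve_one <- function(d) {
    d <- arrange(filter(d, .data$conc_mM > 0), .data$conc_mM)
    pc <- (1 - d$rho) / (x + d$rho)
    if (!all(diff(pc) <= 1e-9)) {
      warn("percent-change curve is not monotone decreasing")
    }
    if (min(pc) > -level) return(NA_real_)
    # rho interpolated log-linearly in log-concentration, then bisection
    lc <- log(d$conc_mM)
    rho_at <- function(lg) exp(stats::approx(lc, log(d$rho), xout = lg,
                                             rule = 2)$y)
    f <- function(lg) (1 - rho_at(lg)) / (x + rho_at(lg)) + level
    lo <- min(lc); hi <- max(lc)
    while (exp(hi) - exp(lo) > 0.1) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    exp((lo + hi) / 2)
  }
  if ("sample" %in% names(curve)) {
    vals <- purrr::map_dbl(split(curve, curve$sample), solve_one)
    qs <- quartile_summary(vals)
    tibble(ic50_mM = qs$median, reached = all(!is.na(vals)),
           q1 = qs$q1, q3 = qs$q3)
  } else {
    v <- solve_one(curve)
    tibble(ic50_mM = v, reached = !is.na(v))
  }
}

#' Two-state receptor summary object
#'
#' Bundles the two-state allosteric quantities for reporting: equilibrium
#' constants, ligand affinity, L50, and the prediction curve.
#'
#' @param curve Percent-change tibble (see [percent_change_curve()]).
#' @param K_star Ligand affinity at the active state (nM).
#' @param L Ligand concentration (nM).
#' @param tau_u Ligand-free equilibrium constant at zero sodium (optional).
#' @return A `two_state_receptor` object.
#' @export
two_state_receptor <- function(curve, K_star = 4, L = 1, tau_u = NULL) {
  structure(list(curve = curve, K_star = K_star, L = L, x = L / K_star,
                 tau_u = tau_u, ic50 = sodium_ic50(curve, x = L / K_star)),
            class = "two_state_receptor")
}

#' @export
print.two_state_receptor <- function(x, ...) {
  cat("<two_state_receptor> x =", x$x, "| IC50 =",
      signif(x$ic50$ic50_mM, 4), "mM\n")
  invisible(x)
}
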