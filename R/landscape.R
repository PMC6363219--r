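#' Build a two-dimensional translocation landscape
#'
#' Constructs a free-energy surface \eqn{U(z, c)} over the ion translocation
#' coordinate \eqn{z} (angstrom) and a dimensionless conformational coordinate
#' \eqn{c}, as a sum of two-dimensional Gaussian wells/barriers plus harmonic
#' confinement of \eqn{c}. Gradients are closed-form, so the same object drives
#' both the Brownian-dynamics generator and the analytic ground-truth oracles.
#'
#' @param wells Data frame with one row per Gaussian term and columns
#'   `amp` (kcal/mol; negative = well, positive = barrier), `z0` (angstrom),
#'   `sz` (angstrom width), `c0`, `sc` (conformational center and width).
#' @param kappa_c Harmonic confinement constant of `c` (kcal/mol per unit^2).
#' @param D_z,D_c Diffusion constants along `z` (angstrom^2/ns) and `c` (1/ns).
#' @param kBT Thermal energy (kcal/mol); default 0.616 (310 K).
#' @param variant `"charged"` or `"neutral"` protonation variant label.
#' @param z_range Length-2 numeric, simulated z domain in angstrom.
#' @return An object of class `memm_landscape`.
#' @export
#' @examples
#' ls <- build_landscape(tibble::tibble(
#'   amp = -5, z0 = 0, sz = 2, c0 = 0, sc = 1e6))
#' landscape_potential(ls, z = 0, c = 0)
build_landscape <- function(wells,
                            kappa_c = 2,
                            D_z = 50,
                            D_c = 2,
                            kBT = KBT_310,
                            variant = c("charged", "neutral"),
                            z_range = c(-35, 40)) {
  variant <- match.arg(variant)
  wells <- as_tibble(wells)
  needed <- c("amp", "z0", "sz", "c0", "sc")
  if (!all(needed %in% names(wells))) {
    abort(paste("wells must have columns", paste(needed, collapse = ", ")))
  }
  if (nrow(wells) > 0 && !all(is.finite(as.matrix(wells[needed])))) {
    abort("non-finite landscape parameters")
  }
  if (nrow(wells) > 0 && any(wells$sz <= 0 | wells$sc <= 0)) {
    abort("degenerate (zero-width) well")
  }
  if (kappa_c < 0 || D_z <= 0 || D_c <= 0 || kBT <= 0) {
    abort("kappa_c must be >= 0 and D_z, D_c, kBT positive")
  }
  structure(
    list(wells = wells, kappa_c = kappa_c, D_z = D_z, D_c = D_c,
         kBT = kBT, variant = variant, z_range = sort(as.numeric(z_range))),
    class = "memm_landscape")
}

wells_matrix <- function(ls) {
  if (nrow(ls$wells) == 0) return(matrix(numeric(0), 0, 5))
  as.matrix(ls$wells[, c("amp", "z0", "sz", "c0", "sc")])
}

#' Evaluate the landscape potential
#'
#' @param ls A `memm_landscape`.
#' @param z,c Coordinates (recycled to a common length).
#' @return Energies in kcal/mol.
#' @export
landscape_potential <- function(ls, z, c = 0) {
  n <- max(length(z), length(c))
  z <- rep_len(as.numeric(z), n)
  c <- rep_len(as.numeric(c), n)
  potential_cpp(wells_matrix(ls), ls$kappa_c, z, c)
}

# range of c the dynamics can visit: well centers +/- a few widths (capped:
# very wide Gaussians are effectively c-independent) and the harmonic
# confinement scale
c_domain <- function(ls) {
  sd_c <- sqrt(ls$kBT / max(ls$kappa_c, 1e-8))
  centers <- if (nrow(ls$wells)) ls$wells$c0 else 0
  # very wide Gaussians are effectively c-independent and do not widen the
  # visited c range
  widths <- if (nrow(ls$wells)) ifelse(ls$wells$sc < 10, ls$wells$sc, 0) else 1
  c(min(centers - 4 * widths, -8 * sd_c), max(centers + 4 * widths, 8 * sd_c))
}

#' Analytic marginal free-energy profile of a landscape
#'
#' Integrates out the conformational coordinate by quadrature:
#' \eqn{G(z) = -k_BT \ln \int \exp(-U(z,c)/k_BT)\, dc}, shifted so the minimum
#' is 0. This is the ground-truth oracle against which estimated profiles are
#' compared.
#'
#' @param ls A `memm_landscape`.
#' @param bins Number of z bins (>= 10).
#' @param nc Number of quadrature nodes along `c`.
#' @return A tibble with columns `z` (bin centers) and `G` (kcal/mol), classed
#'   `fe_profile`.
#' @export
ground_truth_profile <- function(ls, bins = 200, nc = 401) {
  if (bins < 10) abort("bins must be >= 10")
  zc <- bin_centers(ls$z_range, bins)
  cd <- c_domain(ls)
  cg <- seq(cd[1], cd[2], length.out = nc)
  dc <- cg[2] - cg[1]
  W <- wells_matrix(ls)
  G <- vapply(zc, function(z) {
    u <- potential_cpp(W, ls$kappa_c, rep(z, nc), cg)
    -ls$kBT * (logsumexp(-u / ls$kBT) + log(dc))
  }, numeric(1))
  if (!all(is.finite(G))) abort("non-integrable potential")
  new_fe_profile(tibble(z = zc, G = G - min(G)))
}

bin_centers <- function(range, bins) {
  edges <- seq(range[1], range[2], length.out = bins + 1)
  (edges[-1] + edges[-length(edges)]) / 2
}

new_fe_profile <- function(x) {
  class(x) <- c("fe_profile", class(x))
  x
}

#' Oracle mean first passage time on the analytic landscape
#'
#' Discretizes the one-dimensional Smoluchowski diffusion on the marginal
#' profile into a fine birth-death Markov chain (rates
#' \eqn{D/\Delta z^2 \exp(-\Delta G/2k_BT)}) and solves the absorbing-target
#' linear system. The source average is Boltzmann-weighted over the source
#' interval.
#'
#' @param ls A `memm_landscape`.
#' @param source,target Length-2 z intervals (angstrom), disjoint.
#' @param bins Number of discretization bins (>= 500 recommended).
#' @return MFPT in ns.
#' @export
oracle_mfpt <- function(ls, source, target, bins = 1000) {
  source <- sort(as.numeric(source)); target <- sort(as.numeric(target))
  if (source[2] > target[1] && target[2] > source[1]) {
    if (isTRUE(all.equal(source, target))) return(0)
    abort("source and target regions must be disjoint")
  }
  prof <- ground_truth_profile(ls, bins = bins)
  zc <- prof$z
  dz <- zc[2] - zc[1]
  g <- prof$G / ls$kBT
  n <- length(zc)
  r0 <- ls$D_z / dz^2
  up <- r0 * exp(-(g[-1] - g[-n]) / 2)        # i -> i+1
  dn <- r0 * exp(-(g[-n] - g[-1]) / 2)        # i+1 -> i
  in_src <- zc >= source[1] & zc <= source[2]
  in_tgt <- zc >= target[1] & zc <= target[2]
  if (!any(in_src) || !any(in_tgt)) abort("empty source or target region")
  # generator restricted to non-target states
  keep <- which(!in_tgt)
  K <- matrix(0, n, n)
  K[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- up
  K[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- dn
  diag(K) <- -rowSums(K)
  t_all <- rep(0, n)
  t_all[keep] <- solve(K[keep, keep, drop = FALSE], rep(-1, length(keep)))
  wsrc <- exp(-(g[in_src] - min(g[in_src])))
  sum(t_all[in_src] * wsrc) / sum(wsrc)
}

#' Landscape presets
#'
#' Ready-made landscapes mirroring the statistical structure of an ion
#' translocation pathway: flat extracellular/intracellular bulk plateaus, a
#' bound well near `z = 0`, and a cytoplasmic exit barrier. The `"receptor"`
#' preset couples the bound-well depth to a bistable conformational mode so
#' the slow degree of freedom is discoverable by tICA; `"two_well"` keeps the
#' conformational coordinate decoupled.
#'
#' The `"neutral"` variant raises the bound well by `neutral_offset` kcal/mol
#' (shallower binding when the coordinating residue is protonated).
#'
#' @param preset `"two_well"` or `"receptor"`.
#' @param variant `"charged"` or `"neutral"`.
#' @param bound_depth Bound-well depth in kcal/mol (negative).
#' @param barrier_height Cytoplasmic barrier height in kcal/mol (positive).
#' @param neutral_offset Added to the bound-well amplitude for the neutral
#'   variant (kcal/mol).
#' @param ... Passed on to [build_landscape()].
#' @return A `memm_landscape`.
#' @export
landscape_preset <- function(preset = c("two_well", "receptor"),
                             variant = c("charged", "neutral"),
                             bound_depth = -5,
                             barrier_height = 4,
                             neutral_offset = 3,
                             ...) {
  preset <- match.arg(preset)
  variant <- match.arg(variant)
  depth <- if (variant == "neutral") bound_depth + neutral_offset else bound_depth
  big <- 1e6  # effectively c-independent width
  wells <- switch(preset,
    two_well = tibble(
      amp = c(depth, barrier_height),
      z0 = c(0, -12), sz = c(3, 2.5),
      c0 = c(0, 0), sc = c(big, big)),
    receptor = tibble(
      amp = c(depth, barrier_height, 1.5, -2.5, -2.5, -1.2, -1.2),
      z0  = c(0, -12, 18, 35, -31.5, 0, 0),
      sz  = c(5, 4, 3, 2.5, 2, big, big),
      c0  = c(1, 0, 0, 0, 0, 1, -1),
      sc  = c(0.6, big, big, big, big, 0.35, 0.35)))
  build_landscape(wells, variant = variant, ...)
}

#' Calibrate the bound-well depth to a target dissociation constant
#'
#' Adjusts the bound-well amplitude of a landscape until the analytic binding
#' isotherm has the requested dissociation constant. The isotherm uses the
#' grand-canonical convention of the downstream allosteric model: bound-region
#' Boltzmann weight scales linearly with concentration relative to `c_ref`, so
#' \eqn{K_d = c_{ref}\, U/B} with \eqn{B} and \eqn{U} the Boltzmann weights of
#' the bound z-interval and its complement.
#'
#' @param ls A `memm_landscape` whose first well is the bound well.
#' @param kd_target Target dissociation constant (mM).
#' @param c_ref Reference (simulated) concentration in mM.
#' @param bound_range z interval counted as bound (angstrom).
#' @return The landscape with adjusted bound-well amplitude.
#' @export
calibrate_bound_well <- function(ls, kd_target, c_ref = 150,
                                 bound_range = c(-13.25, 10)) {
  if (kd_target <= 0) abort("kd_target must be positive")
  kd_of <- function(depth) {
    ls$wells$amp[1] <- depth
    analytic_kd(ls, c_ref = c_ref, bound_range = bound_range)
  }
  f <- function(depth) log(kd_of(depth)) - log(kd_target)
  sol <- uniroot(f, interval = c(-15, 15), tol = 1e-6)
  ls$wells$amp[1] <- sol$root
  ls
}

#' Analytic dissociation constant of a landscape
#'
#' @inheritParams calibrate_bound_well
#' @return Kd in mM.
#' @export
analytic_kd <- function(ls, c_ref = 150, bound_range = c(-13.25, 10)) {
  prof <- ground_truth_profile(ls, bins = 400)
  wt <- exp(-prof$G / ls$kBT)
  in_b <- prof$z >= bound_range[1] & prof$z <= bound_range[2]
  c_ref * sum(wt[!in_b]) / sum(wt[in_b])
}
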