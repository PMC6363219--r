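#' Umbrella window ladder
#'
#' Harmonic umbrella specifications uniformly spaced along z, with the field's
#' customary defaults: 0.5 angstrom spacing and a force constant of
#' 10 kcal/(mol*angstrom^2).
#'
#' @param from,to z range covered by window centers (angstrom).
#' @param spacing Window spacing (angstrom).
#' @param k_bias Harmonic force constant, kcal/(mol*angstrom^2).
#' @param flat_bottom_radius Optional transverse flat-bottom radius (angstrom);
#'   carried as inert metadata in the one-dimensional geometry.
#' @return A tibble of ensemble specifications (one row per window).
#' @export
#' @examples
#' nrow(umbrella_ladder(-35, 40, spacing = 0.5))
umbrella_ladder <- function(from = -35, to = 40, spacing = 0.5, k_bias = 10,
                            flat_bottom_radius = 15) {
  if (spacing <= 0 || k_bias < 0) abort("spacing must be > 0 and k_bias >= 0")
  centers <- seq(from, to, by = spacing)
  tibble(ensemble_id = paste0("win_", seq_along(centers)),
         kind = "umbrella", z0 = centers, k_bias = k_bias,
         flat_bottom_radius = flat_bottom_radius)
}

#' Unbiased ensemble specification
#'
#' @param id Ensemble id string.
#' @return One-row tibble.
#' @export
unbiased_spec <- function(id = "unbiased") {
  tibble(ensemble_id = id, kind = "unbiased", z0 = NA_real_, k_bias = 0,
         flat_bottom_radius = NA_real_)
}

validate_spec <- function(spec) {
  if (!spec$kind %in% c("unbiased", "umbrella")) abort("unknown ensemble kind")
  if (spec$kind == "umbrella" &&
      (!is.finite(spec$z0) || spec$k_bias < 0)) {
    abort("umbrella spec requires finite z0 and k_bias >= 0")
  }
  invisible(spec)
}

new_traj_set <- function(frames, specs, dt, seed, sensors = NULL) {
  structure(list(frames = as_tibble(frames), specs = as_tibble(specs),
                 dt = dt, seed = seed, sensors = sensors),
            class = "traj_set")
}

#' @export
print.traj_set <- function(x, ...) {
  cat("<traj_set> ", dplyr::n_distinct(x$frames$traj_id), " trajectories, ",
      nrow(x$frames), " frames, dt = ", x$dt, " ns, ",
      nrow(x$specs), " ensembles\n", sep = "")
  invisible(x)
}

# step-size stability: the deterministic drift per step must stay well below
# the narrowest landscape feature; we require drift < 0.5 angstrom at the
# steepest point of U plus bias.
check_step_size <- function(ls, spec, dt) {
  cd <- c_domain(ls)
  g <- max_abs_grad_cpp(wells_matrix(ls), ls$kappa_c,
                        ls$z_range[1], ls$z_range[2], cd[1], cd[2], 201, 41)
  if (spec$kind == "umbrella" && spec$k_bias > 0) {
    # a restrained ion stays within ~6 sd of the window center
    g <- g + spec$k_bias * 6 * sqrt(ls$kBT / spec$k_bias)
  }
  drift <- ls$D_z * g * dt / ls$kBT
  if (drift > 0.5) {
    abort(sprintf(
      "unstable step size: drift/step = %.3g angstrom (dt = %g ns); reduce dt",
      drift, dt))
  }
  invisible(TRUE)
}

#' Simulate one overdamped Langevin trajectory
#'
#' Euler-Maruyama integration of the overdamped Langevin equation on
#' \eqn{U(z,c)}, with an optional harmonic umbrella bias
#' \eqn{\tfrac12 k_{bias}(z - z_0)^2} added along z. Reflecting walls confine
#' z to the landscape domain. Identical seeds give bit-identical trajectories.
#'
#' @param ls A `memm_landscape`.
#' @param spec One-row ensemble specification (see [umbrella_ladder()],
#'   [unbiased_spec()]).
#' @param n_steps Number of integration steps.
#' @param dt Integration step in ns.
#' @param stride Record every `stride`-th step (frame interval = `dt*stride`).
#' @param seed Integer RNG seed.
#' @param z_init,c_init Initial coordinates; `z_init` defaults to the window
#'   center (umbrella) or the domain midpoint (unbiased).
#' @param burn_in Unrecorded equilibration steps before production.
#' @return A `traj_set` with one trajectory.
#' @export
simulate_trajectory <- function(ls, spec, n_steps, dt = 2e-4, stride = 10,
                                seed = 1, z_init = NULL, c_init = 0,
                                burn_in = 0) {
  stopifnot(inherits(ls, "memm_landscape"))
  spec <- as_tibble(spec)[1, ]
  validate_spec(spec)
  if (n_steps < 0) abort("negative n_steps")
  check_step_size(ls, spec, dt)
  if (is.null(z_init)) {
    z_init <- if (spec$kind == "umbrella") spec$z0 else mean(ls$z_range)
  }
  kb <- if (spec$kind == "umbrella") spec$k_bias else -1
  zb <- if (spec$kind == "umbrella") spec$z0 else 0
  out <- bd_simulate_cpp(wells_matrix(ls), ls$kappa_c, ls$kBT,
                         ls$D_z, ls$D_c, ls$z_range[1], ls$z_range[2],
                         zb, kb, z_init, c_init, as.integer(n_steps),
                         dt, as.integer(stride), as.integer(seed),
                         as.integer(burn_in))
  nf <- length(out$z)
  frames <- tibble(traj_id = paste0(spec$ensemble_id, "_t1"),
                   ensemble_id = spec$ensemble_id,
                   time = (seq_len(nf) - 1) * dt * stride,
                   z = out$z, c = out$c)
  new_traj_set(frames, spec, dt * stride, seed)
}

#' Simulate a full biased + unbiased trajectory ensemble
#'
#' Runs every umbrella window in `specs`, then (optionally) an unbiased
#' continuation started from the final frame of each window — mirroring the
#' standard umbrella-sampling-plus-unbiased-follow-up protocol. Per-trajectory
#' seeds are derived from the master seed by a multiplicative counter scheme
#' (`(seed * 7919 + counter * 104729) mod (2^31 - 1)`), which keeps the
#' generator streams of different trajectories well separated while the whole
#' ensemble stays reproducible from one integer.
#'
#' @param ls A `memm_landscape`.
#' @param specs Tibble of umbrella specs (e.g. from [umbrella_ladder()]).
#' @param n_steps Steps per umbrella window.
#' @param unbiased_steps Steps per unbiased continuation (0 = none).
#' @param unbiased_every Start an unbiased continuation from every k-th
#'   window only (default 1 = all windows); fewer but longer unbiased runs
#'   sample closer to equilibrium.
#' @param burn_in Unrecorded equilibration steps prepended to every umbrella
#'   window (default 5000 = 1 ns at the default dt); unbiased continuations
#'   start from the window's final state without burn-in.
#' @param dt,stride,seed See [simulate_trajectory()].
#' @return A `traj_set` containing all windows plus one pooled unbiased
#'   ensemble (`ensemble_id "unbiased"`).
#' @export
simulate_ensembles <- function(ls, specs, n_steps, unbiased_steps = 0,
                               unbiased_every = 1, dt = 2e-4, stride = 10,
                               seed = 1, burn_in = 5000) {
  specs <- as_tibble(specs)
  frames <- vector("list", nrow(specs) * 2)
  counter <- 0L
  traj_seed <- function(k) (seed * 7919 + k * 104729) %% 2147483647
  ub <- unbiased_spec()
  if (nrow(specs) > 0) check_step_size(ls, specs[1, ], dt)
  W <- wells_matrix(ls)
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    validate_spec(sp)
    counter <- counter + 1L
    kb <- if (sp$kind == "umbrella") sp$k_bias else -1
    zb <- if (sp$kind == "umbrella") sp$z0 else 0
    out <- bd_simulate_cpp(W, ls$kappa_c, ls$kBT, ls$D_z, ls$D_c,
                           ls$z_range[1], ls$z_range[2], zb, kb,
                           if (is.finite(sp$z0)) sp$z0 else mean(ls$z_range),
                           0, as.integer(n_steps), dt, as.integer(stride),
                           as.integer(traj_seed(counter)),
                           as.integer(burn_in))
    nf <- length(out$z)
    frames[[2 * i - 1]] <- tibble(
      traj_id = paste0(sp$ensemble_id, "_t1"), ensemble_id = sp$ensemble_id,
      time = (seq_len(nf) - 1) * dt * stride, z = out$z, c = out$c)
    cont <- if ("continue_unbiased" %in% names(specs)) {
      isTRUE(specs$continue_unbiased[i])
    } else (i - 1) %% unbiased_every == 0
    if (unbiased_steps > 0 && cont) {
      counter <- counter + 1L
      ou <- bd_simulate_cpp(W, ls$kappa_c, ls$kBT, ls$D_z, ls$D_c,
                            ls$z_range[1], ls$z_range[2], 0, -1,
                            out$z[nf], out$c[nf], as.integer(unbiased_steps),
                            dt, as.integer(stride),
                            as.integer(traj_seed(counter)), 0L)
      nu <- length(ou$z)
      frames[[2 * i]] <- tibble(
        traj_id = paste0("ub_from_", sp$ensemble_id),
        ensemble_id = ub$ensemble_id,
        time = (seq_len(nu) - 1) * dt * stride, z = ou$z, c = ou$c)
    }
  }
  all_specs <- if (unbiased_steps > 0) bind_rows(specs, ub) else specs
  new_traj_set(bind_rows(frames), all_specs, dt * stride, seed)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Attach synthetic feature vectors to a trajectory set
#'
#' Emits `n_features` observables as smooth deterministic functions of
#' `(z, c)` plus i.i.d. Gaussian noise, emulating inter-residue distance
#' features. Feature 1 is the conformational coordinate itself (noisy), so the
#' slow mode is linearly recoverable; the remaining features mix a saturating
#' response to `c` with a localized "sensor" response in z. Each feature
#' carries a sensor position along z (evenly spaced over the domain) used for
#' density-proximity feature selection.
#'
#' @param trajs A `traj_set`.
#' @param n_features Number of features (>= 2); default 105.
#' @param snr Signal-to-noise ratio (signal amplitude / noise sd); must be
#'   positive. `Inf` disables noise.
#' @param seed Integer seed for the noise.
#' @return The `traj_set` with feature columns `feat_1 ... feat_D` and a
#'   `sensors` tibble (`feature`, `z_sensor`).
#' @export
emit_features <- function(trajs, n_features = 105, snr = 10, seed = 1) {
  stopifnot(inherits(trajs, "traj_set"))
  if (n_features < 2) abort("n_features must be >= 2")
  if (!(snr > 0)) abort("snr must be positive")
  z <- trajs$frames$z
  c_ <- trajs$frames$c
  nf <- length(z)
  zr <- range(z)
  sensors <- tibble(feature = paste0("feat_", seq_len(n_features)),
                    z_sensor = seq(zr[1], zr[2], length.out = n_features))
  noise_sd <- if (is.finite(snr)) 1 / snr else 0
  feats <- with_local_seed(seed, {
    m <- matrix(0, nf, n_features)
    m[, 1] <- c_
    for (d in 2:n_features) {
      a <- 0.5 + 0.5 * ((d * 37) %% 11) / 11   # deterministic mixing weights
      m[, d] <- a * tanh(c_) +
        (1 - a) * exp(-(z - sensors$z_sensor[d])^2 / (2 * 16))
    }
    if (noise_sd > 0) m <- m + matrix(rnorm(nf * n_features, sd = noise_sd),
                                      nf, n_features)
    m
  })
  colnames(feats) <- sensors$feature
  trajs$frames <- dplyr::bind_cols(
    trajs$frames[setdiff(names(trajs$frames), sensors$feature)],
    as_tibble(feats))
  trajs$sensors <- sensors
  trajs
}

feature_cols <- function(frames) grep("^feat_", names(frames), value = TRUE)

#' Write / read trajectory sets as flat files
#'
#' Frames go to `frames.tsv` (columns: traj_id, ensemble_id, time, z, c,
#' feat_1...), ensemble specs to `specs.tsv`, and scalar metadata (frame
#' interval, master seed, column order) to `meta.yaml`.
#'
#' @param trajs A `traj_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectories <- function(trajs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(trajs$frames, file.path(dir, "frames.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(trajs$specs, file.path(dir, "specs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(dt = trajs$dt, seed = trajs$seed,
               columns = names(trajs$frames))
  if (!is.null(trajs$sensors)) meta$sensor_z <- trajs$sensors$z_sensor
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(dir) {
  frames <- as_tibble(utils::read.table(
    file.path(dir, "frames.tsv"), header = TRUE, sep = "\t",
    stringsAsFactors = FALSE))
  specs <- as_tibble(utils::read.table(
    file.path(dir, "specs.tsv"), header = TRUE, sep = "\t",
    stringsAsFactors = FALSE))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  sensors <- NULL
  fc <- feature_cols(frames)
  if (!is.null(meta$sensor_z) && length(fc)) {
    sensors <- tibble(feature = fc, z_sensor = as.numeric(meta$sensor_z))
  }
  new_traj_set(frames[, meta$columns], specs, meta$dt, meta$seed, sensors)
}
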