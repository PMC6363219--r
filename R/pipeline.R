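#' Pipeline configuration
#'
#' Assembles a validated configuration for [run_pipeline()] with defaults
#' matching the method's stated constants where they exist (100 z-bins, tICA
#' lag 0.1 ns, model lag 200 frames = 0.4 ns, 12 bootstrap samples at 90%
#' frames, correlation threshold 0.6, density factor 7 and cutoff 4.4 A,
#' k_off 1e6 /s, D_Na 20 nm^2/us, encounter radius 1.5 nm, reference
#' concentration 150 mM) and desk-scale simulation sizes elsewhere.
#'
#' @param ... Overrides of the default keys (unknown keys are rejected).
#' @return A `pipeline_config` (named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    preset = "receptor",
    z_range = c(-35, 40),
    window_spacing = 1,
    k_bias = 0.5,
    pin_range = c(-17, -7),
    pin_spacing = 1,
    pin_k_bias = 4,
    steps_per_window = 240000,
    unbiased_steps = 180000,
    unbiased_every = 3,
    dt = 2e-4,
    stride = 10,
    n_features = 12,
    snr = 10,
    tica_lag = 0.1,
    n_tics = 2,
    n_zbins = 100,
    k_clusters = 2,
    tram_lag = 200,
    tram_tol = 1e-10,
    n_pcca = 8,
    groups = list(cytoplasmic = c(1, 10), bound = c(30, 60),
                  extracellular = c(90, 100)),
    corr_threshold = 0.6,
    density_factor = 7,
    density_cutoff = 4.4,
    relent_threshold = 0.2,
    systems = list(inactive = list(kd = 23), active = list(kd = 850)),
    constant_ph = FALSE,
    neutral_offset = 3,
    pKa = 9, pH = 7, k_off = 1e6,
    D_Na = 20, r_EC = 1.5,
    gamma = 0.5,
    c_ref = 150,
    conc_grid = c(10, 30, 100, 300, 1000),
    ligand_conc = 1, K_star = 4,
    n_bootstrap = 0, bootstrap_frac = 0.9,
    seed = 1,
    out_dir = NULL)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  cfg[names(overrides)] <- overrides   # replacement, never deep-merged
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys take their defaults; unknown keys are rejected with a
#' key-level message. An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipeline_config, raw)
}

#' Save a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run one system (landscape) through the estimation chain
#'
#' simulate -> featurize -> tICA -> cluster -> discretize -> TRAM ->
#' macrostates; returns all intermediate fitted objects.
#'
#' @param ls A `memm_landscape`.
#' @param config A `pipeline_config`.
#' @param seed Integer seed for this system.
#' @return List: `trajs`, `tica`, `clusters`, `map`, `dtrajs`, `memm`,
#'   `profile`, `macro`, `gamma`.
#' @export
run_system <- function(ls, config, seed = config$seed) {
  ladder <- umbrella_ladder(ls$z_range[1] + config$window_spacing / 2,
                            ls$z_range[2] - config$window_spacing / 2,
                            spacing = config$window_spacing,
                            k_bias = config$k_bias)
  ladder$continue_unbiased <-
    (seq_len(nrow(ladder)) - 1) %% config$unbiased_every == 0
  if (!is.null(config$pin_range)) {
    # stiff auxiliary windows pin sampling on steep barrier slopes, where
    # soft wide windows slide off and would leave the region unsampled;
    # every pin gets an unbiased continuation so barrier-top transitions
    # enter the kinetic (unbiased-connected) state set
    pins <- umbrella_ladder(config$pin_range[1], config$pin_range[2],
                            spacing = config$pin_spacing,
                            k_bias = config$pin_k_bias)
    pins$ensemble_id <- paste0("pin_", seq_len(nrow(pins)))
    pins$continue_unbiased <- TRUE
    ladder <- bind_rows(ladder, pins)
  }
  trajs <- simulate_ensembles(ls, ladder,
                              n_steps = config$steps_per_window,
                              unbiased_steps = config$unbiased_steps,
                              dt = config$dt, stride = config$stride,
                              seed = seed)
  trajs <- emit_features(trajs, n_features = config$n_features,
                         snr = config$snr, seed = seed + 7919)
  tica <- estimate_tica(trajs, lag = config$tica_lag,
                        n_components = config$n_tics)
  trajs <- project_tica(trajs, tica)
  clusters <- cluster_tic_space(trajs, k = config$k_clusters,
                                seed = seed + 104729)
  map <- microstate_map(ls$z_range, n_zbins = config$n_zbins,
                        clusters = clusters)
  dtrajs <- assign_microstates(trajs, map)
  memm <- estimate_tram(dtrajs, lag = config$tram_lag,
                        tol = config$tram_tol, kBT = ls$kBT)
  profile <- free_energy_profile(memm)
  macro <- macrostates(memm, n_macro = config$n_pcca, groups = config$groups)

  # reweighted 1D ion density along z (per-frame weights from the TRAM
  # stationary distribution) and the density-proximity feature report
  dens <- density_from_memm(trajs, dtrajs, memm)
  near <- select_features_near_density(dens, trajs$sensors,
                                       cutoff = config$density_cutoff,
                                       factor = config$density_factor)

  boot <- NULL
  if (config$n_bootstrap > 0) {
    boot <- purrr::map(
      bootstrap_resample(trajs, n_samples = config$n_bootstrap,
                         frac = config$bootstrap_frac,
                         seed = seed + 555),
      function(b) {
        db <- suppressMessages(assign_microstates(b, map))
        mb <- suppressWarnings(
          estimate_tram(db, lag = config$tram_lag, tol = config$tram_tol,
                        kBT = ls$kBT))
        list(memm = mb, weights = tryCatch(
          state_weights(mb, groups = config$groups),
          error = function(e) NULL))
      })
    qg <- apply(vapply(boot, function(b) free_energy_profile(b$memm)$G,
                       numeric(config$n_zbins)), 1, function(g) {
      g <- g[is.finite(g)]
      if (length(g) < 2) c(NA_real_, NA_real_)
      else unlist(quartile_summary(g)[c("err_lo", "err_hi")])
    })
    profile$err_lo <- qg[1, ]
    profile$err_hi <- qg[2, ]
  }
  gam <- if (identical(config$gamma, "estimate")) {
    zr <- zbin_to_z(map, config$groups$extracellular)
    br <- zbin_to_z(map, config$groups$bound)
    g <- estimate_gamma(trajs, enter_range = zr, bound_range = br)$gamma
    if (!is.finite(g) || g <= 0 || g >= 1) 0.5 else g
  } else config$gamma
  list(trajs = trajs, tica = tica, clusters = clusters, map = map,
       dtrajs = dtrajs, memm = memm, profile = profile, macro = macro,
       density = dens, features_near_density = near,
       bootstrap = boot, gamma = gam)
}

# 1D bulk-normalized ion density along z, reweighting every frame by the
# TRAM stationary weight of its microstate
density_from_memm <- function(trajs, dtrajs, memm) {
  counts <- tabulate(dtrajs$frames$microstate + 1L, memm$map$M)
  w_state <- ifelse(counts > 0, memm$pi / pmax(counts, 1), 0)
  w_frame <- w_state[dtrajs$frames$microstate + 1L]
  zr <- memm$map$edges[c(1, length(memm$map$edges))]
  # frame order is preserved by assignment up to dropped frames; recover z
  # from the bin centers of the discrete states (bin resolution suffices)
  zc <- (memm$map$edges[-1] + memm$map$edges[-length(memm$map$edges)]) / 2
  z <- zc[microstate_zbin(memm$map, dtrajs$frames$microstate)]
  build_density_grid(matrix(z, ncol = 1), extent = diff(zr),
                     spacing = diff(memm$map$edges)[1], origin = zr[1],
                     weights = w_frame)
}

zbin_to_z <- function(map, bins) {
  c(map$edges[bins[1]], map$edges[bins[2] + 1])
}

#' Run the full analysis pipeline
#'
#' Builds the configured landscape variants (bound-well depths calibrated to
#' each system's target sodium affinity), runs every system through
#' [run_system()], optionally adds the neutral variant and the constant-pH
#' mixed model of the active receptor, computes concentration-dependent
#' kinetics per system, and evaluates the two-state allosteric prediction
#' (stabilization ratio \eqn{\rho}, percent-change curve and sodium IC50).
#' Identical configuration and seed reproduce the result exactly; outputs
#' written to `config$out_dir` carry the configuration hash and seed.
#'
#' @param config A `pipeline_config`.
#' @return A `pipeline_result` list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- rlang::hash(unclass(config))
  systems <- list()
  landscapes <- list()
  i <- 0
  for (nm in names(config$systems)) {
    i <- i + 1
    ls <- landscape_preset(config$preset, variant = "charged",
                           z_range = config$z_range)
    kd <- config$systems[[nm]]$kd
    if (!is.null(kd)) {
      ls <- calibrate_bound_well(ls, kd, c_ref = config$c_ref,
                                 bound_range = zbin_to_z(
                                   microstate_map(config$z_range,
                                                  config$n_zbins),
                                   config$groups$bound))
    }
    landscapes[[nm]] <- ls
    systems[[nm]] <- run_system(ls, config, seed = config$seed + 1000 * i)
  }

  mix <- NULL
  if (isTRUE(config$constant_ph) && "active" %in% names(systems)) {
    ls_n <- landscapes[["active"]]
    ls_n$wells$amp[1] <- ls_n$wells$amp[1] + config$neutral_offset
    ls_n$variant <- "neutral"
    landscapes[["active_neutral"]] <- ls_n
    systems[["active_neutral"]] <- run_system(ls_n, config,
                                              seed = config$seed + 1000 * (i + 1))
    mix <- mix_protonation_states(systems$active$memm,
                                  systems$active_neutral$memm,
                                  pKa = config$pKa, pH = config$pH,
                                  k_off = config$k_off,
                                  bulk_bins = config$groups$extracellular)
  }

  kin <- purrr::imap(systems, function(s, nm) {
    tryCatch(
      concentration_kinetics(s$macro, config$conc_grid,
                             D = config$D_Na, r_EC = config$r_EC,
                             gamma = s$gamma, groups = config$groups),
      error = function(e) {
        warn(sprintf("kinetics for system '%s' unavailable: %s",
                     nm, conditionMessage(e)))
        NULL
      })
  })

  allostery <- NULL
  if (all(c("inactive", "active") %in% names(systems))) {
    active_model <- if (!is.null(mix)) mix else systems$active$macro
    pr <- partition_ratio(systems$inactive$macro, active_model,
                          conc = config$conc_grid, c_ref = config$c_ref,
                          groups = config$groups)
    x <- config$ligand_conc / config$K_star
    curve <- percent_change_curve(rho_of_sodium(pr), x = x)
    allostery <- two_state_receptor(curve, K_star = config$K_star,
                                    L = config$ligand_conc)
    bI <- systems$inactive$bootstrap
    bA <- systems$active$bootstrap
    if (!is.null(bI) && !is.null(bA)) {
      # pair bootstrap replicas across systems; quartile band on the IC50
      n_bs <- min(length(bI), length(bA))
      samples <- purrr::map_dfr(seq_len(n_bs), function(s) {
        wi <- bI[[s]]$weights; wa <- bA[[s]]$weights
        if (is.null(wi) || is.null(wa)) return(tibble())
        pb <- partition_ratio(wi, wa, conc = config$conc_grid,
                              c_ref = config$c_ref)
        mutate(percent_change_curve(pb, x = x), sample = s)
      })
      samples <- bind_rows(samples,
                           mutate(curve, sample = 0L))   # full estimate
      allostery$ic50 <- sodium_ic50(samples, x = x)
      allostery$bootstrap_curves <- samples
    }
  }

  res <- structure(
    list(config = config, hash = hash, seed = config$seed,
         landscapes = landscapes, systems = systems, mix = mix,
         kinetics = kin, allostery = allostery),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> config", substr(x$hash, 1, 8), "seed", x$seed, "\n")
  for (nm in names(x$systems)) {
    pr <- x$systems[[nm]]$profile
    cat(sprintf("  %s: %d active microstates, well depth %.2f kcal/mol\n",
                nm, length(x$systems[[nm]]$memm$active),
                -max(pr$G[is.finite(pr$G)] - min(pr$G[is.finite(pr$G)]))))
  }
  if (!is.null(x$allostery)) print(x$allostery)
  invisible(x)
}

write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(config_hash = res$hash, seed = res$seed,
               package_version = as.character(utils::packageVersion("memmkin")))
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  for (nm in names(res$systems)) {
    utils::write.table(res$systems[[nm]]$profile,
                       file.path(dir, paste0("profile_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(res$kinetics[[nm]])) {
      utils::write.table(res$kinetics[[nm]],
                         file.path(dir, paste0("kinetics_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(res$allostery)) {
    utils::write.table(res$allostery$curve,
                       file.path(dir, "allostery_curve.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Boltzmann-average a fine profile onto coarse bins
#'
#' Aggregates a fine free-energy profile onto coarser bin edges by Boltzmann
#' averaging, the correct analytic reference for bin-discretized estimates:
#' \eqn{G_{bin} = -k_BT \ln \langle e^{-G/k_BT} \rangle_{bin}}.
#'
#' @param profile An `fe_profile` (columns `z`, `G`).
#' @param edges Coarse bin edges.
#' @param kBT Thermal energy (kcal/mol).
#' @return An `fe_profile` on the coarse bins (min-anchored).
#' @export
bin_average_profile <- function(profile, edges, kBT = KBT_310) {
  b <- findInterval(profile$z, edges, rightmost.closed = TRUE)
  keep <- b >= 1 & b <= length(edges) - 1
  d <- tibble(z_bin = b[keep], G = profile$G[keep])
  out <- d |>
    group_by(.data$z_bin) |>
    summarise(G = -kBT * (logsumexp(-.data$G / kBT) - log(dplyr::n()))) |>
    ungroup()
  zc <- (edges[-1] + edges[-length(edges)]) / 2
  out <- mutate(out, z = zc[.data$z_bin], G = .data$G - min(.data$G))
  new_fe_profile(select(out, "z_bin", "z", "G"))
}
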