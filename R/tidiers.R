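#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.tica_model <- function(x, ...) {
  tibble(component = paste0("tic_", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         timescale_ns = ifelse(x$eigenvalues > 0 & x$eigenvalues < 1,
                               -x$lag / log(x$eigenvalues), NA_real_))
}

#' @export
glance.tica_model <- function(x, ...) {
  tibble(lag_ns = x$lag, n_features = length(x$features),
         n_components = length(x$eigenvalues), n_pairs = x$n_pairs)
}

#' @export
tidy.memm <- function(x, ...) {
  map <- x$map
  ids <- x$active
  tibble(microstate = ids,
         z_bin = microstate_zbin(map, ids),
         cluster = microstate_cluster(map, ids),
         pi = x$pi[ids + 1L],
         G = x$G[ids + 1L])
}

#' @export
glance.memm <- function(x, ...) {
  tibble(n_microstates = x$map$M, n_active = length(x$active),
         lag_ns = x$lag_ns, converged = x$converged,
         iterations = x$iterations,
         loglik = tail(x$loglik, 1))
}

#' @export
tidy.macro_model <- function(x, ...) {
  dplyr::left_join(
    x$labels,
    tibble(macrostate = seq_along(x$pi_coarse), pi_coarse = x$pi_coarse),
    by = "macrostate")
}

#' @export
glance.macro_model <- function(x, ...) {
  tibble(n_macrostates = ncol(x$chi),
         n_labeled = sum(x$labels$label != "unassigned"),
         lag_ns = x$lag_ns)
}

#' @export
tidy.protonation_mix <- function(x, ...) x$p_alpha

#' @export
glance.protonation_mix <- function(x, ...) {
  tibble(n_states = length(x$active) * 2, dG0_kcal = x$dG0,
         k_off_s = x$k_off, lag_ns = x$lag_ns)
}

#' @export
tidy.wham_result <- function(x, ...) {
  tibble(bin = seq_along(x$p), p = x$p)
}

#' @export
glance.wham_result <- function(x, ...) {
  tibble(iterations = x$iterations, converged = x$converged,
         loglik = tail(x$loglik, 1))
}

#' @export
tidy.two_state_receptor <- function(x, ...) x$curve

#' @export
glance.two_state_receptor <- function(x, ...) {
  tibble(x_reduced = x$x, K_star_nM = x$K_star, L_nM = x$L,
         ic50_mM = x$ic50$ic50_mM, reached = x$ic50$reached)
}
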