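#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   labs scale_x_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Plot a free-energy profile
#'
#' @param object An `fe_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fe_profile <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), is.finite(.data$G))
  p <- ggplot(d, aes(x = .data$z, y = .data$G))
  if (all(c("err_lo", "err_hi") %in% names(d))) {
    p <- p + geom_ribbon(aes(ymin = .data$G - .data$err_lo,
                             ymax = .data$G + .data$err_hi), alpha = 0.25)
  }
  p + geom_line() +
    labs(x = "z (Å)", y = "G(z) (kcal/mol)") +
    theme_minimal()
}

#' Plot concentration-dependent kinetics
#'
#' @param object A `conc_kinetics` tibble.
#' @param ... Unused.
#' @return A ggplot (binding/dissociation/egress times vs concentration).
#' @export
autoplot.conc_kinetics <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
                           c("t_binding_ns", "t_dissociation_ns",
                             "t_egress_ns"),
                           names_to = "process", values_to = "time_ns")
  ggplot(d, aes(x = .data$conc_mM, y = .data$time_ns)) +
    geom_line() + geom_point() +
    ggplot2::facet_wrap(~process, scales = "free_y") +
    scale_x_log10() + ggplot2::scale_y_log10() +
    labs(x = "[Na+] (mM)", y = "transition time (ns)") +
    theme_minimal()
}

#' Plot the allosteric percent-change prediction
#'
#' @param object A `two_state_receptor`.
#' @param ... Unused.
#' @return A ggplot of percent change in agonist binding vs sodium.
#' @export
autoplot.two_state_receptor <- function(object, ...) {
  d <- dplyr::filter(object$curve, .data$conc_mM > 0)
  ggplot(d, aes(x = .data$conc_mM, y = 100 * .data$pct_change)) +
    geom_line() +
    scale_x_log10() +
    labs(x = "[Na+] (mM)", y = "% change in agonist binding") +
    theme_minimal()
}

#' Plot implied-timescale convergence
#'
#' @param its Output of [implied_timescales_ladder()].
#' @return A ggplot.
#' @export
plot_implied_timescales <- function(its) {
  ggplot(dplyr::filter(its, is.finite(.data$timescale_ns)),
         aes(x = .data$lag_ns, y = .data$timescale_ns,
             group = .data$index)) +
    geom_line() + geom_point() +
    ggplot2::scale_y_log10() +
    labs(x = "lag (ns)", y = "implied timescale (ns)") +
    theme_minimal()
}
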