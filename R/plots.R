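# ggplot2 figures for the standard result types.

#' Plot cumulative permeation events
#'
#' Step curves of N+, N- and their sum versus time.
#' @param events An `aq_events` tibble.
#' @return A ggplot.
#' @export
plot_cumulative_events <- function(events) {
  cum <- cumulative_events(events)
  long <- tidyr::pivot_longer(cum, c("N_plus", "N_minus", "N_pm"),
                              names_to = "series", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$time / 1000, .data$count,
                                     colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ns)", y = "accumulated permeation events",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @rdname plot_cumulative_events
#' @param object An `aq_events` tibble.
#' @param ... Unused.
#' @export
autoplot.aq_events <- function(object, ...) plot_cumulative_events(object)

#' Plot the collective coordinate n(t)
#' @param series An `aq_collective` tibble.
#' @return A ggplot.
#' @export
plot_collective <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$time / 1000, .data$n,
                                       colour = .data$monomer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "collective coordinate n") +
    ggplot2::theme_bw()
}

#' @rdname plot_collective
#' @param object An `aq_collective` tibble.
#' @param ... Unused.
#' @export
autoplot.aq_collective <- function(object, ...) plot_collective(object)

#' Plot the MSD of n with its linear fit
#' @param msd An `aq_msd` tibble or an `aq_dnfit` object.
#' @return A ggplot.
#' @export
plot_msd <- function(msd) {
  fit <- NULL
  if (inherits(msd, "aq_dnfit")) { fit <- msd$result; msd <- msd$msd }
  p <- ggplot2::ggplot(msd, ggplot2::aes(.data$lag, .data$msd,
                                         colour = .data$monomer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ps)", y = expression(group("<", n^2, ">"))) +
    ggplot2::theme_bw()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(
      data = fit,
      mapping = ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                             colour = .data$monomer),
      linetype = 2)
  }
  p
}

#' @rdname plot_msd
#' @param object An `aq_msd` tibble.
#' @param ... Unused.
#' @export
autoplot.aq_msd <- function(object, ...) plot_msd(object)

#' Plot occupancy histograms per monomer
#' @param occupancy Result of [occupancy_histogram()].
#' @return A ggplot.
#' @export
plot_occupancy <- function(occupancy) {
  h <- occupancy$histogram
  ggplot2::ggplot(h, ggplot2::aes(.data$occupancy, .data$n_frames_at)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~monomer) +
    ggplot2::labs(x = "waters in constriction region", y = "frames") +
    ggplot2::theme_bw()
}

#' Plot dipole order-parameter profiles P1(z), P2(z)
#' @param profile An `aq_orientation` tibble.
#' @return A ggplot.
#' @export
plot_order_parameters <- function(profile) {
  long <- tidyr::pivot_longer(tibble::as_tibble(profile), c("P1", "P2"),
                              names_to = "parameter", values_to = "value")
  sds <- tidyr::pivot_longer(tibble::as_tibble(profile), c("P1_sd", "P2_sd"),
                             names_to = "parameter", values_to = "sd")
  long$sd <- sds$sd
  ggplot2::ggplot(long, ggplot2::aes(.data$z, .data$value, colour = .data$monomer)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0.2, alpha = 0.5) +
    ggplot2::facet_wrap(~parameter, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "z (Angstrom)", y = NULL) +
    ggplot2::theme_bw()
}

#' @rdname plot_order_parameters
#' @param object An `aq_orientation` tibble.
#' @param ... Unused.
#' @export
autoplot.aq_orientation <- function(object, ...) plot_order_parameters(object)

#' Plot a pore radius profile
#' @param profile An `aq_radiusprofile` tibble.
#' @return A ggplot.
#' @export
plot_radius_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$z, .data$r_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r_mean - .data$r_sd,
                                      ymax = .data$r_mean + .data$r_sd),
                         alpha = 0.2) +
    ggplot2::labs(x = "z (Angstrom)", y = "pore radius (Angstrom)") +
    ggplot2::theme_bw()
}

#' @rdname plot_radius_profile
#' @param object An `aq_radiusprofile` tibble.
#' @param ... Unused.
#' @export
autoplot.aq_radiusprofile <- function(object, ...) plot_radius_profile(object)
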