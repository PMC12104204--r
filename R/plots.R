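#' Plot residency-weighted space use
#'
#' One line per individual-year of mean weighted occurrence against bin
#' centroid latitude, faceted by year. Only qualifying individual-years are
#' drawn by default.
#'
#' @param object A [space_use_distribution()] result.
#' @param included_only Drop non-qualifying individual-years (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot secr_space_use
#' @export
autoplot.secr_space_use <- function(object, included_only = TRUE, ...) {
  grid <- attr(object, "grid")
  df <- tibble::as_tibble(object)
  if (included_only) df <- dplyr::filter(df, included)
  df <- dplyr::mutate(df, latitude = grid$centroids[bin_index])
  ggplot2::ggplot(df, ggplot2::aes(latitude, mean_weighted_occurrence,
                                   group = individual_id,
                                   colour = individual_id)) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(x = "Latitude (deg N)",
                  y = "Mean residency-weighted occurrence") +
    ggplot2::theme_minimal()
}

#' Plot posterior stressor exposure summaries
#'
#' Per-individual-year posterior median exposure with its central 90%
#' interval, by year, with the annual mean-of-medians (orange) and overall
#' mean-of-medians (black) reference lines.
#'
#' @param object An [exposure_distribution()] result.
#' @param included_only Drop non-qualifying individual-years (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot secr_exposure
#' @export
autoplot.secr_exposure <- function(object, included_only = TRUE, ...) {
  df <- tibble::as_tibble(object)
  if (included_only) df <- dplyr::filter(df, included)
  annual <- attr(object, "annual_mean_of_medians")
  overall <- attr(object, "overall_mean_of_medians")
  ggplot2::ggplot(df, ggplot2::aes(median, individual_id)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = lo90, xmax = hi90),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::geom_vline(data = annual,
                        ggplot2::aes(xintercept = mean_of_medians),
                        colour = "orange") +
    ggplot2::geom_vline(xintercept = overall, colour = "black",
                        linetype = "dashed") +
    ggplot2::facet_wrap(~year, scales = "free_y") +
    ggplot2::labs(x = sprintf("Exposure to %s", df$stressor[1]),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Trace plot of population-level parameters
#'
#' @param fit A [secr_fit()] object.
#' @param params Parameter names (default the population parameters).
#' @return A ggplot object.
#' @export
plot_traces <- function(fit, params = c("mu", "omega", "beta_e")) {
  df <- posterior_draws(fit, params)
  ggplot2::ggplot(df, ggplot2::aes(draw, value, colour = factor(chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "chain") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
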