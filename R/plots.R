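#' Time-course plot of incorporation results
#'
#' Group mean +/- sd of incorporation (rate or absolute) over incubation
#' time, one panel per channel, coloured by treatment -- the standard
#' diagnostic view of an incubation experiment.
#'
#' @param incorp An [incorporation()] result.
#' @param what `"rate"` (nmol/h/g) or `"absolute"` (nmol/g).
#' @return A ggplot object.
#' @examples
#' vials <- sim_vials(sim_config(), seed = 1)
#' plot_incorporation(incorporation(vials) |> mg_adjust())
#' @export
plot_incorporation <- function(incorp, what = c("rate", "absolute")) {
  what <- arg_match(what)
  s <- summarise_incorporation(incorp)
  if (what == "rate") {
    s <- s |> mutate(y = .data$mean_rate, ymin = .data$mean_rate - .data$sd_rate,
                     ymax = .data$mean_rate + .data$sd_rate)
    ylab <- "incorporation rate (nmol h⁻¹ g⁻¹)"
  } else {
    s <- s |> mutate(y = .data$mean_absolute,
                     ymin = .data$mean_absolute - .data$sd_absolute,
                     ymax = .data$mean_absolute + .data$sd_absolute)
    ylab <- "absolute incorporation (nmol g⁻¹)"
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$timepoint_h, y = .data$y,
                                  colour = .data$treatment)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ymin,
                                          ymax = .data$ymax),
                             position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "incubation time (h)", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the buffered CO2-release ratio over a condition grid
#'
#' @param grid A [psi_grid()] result.
#' @param x Column mapped to the x axis (tidy-eval; default `ph`).
#' @return A ggplot object.
#' @export
plot_psi_grid <- function(grid, x = ph) {
  ggplot2::ggplot(grid, ggplot2::aes(x = {{ x }}, y = .data$psi,
                                     colour = factor(.data$temperature),
                                     group = interaction(
                                       .data$temperature, .data$salinity,
                                       .data$total_alkalinity))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = expression(psi ~ "(mol CO"[2] ~ "per mol CO"[3]^"2-" * ")"),
                  colour = "temperature (°C)") +
    ggplot2::theme_minimal()
}

#' Bar chart of the carbon-budget partition
#'
#' Terminal-sink fractions with Monte-Carlo uncertainties from a
#' [budget_propagate()] table.
#'
#' @param object A [budget_propagate()] (or [budget_propagate_delta()])
#'   result.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' input <- tibble::tribble(
#'   ~component, ~mean, ~sd, ~n,
#'   "organic", 39, 14, 8, "skeleton", 38, 22, 8, "net_release", 23, 3, 8)
#' autoplot(budget_propagate(input, n_draws = 2000, seed = 1))
#' @exportS3Method ggplot2::autoplot
autoplot.coralcarb_budget <- function(object, ...) {
  fracs <- c("frac_skeleton", "frac_organic", "frac_net_release",
             "frac_calc_demand", "recycled_of_produced")
  d <- object |> filter(.data$quantity %in% fracs) |>
    mutate(quantity = factor(.data$quantity, levels = fracs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quantity, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
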