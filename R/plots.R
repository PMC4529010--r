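#' Plot a concentration series
#'
#' Minute-resolution traces, one line per source, in reporting units
#' (ug/m3 for PM2.5, mg/m3 for CO).
#'
#' @param object A `concentration_series` from [simulate_day()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concentration_series
#' @export
autoplot.concentration_series <- function(object, ...) {
  p <- object$pollutant[1]
  df <- dplyr::mutate(tibble::as_tibble(object),
                      concentration = .data$concentration * report_factor(p))
  ggplot2::ggplot(df, ggplot2::aes(.data$minute / 60, .data$concentration,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Hour of day",
                  y = paste0("Concentration (", report_units(p), ")"),
                  colour = "Source") +
    ggplot2::theme_minimal()
}

#' Plot a displacement sweep
#'
#' 24-hr mean kitchen concentration against displacement fraction, one
#' line per new stove, facetted by pollutant, with guideline targets as
#' dashed lines.
#'
#' @param object A `displacement_sweep` from [displacement_sweep()].
#' @param targets Guideline targets to draw. Default [guideline_targets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot displacement_sweep
#' @export
autoplot.displacement_sweep <- function(object, targets = guideline_targets(),
                                        ...) {
  df <- tibble::as_tibble(object)
  tg <- dplyr::filter(targets, .data$pollutant %in% unique(df$pollutant))
  ggplot2::ggplot(df, ggplot2::aes(.data$displacement, .data$kitchen_mean,
                                   colour = .data$new_stove)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = tg,
                        ggplot2::aes(yintercept = .data$level),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pollutant), scales = "free_y") +
    ggplot2::labs(x = sprintf("Fraction of cooking displaced from %s",
                              attr(object, "baseline") %||% "baseline"),
                  y = "24-hr mean kitchen concentration",
                  colour = "New stove") +
    ggplot2::theme_minimal()
}

#' Plot single-stove usage versus concentration
#'
#' The daily-mean kitchen concentration as a function of minutes of
#' exclusive use, for one pollutant, with guideline levels overlaid.
#'
#' @param stoves Registry names to draw.
#' @param kitchen A [kitchen()].
#' @param pollutant `"pm25"` or `"co"`.
#' @param max_minutes Upper end of the usage axis. Default 120.
#' @param targets Guideline targets tibble.
#' @return A ggplot object.
#' @export
#' @family reporting
plot_usage_limits <- function(stoves = c("tsf", "charcoal_traditional"),
                              kitchen = stoveuse::kitchen(),
                              pollutant = "pm25", max_minutes = 120,
                              targets = guideline_targets()) {
  df <- tidyr::crossing(stove = stoves,
                        usage = seq(0, max_minutes, length.out = 121)) |>
    dplyr::rowwise() |>
    dplyr::mutate(kitchen_mean = closed_form_daily_mean(
      as_stove(.data$stove)[[rate_column(pollutant)]],
      .data$usage, kitchen) * report_factor(pollutant)) |>
    dplyr::ungroup()
  tg <- dplyr::filter(targets, .data$pollutant == !!pollutant)
  ggplot2::ggplot(df, ggplot2::aes(.data$usage, .data$kitchen_mean,
                                   colour = .data$stove)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = tg, ggplot2::aes(yintercept = .data$level),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Daily stove use (min)",
                  y = paste0("24-hr mean kitchen concentration (",
                             report_units(pollutant), ")"),
                  colour = "Stove") +
    ggplot2::theme_minimal()
}

#' Plot fuel savings against displacement
#'
#' One line per new-stove efficiency tier against a common baseline.
#'
#' @param baseline_eta Baseline thermal efficiency. Default 0.15 (TSF).
#' @param stoves Registry names for the new stoves.
#' @return A ggplot object.
#' @export
#' @family fuel
plot_fuel_savings <- function(baseline_eta = 0.15,
                              stoves = c("tier1", "tier2", "tier3", "tier4")) {
  reg <- stove_registry()
  etas <- reg[reg$stove %in% stoves, c("stove", "thermal_efficiency")]
  df <- tidyr::crossing(etas, displacement = seq(0, 1, by = 0.02)) |>
    dplyr::mutate(savings = fuel_savings(baseline_eta,
                                         .data$thermal_efficiency,
                                         .data$displacement,
                                         allow_negative = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(.data$displacement, 100 * .data$savings,
                                   colour = .data$stove)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Fraction of cooking displaced",
                  y = "Fuel savings (%)", colour = "New stove") +
    ggplot2::theme_minimal()
}
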