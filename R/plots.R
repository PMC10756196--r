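#' Plot an ensemble projection of total family size
#'
#' Median total family size over calendar time with the 80% projection
#' interval as a ribbon, one panel per location, coloured by Focal age.
#'
#' @param object A `kin_projection` from [run_kinship_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kin_projection <- function(object, ...) {
  d <- object$summary$family
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$median,
                                  colour = factor(.data$focal_age),
                                  fill = factor(.data$focal_age))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo80, ymax = .data$hi80),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~location) +
    ggplot2::labs(x = "year", y = "expected living kin",
                  colour = "Focal age", fill = "Focal age",
                  title = "Total family size",
                  subtitle = "median and 80% projection interval") +
    ggplot2::theme_minimal()
}

#' Plot kin age distributions
#'
#' Age distributions of selected kin types of a Focal of a given age —
#' each "population" consists of one type of relative — with the
#' count-weighted mean age marked by a vertical line.
#'
#' @param net A `kin_network` or `kin_network_series`.
#' @param focal_age Focal age in years.
#' @param year Calendar year (network series only).
#' @param types Kin-type codes to show (see [kin_categories()]).
#' @param sex `"female"`, `"male"` or `"both"` kin.
#' @return A ggplot object.
#' @export
plot_kin_age_distribution <- function(net, focal_age, year = NULL,
                                      types = c("a", "d", "g", "m"),
                                      sex = "both") {
  cats <- kin_categories()
  d <- purrr::map_dfr(types, function(tp) {
    kc <- kin_counts(net, tp, focal_age, year)
    if (sex != "both") kc <- kc[kc$sex == sex, ]
    kc |>
      dplyr::group_by(.data$kin_age) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(kin_type = cats$category[match(tp, cats$code)])
  })
  means <- d |>
    dplyr::group_by(.data$kin_type) |>
    dplyr::summarise(
      mean_age = if (sum(.data$count) > 0)
        mean_kin_age(dplyr::pick(dplyr::everything())) else NA_real_,
      .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kin_age, y = .data$count)) +
    ggplot2::geom_col(width = net$grid$step_years * 0.9,
                      just = 0, fill = "grey55") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean_age),
                        linetype = 2) +
    ggplot2::facet_wrap(~kin_type, scales = "free_y") +
    ggplot2::labs(x = "age of kin (years)", y = "expected count",
                  title = sprintf("Kin age distributions, Focal aged %d",
                                  focal_age)) +
    ggplot2::theme_minimal()
}
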