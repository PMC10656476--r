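# ggplot2 visualisations for projection results and error reports.

#' Plot national (or unit) population trajectories
#'
#' @param object A `projection_result`.
#' @param level `"national"`, `"province"` or `"city"`.
#' @param ... Unused.
#' @return A ggplot object: total population against year, one line per
#'   unit.
#' @export
autoplot.projection_result <- function(object, level = "national", ...) {
  d <- tidy(object, level = level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$total,
                                  colour = .data$unit)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "population (persons)",
                  colour = level,
                  title = sprintf("Projected %s population (%s)", level,
                                  unique(d$scenario))) +
    ggplot2::theme_minimal()
}

#' Compare national trajectories across a scenario grid
#'
#' @param object A `projection_grid`.
#' @param level Aggregation level (default national).
#' @param ... Unused.
#' @return A ggplot: one line per scenario, coloured by fertility scenario,
#'   line type by migration scenario.
#' @export
autoplot.projection_grid <- function(object, level = "national", ...) {
  d <- tidy(object, level = level)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$year, y = .data$total,
    colour = factor(.data$fertility_id),
    linetype = factor(.data$migration_id),
    group = interaction(.data$scenario, .data$unit))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "population (persons)",
                  colour = "fertility", linetype = "migration") +
    ggplot2::theme_minimal()
}

#' Population pyramid for one year
#'
#' @param state A [population_state()].
#' @param city Optional city to restrict to; default aggregates all cities.
#' @return A ggplot pyramid (males left, females right, single-year ages).
#' @export
plot_pyramid <- function(state, city = NULL) {
  d <- tibble::as_tibble(state)
  if (!is.null(city)) d <- d[d$city %in% city, ]
  d <- d |>
    dplyr::summarise(population = sum(.data$population),
                     .by = c("sex", "age")) |>
    dplyr::mutate(signed = ifelse(.data$sex == "M", -1, 1) * .data$population)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$signed,
                                  fill = .data$sex)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(labels = function(x) format(abs(x))) +
    ggplot2::labs(x = "age", y = "persons", fill = "sex") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of city projection errors
#'
#' @param object An [error_report()].
#' @param ... Unused.
#' @return A ggplot histogram of city APEs with the threshold shares
#'   annotated in the subtitle.
#' @export
autoplot.error_report <- function(object, ...) {
  d <- object$units[object$units$level == "city", ]
  sub <- paste(sprintf("APE < %g%%: %.1f%% of cities",
                       object$threshold_shares$threshold,
                       100 * object$threshold_shares$share),
               collapse = "; ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ape)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::labs(x = "city APE (%)", y = "cities",
                  title = sprintf("City projection errors, %d", object$year),
                  subtitle = sub) +
    ggplot2::theme_minimal()
}
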