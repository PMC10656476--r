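# broom-style tidiers for fitted/projected objects.

#' Tidy a projection result
#'
#' @param x A `projection_result`.
#' @param level Restrict to `"city"`, `"province"` or `"national"` totals;
#'   `NULL` (default) returns all levels.
#' @param ... Unused.
#' @return Tibble with `fertility_id`, `migration_id`, `scenario`, `level`,
#'   `unit`, `year`, `total`.
#' @export
tidy.projection_result <- function(x, level = NULL, ...) {
  out <- x$summaries
  if (!is.null(level)) {
    out <- out[out$level %in% level, ]
  }
  if (!is.null(x$scenario)) {
    out <- tibble::add_column(
      out,
      fertility_id = x$scenario$fertility_id,
      migration_id = x$scenario$migration_id,
      scenario = .scenario_label(x$scenario), .before = 1)
  } else {
    out <- tibble::add_column(out, fertility_id = NA_integer_,
                              migration_id = NA_integer_,
                              scenario = "CONST", .before = 1)
  }
  out
}

#' Glance at a projection result
#'
#' @param x A `projection_result`.
#' @param ... Unused.
#' @return One-row tibble: scenario ids, year span, number of cities,
#'   baseline and final national totals, the peak year and peak total, the
#'   cumulative clamped shortfall and the number of ceiling activations.
#' @export
glance.projection_result <- function(x, ...) {
  nat <- x$summaries[x$summaries$level == "national", ]
  peak <- nat[which.max(nat$total), ]
  tibble::tibble(
    fertility_id = if (is.null(x$scenario)) NA_integer_ else x$scenario$fertility_id,
    migration_id = if (is.null(x$scenario)) NA_integer_ else x$scenario$migration_id,
    start_year = min(x$years), end_year = max(x$years),
    n_cities = nrow(x$geo$cities),
    total_start = nat$total[1], total_end = nat$total[nrow(nat)],
    peak_year = peak$year, peak_total = peak$total,
    shortfall = sum(x$vitals$shortfall),
    n_ceiling_events = nrow(x$events))
}

#' Tidy a projection grid
#'
#' @param x A `projection_grid` from [project_grid()].
#' @inheritParams tidy.projection_result
#' @return Row-bound [tidy.projection_result()] tables for every scenario.
#' @export
tidy.projection_grid <- function(x, level = NULL, ...) {
  purrr::map_dfr(unclass(x), tidy, level = level)
}

#' @rdname tidy.projection_grid
#' @export
glance.projection_grid <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}

#' Tidy an error report
#'
#' @param x An [error_report()].
#' @param ... Unused.
#' @return The per-unit error table (`level`, `unit`, `year`, `projected`,
#'   `actual`, `pe`, `ape`).
#' @export
tidy.error_report <- function(x, ...) {
  x$units
}

#' @rdname tidy.error_report
#' @return `glance()`: one row with the national PE, provincial and city
#'   mean APEs, and the city share under each APE threshold.
#' @export
glance.error_report <- function(x, ...) {
  nat <- x$units[x$units$level == "national", ]
  m <- function(lv, col) {
    v <- x$means[x$means$level == lv, ][[col]]
    if (length(v)) v else NA_real_
  }
  out <- tibble::tibble(
    year = x$year,
    national_pe = nat$pe,
    provincial_mean_ape = m("province", "mean_ape"),
    city_mean_ape = m("city", "mean_ape"),
    n_excluded = length(x$excluded_cities))
  for (i in seq_len(nrow(x$threshold_shares))) {
    out[[sprintf("share_ape_lt%g", x$threshold_shares$threshold[i])]] <-
      x$threshold_shares$share[i]
  }
  out
}
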