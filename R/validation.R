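# Projection-accuracy metrics: algebraic and absolute percentage error,
# and the multi-level error report (national / provincial / city totals,
# APE threshold shares, national age-structure proportion errors).

#' Algebraic and absolute percentage error
#'
#' `pe(p, a) = (p - a) / a * 100` (positive = overestimate);
#' `ape(p, a) = |pe(p, a)|`.  Both are vectorized and require strictly
#' positive actual values.
#'
#' @param projected Projected value(s), persons.
#' @param actual Observed value(s), persons; must be > 0.
#' @return Percent error(s).
#' @examples
#' pe(103, 100)
#' ape(97, 100)
#' @export
pe <- function(projected, actual) {
  if (any(!is.finite(actual)) || any(actual <= 0)) {
    abort_validation("`actual` must be positive to compute a percentage error")
  }
  (projected - actual) / actual * 100
}

#' @rdname pe
#' @export
ape <- function(projected, actual) {
  abs(pe(projected, actual))
}

# Default age grouping: 0-14, then 5-year groups 15-19 .. 80-84, then 85+.
.default_age_breaks <- c(0, seq(15, 85, by = 5))

.age_group_labels <- function(breaks) {
  lo <- breaks
  hi <- c(breaks[-1] - 1, Inf)
  ifelse(is.infinite(hi), paste0(lo, "+"), paste0(lo, "-", hi))
}

.assign_age_group <- function(age, breaks) {
  labs <- .age_group_labels(breaks)
  labs[findInterval(age, breaks)]
}

#' Multi-level projection error report against a census truth
#'
#' Compares a projection with an observed (or pseudo-census) population
#' state for one year: per-unit PE/APE on totals at city, province and
#' national level; level means; the share of cities under APE thresholds
#' (count-weighted and truth-population-weighted); and PE/APE on national
#' age-group *proportions* (shares of the total, not counts).  Cities
#' present in the projection but absent from the truth are excluded from
#' all comparisons and listed in the report; cities with a zero truth total
#' are likewise excluded, with a warning, rather than producing infinite
#' errors.
#'
#' @param projection A `projection_result` from [project()].
#' @param truth A [population_state()] whose year lies in the projected
#'   range.
#' @param geo A [geo_hierarchy()].
#' @param age_breaks Lower bounds of the age groups for the age-structure
#'   comparison (default 0, 15, 20, ..., 85: 0-14 then five-year groups to
#'   85+).
#' @param thresholds APE thresholds (percent) for the city share table.
#' @return An object of class `error_report` with elements `year`, `units`
#'   (per-unit errors), `means`, `threshold_shares`, `age_structure`,
#'   and `excluded_cities`.
#' @export
error_report <- function(projection, truth, geo,
                         age_breaks = .default_age_breaks,
                         thresholds = c(5, 10)) {
  stopifnot(inherits(projection, "projection_result"))
  truth <- tibble::as_tibble(truth)
  yr <- truth$year[1]
  if (!yr %in% projection$years) {
    abort_citypop(sprintf("truth year %d is outside the projected range", yr))
  }
  proj_state <- tibble::as_tibble(get_state(projection, yr))
  proj_cities <- unique(proj_state$city)
  truth_cities <- unique(truth$city)
  common <- intersect(proj_cities, truth_cities)
  if (!length(common)) {
    abort_citypop("projection and truth share no cities")
  }
  excluded <- sort(setdiff(proj_cities, truth_cities))

  proj_tot <- total_population(proj_state[proj_state$city %in% common, ], "city")
  truth_tot <- total_population(truth[truth$city %in% common, ], "city")
  tab <- dplyr::inner_join(
    dplyr::rename(proj_tot, projected = "total"),
    dplyr::rename(truth_tot, actual = "total"),
    by = c("year", "city"))
  zero <- tab$city[tab$actual <= 0]
  if (length(zero)) {
    warn(sprintf("excluding %d city(ies) with zero truth population: %s",
                 length(zero), paste(zero, collapse = ", ")))
    tab <- tab[!tab$city %in% zero, ]
    excluded <- sort(c(excluded, zero))
  }
  city_err <- tab |>
    dplyr::mutate(pe = pe(.data$projected, .data$actual),
                  ape = abs(.data$pe)) |>
    dplyr::rename(unit = "city") |>
    dplyr::mutate(level = "city", .before = 1)

  prov_err <- tab |>
    dplyr::left_join(geo$cities[c("city", "province")], by = "city") |>
    dplyr::summarise(projected = sum(.data$projected),
                     actual = sum(.data$actual),
                     .by = c("year", "province")) |>
    dplyr::mutate(pe = pe(.data$projected, .data$actual),
                  ape = abs(.data$pe)) |>
    dplyr::rename(unit = "province") |>
    dplyr::mutate(level = "province", .before = 1)

  nat_err <- tab |>
    dplyr::summarise(projected = sum(.data$projected),
                     actual = sum(.data$actual), .by = "year") |>
    dplyr::mutate(unit = "national",
                  pe = pe(.data$projected, .data$actual),
                  ape = abs(.data$pe)) |>
    dplyr::mutate(level = "national", .before = 1)

  units <- dplyr::bind_rows(nat_err, prov_err, city_err) |>
    dplyr::select("level", "unit", "year", "projected", "actual", "pe", "ape")

  means <- units |>
    dplyr::summarise(mean_pe = mean(.data$pe), mean_ape = mean(.data$ape),
                     .by = "level")

  shares <- purrr::map_dfr(thresholds, function(t) {
    below <- city_err$ape < t
    tibble::tibble(
      threshold = t,
      n_below = sum(below),
      share = mean(below),
      pop_share = sum(city_err$actual[below]) / sum(city_err$actual))
  })

  # age structure: national age-group proportions, projection vs truth
  grp <- function(x) {
    x |>
      dplyr::filter(.data$city %in% tab$city) |>
      dplyr::mutate(group = .assign_age_group(.data$age, age_breaks)) |>
      dplyr::summarise(n = sum(.data$population), .by = "group") |>
      dplyr::mutate(share = .data$n / sum(.data$n))
  }
  pg <- grp(proj_state)
  tg <- grp(truth)
  age_structure <- dplyr::inner_join(
    dplyr::select(pg, "group", proj_share = "share"),
    dplyr::select(tg, "group", actual_share = "share"), by = "group") |>
    dplyr::mutate(pe = pe(.data$proj_share, .data$actual_share),
                  ape = abs(.data$pe)) |>
    dplyr::arrange(match(.data$group, .age_group_labels(age_breaks)))

  structure(list(
    year = yr, units = units, means = means, threshold_shares = shares,
    age_structure = age_structure, excluded_cities = excluded
  ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  nat <- x$units[x$units$level == "national", ]
  cat(sprintf("<error_report: year %d>\n", x$year))
  cat(sprintf("  national PE %.2f%%, APE %.2f%%\n", nat$pe, nat$ape))
  for (lv in c("province", "city")) {
    m <- x$means[x$means$level == lv, ]
    if (nrow(m)) {
      cat(sprintf("  %s mean PE %.2f%%, mean APE %.2f%%\n", lv,
                  m$mean_pe, m$mean_ape))
    }
  }
  for (i in seq_len(nrow(x$threshold_shares))) {
    s <- x$threshold_shares[i, ]
    cat(sprintf("  cities APE < %g%%: %d (%.1f%%), %.1f%% of population\n",
                s$threshold, s$n_below, 100 * s$share, 100 * s$pop_share))
  }
  if (length(x$excluded_cities)) {
    cat(sprintf("  excluded cities: %s\n",
                paste(x$excluded_cities, collapse = ", ")))
  }
  invisible(x)
}

#' Write an error report as a set of CSV blocks
#'
#' Emits `errors_units.csv`, `errors_means.csv`,
#' `errors_threshold_shares.csv` and `errors_age_structure.csv` into `dir`.
#'
#' @param report An [error_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_error_report <- function(report, dir) {
  stopifnot(inherits(report, "error_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$units, file.path(dir, "errors_units.csv"),
                   progress = FALSE)
  readr::write_csv(report$means, file.path(dir, "errors_means.csv"),
                   progress = FALSE)
  readr::write_csv(report$threshold_shares,
                   file.path(dir, "errors_threshold_shares.csv"),
                   progress = FALSE)
  readr::write_csv(report$age_structure,
                   file.path(dir, "errors_age_structure.csv"),
                   progress = FALSE)
  invisible(dir)
}
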