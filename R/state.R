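# Population state: counts by (city, sex, single age 0..100+) for one year,
# stored long and tidy; matrix helpers for the projection engine.

#' Construct a population state
#'
#' A `population_state` is a long tibble of person counts by city, sex and
#' single year of age for one calendar year.  Counts are real numbers (no
#' rounding is performed anywhere in the pipeline, so that 90 annual steps do
#' not accumulate rounding bias).  The age axis has exactly 101 categories:
#' 0..99 plus the absorbing open interval `100+` (stored as integer 100).
#'
#' @param x A data frame with columns `year`, `city`, `sex` (`"M"`/`"F"`),
#'   `age` (integer 0..100 or labels `"0"`..`"99"`, `"100+"`) and
#'   `population` (persons, >= 0).  Missing (city, sex, age) combinations
#'   are completed with 0.
#' @return A tibble of class `population_state` with one row per
#'   (city, sex, age), integer `age`, sorted by city, sex, age.
#' @export
population_state <- function(x) {
  x <- tibble::as_tibble(x)
  for (col in c("year", "city", "sex", "age", "population")) {
    if (!col %in% names(x)) {
      abort_validation(sprintf("population state lacks column `%s`", col))
    }
  }
  if (length(unique(x$year)) != 1L) {
    abort_validation("a population_state holds exactly one calendar year")
  }
  bad_sex <- setdiff(unique(x$sex), .SEXES)
  if (length(bad_sex)) {
    abort_validation(sprintf("unknown sex label(s): %s",
                             paste(bad_sex, collapse = ", ")))
  }
  x$age <- age_to_int(x$age)
  x$population <- as.numeric(x$population)
  if (anyNA(x$population) || any(x$population < 0)) {
    abort_validation("population counts must be non-negative and non-missing")
  }
  if (anyDuplicated(x[c("city", "sex", "age")])) {
    abort_validation("duplicate (city, sex, age) rows in population state")
  }
  yr <- as.integer(x$year[1])
  out <- tidyr::complete(
    dplyr::select(x, "city", "sex", "age", "population"),
    city = unique(x$city), sex = .SEXES, age = .AGES,
    fill = list(population = 0)
  )
  out <- dplyr::arrange(out, .data$city, .data$sex, .data$age)
  out <- tibble::add_column(out, year = yr, .before = 1L)
  class(out) <- c("population_state", class(tibble::tibble()))
  out
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state: year %d, %d cities, total %.6g persons>\n",
              x$year[1], length(unique(x$city)), sum(x$population)))
  NextMethod()
}

#' Read / write a population state as long-format CSV
#'
#' The on-disk dialect has header `year,city,sex,age,population` with ages
#' serialized as `"0"`..`"99"`, `"100+"`.  The round trip is lossless.
#'
#' @param path CSV path.
#' @param state A [population_state()].
#' @return `read_population_state()` returns a `population_state`;
#'   `write_population_state()` returns `path` invisibly.
#' @export
read_population_state <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(age = readr::col_character()))
  population_state(x)
}

#' @rdname read_population_state
#' @export
write_population_state <- function(state, path) {
  stopifnot(inherits(state, "population_state"))
  out <- dplyr::mutate(tibble::as_tibble(state), age = age_to_label(.data$age))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Aggregate a population state to city, province or national totals
#'
#' Totals are sums over sex and age; by construction the national total
#' equals the sum of provincial totals equals the sum of city totals.
#'
#' @param state A [population_state()] (or any tibble with `year`, `city`,
#'   `sex`, `age`, `population` columns, possibly spanning several years).
#' @param level `"city"`, `"province"` or `"national"`.
#' @param geo A [geo_hierarchy()]; required for `"province"`, and used to
#'   validate that every city in `state` is known when supplied.
#' @return A tibble with `year`, the unit column (`city` / `province` /
#'   none), and `total`.
#' @examples
#' st <- population_state(data.frame(
#'   year = 2010, city = "A", sex = c("M", "F"), age = 0,
#'   population = c(10, 5)
#' ))
#' total_population(st, "city")
#' @export
total_population <- function(state, level = c("city", "province", "national"),
                             geo = NULL) {
  level <- match.arg(level)
  x <- tibble::as_tibble(state)
  if (!is.null(geo)) {
    missing_city <- setdiff(unique(x$city), geo$cities$city)
    if (length(missing_city)) {
      abort_citypop(sprintf("city in state missing from geography: %s",
                            paste(missing_city, collapse = ", ")))
    }
  }
  if (level == "city") {
    out <- dplyr::summarise(x, total = sum(.data$population),
                            .by = c("year", "city"))
  } else if (level == "province") {
    if (is.null(geo)) {
      abort_citypop("`geo` is required for province-level totals")
    }
    out <- x |>
      dplyr::left_join(geo$cities[c("city", "province")], by = "city") |>
      dplyr::summarise(total = sum(.data$population),
                       .by = c("year", "province"))
  } else {
    out <- dplyr::summarise(x, total = sum(.data$population), .by = "year")
  }
  dplyr::arrange(out, dplyr::pick(dplyr::everything()))
}

# ---- matrix representation used by the engine -------------------------------
# One matrix per sex, cities (geo order) x 101 ages.

.state_to_mats <- function(state, geo) {
  x <- tibble::as_tibble(state)
  missing_city <- setdiff(unique(x$city), geo$cities$city)
  if (length(missing_city)) {
    abort_citypop(sprintf("city in state missing from geography: %s",
                          paste(missing_city, collapse = ", ")))
  }
  cities <- geo$cities$city
  out <- lapply(.SEXES, function(s) {
    m <- matrix(0, nrow = length(cities), ncol = length(.AGES),
                dimnames = list(cities, .AGE_LABELS))
    sub <- x[x$sex == s, ]
    m[cbind(match(sub$city, cities), sub$age + 1L)] <- sub$population
    m
  })
  names(out) <- .SEXES
  out$year <- as.integer(x$year[1])
  out
}

.mats_to_state <- function(mats, year) {
  cities <- rownames(mats$M)
  n <- length(cities)
  tib <- tibble::tibble(
    year = as.integer(year),
    city = rep(cities, each = 2L * length(.AGES)),
    sex = rep(rep(.SEXES, each = length(.AGES)), times = n),
    age = rep(.AGES, times = 2L * n),
    population = as.numeric(t(cbind(mats$M, mats$F)))
  )
  # rebuild in canonical order via the constructor (also validates)
  population_state(tib)
}
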