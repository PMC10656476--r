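# Rate schedules: age-specific fertility, age/sex-specific mortality, and
# net migration rates at city and province level.

#' Construct a set of demographic rate schedules
#'
#' A `rate_set` bundles the four schedules that drive a projection:
#'
#' * `asfr` — age-specific fertility rates, births per woman per year, by
#'   (city, age 15..49);
#' * `asmr` — annual death probabilities in `[0, 1]`, by (city, sex,
#'   age 0..100+);
#' * `city_mig` — net migration rates (fraction of the resident cohort per
#'   year, may be negative but must exceed -1), by (city, sex, age);
#' * `prov_mig` — net migration rates by (province, sex, age).  A scalar
#'   per province (one row per province, no `sex`/`age` columns, column
#'   `rate`) is also accepted and broadcast across sexes and ages.
#'
#' @param asfr Tibble with columns `city`, `age`, `rate`.
#' @param asmr Tibble with columns `city`, `sex`, `age`, `rate`.
#' @param city_mig Tibble with columns `city`, `sex`, `age`, `rate`.
#' @param prov_mig Tibble with columns `province`, `sex`, `age`, `rate`, or
#'   a per-province scalar table with columns `province`, `rate`.
#' @return An object of class `rate_set`.
#' @export
rate_set <- function(asfr, asmr, city_mig, prov_mig) {
  asfr <- tibble::as_tibble(asfr)
  asmr <- tibble::as_tibble(asmr)
  city_mig <- tibble::as_tibble(city_mig)
  prov_mig <- tibble::as_tibble(prov_mig)

  asfr$age <- age_to_int(asfr$age)
  if (any(!asfr$age %in% .FERT_AGES)) {
    abort_validation("asfr ages must lie in 15..49")
  }
  if (any(asfr$rate < 0 | !is.finite(asfr$rate))) {
    abort_validation("asfr must be finite and >= 0")
  }
  asmr$age <- age_to_int(asmr$age)
  if (any(asmr$rate < 0 | asmr$rate > 1 | !is.finite(asmr$rate))) {
    abort_validation("asmr must be death probabilities in [0, 1]")
  }
  if (!all(c("sex", "age") %in% names(prov_mig))) {
    # scalar per province: broadcast across sex and age
    prov_mig <- tidyr::expand_grid(
      prov_mig[c("province", "rate")], sex = .SEXES, age = .AGES
    )[c("province", "sex", "age", "rate")]
  }
  city_mig$age <- age_to_int(city_mig$age)
  prov_mig$age <- age_to_int(prov_mig$age)
  for (m in list(city_mig, prov_mig)) {
    if (any(m$rate <= -1 | !is.finite(m$rate))) {
      abort_validation("migration rates must be finite and > -1")
    }
  }
  structure(list(asfr = asfr, asmr = asmr,
                 city_mig = city_mig, prov_mig = prov_mig),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf(
    "<rate_set: %d cities (asfr), %d cities (asmr), %d provinces (migration)>\n",
    length(unique(x$asfr$city)), length(unique(x$asmr$city)),
    length(unique(x$prov_mig$province))))
  invisible(x)
}

#' City total fertility rates implied by a rate set
#'
#' @param rates A [rate_set()] (or a bare `asfr` tibble).
#' @return Tibble with columns `city`, `tfr` (sum of ASFR over ages 15-49).
#' @export
city_tfr <- function(rates) {
  asfr <- if (inherits(rates, "rate_set")) rates$asfr else tibble::as_tibble(rates)
  dplyr::summarise(asfr, tfr = sum(.data$rate), .by = "city")
}

#' Read / write a rate set as a directory of CSV files
#'
#' Writes `asfr.csv`, `asmr.csv`, `city_migration.csv` and
#' `province_migration.csv` into `dir` (ages serialized as `"0"`..`"100+"`).
#'
#' @param rates A [rate_set()].
#' @param dir Directory path (created if needed).
#' @return `write_rate_set()` returns `dir` invisibly; `read_rate_set()`
#'   returns a `rate_set`.
#' @export
write_rate_set <- function(rates, dir) {
  stopifnot(inherits(rates, "rate_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lab <- function(x) dplyr::mutate(x, age = age_to_label(.data$age))
  readr::write_csv(lab(rates$asfr), file.path(dir, "asfr.csv"), progress = FALSE)
  readr::write_csv(lab(rates$asmr), file.path(dir, "asmr.csv"), progress = FALSE)
  readr::write_csv(lab(rates$city_mig), file.path(dir, "city_migration.csv"),
                   progress = FALSE)
  readr::write_csv(lab(rates$prov_mig), file.path(dir, "province_migration.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_rate_set
#' @export
read_rate_set <- function(dir) {
  rd <- function(f) {
    readr::read_csv(file.path(dir, f), show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(age = readr::col_character()))
  }
  rate_set(asfr = rd("asfr.csv"), asmr = rd("asmr.csv"),
           city_mig = rd("city_migration.csv"),
           prov_mig = rd("province_migration.csv"))
}

# ---- matrix views (engine internals) ---------------------------------------

.rates_to_mats <- function(rates, geo) {
  cities <- geo$cities$city
  provs <- geo$provinces$province
  miss <- setdiff(cities, unique(rates$asmr$city))
  if (length(miss)) {
    abort_citypop(sprintf("missing mortality schedule for city: %s",
                          paste(miss, collapse = ", ")))
  }
  miss <- setdiff(cities, unique(rates$asfr$city))
  if (length(miss)) {
    abort_citypop(sprintf("missing fertility schedule for city: %s",
                          paste(miss, collapse = ", ")))
  }
  fill_mat <- function(tab, units, unit_col, ages) {
    m <- matrix(0, nrow = length(units), ncol = length(ages),
                dimnames = list(units, as.character(ages)))
    keep <- tab[[unit_col]] %in% units
    tab <- tab[keep, ]
    m[cbind(match(tab[[unit_col]], units), match(tab$age, ages))] <- tab$rate
    m
  }
  sex_mats <- function(tab, units, unit_col) {
    out <- lapply(.SEXES, function(s) {
      fill_mat(tab[tab$sex == s, ], units, unit_col, .AGES)
    })
    names(out) <- .SEXES
    out
  }
  list(
    asfr = fill_mat(rates$asfr, cities, "city", .FERT_AGES),
    asmr = sex_mats(rates$asmr, cities, "city"),
    cmig = sex_mats(rates$city_mig, cities, "city"),
    pmig = sex_mats(rates$prov_mig, provs, "province")
  )
}
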