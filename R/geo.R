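# Geographic hierarchy: provinces (with east / middle-west region labels) and
# cities (with tier classification and optional population ceiling).

#' Construct a geographic hierarchy
#'
#' A `geo_hierarchy` holds the fixed policy geography of a projection: the
#' provinces with their macro-region label (`east` provinces gain migrants,
#' `middle_west` provinces lose them) and the cities with their tier
#' classification (`T1`, `NT1` new-tier-1, `T2`, `T3`) and an optional
#' population ceiling in persons for megacities under a ceiling policy.
#'
#' @param cities A data frame with columns `city`, `province`, `tier` and
#'   optionally `ceiling` (persons, `NA` = no ceiling).
#' @param provinces A data frame with columns `province` and `region`
#'   (`"east"` or `"middle_west"`).
#' @return An object of class `geo_hierarchy`: a list with tibbles
#'   `$provinces` and `$cities`.
#' @seealso [load_geo()] to build one from a flat city register.
#' @export
geo_hierarchy <- function(cities, provinces) {
  provinces <- tibble::as_tibble(provinces)
  cities <- tibble::as_tibble(cities)
  for (col in c("province", "region")) {
    if (!col %in% names(provinces)) {
      abort_validation(sprintf("provinces table lacks column `%s`", col))
    }
  }
  for (col in c("city", "province", "tier")) {
    if (!col %in% names(cities)) {
      abort_validation(sprintf("cities table lacks column `%s`", col))
    }
  }
  if (!"ceiling" %in% names(cities)) cities$ceiling <- NA_real_
  provinces <- dplyr::select(provinces, "province", "region")
  cities <- dplyr::select(cities, "city", "province", "tier", "ceiling")
  provinces$province <- as.character(provinces$province)
  cities$province <- as.character(cities$province)
  cities$city <- as.character(cities$city)
  cities$ceiling <- as.numeric(cities$ceiling)

  if (anyDuplicated(provinces$province)) {
    abort_validation("duplicate province id in geography")
  }
  if (anyDuplicated(cities$city)) {
    abort_validation("duplicate city id in geography")
  }
  bad_region <- setdiff(unique(provinces$region), .REGIONS)
  if (length(bad_region)) {
    abort_validation(sprintf("unknown region label(s): %s",
                             paste(bad_region, collapse = ", ")))
  }
  bad_tier <- setdiff(unique(cities$tier), .TIERS)
  if (length(bad_tier)) {
    abort_validation(sprintf("unknown tier label(s): %s",
                             paste(bad_tier, collapse = ", ")))
  }
  orphan <- setdiff(cities$province, provinces$province)
  if (length(orphan)) {
    abort_validation(sprintf("city assigned to unknown province(s): %s",
                             paste(orphan, collapse = ", ")))
  }
  empty <- setdiff(provinces$province, cities$province)
  if (length(empty)) {
    abort_validation(sprintf("province(s) without any city: %s",
                             paste(empty, collapse = ", ")))
  }
  if (any(!is.na(cities$ceiling) & cities$ceiling <= 0)) {
    abort_validation("population ceilings must be > 0")
  }
  structure(list(provinces = provinces, cities = cities),
            class = "geo_hierarchy")
}

#' Load a geographic hierarchy from a city register
#'
#' The register is one row per city with columns `city`, `province`,
#' `region`, `tier` and optionally `ceiling` (blank = no ceiling), the layout
#' used by `city_name.csv`-style files.  The province list and its region
#' labels are derived from the city rows; a province whose rows disagree on
#' `region` is rejected.
#'
#' @param x A data frame with the register columns, or a path to a CSV file.
#' @return A [geo_hierarchy()].
#' @examples
#' reg <- data.frame(
#'   city = c("A1", "A2", "B1"),
#'   province = c("P1", "P1", "P2"),
#'   region = c("east", "east", "middle_west"),
#'   tier = c("T1", "T3", "T3"),
#'   ceiling = c(2.3e7, NA, NA)
#' )
#' geo <- load_geo(reg)
#' geo$provinces
#' @export
load_geo <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  for (col in c("city", "province", "region", "tier")) {
    if (!col %in% names(x)) {
      abort_validation(sprintf("city register lacks column `%s`", col))
    }
  }
  provinces <- dplyr::distinct(x, .data$province, .data$region)
  if (anyDuplicated(provinces$province)) {
    abort_validation("province with inconsistent region labels in register")
  }
  geo_hierarchy(cities = x, provinces = provinces)
}

#' Write a geographic hierarchy back to a flat city register CSV
#'
#' @param geo A [geo_hierarchy()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_geo <- function(geo, path) {
  stopifnot(inherits(geo, "geo_hierarchy"))
  reg <- dplyr::left_join(geo$cities, geo$provinces, by = "province") |>
    dplyr::select("city", "province", "region", "tier", "ceiling")
  readr::write_csv(reg, path, progress = FALSE)
  invisible(path)
}

#' @export
print.geo_hierarchy <- function(x, ...) {
  cat(sprintf("<geo_hierarchy: %d provinces, %d cities (%d with ceiling)>\n",
              nrow(x$provinces), nrow(x$cities),
              sum(!is.na(x$cities$ceiling))))
  invisible(x)
}

# Index of each city's province position, in geo order.
.prov_index <- function(geo) {
  match(geo$cities$province, geo$provinces$province)
}

#' Reference register of the named tier-classified cities
#'
#' The cities with an explicit tier classification (the four Tier-1 cities,
#' the fifteen New-Tier-1 and the thirty Tier-2 cities), their provinces,
#' macro-region labels, and the one published population-ceiling parameter
#' (Beijing, 23 million permanent residents).  The remaining ~313
#' prefecture-level cities are Tier 3 and are not enumerated here; a full
#' national run needs a complete register assembled externally.
#'
#' @return A [geo_hierarchy()] built from the shipped register.
#' @examples
#' reg <- china_tier_register()
#' reg$cities[reg$cities$city == "Beijing", ]
#' @export
china_tier_register <- function() {
  load_geo(system.file("extdata", "china_tier_cities.csv",
                       package = "citypop", mustWork = TRUE))
}
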