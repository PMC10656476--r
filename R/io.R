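# Writers matching the published data layout: one CSV per unit and
# scenario ("Pop_TOTAL_<name>_SSPFer<x>_SSPMigr<x>.csv"), cross-scenario
# summary files (City_TOTAL.csv, Province_TOTAL.csv, Pop_TOTAL.csv) and the
# city register (city_name.csv).

# Fixed float formatting (6 significant digits) so identical runs produce
# byte-identical files.
.fmt_num <- function(x) sprintf("%.6g", x)

.sanitize_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

# long (year, sex, age, population) table for one unit from a result
.unit_long <- function(result, rows, pooled = FALSE) {
  # rows: indices into the city dimension; pooled=TRUE sums them
  yrs <- result$years
  out <- vector("list", length(yrs))
  for (i in seq_along(yrs)) {
    m <- result$counts[rows, , , i, drop = FALSE]
    bysex <- apply(m, c(2, 3), sum)   # age x sex
    out[[i]] <- tibble::tibble(
      year = yrs[i],
      sex = rep(.SEXES, each = length(.AGES)),
      age = rep(.AGE_LABELS, times = 2L),
      population = c(bysex[, "M"], bysex[, "F"]))
  }
  dplyr::bind_rows(out)
}

.write_formatted <- function(tab, path) {
  tab$population <- .fmt_num(tab$population)
  readr::write_csv(tab, path, progress = FALSE)
  nrow(tab)
}

#' Write projection results in the published CSV layout
#'
#' For every scenario and unit writes
#' `Pop_TOTAL_<unit>_SSPFer<f>_SSPMigr<m>.csv` (cities and provinces; the
#' national file drops the unit name) with columns `year`, `sex` (`M`/`F`),
#' `age` (`0`..`99`, `100+`) and `population`; plus the cross-scenario
#' summary files `City_TOTAL.csv`, `Province_TOTAL.csv` and `Pop_TOTAL.csv`
#' with columns `(unit, year, scenario, population)`, and `city_name.csv`
#' mapping cities to provinces.  Unit names are sanitized for filenames
#' (anything outside `[A-Za-z0-9_.-]` becomes `_`); the mapping is recorded
#' in the manifest.  Counts are written with 6 significant digits and fixed
#' row ordering, so writers are deterministic.
#'
#' @param results A `projection_grid`, a list of `projection_result`s, or a
#'   single `projection_result`.
#' @param geo A [geo_hierarchy()].
#' @param outdir Output directory (created if needed).
#' @return A tibble manifest (file, unit, scenario, rows), invisibly; also
#'   written as `manifest.csv`.
#' @export
write_outputs <- function(results, geo, outdir) {
  if (inherits(results, "projection_result")) results <- list(results)
  if (!length(results)) abort_citypop("`results` is empty")
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_citypop(sprintf("cannot create output directory %s", outdir))
  }
  cities <- geo$cities$city
  provs <- geo$provinces$province
  pidx <- .prov_index(geo)
  manifest <- list()
  add <- function(file, unit, scenario, rows) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      file = file, unit = unit, scenario = scenario, rows = rows)
  }
  city_sum <- list(); prov_sum <- list(); nat_sum <- list()

  for (res in results) {
    if (!inherits(res, "projection_result")) {
      abort_citypop("`results` must contain projection_result objects")
    }
    lab <- if (is.null(res$scenario)) "CONST" else .scenario_label(res$scenario)
    for (ci in seq_along(cities)) {
      f <- sprintf("Pop_TOTAL_%s_%s.csv", .sanitize_name(cities[ci]), lab)
      n <- .write_formatted(.unit_long(res, ci), file.path(outdir, f))
      add(f, cities[ci], lab, n)
    }
    for (pi in seq_along(provs)) {
      f <- sprintf("Pop_TOTAL_%s_%s.csv", .sanitize_name(provs[pi]), lab)
      n <- .write_formatted(.unit_long(res, which(pidx == pi)),
                            file.path(outdir, f))
      add(f, provs[pi], lab, n)
    }
    f <- sprintf("Pop_TOTAL_%s.csv", lab)
    n <- .write_formatted(.unit_long(res, seq_along(cities)),
                          file.path(outdir, f))
    add(f, "national", lab, n)

    sm <- res$summaries
    city_sum[[lab]] <- sm[sm$level == "city", ] |>
      dplyr::transmute(city = .data$unit, year = .data$year, scenario = lab,
                       population = .data$total)
    prov_sum[[lab]] <- sm[sm$level == "province", ] |>
      dplyr::transmute(province = .data$unit, year = .data$year,
                       scenario = lab, population = .data$total)
    nat_sum[[lab]] <- sm[sm$level == "national", ] |>
      dplyr::transmute(year = .data$year, scenario = lab,
                       population = .data$total)
  }

  n <- .write_formatted(dplyr::bind_rows(city_sum),
                        file.path(outdir, "City_TOTAL.csv"))
  add("City_TOTAL.csv", "all cities", "all", n)
  n <- .write_formatted(dplyr::bind_rows(prov_sum),
                        file.path(outdir, "Province_TOTAL.csv"))
  add("Province_TOTAL.csv", "all provinces", "all", n)
  n <- .write_formatted(dplyr::bind_rows(nat_sum),
                        file.path(outdir, "Pop_TOTAL.csv"))
  add("Pop_TOTAL.csv", "national", "all", n)

  cn <- tibble::tibble(city = cities,
                       province = geo$cities$province)
  readr::write_csv(cn, file.path(outdir, "city_name.csv"), progress = FALSE)
  add("city_name.csv", "register", "all", nrow(cn))

  manifest <- dplyr::bind_rows(manifest)
  readr::write_csv(manifest, file.path(outdir, "manifest.csv"),
                   progress = FALSE)
  invisible(manifest)
}

#' Read back a per-unit projection output file
#'
#' @param path A `Pop_TOTAL_*.csv` file written by [write_outputs()].
#' @return Tibble with `year`, `sex`, `age` (integer, 100 = open interval)
#'   and `population`.
#' @export
read_pop_total <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(age = readr::col_character()))
  x$age <- age_to_int(x$age)
  x
}
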