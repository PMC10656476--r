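# The annual cohort-component recursion: births, survival + internal
# migration + international migration, ceiling triggers, and the
# baseline-to-2100 loop over the scenario grid.

#' Newborns by city and sex
#'
#' Total births per city are the sum over ages 15-49 of the previous year's
#' female counts times the year's age-specific fertility rates; the total
#' is split into sexes by the sex ratio at birth (`male = srb / (1 + srb)`).
#' Newborns are not subject to mortality, migration or the international
#' migration factor in their birth year.
#'
#' @param prev A [population_state()] for the previous year.
#' @param asfr Tibble `city`, `age`, `rate` (ages 15..49), e.g. from
#'   [scale_asfr()].
#' @param srb Sex ratio at birth for the year.
#' @return Tibble with columns `city`, `sex`, `births`.
#' @examples
#' st <- population_state(data.frame(year = 2010, city = "A", sex = "F",
#'                                   age = 25, population = 1000))
#' births(st, data.frame(city = "A", age = 25, rate = 0.1), srb = 1.07)
#' @export
births <- function(prev, asfr, srb) {
  srb <- .check_scalar_number(srb, "srb", min = 1e-9)
  asfr <- tibble::as_tibble(asfr)
  asfr$age <- age_to_int(asfr$age)
  fem <- tibble::as_tibble(prev) |>
    dplyr::filter(.data$sex == "F", .data$age %in% .FERT_AGES)
  tot <- fem |>
    dplyr::left_join(asfr, by = c("city", "age")) |>
    dplyr::mutate(rate = dplyr::coalesce(.data$rate, 0)) |>
    dplyr::summarise(total = sum(.data$population * .data$rate), .by = "city")
  sh <- birth_shares(srb)
  dplyr::bind_rows(
    dplyr::mutate(tot, sex = "M", births = .data$total * sh$male),
    dplyr::mutate(tot, sex = "F", births = .data$total * sh$female)
  ) |>
    dplyr::select("city", "sex", "births") |>
    dplyr::arrange(.data$city, .data$sex)
}

# survival + migration + international factor, matrix form; one sex.
# Returns the next-year matrix (age 0 column left at 0), total deaths, the
# international-migration person effect, and the clamped shortfall.
.advance_mat <- function(prev, q, flow, netgim) {
  surv <- prev * (1 - q)
  moved <- (surv + flow) * (1 + netgim)
  shortfall <- -sum(moved[moved < 0])
  moved[moved < 0] <- 0
  nc <- ncol(prev)
  new <- matrix(0, nrow = nrow(prev), ncol = nc, dimnames = dimnames(prev))
  new[, 2:nc] <- moved[, 1:(nc - 1)]
  new[, nc] <- new[, nc] + moved[, nc]   # survivors of 100+ stay in 100+
  list(counts = new,
       deaths = sum(prev * q),
       netgim_effect = netgim * sum(surv + flow),
       shortfall = shortfall)
}

#' Age every cohort one year under mortality, migration and the
#' international factor
#'
#' Implements the survival recursion
#' `P[yr, a+1] = (P[yr-1, a] (1 - q[a]) + flow[a]) (1 + netgim)`: each
#' cohort ages one year, survivors of age 99 and of the open interval are
#' pooled into `100+`, and any cohort driven negative by outflow is clamped
#' at zero with the shortfall recorded.  The age-0 slot of the returned
#' state is zero; fill it with [births()].
#'
#' @param prev A [population_state()] for the previous year.
#' @param asmr Tibble `city`, `sex`, `age`, `rate` of death probabilities.
#' @param flows A [migration_flows()] whose `city_net_adj` is used (or
#'   `NULL` for no migration).
#' @param netgim Net international migration rate for the year (fraction).
#' @return A `population_state` for `prev$year + 1` with attributes
#'   `shortfall` (persons clamped) and `deaths` (total deaths).
#' @export
advance_cohorts <- function(prev, asmr, flows = NULL, netgim = 0) {
  netgim <- .check_scalar_number(netgim, "netgim", min = -1 + 1e-12)
  cities <- sort(unique(tibble::as_tibble(prev)$city))
  pm <- .flow_tab_to_mats(tibble::as_tibble(prev), "city", "population", cities)
  am <- tibble::as_tibble(asmr)
  miss <- setdiff(cities, unique(am$city))
  if (length(miss)) {
    abort_citypop(sprintf("missing mortality schedule for city: %s",
                          paste(miss, collapse = ", ")))
  }
  qm <- .flow_tab_to_mats(am, "city", "rate", cities)
  if (is.null(flows)) {
    zero <- matrix(0, nrow = length(cities), ncol = length(.AGES),
                   dimnames = list(cities, .AGE_LABELS))
    fm <- list(M = zero, F = zero)
  } else {
    stopifnot(inherits(flows, "migration_flows"))
    if (is.null(flows$city_net_adj)) {
      abort_citypop("`flows` must carry adjusted city flows (city_net_adj)")
    }
    fm <- .flow_tab_to_mats(flows$city_net_adj, "city", "net_adj", cities)
  }
  res <- lapply(.SEXES, function(s) .advance_mat(pm[[s]], qm[[s]], fm[[s]], netgim))
  names(res) <- .SEXES
  out <- .mats_to_state(list(M = res$M$counts, F = res$F$counts),
                        year = tibble::as_tibble(prev)$year[1] + 1L)
  attr(out, "shortfall") <- res$M$shortfall + res$F$shortfall
  attr(out, "deaths") <- res$M$deaths + res$F$deaths
  out
}

#' Precompute the projection basis from the baseline
#'
#' The basis anchors the scenario machinery to the baseline census: the
#' female-population-weighted baseline national TFR (the denominator of the
#' fertility scaling factor), the baseline life expectancy of every city by
#' sex, and the population-weighted national life expectancy by sex (the
#' reference of the one-year-per-decade rule).
#'
#' @param baseline_state The baseline [population_state()].
#' @param rates The baseline [rate_set()].
#' @param geo A [geo_hierarchy()].
#' @return A list of class `projection_basis`.
#' @export
projection_basis <- function(baseline_state, rates, geo) {
  rm <- .rates_to_mats(rates, geo)
  sm <- .state_to_mats(baseline_state, geo)
  e0 <- lapply(.SEXES, function(s) {
    apply(rm$asmr[[s]], 1, life_expectancy)
  })
  names(e0) <- .SEXES
  wts <- lapply(.SEXES, function(s) rowSums(sm[[s]]))
  names(wts) <- .SEXES
  e0_nat <- vapply(.SEXES, function(s) {
    if (sum(wts[[s]]) > 0) sum(e0[[s]] * wts[[s]]) / sum(wts[[s]])
    else mean(e0[[s]])
  }, numeric(1))
  structure(list(
    tfr0 = national_tfr(rates, baseline_state),
    e0_city = e0,
    e0_national = e0_nat,
    baseline_year = as.integer(tibble::as_tibble(baseline_state)$year[1])
  ), class = "projection_basis")
}

# Year's mortality matrices (city x age per sex), scaled to the city
# life-expectancy targets; memoised in `cache` because the mortality path is
# scenario-invariant and shared across the whole scenario grid.
.year_asmr <- function(rm, basis, year, cache = NULL) {
  key <- as.character(year)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  out <- lapply(.SEXES, function(s) {
    base <- rm$asmr[[s]]
    tgt <- le_target(year, basis$e0_city[[s]], basis$e0_national[[s]],
                     baseline_year = basis$baseline_year)
    res <- base
    for (i in seq_len(nrow(base))) {
      # a city with no mortality (e.g. a zero-rate toy) has infinite life
      # expectancy and an undefined target; its schedule stays as-is
      if (!is.finite(tgt[i]) || all(base[i, ] == 0)) next
      res[i, ] <- mortality_for_target(base[i, ], tgt[i])
    }
    res
  })
  names(out) <- .SEXES
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# One scenario step in matrix form.  Returns next-year matrices plus audit
# quantities.
.step_scenario <- function(prev, rm, geo, pidx, year, spec, basis, cache) {
  ykey <- as.character(year)
  # (1) year rates; a zero-fertility baseline stays at zero births (there is
  # no shape to rescale toward the scenario TFR)
  f <- if (basis$tfr0 > 0) spec$tfr[[ykey]] / basis$tfr0 else 1
  asfr_y <- rm$asfr * f
  q <- .year_asmr(rm, basis, year, cache)
  totals <- rowSums(prev$M) + rowSums(prev$F)
  mig <- .mig_rates_core(rm, geo, spec$migration_id, year, totals)
  g <- spec$netgim[[ykey]]
  srb <- spec$srb[[ykey]]
  # (2) flows + two-level balance
  provM <- rowsum(prev$M, pidx, reorder = TRUE)
  provF <- rowsum(prev$F, pidx, reorder = TRUE)
  cflM <- prev$M * mig$cmig$M
  cflF <- prev$F * mig$cmig$F
  padjM <- .balance_cols(provM * mig$pmig$M)
  padjF <- .balance_cols(provF * mig$pmig$F)
  cadjM <- .reconcile_mats(cflM, padjM, pidx, prev$M)
  cadjF <- .reconcile_mats(cflF, padjF, pidx, prev$F)
  # (3) births from previous-year females, year's fertility
  B <- rowSums(prev$F[, .FERT_AGES + 1L, drop = FALSE] * asfr_y)
  # (4) survival + migration + international factor
  aM <- .advance_mat(prev$M, q$M, cadjM, g)
  aF <- .advance_mat(prev$F, q$F, cadjF, g)
  aM$counts[, 1L] <- B * (srb / (1 + srb))
  aF$counts[, 1L] <- B * (1 / (1 + srb))
  list(M = aM$counts, F = aF$counts,
       births = sum(B),
       deaths = aM$deaths + aF$deaths,
       netgim_effect = aM$netgim_effect + aF$netgim_effect,
       shortfall = aM$shortfall + aF$shortfall,
       at_ceiling = mig$at_ceiling)
}

#' Advance a population state one year under a scenario
#'
#' Composes, in order: the year's rate schedules (fertility scaled to the
#' scenario TFR, mortality scaled to the life-expectancy targets, migration
#' rates with tier/region multipliers, settlement-policy factors and
#' ceiling checks against the previous year's totals), the two-level
#' migration balance, births, and cohort survival.
#'
#' @param prev A [population_state()].
#' @param scenario A [scenario_spec()] covering `prev$year + 1`.
#' @param rates The baseline [rate_set()].
#' @param geo A [geo_hierarchy()].
#' @param basis Optional [projection_basis()]; computed from `prev` when
#'   absent (pass the true baseline basis for exact scenario anchoring,
#'   which [project()] does automatically).
#' @return A `population_state` for the next year, with attributes
#'   `shortfall`, `deaths`, `births` and `at_ceiling` (cities whose
#'   migration was zeroed by their ceiling this year).
#' @export
step_year <- function(prev, scenario, rates, geo, basis = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  year <- tibble::as_tibble(prev)$year[1] + 1L
  if (!year %in% scenario$years) {
    abort_citypop(sprintf("scenario paths do not cover year %d", year))
  }
  basis <- basis %||% projection_basis(prev, rates, geo)
  rm <- .rates_to_mats(rates, geo)
  sm <- .state_to_mats(prev, geo)
  pidx <- .prov_index(geo)
  st <- .step_scenario(sm, rm, geo, pidx, year, scenario, basis, cache = NULL)
  out <- .mats_to_state(list(M = st$M, F = st$F), year)
  attr(out, "shortfall") <- st$shortfall
  attr(out, "deaths") <- st$deaths
  attr(out, "births") <- st$births
  attr(out, "at_ceiling") <- st$at_ceiling
  out
}

# Assemble a projection_result from the stored count array.
.make_result <- function(arr, years, geo, scenario, vitals, events) {
  cities <- geo$cities$city
  n_age <- length(.AGES)
  # city totals per year
  ct <- apply(arr, c(1, 4), sum)           # city x year
  pidx <- .prov_index(geo)
  pt <- rowsum(ct, pidx, reorder = TRUE)
  rownames(pt) <- geo$provinces$province
  nt <- colSums(ct)
  summaries <- dplyr::bind_rows(
    tibble::tibble(level = "city",
                   unit = rep(cities, times = length(years)),
                   year = rep(years, each = length(cities)),
                   total = as.numeric(ct)),
    tibble::tibble(level = "province",
                   unit = rep(geo$provinces$province, times = length(years)),
                   year = rep(years, each = nrow(pt)),
                   total = as.numeric(pt)),
    tibble::tibble(level = "national", unit = "national",
                   year = years, total = as.numeric(nt))
  )
  structure(list(
    counts = arr, years = years, geo = geo, scenario = scenario,
    summaries = summaries, vitals = vitals, events = events
  ), class = "projection_result")
}

.project_loop <- function(baseline_state, rates, geo, end_year, stepper) {
  sm <- .state_to_mats(baseline_state, geo)
  y0 <- sm$year
  if (end_year < y0) abort_citypop("`end_year` precedes the baseline year")
  years <- seq.int(y0, end_year)
  cities <- geo$cities$city
  arr <- array(0, dim = c(length(cities), length(.AGES), 2L, length(years)),
               dimnames = list(cities, .AGE_LABELS, .SEXES, years))
  arr[, , "M", 1L] <- sm$M
  arr[, , "F", 1L] <- sm$F
  vit <- vector("list", length(years) - 1L)
  ev <- list()
  prev <- list(M = sm$M, F = sm$F)
  for (i in seq_along(years)[-1L]) {
    st <- stepper(prev, years[i])
    arr[, , "M", i] <- st$M
    arr[, , "F", i] <- st$F
    vit[[i - 1L]] <- tibble::tibble(
      year = years[i], births = st$births, deaths = st$deaths,
      net_international = st$netgim_effect, shortfall = st$shortfall)
    if (length(st$at_ceiling)) {
      ev[[length(ev) + 1L]] <- tibble::tibble(year = years[i],
                                              city = st$at_ceiling)
    }
    prev <- list(M = st$M, F = st$F)
  }
  vitals <- dplyr::bind_rows(vit)
  events <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(year = integer(), city = character())
  list(arr = arr, years = years, vitals = vitals, events = events)
}

#' Project a multi-city population system under one scenario
#'
#' Iterates the annual cohort-component step from the baseline year to
#' `end_year` under the chosen fertility (1..5) and migration (1..3)
#' scenario.  Deterministic: identical inputs give bit-identical outputs.
#'
#' @param baseline_state The baseline [population_state()].
#' @param rates The baseline [rate_set()].
#' @param geo A [geo_hierarchy()].
#' @param fertility_id,migration_id Scenario ids.
#' @param end_year Last projected year (default 2100).
#' @param baseline_srb Sex ratio at birth in the baseline year.
#' @param basis Optional precomputed [projection_basis()].
#' @param mort_cache Optional environment memoising the (scenario-invariant)
#'   annual mortality schedules; [project_grid()] shares one across the
#'   grid.
#' @return An object of class `projection_result`: yearly counts by (city,
#'   sex, age), summary totals at city/province/national level, the
#'   scenario used, annual vital statistics (births, deaths, international
#'   effect, clamped shortfall) and a log of ceiling activations.
#' @seealso [project_grid()], [get_state()], [tidy.projection_result()]
#' @export
project <- function(baseline_state, rates, geo, fertility_id, migration_id,
                    end_year = 2100, baseline_srb = 1.18, basis = NULL,
                    mort_cache = NULL) {
  y0 <- tibble::as_tibble(baseline_state)$year[1]
  spec <- scenario_spec(fertility_id, migration_id, baseline_srb = baseline_srb,
                        baseline_year = y0, end_year = end_year)
  basis <- basis %||% projection_basis(baseline_state, rates, geo)
  cache <- mort_cache %||% new.env(parent = emptyenv())
  rm <- .rates_to_mats(rates, geo)
  pidx <- .prov_index(geo)
  res <- .project_loop(baseline_state, rates, geo, end_year,
                       stepper = function(prev, year) {
                         .step_scenario(prev, rm, geo, pidx, year, spec,
                                        basis, cache)
                       })
  .make_result(res$arr, res$years, geo, spec, res$vitals, res$events)
}

#' Project under constant rates (no scenario adjustment)
#'
#' Holds the baseline rate schedules fixed in every year: no fertility or
#' mortality scaling, no migration multipliers, policy factors or ceiling
#' checks (migration flows are still computed from the fixed rates and
#' balanced).  This is the pure linear cohort-component operator -- with a
#' single region and no migration it is exactly a Leslie-matrix iteration,
#' which makes it the natural object for conservation and oracle checks,
#' and a useful no-policy reference run.
#'
#' @inheritParams project
#' @param srb Constant sex ratio at birth.
#' @param netgim Constant net international migration rate.
#' @return A `projection_result` (with `scenario = NULL`).
#' @export
project_constant <- function(baseline_state, rates, geo, end_year,
                             srb = 1.07, netgim = 0) {
  rm <- .rates_to_mats(rates, geo)
  pidx <- .prov_index(geo)
  shares <- birth_shares(srb)
  stepper <- function(prev, year) {
    provM <- rowsum(prev$M, pidx, reorder = TRUE)
    provF <- rowsum(prev$F, pidx, reorder = TRUE)
    cadjM <- .reconcile_mats(prev$M * rm$cmig$M,
                             .balance_cols(provM * rm$pmig$M), pidx, prev$M)
    cadjF <- .reconcile_mats(prev$F * rm$cmig$F,
                             .balance_cols(provF * rm$pmig$F), pidx, prev$F)
    B <- rowSums(prev$F[, .FERT_AGES + 1L, drop = FALSE] * rm$asfr)
    aM <- .advance_mat(prev$M, rm$asmr$M, cadjM, netgim)
    aF <- .advance_mat(prev$F, rm$asmr$F, cadjF, netgim)
    aM$counts[, 1L] <- B * shares$male
    aF$counts[, 1L] <- B * shares$female
    list(M = aM$counts, F = aF$counts, births = sum(B),
         deaths = aM$deaths + aF$deaths,
         netgim_effect = aM$netgim_effect + aF$netgim_effect,
         shortfall = aM$shortfall + aF$shortfall,
         at_ceiling = character())
  }
  res <- .project_loop(baseline_state, rates, geo, end_year, stepper)
  .make_result(res$arr, res$years, geo, NULL, res$vitals, res$events)
}

#' Project the full fertility x migration scenario grid
#'
#' Runs [project()] for every requested (fertility, migration) pair,
#' sharing the projection basis and the scenario-invariant mortality path
#' across runs.
#'
#' @inheritParams project
#' @param fertility_ids,migration_ids Scenario ids to cross (defaults: the
#'   full 5 x 3 grid).
#' @return An object of class `projection_grid`: a named list of
#'   `projection_result`s keyed by scenario label (`SSPFer<f>_SSPMigr<m>`).
#' @export
project_grid <- function(baseline_state, rates, geo,
                         fertility_ids = 1:5, migration_ids = 1:3,
                         end_year = 2100, baseline_srb = 1.18) {
  basis <- projection_basis(baseline_state, rates, geo)
  cache <- new.env(parent = emptyenv())
  out <- list()
  for (f in fertility_ids) {
    for (m in migration_ids) {
      r <- project(baseline_state, rates, geo, f, m, end_year = end_year,
                   baseline_srb = baseline_srb, basis = basis,
                   mort_cache = cache)
      out[[.scenario_label(r$scenario)]] <- r
    }
  }
  structure(out, class = "projection_grid")
}

#' Extract one year's population state from a projection
#'
#' @param result A `projection_result`.
#' @param year A year within the projected range.
#' @return A [population_state()].
#' @export
get_state <- function(result, year) {
  stopifnot(inherits(result, "projection_result"))
  if (!year %in% result$years) {
    abort_citypop(sprintf("year %d is not in the projected range %d-%d",
                          year, min(result$years), max(result$years)))
  }
  i <- match(year, result$years)
  dn <- dimnames(result$counts)
  slice <- function(s) {
    matrix(result$counts[, , s, i], nrow = length(dn[[1]]),
           dimnames = dn[1:2])
  }
  .mats_to_state(list(M = slice("M"), F = slice("F")), year)
}

#' @export
print.projection_result <- function(x, ...) {
  lab <- if (is.null(x$scenario)) "constant rates" else .scenario_label(x$scenario)
  nat <- x$summaries[x$summaries$level == "national", ]
  cat(sprintf(
    "<projection_result: %s, %d-%d, %d cities>\n  national total: %.6g (%d) -> %.6g (%d)\n",
    lab, min(x$years), max(x$years), nrow(x$geo$cities),
    nat$total[1], min(x$years), nat$total[nrow(nat)], max(x$years)))
  invisible(x)
}

#' @export
print.projection_grid <- function(x, ...) {
  cat(sprintf("<projection_grid: %d scenarios: %s>\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}
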