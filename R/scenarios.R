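# Scenario machinery: time-varying parameter paths for the 5 fertility x 3
# migration scenario grid, plus the policy overlays (population ceilings,
# settlement-reform reductions for small/middle-sized cities).

# Fertility targets by scenario id (births per woman).
.TFR_TARGETS_2050 <- c(0.7, 1.3, 1.5, 1.8, 1.8)
.TFR_TARGETS_2100 <- c(0.9, 1.3, 1.8, 1.8, 2.1)
# Shared historical anchors (observed): identical across scenarios.
.TFR_HIST_YEARS <- c(2010, 2013, 2017, 2020)
.TFR_HIST_VALUES <- c(1.5, 1.50, 1.88, 1.30)

# Net international migration rate (fraction of population per year).
.NETGIM_RATE <- -0.3015e-3
# Internal migration winds down to zero by this year in every scenario.
.MIG_ZERO_YEAR <- 2035
.MIG_PIVOT_YEAR <- 2020

#' Total fertility rate path for a fertility scenario
#'
#' Piecewise-linear through the observed anchors (2010, 1.5), (2013, 1.50),
#' (2017, 1.88), (2020, 1.30) -- shared by all five scenarios, since history
#' is observed -- then linear to the scenario's 2050 target and on to its
#' 2100 target, constant after 2100.  Targets (births/woman):
#'
#' | scenario | 2050 | 2100 | narrative |
#' |---|---|---|---|
#' | 1 | 0.7 | 0.9 | low |
#' | 2 | 1.3 | 1.3 | stable |
#' | 3 | 1.5 | 1.8 | medium |
#' | 4 | 1.8 | 1.8 | high |
#' | 5 | 1.8 | 2.1 | extremely high |
#'
#' @param fertility_id Integer 1..5.
#' @param years Integer vector of calendar years (>= 2010).
#' @return Numeric vector of TFR values, one per element of `years`.
#' @examples
#' tfr_path(3, c(2020, 2050, 2100))
#' @export
tfr_path <- function(fertility_id, years) {
  if (length(fertility_id) != 1L || !fertility_id %in% 1:5) {
    abort_validation("`fertility_id` must be an integer in 1..5")
  }
  if (any(years < 2010)) {
    abort_validation("TFR path is defined from 2010 onward")
  }
  anchors_x <- c(.TFR_HIST_YEARS, 2050, 2100)
  anchors_y <- c(.TFR_HIST_VALUES,
                 .TFR_TARGETS_2050[fertility_id],
                 .TFR_TARGETS_2100[fertility_id])
  approx(anchors_x, anchors_y, xout = pmin(years, 2100))$y
}

#' Sex ratio at birth path
#'
#' Linear from `baseline_srb` in 2010 to the long-term target of 1.07 in
#' 2050, constant thereafter.
#'
#' @param year Calendar year(s), >= 2010.
#' @param baseline_srb Sex ratio at birth (male births per female birth) in
#'   2010.  The default 1.18 is a typical high starting value; the target
#'   path only pins the 2050 endpoint, so the start is a parameter.
#' @return Numeric vector of sex ratios.
#' @export
srb_path <- function(year, baseline_srb = 1.18) {
  baseline_srb <- .check_scalar_number(baseline_srb, "baseline_srb", min = 1e-9)
  if (any(year < 2010)) {
    abort_validation("SRB path is defined from 2010 onward")
  }
  frac <- (pmin(year, 2050) - 2010) / 40
  baseline_srb + (1.07 - baseline_srb) * frac
}

#' Newborn sex shares from a sex ratio at birth
#'
#' `Bm = srb / (1 + srb)`, `Bf = 1 / (1 + srb)`; the shares always sum to 1.
#'
#' @param srb Sex ratio at birth (male per female births), > 0.
#' @return Tibble with columns `srb`, `male`, `female`.
#' @examples
#' birth_shares(1.07)
#' @export
birth_shares <- function(srb) {
  if (any(srb <= 0)) abort_validation("`srb` must be > 0")
  tibble::tibble(srb = srb, male = srb / (1 + srb), female = 1 / (1 + srb))
}

#' Net international migration rate path
#'
#' Constant at -0.3015 per thousand per year from 2010 through 2050, then
#' declining linearly to exactly 0 at 2100.
#'
#' @param year Calendar year(s) in 2010..2100.
#' @return Net international migration rate as a fraction per year
#'   (negative = net emigration).
#' @examples
#' netgim_path(c(2020, 2075, 2100)) * 1000  # per mille
#' @export
netgim_path <- function(year) {
  if (any(year < 2010 | year > 2100)) {
    abort_validation("international migration path covers 2010..2100 only")
  }
  ifelse(year <= 2050, .NETGIM_RATE, .NETGIM_RATE * (2100 - year) / 50)
}

#' Scale city fertility schedules to a national TFR target
#'
#' Every city's ASFR is multiplied by the single factor
#' `target / baseline national TFR`, where the baseline national TFR is the
#' female-population-weighted (women aged 15-49) mean of city TFRs.  City
#' relative differences and schedule shapes are preserved; only the national
#' level moves.
#'
#' @param rates A [rate_set()] (or bare `asfr` tibble with `city`, `age`,
#'   `rate`).
#' @param target_tfr Target national TFR, births per woman.
#' @param baseline_state A [population_state()] providing the female weights.
#' @return The scaled `asfr` tibble.
#' @export
scale_asfr <- function(rates, target_tfr, baseline_state) {
  target_tfr <- .check_scalar_number(target_tfr, "target_tfr", min = 0)
  asfr <- if (inherits(rates, "rate_set")) rates$asfr else tibble::as_tibble(rates)
  base_tfr <- national_tfr(asfr, baseline_state)
  if (base_tfr <= 0) {
    abort_citypop("baseline national TFR is zero; cannot scale fertility")
  }
  dplyr::mutate(asfr, rate = .data$rate * (target_tfr / base_tfr))
}

#' Female-population-weighted national TFR
#'
#' @inheritParams scale_asfr
#' @param state A [population_state()] providing women aged 15-49 as weights.
#' @return A single number: the weighted mean of city TFRs.
#' @export
national_tfr <- function(rates, state) {
  tfr <- city_tfr(rates)
  w <- tibble::as_tibble(state) |>
    dplyr::filter(.data$sex == "F", .data$age %in% .FERT_AGES) |>
    dplyr::summarise(w = sum(.data$population), .by = "city")
  tab <- dplyr::inner_join(tfr, w, by = "city")
  if (sum(tab$w) <= 0) {
    # no women of childbearing age anywhere: fall back to unweighted mean
    return(mean(tfr$tfr))
  }
  sum(tab$tfr * tab$w) / sum(tab$w)
}

#' City life-expectancy target under the one-year-per-decade rule
#'
#' Life expectancy grows by one year per decade nationally, attenuated (or
#' amplified) per city by its initial ratio to the national level:
#' `target = e0_city + ((year - 2010) / 10) * e0_city / e0_national`.
#' Cities below the national baseline therefore gain slightly less than one
#' year per decade, which aggregates to a national gain a little under one
#' year per decade.
#'
#' @param year Calendar year(s).
#' @param city_e0 Baseline (2010) city life expectancy, years.
#' @param national_e0 Baseline (2010) national life expectancy, years.  Use
#'   sex-specific values when sex-specific baselines are available.
#' @param baseline_year Reference year of the baselines (default 2010).
#' @return Target life expectancy in years.
#' @export
le_target <- function(year, city_e0, national_e0, baseline_year = 2010) {
  if (any(city_e0 <= 0) || any(national_e0 <= 0)) {
    abort_validation("baseline life expectancies must be > 0")
  }
  city_e0 + ((year - baseline_year) / 10) * (city_e0 / national_e0)
}

# ---- migration multipliers and policy overlays -----------------------------

#' Scenario multipliers for provincial migration rates (2020 pivot)
#'
#' By 2020 provincial net migration rates scale relative to their 2010
#' absolute value: scenario 1 amplifies flows by 50% on both sides (eastern
#' gains grow 50%, middle-western losses deepen 50%), scenario 2 by 25%,
#' scenario 3 keeps 2010 rates.  The multiplier applies to the signed rate,
#' so amplification preserves sign.
#'
#' @param region `"east"` or `"middle_west"` (vectorized).
#' @param migration_id Integer 1..3.
#' @return Numeric multiplier(s) on the signed 2010 rate.
#' @export
region_multiplier <- function(region, migration_id) {
  .check_flag_in(migration_id, "migration_id", 1:3)
  if (any(!region %in% .REGIONS)) {
    abort_validation("unknown region label")
  }
  rep(c(1.5, 1.25, 1)[migration_id], length(region))
}

#' Scenario multipliers for city migration rates by tier (2020 pivot)
#'
#' 2020 rates relative to 2010: scenario 1 -- Tier 1 +100%, New-Tier 1 +75%,
#' Tier 2 +50%, Tier 3 -75%; scenario 2 -- +50% / +25% / unchanged / -25%;
#' scenario 3 -- all unchanged.  For Tier 3 the reduction shrinks the
#' magnitude of the rate toward zero.
#'
#' @param tier `"T1"`, `"NT1"`, `"T2"` or `"T3"` (vectorized).
#' @param migration_id Integer 1..3.
#' @return Numeric multiplier(s) on the signed 2010 rate.
#' @export
tier_multiplier <- function(tier, migration_id) {
  .check_flag_in(migration_id, "migration_id", 1:3)
  if (any(!tier %in% .TIERS)) {
    abort_validation("unknown tier label")
  }
  tab <- rbind(
    `1` = c(T1 = 2.00, NT1 = 1.75, T2 = 1.50, T3 = 0.25),
    `2` = c(T1 = 1.50, NT1 = 1.25, T2 = 1.00, T3 = 0.75),
    `3` = c(T1 = 1.00, NT1 = 1.00, T2 = 1.00, T3 = 1.00)
  )
  unname(tab[migration_id, tier])
}

#' Settlement-reform scale factor for city migration by population size
#'
#' The labor-mobility reform reduces the migration scale of small cities
#' (population below 3 million) by 50% before 2020 and 90% from 2020 on,
#' and of middle-sized cities (3-5 million) by 50% before 2020 and 75%
#' from 2020 on.  Larger cities are unaffected.  The size class is
#' evaluated from the previous year's total city population, re-checked
#' annually.
#'
#' @param population Previous-year total city population, persons
#'   (vectorized).
#' @param year Calendar year the factor applies to.
#' @return Multiplicative factor(s) in `(0, 1]`.
#' @export
size_policy_factor <- function(population, year) {
  before <- year < .MIG_PIVOT_YEAR
  ifelse(population < 3e6, ifelse(before, 0.5, 0.1),
         ifelse(population < 5e6, ifelse(before, 0.5, 0.25), 1))
}

#' Internal migration rates for a given year under a migration scenario
#'
#' Builds the year's city and provincial net migration rate schedules from
#' the 2010 baseline rates: (1) the scenario multiplier ([tier_multiplier()]
#' per city, [region_multiplier()] per province) defines the 2020 rate;
#' (2) rates interpolate linearly from the 2010 value to that 2020 value,
#' then linearly down to exactly 0 at 2035, and stay 0 afterwards;
#' (3) the settlement-reform [size_policy_factor()] multiplies city rates;
#' (4) a city at or above its population ceiling (previous-year total) gets
#' rate 0 for the year, overriding everything else.
#'
#' @param rates Baseline (2010) [rate_set()].
#' @param geo A [geo_hierarchy()].
#' @param migration_id Integer 1..3.
#' @param year Calendar year >= 2010.
#' @param prev A [population_state()] for the previous year (supplies the
#'   totals for the size policy and ceiling checks).
#' @return A list with tibbles `city_mig` and `prov_mig` (columns as in
#'   [rate_set()]).
#' @export
migration_rate_at <- function(rates, geo, migration_id, year, prev) {
  .check_flag_in(migration_id, "migration_id", 1:3)
  year <- .check_scalar_number(year, "year", min = 2010)
  rm <- .rates_to_mats(rates, geo)
  prev_tot <- .state_to_mats(prev, geo)
  totals <- rowSums(prev_tot$M) + rowSums(prev_tot$F)
  out <- .mig_rates_core(rm, geo, migration_id, year, totals)
  to_tib <- function(mats, units, unit_col) {
    purrr::map_dfr(.SEXES, function(s) {
      m <- mats[[s]]
      tibble::tibble(
        "{unit_col}" := rep(units, times = length(.AGES)),
        sex = s,
        age = rep(.AGES, each = length(units)),
        rate = as.numeric(m)
      )
    }) |>
      dplyr::arrange(.data[[unit_col]], .data$sex, .data$age)
  }
  list(city_mig = to_tib(out$cmig, geo$cities$city, "city"),
       prov_mig = to_tib(out$pmig, geo$provinces$province, "province"))
}

# Matrix core shared with the engine.  `prev_city_totals` is a vector of
# previous-year total population per city (geo order).
.mig_rates_core <- function(rm, geo, migration_id, year, prev_city_totals) {
  # temporal shape: multiplier path m(t) applied to the signed 2010 rate
  path_factor <- function(mult2020) {
    if (year <= .MIG_PIVOT_YEAR) {
      1 + (mult2020 - 1) * (year - 2010) / (.MIG_PIVOT_YEAR - 2010)
    } else if (year < .MIG_ZERO_YEAR) {
      mult2020 * (.MIG_ZERO_YEAR - year) / (.MIG_ZERO_YEAR - .MIG_PIVOT_YEAR)
    } else {
      mult2020 * 0
    }
  }
  tier_m <- tier_multiplier(geo$cities$tier, migration_id)
  reg <- geo$provinces$region
  reg_m <- region_multiplier(reg, migration_id)
  city_f <- path_factor(tier_m)
  prov_f <- path_factor(reg_m)
  # policy overlays (cities only)
  city_f <- city_f * size_policy_factor(prev_city_totals, year)
  ceil <- geo$cities$ceiling
  at_ceiling <- !is.na(ceil) & prev_city_totals >= ceil
  city_f[at_ceiling] <- 0
  list(
    cmig = lapply(rm$cmig, function(m) m * city_f),
    pmig = lapply(rm$pmig, function(m) m * prov_f),
    at_ceiling = geo$cities$city[at_ceiling]
  )
}

# ---- scenario spec ----------------------------------------------------------

#' Build a full scenario specification
#'
#' Combines one fertility scenario (1..5) and one migration scenario (1..3)
#' into a `scenario_spec` carrying every derived annual parameter path:
#' TFR, sex ratio at birth, international migration rate, the 2020
#' migration multipliers, the 2035 migration-zero year and the
#' settlement-policy factors.
#'
#' @param fertility_id Integer 1..5.
#' @param migration_id Integer 1..3.
#' @param baseline_srb Sex ratio at birth in 2010 (see [srb_path()]).
#' @param baseline_year First projection year (default 2010).
#' @param end_year Last projection year (default and maximum 2100).
#' @return An object of class `scenario_spec`.
#' @examples
#' spec <- scenario_spec(2, 3)  # stable fertility, stable migration (BAU)
#' spec
#' @export
scenario_spec <- function(fertility_id, migration_id, baseline_srb = 1.18,
                          baseline_year = 2010, end_year = 2100) {
  .check_flag_in(fertility_id, "fertility_id", 1:5)
  .check_flag_in(migration_id, "migration_id", 1:3)
  if (end_year > 2100 || end_year < baseline_year) {
    abort_validation("`end_year` must lie in [baseline_year, 2100]")
  }
  years <- seq.int(baseline_year, end_year)
  structure(list(
    fertility_id = as.integer(fertility_id),
    migration_id = as.integer(migration_id),
    baseline_year = as.integer(baseline_year),
    end_year = as.integer(end_year),
    baseline_srb = baseline_srb,
    years = years,
    tfr = setNames(tfr_path(fertility_id, years), years),
    srb = setNames(srb_path(years, baseline_srb), years),
    netgim = setNames(netgim_path(years), years),
    mig_zero_year = .MIG_ZERO_YEAR
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec: fertility %d, migration %d (SSPFer%d_SSPMigr%d), %d-%d>\n",
    x$fertility_id, x$migration_id, x$fertility_id, x$migration_id,
    x$baseline_year, x$end_year))
  invisible(x)
}

#' Export all parameter paths of a scenario as a tidy table
#'
#' @param spec A [scenario_spec()].
#' @return Tibble with columns `year`, `parameter`, `unit`, `value`, ready
#'   for audit or CSV export.
#' @export
scenario_paths <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  dplyr::bind_rows(
    tibble::tibble(year = spec$years, parameter = "tfr",
                   unit = "births per woman", value = unname(spec$tfr)),
    tibble::tibble(year = spec$years, parameter = "srb",
                   unit = "male per female births", value = unname(spec$srb)),
    tibble::tibble(year = spec$years, parameter = "netgim",
                   unit = "fraction per year", value = unname(spec$netgim))
  )
}

.scenario_label <- function(spec) {
  sprintf("SSPFer%d_SSPMigr%d", spec$fertility_id, spec$migration_id)
}
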