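# Seeded synthetic baselines: geography, stable-population pyramids, rate
# schedules with the statistical structure the projection model assumes,
# and a pseudo-census "truth" for exercising the validation module.

#' Configuration for the synthetic-baseline generator
#'
#' Defaults describe a desk-scale system resembling the modelled country in
#' 2010: total fertility 1.5 births per woman, life expectancy 72.4 (male) /
#' 77.4 (female) years, sex ratio at birth 1.18, provincial net migration on
#' the order of a few per thousand per year, and a tier mix dominated by
#' ordinary (T3) cities.
#'
#' @param n_provinces Number of provinces (>= 1).
#' @param cities_per_province Cities in each province (>= 1).
#' @param tier_mix Proportions over tiers `T1`, `NT1`, `T2`, `T3`; must sum
#'   to 1.  Cities are allocated by largest remainder, then shuffled.
#' @param east_fraction Proportion of provinces labeled `east`
#'   (gain region); the rest are `middle_west` (loss region).
#' @param total_population Total persons across all cities.
#' @param baseline_tfr Baseline city TFR, births per woman.
#' @param baseline_e0 Named vector `c(M = , F = )` of baseline life
#'   expectancies in years.
#' @param baseline_srb Sex ratio at birth in the baseline year.
#' @param mig_rate_scale Typical magnitude of provincial net migration
#'   rates (fraction per year).
#' @param baseline_year Calendar year of the baseline (default 2010).
#' @param seed Integer master seed; all generator randomness derives from
#'   it through fixed per-component substreams.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_provinces = 5, cities_per_province = 4,
                         tier_mix = c(T1 = 0.05, NT1 = 0.10, T2 = 0.20, T3 = 0.65),
                         east_fraction = 0.4, total_population = 2e7,
                         baseline_tfr = 1.5,
                         baseline_e0 = c(M = 72.4, F = 77.4),
                         baseline_srb = 1.18, mig_rate_scale = 0.004,
                         baseline_year = 2010, seed = 1L) {
  if (n_provinces < 1) abort_validation("`n_provinces` must be >= 1")
  if (cities_per_province < 1) {
    abort_validation("`cities_per_province` must be >= 1")
  }
  tier_mix <- tier_mix[.TIERS]
  if (anyNA(tier_mix) || any(tier_mix < 0) ||
      abs(sum(tier_mix) - 1) > 1e-8) {
    abort_validation("`tier_mix` must be proportions over T1,NT1,T2,T3 summing to 1")
  }
  .check_scalar_number(east_fraction, "east_fraction", min = 0, max = 1)
  .check_scalar_number(total_population, "total_population", min = 1)
  .check_scalar_number(baseline_tfr, "baseline_tfr", min = 0)
  if (!all(c("M", "F") %in% names(baseline_e0))) {
    abort_validation("`baseline_e0` must be a named vector with M and F")
  }
  structure(list(
    n_provinces = as.integer(n_provinces),
    cities_per_province = as.integer(cities_per_province),
    tier_mix = tier_mix, east_fraction = east_fraction,
    total_population = total_population, baseline_tfr = baseline_tfr,
    baseline_e0 = baseline_e0[c("M", "F")], baseline_srb = baseline_srb,
    mig_rate_scale = mig_rate_scale,
    baseline_year = as.integer(baseline_year), seed = as.integer(seed)
  ), class = "synth_config")
}

#' Read a synthetic-generator configuration from a YAML file
#'
#' Keys mirror the arguments of [synth_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort_validation(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  # YAML 1.1 floats like 1.0e6 (no signed exponent) arrive as strings
  num_keys <- c("n_provinces", "cities_per_province", "east_fraction",
                "total_population", "baseline_tfr", "baseline_srb",
                "mig_rate_scale", "baseline_year", "seed")
  for (k in intersect(names(y), num_keys)) y[[k]] <- as.numeric(y[[k]])
  for (k in intersect(names(y), c("tier_mix", "baseline_e0"))) {
    v <- unlist(y[[k]])
    y[[k]] <- setNames(as.numeric(v), names(v))
  }
  do.call(synth_config, y)
}

#' Generate a synthetic geographic hierarchy
#'
#' Provinces get region labels with exactly `round(east_fraction *
#' n_provinces)` eastern provinces (at least one of each region when
#' `n_provinces >= 2`); tiers are allocated across all cities by largest
#' remainder of `tier_mix` and assigned by a seeded shuffle.  Tier-1 cities
#' receive a population ceiling of 1.2x their expected baseline population.
#' Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A [geo_hierarchy()]; the expected city population shares used by
#'   [make_baseline()] are attached as attribute `size_share`.
#' @export
make_geo <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(.substream_seed(config$seed, 101L), {
    np <- config$n_provinces
    provs <- sprintf("P%02d", seq_len(np))
    n_east <- round(config$east_fraction * np)
    if (np >= 2) n_east <- min(max(n_east, 1L), np - 1L)
    region <- rep("middle_west", np)
    region[sample.int(np, n_east)] <- "east"
    nc <- np * config$cities_per_province
    cities <- tibble::tibble(
      city = sprintf("%s_C%02d", rep(provs, each = config$cities_per_province),
                     rep(seq_len(config$cities_per_province), times = np)),
      province = rep(provs, each = config$cities_per_province)
    )
    # largest-remainder tier allocation, shuffled assignment
    raw <- config$tier_mix * nc
    cnt <- floor(raw)
    left <- nc - sum(cnt)
    if (left > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
    }
    tiers <- rep(.TIERS, times = cnt)
    cities$tier <- tiers[sample.int(nc)]
    # expected city size shares: larger for higher tiers, lognormal spread
    tier_w <- c(T1 = 8, NT1 = 4, T2 = 2, T3 = 1)
    w <- tier_w[cities$tier] * rlnorm(nc, 0, 0.3)
    share <- w / sum(w)
    cities$ceiling <- ifelse(
      cities$tier == "T1",
      round(1.2 * config$total_population * share), NA_real_)
    geo <- geo_hierarchy(cities,
                         tibble::tibble(province = provs, region = region))
    attr(geo, "size_share") <- setNames(share, cities$city)
    geo
  })
}

# Gompertz-style mortality schedule: hazard a*exp(b*(x + 0.5)) evaluated at
# midpoints, converted to annual death probabilities.
.gompertz_qx <- function(alpha, beta) {
  mu <- alpha * exp(beta * (.AGES + 0.5))
  pmin(1, 1 - exp(-mu))
}

# Calibrate alpha so that life expectancy hits `target` (bisection; e0 is
# decreasing in alpha).
.calibrate_gompertz <- function(target, beta) {
  f <- function(a) life_expectancy(.gompertz_qx(a, beta)) - target
  lo <- 1e-9; hi <- 0.05
  for (i in 1:100) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < 0.005) return(mid)
  }
  sqrt(lo * hi)
}

# Unimodal fertility schedule over ages 15..49, peaking in the mid-20s.
.asfr_shape <- function() {
  s <- dgamma(.FERT_AGES - 14, shape = 5, rate = 0.33)
  s / sum(s)
}

#' Generate a synthetic baseline population and rate set
#'
#' Mortality follows a Gompertz-style hazard per city and sex, calibrated
#' so each city's life expectancy sits near `baseline_e0` (small seeded
#' city-level jitter).  Fertility is a unimodal schedule over ages 15-49
#' scaled so each city's TFR is within about 1% of `baseline_tfr`.  The age
#' pyramid of every city is the stable-age distribution implied by its own
#' mortality and fertility (Lotka growth rate), with multiplicative noise,
#' so the baseline carries no artificial cohort waves.  Provincial net
#' migration rates are positive in the east and negative in the
#' middle-west, follow a young-adult age profile, and are scaled so the
#' national person-weighted sum of provincial flows is approximately zero;
#' city rates vary around their provincial value.  Deterministic given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @param geo The [geo_hierarchy()] from [make_geo()] (its `size_share`
#'   attribute fixes the city size distribution; equal shares are used if
#'   absent).
#' @return A list with elements `state` (a [population_state()]) and
#'   `rates` (a [rate_set()]).
#' @export
make_baseline <- function(config, geo) {
  stopifnot(inherits(config, "synth_config"), inherits(geo, "geo_hierarchy"))
  cities <- geo$cities$city
  nc <- length(cities)
  if (nc != config$n_provinces * config$cities_per_province) {
    abort_validation("`geo` does not match `config` (city count differs)")
  }
  share <- attr(geo, "size_share")
  if (is.null(share)) share <- setNames(rep(1 / nc, nc), cities)
  share <- share[cities]

  withr::with_seed(.substream_seed(config$seed, 202L), {
    beta <- c(M = 0.095, F = 0.105)
    e0_jit <- matrix(pmax(pmin(rnorm(nc * 2, 0, 0.12), 0.35), -0.35),
                     nrow = nc, dimnames = list(cities, .SEXES))
    qx <- list()
    for (s in .SEXES) {
      m <- matrix(0, nrow = nc, ncol = length(.AGES),
                  dimnames = list(cities, .AGE_LABELS))
      for (i in seq_len(nc)) {
        a <- .calibrate_gompertz(config$baseline_e0[[s]] + e0_jit[i, s],
                                 beta[[s]])
        m[i, ] <- .gompertz_qx(a, beta[[s]])
      }
      qx[[s]] <- m
    }
    shape <- .asfr_shape()
    tfr_city <- config$baseline_tfr * runif(nc, 0.995, 1.005)
    asfr_m <- outer(tfr_city, shape)
    dimnames(asfr_m) <- list(cities, as.character(.FERT_AGES))

    # stable-age pyramid per city from its own schedules
    srb <- config$baseline_srb
    bf <- 1 / (1 + srb)
    pyr <- list(M = matrix(0, nc, length(.AGES), dimnames = list(cities, .AGE_LABELS)),
                F = matrix(0, nc, length(.AGES), dimnames = list(cities, .AGE_LABELS)))
    for (i in seq_len(nc)) {
      ltF <- .life_table(qx$F[i, ])
      ltM <- .life_table(qx$M[i, ])
      LF <- ltF$Lx; LM <- ltM$Lx
      LF[!is.finite(LF)] <- 0; LM[!is.finite(LM)] <- 0
      lotka <- function(r) {
        sum(exp(-r * (.FERT_AGES + 0.5)) * LF[.FERT_AGES + 1L] *
              asfr_m[i, ] * bf) - 1
      }
      r <- tryCatch(uniroot(lotka, c(-0.08, 0.08), tol = 1e-10)$root,
                    error = function(e) 0)
      wF <- exp(-r * (.AGES + 0.5)) * LF
      wM <- srb * exp(-r * (.AGES + 0.5)) * LM
      noise <- exp(rnorm(2L * length(.AGES), 0, 0.02))
      wF <- wF * noise[seq_along(.AGES)]
      wM <- wM * noise[length(.AGES) + seq_along(.AGES)]
      tot_i <- config$total_population * share[i]
      pyr$F[i, ] <- tot_i * wF / (sum(wF) + sum(wM))
      pyr$M[i, ] <- tot_i * wM / (sum(wF) + sum(wM))
    }

    # migration: young-adult profile, east gains / middle-west losses,
    # person-weighted provincial flows summing to ~0 nationally
    prof <- dnorm(.AGES, 25, 9)
    pop_age <- colSums(pyr$M) + colSums(pyr$F)
    prof <- prof / (sum(pop_age * prof) / sum(pop_age))
    provs <- geo$provinces$province
    region <- geo$provinces$region
    sgn <- ifelse(region == "east", 1, -1)
    mag <- config$mig_rate_scale * runif(length(provs), 0.6, 1.4)
    scalar_p <- sgn * mag
    pidx <- .prov_index(geo)
    prov_pop_age <- rowsum(pyr$M + pyr$F, pidx, reorder = TRUE)
    Wp <- as.numeric(prov_pop_age %*% prof)
    S_pos <- sum(pmax(Wp * scalar_p, 0))
    S_neg <- -sum(pmin(Wp * scalar_p, 0))
    if (S_pos > 0 && S_neg > 0) {
      scalar_p[scalar_p < 0] <- scalar_p[scalar_p < 0] * (S_pos / S_neg)
    }
    scalar_c <- scalar_p[pidx] * rnorm(nc, 1, 0.3)
    prov_mig <- tidyr::expand_grid(province = provs, sex = .SEXES, age = .AGES)
    prov_mig$rate <- pmax(scalar_p[match(prov_mig$province, provs)] *
                            prof[prov_mig$age + 1L], -0.5)
    city_mig <- tidyr::expand_grid(city = cities, sex = .SEXES, age = .AGES)
    city_mig$rate <- pmax(scalar_c[match(city_mig$city, cities)] *
                            prof[city_mig$age + 1L], -0.5)

    asfr_tab <- tidyr::expand_grid(city = cities, age = .FERT_AGES)
    asfr_tab$rate <- asfr_m[cbind(match(asfr_tab$city, cities),
                                  match(asfr_tab$age, .FERT_AGES))]
    asmr_tab <- tidyr::expand_grid(city = cities, sex = .SEXES, age = .AGES)
    asmr_tab$rate <- ifelse(asmr_tab$sex == "M",
                            qx$M[cbind(match(asmr_tab$city, cities),
                                       asmr_tab$age + 1L)],
                            qx$F[cbind(match(asmr_tab$city, cities),
                                       asmr_tab$age + 1L)])

    state <- .mats_to_state(pyr, config$baseline_year)
    rates <- rate_set(asfr = asfr_tab, asmr = asmr_tab,
                      city_mig = city_mig, prov_mig = prov_mig)
    list(state = state, rates = rates)
  })
}

#' Generate a pseudo-census "truth" by perturbing a projection
#'
#' Projects the baseline to `truth_year` under the given scenario, then
#' multiplies every city's counts by an independent lognormal factor with
#' log-scale standard deviation `perturb_sd` (one factor per city, applied
#' uniformly over sex and age).  With `perturb_sd = 0` the projection
#' itself is returned, so every projection error against it is zero.
#'
#' @param baseline A list with `state` and `rates` as returned by
#'   [make_baseline()].
#' @param geo A [geo_hierarchy()].
#' @param scenario A [scenario_spec()] (its fertility/migration ids are
#'   used).
#' @param truth_year Year of the pseudo-census, after the baseline year.
#' @param perturb_sd Lognormal sigma of the city-level factors (>= 0).
#' @param seed Integer seed for the perturbation draw.
#' @return A [population_state()] for `truth_year`.
#' @export
make_pseudo_census <- function(baseline, geo, scenario, truth_year,
                               perturb_sd = 0.05, seed = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"))
  y0 <- tibble::as_tibble(baseline$state)$year[1]
  if (truth_year <= y0) {
    abort_validation("`truth_year` must be after the baseline year")
  }
  if (perturb_sd < 0) abort_validation("`perturb_sd` must be >= 0")
  res <- project(baseline$state, baseline$rates, geo,
                 scenario$fertility_id, scenario$migration_id,
                 end_year = truth_year, baseline_srb = scenario$baseline_srb)
  st <- get_state(res, truth_year)
  if (perturb_sd == 0) return(st)
  cities <- geo$cities$city
  fac <- withr::with_seed(.substream_seed(seed, 303L),
                          rlnorm(length(cities), 0, perturb_sd))
  out <- tibble::as_tibble(st)
  out$population <- out$population * fac[match(out$city, cities)]
  population_state(out)
}
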