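# Shared fixtures, built in code.  The default synthetic baseline is
# memoised because several files exercise it.

toy_geo <- function(ceiling_a = NA) {
  load_geo(data.frame(
    city = c("A1", "A2", "B1", "B2"),
    province = c("PE", "PE", "PW", "PW"),
    region = c("east", "east", "middle_west", "middle_west"),
    tier = c("T1", "T3", "T2", "T3"),
    ceiling = c(ceiling_a, NA, NA, NA)
  ))
}

# uniform state: same count in every (city, sex, age) cell
flat_state <- function(geo, per_cell = 100, year = 2010) {
  population_state(expand.grid(
    year = year, city = geo$cities$city, sex = c("M", "F"), age = 0:100,
    population = per_cell, stringsAsFactors = FALSE))
}

zero_rates <- function(geo) {
  rate_set(
    asfr = expand.grid(city = geo$cities$city, age = 15:49, rate = 0,
                       stringsAsFactors = FALSE),
    asmr = expand.grid(city = geo$cities$city, sex = c("M", "F"),
                       age = 0:100, rate = 0, stringsAsFactors = FALSE),
    city_mig = expand.grid(city = geo$cities$city, sex = c("M", "F"),
                           age = 0:100, rate = 0, stringsAsFactors = FALSE),
    prov_mig = expand.grid(province = geo$provinces$province,
                           sex = c("M", "F"), age = 0:100, rate = 0,
                           stringsAsFactors = FALSE))
}

# constant-rate rate_set for single-city Leslie comparisons
const_rates <- function(geo, asfr_fun, qx_m, qx_f) {
  asfr <- expand.grid(city = geo$cities$city, age = 15:49,
                      stringsAsFactors = FALSE)
  asfr$rate <- asfr_fun(asfr$age)
  asmr <- expand.grid(city = geo$cities$city, sex = c("M", "F"),
                      age = 0:100, stringsAsFactors = FALSE)
  asmr$rate <- ifelse(asmr$sex == "M", qx_m[asmr$age + 1], qx_f[asmr$age + 1])
  zr <- zero_rates(geo)
  rate_set(asfr = asfr, asmr = asmr,
           city_mig = zr$city_mig, prov_mig = zr$prov_mig)
}

.fx <- new.env()

fx_baseline <- function() {
  if (is.null(.fx$base)) {
    cfg <- synth_config(seed = 42L)
    geo <- make_geo(cfg)
    .fx$cfg <- cfg
    .fx$geo <- geo
    .fx$base <- make_baseline(cfg, geo)
  }
  list(cfg = .fx$cfg, geo = .fx$geo, state = .fx$base$state,
       rates = .fx$base$rates)
}
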