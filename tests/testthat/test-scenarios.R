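test_that("TFR paths hit every anchor and stay continuous", {
  # shared history
  for (f in 1:5) {
    expect_equal(tfr_path(f, 2010), 1.5)
    expect_equal(tfr_path(f, 2013), 1.50)
    expect_equal(tfr_path(f, 2017), 1.88)
    expect_equal(tfr_path(f, 2020), 1.30)
  }
  # scenario targets
  expect_equal(tfr_path(1, c(2050, 2100)), c(0.7, 0.9))
  expect_equal(tfr_path(2, c(2050, 2100)), c(1.3, 1.3))
  expect_equal(tfr_path(3, c(2050, 2100)), c(1.5, 1.8))
  expect_equal(tfr_path(4, c(2050, 2100)), c(1.8, 1.8))
  expect_equal(tfr_path(5, c(2050, 2100)), c(1.8, 2.1))
  # constant segment between equal anchors; constant after 2100
  expect_equal(tfr_path(2, 2035), 1.3)
  expect_equal(tfr_path(5, 2130), 2.1)
  # continuity: adjacent-year jumps bounded by the steepest anchor slope
  for (f in 1:5) {
    v <- tfr_path(f, 2010:2100)
    expect_lte(max(abs(diff(v))), (1.88 - 1.30) / 3 + 1e-12)
  }
  expect_error(tfr_path(6, 2050), class = "citypop_validation_error")
  expect_error(tfr_path(3, 2005), class = "citypop_validation_error")
})

test_that("SRB path reaches 1.07 in 2050 and stays there", {
  expect_equal(srb_path(2050), 1.07)
  expect_equal(srb_path(2080), 1.07)
  expect_equal(srb_path(2010, baseline_srb = 1.18), 1.18)
  expect_equal(srb_path(2030, baseline_srb = 1.18), (1.18 + 1.07) / 2)
})

test_that("birth shares follow Bm = srb/(1+srb) and sum to one", {
  sh <- birth_shares(1.0)
  expect_equal(sh$male, 0.5)
  expect_equal(sh$female, 0.5)
  srbs <- runif(25, 0.8, 1.3)
  sh <- birth_shares(srbs)
  expect_equal(sh$male + sh$female, rep(1, 25))
  expect_equal(sh$male / sh$female, srbs)
})

test_that("international migration is -0.3015 per mille then decays to zero", {
  expect_equal(netgim_path(2020), -3.015e-4)
  expect_equal(netgim_path(2050), -3.015e-4)
  expect_equal(netgim_path(2075), -1.5075e-4)
  expect_equal(netgim_path(2100), 0)
  expect_error(netgim_path(2105), class = "citypop_validation_error")
})

test_that("ASFR scaling preserves shapes and hits the weighted target", {
  fx <- fx_baseline()
  base_tfr <- national_tfr(fx$rates, fx$state)

  unchanged <- scale_asfr(fx$rates, base_tfr, fx$state)
  expect_equal(unchanged$rate, fx$rates$asfr$rate)

  doubled <- scale_asfr(fx$rates, 2 * base_tfr, fx$state)
  expect_equal(doubled$rate, 2 * fx$rates$asfr$rate)

  scaled <- scale_asfr(fx$rates, 1.8, fx$state)
  expect_equal(national_tfr(scaled, fx$state), 1.8, tolerance = 1e-12)
})

test_that("life-expectancy targets follow the ratio-weighted decade rule", {
  expect_equal(le_target(2060, 70, 70), 75)
  expect_equal(le_target(2010, 81.3, 76), 81.3)
  expect_equal(le_target(2110, 63, 70), 63 + 10 * 0.9)
})

test_that("migration multipliers reproduce the scenario tables", {
  expect_equal(region_multiplier("east", 1), 1.5)
  expect_equal(region_multiplier("middle_west", 1), 1.5)
  expect_equal(region_multiplier("east", 2), 1.25)
  expect_equal(region_multiplier("east", 3), 1)
  expect_equal(tier_multiplier(c("T1", "NT1", "T2", "T3"), 1),
               c(2, 1.75, 1.5, 0.25))
  expect_equal(tier_multiplier(c("T1", "NT1", "T2", "T3"), 2),
               c(1.5, 1.25, 1, 0.75))
  expect_equal(tier_multiplier(c("T1", "NT1", "T2", "T3"), 3),
               c(1, 1, 1, 1))
  expect_error(tier_multiplier("T1", 4), class = "citypop_validation_error")
})

test_that("settlement-reform factors match the published reductions", {
  expect_equal(size_policy_factor(2e6, 2015), 0.5)   # small, before 2020
  expect_equal(size_policy_factor(2e6, 2025), 0.1)   # small, 90% cut after
  expect_equal(size_policy_factor(4e6, 2015), 0.5)   # middle, before 2020
  expect_equal(size_policy_factor(4e6, 2025), 0.25)  # middle, 75% cut after
  expect_equal(size_policy_factor(8e6, 2025), 1)     # large: unaffected
})

test_that("year-specific migration rates follow the interpolate-then-fade path", {
  geo <- toy_geo()
  st <- flat_state(geo, per_cell = 5e6 / 202)  # every city ~5M: no size policy
  cm <- expand.grid(city = geo$cities$city, sex = c("M", "F"), age = 0:100,
                    stringsAsFactors = FALSE)
  cm$rate <- 0.01
  pm <- expand.grid(province = geo$provinces$province, sex = c("M", "F"),
                    age = 0:100, stringsAsFactors = FALSE)
  pm$rate <- ifelse(pm$province == "PE", 0.004, -0.004)
  rates <- rate_set(asfr = zero_rates(geo)$asfr, asmr = zero_rates(geo)$asmr,
                    city_mig = cm, prov_mig = pm)

  # T1 city, scenario 1, 2020: twice its 2010 rate
  r2020 <- migration_rate_at(rates, geo, 1, 2020, st)
  a1 <- subset(r2020$city_mig, city == "A1" & sex == "M" & age == 30)$rate
  expect_equal(a1, 0.02)
  # scenario 3 leaves 2010 rates unchanged in 2020
  r3 <- migration_rate_at(rates, geo, 3, 2020, st)
  expect_equal(subset(r3$city_mig, city == "A1" & sex == "M" & age == 30)$rate,
               0.01)
  # provinces: scenario 1 amplifies both signs by 50% at the 2020 pivot
  expect_equal(subset(r2020$prov_mig, province == "PE" & sex == "F" &
                        age == 20)$rate, 0.006)
  expect_equal(subset(r2020$prov_mig, province == "PW" & sex == "F" &
                        age == 20)$rate, -0.006)
  # midway through the fade, 2030 under scenario 3: 5/15 of the 2020 level
  r2030 <- migration_rate_at(rates, geo, 3, 2030, st)
  expect_equal(subset(r2030$city_mig, city == "A1" & sex == "M" &
                        age == 30)$rate, 0.01 * 5 / 15)
  # zero from 2035 in every scenario, city and province alike
  for (m in 1:3) {
    r2035 <- migration_rate_at(rates, geo, m, 2035, st)
    expect_true(all(r2035$city_mig$rate == 0))
    expect_true(all(r2035$prov_mig$rate == 0))
  }
})

test_that("a city at its ceiling gets migration rate zero that year", {
  geo <- toy_geo(ceiling_a = 9e6)
  st <- flat_state(geo, per_cell = 5e7 / 202)  # every city ~50M > ceiling
  cm <- expand.grid(city = geo$cities$city, sex = c("M", "F"), age = 0:100,
                    stringsAsFactors = FALSE)
  cm$rate <- 0.01
  rates <- rate_set(asfr = zero_rates(geo)$asfr, asmr = zero_rates(geo)$asmr,
                    city_mig = cm, prov_mig = zero_rates(geo)$prov_mig)
  r <- migration_rate_at(rates, geo, 1, 2020, st)
  expect_true(all(subset(r$city_mig, city == "A1")$rate == 0))
  expect_true(all(subset(r$city_mig, city == "A2")$rate != 0))
})

test_that("scenario specs validate ids and expose tidy paths", {
  expect_error(scenario_spec(9, 1), class = "citypop_validation_error")
  expect_error(scenario_spec(1, 0), class = "citypop_validation_error")
  spec <- scenario_spec(2, 3)
  expect_equal(unname(spec$tfr[as.character(2050)]), 1.3)
  p <- scenario_paths(spec)
  expect_setequal(unique(p$parameter), c("tfr", "srb", "netgim"))
  expect_equal(p$value[p$parameter == "srb" & p$year == 2050], 1.07)
})
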