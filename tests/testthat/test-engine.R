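test_that("births follow the fertility sum and the sex split", {
  st <- population_state(data.frame(year = 2010, city = "A", sex = "F",
                                    age = 25, population = 1000))
  b <- births(st, data.frame(city = "A", age = 25, rate = 0.1), srb = 1.07)
  expect_equal(sum(b$births), 100)
  expect_equal(b$births[b$sex == "M"], 100 * 1.07 / 2.07)
  expect_equal(b$births[b$sex == "F"], 100 / 2.07)

  # zero fertility: zero births
  b0 <- births(st, data.frame(city = "A", age = 25, rate = 0), srb = 1.07)
  expect_equal(sum(b0$births), 0)

  # male + female equals the total for random inputs
  set.seed(3)
  for (i in 1:10) {
    pop <- population_state(data.frame(
      year = 2010, city = "A", sex = "F", age = 15:49,
      population = runif(35, 0, 1e4)))
    asfr <- data.frame(city = "A", age = 15:49, rate = runif(35, 0, 0.2))
    srb <- runif(1, 0.9, 1.3)
    b <- births(pop, asfr, srb)
    d <- tibble::as_tibble(pop)
    manual <- sum(d$population[d$sex == "F" & d$age %in% 15:49] *
                    asfr$rate[match(15:49, asfr$age)])
    expect_equal(sum(b$births), manual)
    expect_equal(b$births[b$sex == "M"] / b$births[b$sex == "F"], srb)
  }
})

test_that("cohort advancement shifts, pools 100+ and applies the factors", {
  geo1 <- load_geo(data.frame(city = "A", province = "P", region = "east",
                              tier = "T3"))
  st <- flat_state(geo1, per_cell = 10)
  zr <- zero_rates(geo1)

  # no mortality, no flows: pure shift conserves persons
  nxt <- advance_cohorts(st, zr$asmr, flows = NULL, netgim = 0)
  expect_equal(sum(nxt$population), sum(st$population))
  d <- tibble::as_tibble(nxt)
  expect_equal(d$population[d$sex == "M" & d$age == 0], 0)
  expect_equal(d$population[d$sex == "M" & d$age == 100], 20)  # pooled 99 + 100+

  # q = 0.1, flow +5: 100 * 0.9 + 5 = 95
  st2 <- population_state(data.frame(year = 2010, city = "A", sex = "M",
                                     age = 30, population = 100))
  asmr <- expand.grid(city = "A", sex = c("M", "F"), age = 0:100,
                      stringsAsFactors = FALSE)
  asmr$rate <- 0.1
  fl <- migration_flows(
    city_net = data.frame(city = "A", sex = "M", age = 30, net = 5),
    prov_net = data.frame(province = "P", sex = "M", age = 30, net = 0))
  fl$city_net_adj <- tibble::tibble(city = "A", sex = "M", age = 30,
                                    net_adj = 5)
  nxt2 <- advance_cohorts(st2, asmr, fl, netgim = 0)
  d2 <- tibble::as_tibble(nxt2)
  expect_equal(d2$population[d2$sex == "M" & d2$age == 31], 95)

  # with the international factor applied after survival + migration
  nxt3 <- advance_cohorts(st2, asmr, fl, netgim = -3.015e-4)
  d3 <- tibble::as_tibble(nxt3)
  expect_equal(d3$population[d3$sex == "M" & d3$age == 31],
               95 * (1 - 3.015e-4))

  # outflow beyond the cohort clamps at zero and logs the shortfall
  fl$city_net_adj$net_adj <- -200
  nxt4 <- advance_cohorts(st2, asmr, fl, netgim = 0)
  expect_true(all(nxt4$population >= 0))
  expect_equal(attr(nxt4, "shortfall"), 110)
})

test_that("a single closed city reproduces its Leslie matrix over 50 years", {
  geo1 <- load_geo(data.frame(city = "A", province = "P", region = "east",
                              tier = "T3"))
  qx_f <- pmin(1, 1 - exp(-4e-5 * exp(0.105 * (0:100 + 0.5))))
  qx_m <- pmin(1, 1 - exp(-6e-5 * exp(0.097 * (0:100 + 0.5))))
  asfr_fun <- function(a) 1.6 * dgamma(a - 14, 5, 0.33) /
    sum(dgamma(15:49 - 14, 5, 0.33))
  rates <- const_rates(geo1, asfr_fun, qx_m, qx_f)
  srb <- 1.12

  set.seed(21)
  st <- population_state(data.frame(
    year = 2010,
    city = "A",
    sex = rep(c("M", "F"), each = 101),
    age = rep(0:100, 2),
    population = runif(202, 100, 1000)))

  res <- project_constant(st, rates, geo1, end_year = 2060, srb = srb)

  A <- oracle_leslie(setNames(asfr_fun(15:49), 15:49), qx_f, qx_m, srb)
  x <- leslie_vec(st)
  for (yr in 2011:2060) x <- A %*% x
  got <- leslie_vec(get_state(res, 2060))
  expect_lt(max(abs(got - x) / pmax(abs(x), 1e-12)), 1e-9)
})

test_that("mass is conserved and accounted for exactly", {
  fx <- fx_baseline()

  # all rates zero: constant national total across 90 years
  zr <- zero_rates(fx$geo)
  rc <- project_constant(fx$state, zr, fx$geo, end_year = 2100, netgim = 0)
  nat <- subset(rc$summaries, level == "national")
  expect_lt(max(abs(nat$total - nat$total[1])) / nat$total[1], 1e-6)

  # rates on: total(t+1) = total(t) + births - deaths + net international,
  # provided no clamping fired
  res <- project(fx$state, fx$rates, fx$geo, 2, 3, end_year = 2060,
                 baseline_srb = fx$cfg$baseline_srb)
  expect_equal(sum(res$vitals$shortfall), 0)
  nat <- subset(res$summaries, level == "national")
  lhs <- nat$total[-1]
  rhs <- nat$total[-nrow(nat)] + res$vitals$births - res$vitals$deaths +
    res$vitals$net_international
  expect_lt(max(abs(lhs - rhs) / lhs), 1e-9)

  # no negative counts in any emitted state
  expect_true(all(res$counts >= 0))
})

test_that("stepping one year matches the documented composition", {
  fx <- fx_baseline()
  spec <- scenario_spec(2, 3, baseline_srb = fx$cfg$baseline_srb)
  basis <- projection_basis(fx$state, fx$rates, fx$geo)
  st1 <- step_year(fx$state, spec, fx$rates, fx$geo, basis = basis)
  res <- project(fx$state, fx$rates, fx$geo, 2, 3, end_year = 2011,
                 baseline_srb = fx$cfg$baseline_srb)
  expect_equal(as.data.frame(tibble::as_tibble(st1)),
               as.data.frame(tibble::as_tibble(get_state(res, 2011))),
               ignore_attr = TRUE)
  expect_error(step_year(st1, scenario_spec(2, 3, end_year = 2011),
                         fx$rates, fx$geo), "do not cover")
})

test_that("ceilings zero a city's migration in the engine", {
  geo <- toy_geo(ceiling_a = 1e6)  # A1 capped below its current size
  st <- flat_state(geo, per_cell = 2e6 / 202)
  cm <- expand.grid(city = geo$cities$city, sex = c("M", "F"), age = 0:100,
                    stringsAsFactors = FALSE)
  cm$rate <- 0.01
  zr <- zero_rates(geo)
  asmr <- zr$asmr
  rates <- rate_set(asfr = zr$asfr, asmr = asmr, city_mig = cm,
                    prov_mig = zr$prov_mig)
  spec <- scenario_spec(2, 3)
  nxt <- step_year(st, spec, rates, geo)
  expect_true("A1" %in% attr(nxt, "at_ceiling"))
})

test_that("projection bounds and determinism behave", {
  fx <- fx_baseline()
  # end year = baseline year: only the baseline state
  r0 <- project(fx$state, fx$rates, fx$geo, 2, 3, end_year = 2010)
  expect_equal(r0$years, 2010L)
  expect_equal(tibble::as_tibble(get_state(r0, 2010)),
               tibble::as_tibble(fx$state))

  # identical inputs give bit-identical outputs
  r1 <- project(fx$state, fx$rates, fx$geo, 1, 2, end_year = 2025)
  r2 <- project(fx$state, fx$rates, fx$geo, 1, 2, end_year = 2025)
  expect_identical(r1$counts, r2$counts)
})

test_that("with zero migration, city trajectories ignore the geography", {
  fx <- fx_baseline()
  zr <- zero_rates(fx$geo)
  rates_nomig <- rate_set(asfr = fx$rates$asfr, asmr = fx$rates$asmr,
                          city_mig = zr$city_mig, prov_mig = zr$prov_mig)
  res_all <- project(fx$state, rates_nomig, fx$geo, 3, 1, end_year = 2020,
                     baseline_srb = fx$cfg$baseline_srb)

  # same city embedded in a single-city geography
  cty <- fx$geo$cities$city[1]
  geo1 <- geo_hierarchy(fx$geo$cities[1, ], fx$geo$provinces[
    fx$geo$provinces$province == fx$geo$cities$province[1], ])
  st1 <- population_state(subset(tibble::as_tibble(fx$state), city == cty))
  sub_rates <- rate_set(
    asfr = subset(rates_nomig$asfr, city == cty),
    asmr = subset(rates_nomig$asmr, city == cty),
    city_mig = subset(rates_nomig$city_mig, city == cty),
    prov_mig = subset(rates_nomig$prov_mig,
                      province == fx$geo$cities$province[1]))
  basis_all <- projection_basis(fx$state, rates_nomig, fx$geo)
  res_1 <- project(st1, sub_rates, geo1, 3, 1, end_year = 2020,
                   baseline_srb = fx$cfg$baseline_srb, basis = basis_all)
  expect_equal(res_1$counts[cty, , , ], res_all$counts[cty, , , ],
               tolerance = 1e-12)
})
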