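test_that("percentage errors follow their definitions", {
  expect_equal(pe(103, 100), 3.0)
  expect_equal(pe(97, 100), -3.0)
  expect_equal(pe(250, 250), 0.0)
  expect_equal(ape(97, 100), 3.0)
  expect_equal(ape(103, 100), 3.0)
  expect_error(pe(10, 0), class = "citypop_validation_error")
  expect_error(ape(10, -5), class = "citypop_validation_error")

  set.seed(8)
  p <- runif(50, 50, 150)
  a <- runif(50, 50, 150)
  expect_equal(ape(p, a), abs(pe(p, a)))
})

# build a tiny projection whose truth we can distort by hand
toy_projection <- function() {
  geo <- toy_geo()
  st <- flat_state(geo, per_cell = 100)
  zr <- zero_rates(geo)
  project_constant(st, zr, geo, end_year = 2012, netgim = 0)
}

distort <- function(state, factors) {
  d <- tibble::as_tibble(state)
  d$population <- d$population * factors[d$city]
  population_state(d)
}

test_that("hand-set errors give the expected report", {
  res <- toy_projection()
  truth_state <- get_state(res, 2012)
  # projected = truth * (1 + pe/100)  =>  truth = projected / (1 + pe/100)
  pe_set <- c(A1 = 5, A2 = -5, B1 = 15, B2 = 0)
  truth <- distort(truth_state, 1 / (1 + pe_set / 100))
  rep <- error_report(res, truth, toy_geo())

  cities <- subset(rep$units, level == "city")
  expect_equal(setNames(cities$pe, cities$unit), pe_set[cities$unit],
               tolerance = 1e-9)
  m <- subset(rep$means, level == "city")
  expect_equal(m$mean_ape, 6.25)
  expect_equal(m$mean_pe, 3.75)
  expect_equal(subset(rep$threshold_shares, threshold == 10)$share, 0.75)
  # shares are monotone in the threshold
  expect_true(all(diff(rep$threshold_shares$share) >= 0))
})

test_that("a perfect truth yields identically zero errors", {
  res <- toy_projection()
  truth <- get_state(res, 2012)
  rep <- error_report(res, truth, toy_geo())
  expect_true(all(rep$units$pe == 0))
  expect_true(all(rep$units$ape == 0))
  expect_true(all(rep$threshold_shares$share == 1))
  expect_true(all(rep$age_structure$ape == 0))
})

test_that("reports are invariant to city order and obey the triangle bound", {
  res <- toy_projection()
  truth_state <- get_state(res, 2012)
  set.seed(12)
  for (i in 1:5) {
    f <- setNames(exp(rnorm(4, 0, 0.08)), toy_geo()$cities$city)
    truth <- distort(truth_state, f)
    shuffled <- population_state(
      tibble::as_tibble(truth)[sample.int(nrow(truth)), ])
    r1 <- error_report(res, truth, toy_geo())
    r2 <- error_report(res, shuffled, toy_geo())
    expect_equal(r1$units, r2$units)
    expect_true(all(r1$means$mean_ape >= abs(r1$means$mean_pe) - 1e-12))
  }
})

test_that("age-structure errors compare proportions that sum to one", {
  res <- toy_projection()
  truth <- distort(get_state(res, 2012), c(A1 = 1.1, A2 = 0.9, B1 = 1, B2 = 1))
  rep <- error_report(res, truth, toy_geo())
  expect_equal(nrow(rep$age_structure), 16)  # 0-14, 15-19 ... 80-84, 85+
  expect_equal(sum(rep$age_structure$proj_share), 1)
  expect_equal(sum(rep$age_structure$actual_share), 1)
})

test_that("cities missing from the truth are excluded and listed", {
  res <- toy_projection()
  truth <- get_state(res, 2012)
  truth_sub <- population_state(subset(tibble::as_tibble(truth),
                                       city != "B2"))
  rep <- error_report(res, truth_sub, toy_geo())
  expect_equal(rep$excluded_cities, "B2")
  expect_false("B2" %in% rep$units$unit)

  # a zero-truth city is excluded with a warning, not an infinite APE
  z <- tibble::as_tibble(truth)
  z$population[z$city == "A2"] <- 0
  expect_warning(rep2 <- error_report(res, population_state(z), toy_geo()),
                 "zero truth population")
  expect_false("A2" %in% subset(rep2$units, level == "city")$unit)

  # disjoint city sets are an error
  other <- population_state(data.frame(year = 2012, city = "Zed", sex = "M",
                                       age = 0, population = 1))
  expect_error(error_report(res, other, toy_geo()), "no cities")
})

test_that("pseudo-census APE matches its Monte-Carlo expectation", {
  # many cities so the mean is tight; short horizon keeps it cheap
  cfg <- synth_config(n_provinces = 10, cities_per_province = 20,
                      total_population = 5e7, seed = 77L)
  geo <- make_geo(cfg)
  base <- make_baseline(cfg, geo)
  spec <- scenario_spec(2, 3, baseline_srb = cfg$baseline_srb)
  truth <- make_pseudo_census(base, geo, spec, truth_year = 2012,
                              perturb_sd = 0.05, seed = 4L)
  res <- project(base$state, base$rates, geo, 2, 3, end_year = 2012,
                 baseline_srb = cfg$baseline_srb)
  rep <- error_report(res, truth, geo)
  got <- subset(rep$means, level == "city")$mean_ape

  # Monte-Carlo oracle: city APE = |1/f - 1| * 100 with log f ~ N(0, 0.05)
  set.seed(1)
  expected <- mean(abs(1 / rlnorm(2e5, 0, 0.05) - 1)) * 100
  expect_lt(abs(got - expected), 0.7)  # ~3 standard errors for 200 cities
})
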