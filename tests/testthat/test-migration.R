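make_flows <- function(prov_nets, city_nets = NULL, city_provs = NULL,
                       weights = NULL) {
  # single (sex = M, age = 30) slice helpers for hand toys
  prov <- tibble::tibble(province = names(prov_nets), sex = "M", age = 30,
                         net = unname(prov_nets))
  city <- if (is.null(city_nets)) {
    tibble::tibble(city = "c1", sex = "M", age = 30, net = 0)
  } else {
    tibble::tibble(city = names(city_nets), sex = "M", age = 30,
                   net = unname(city_nets))
  }
  migration_flows(city, prov, weights = weights)
}

test_that("flows are population times rate, elementwise", {
  geo <- toy_geo()
  st <- population_state(data.frame(year = 2010, city = "A1", sex = "M",
                                    age = 30, population = 1000))
  cm <- expand.grid(city = geo$cities$city, sex = c("M", "F"), age = 0:100,
                    stringsAsFactors = FALSE)
  cm$rate <- ifelse(cm$city == "A1" & cm$sex == "M" & cm$age == 30, 0.02, 0)
  zr <- zero_rates(geo)
  rates <- rate_set(asfr = zr$asfr, asmr = zr$asmr, city_mig = cm,
                    prov_mig = zr$prov_mig)
  fl <- flows_from_rates(st, rates, geo)
  expect_equal(subset(fl$city_net, city == "A1" & sex == "M" & age == 30)$net,
               20)
  expect_equal(sum(abs(fl$city_net$net)), 20)  # everything else is zero
  expect_true(all(fl$prov_net$net == 0))

  # zero rates annihilate
  fl0 <- flows_from_rates(st, zr, geo)
  expect_true(all(fl0$city_net$net == 0))

  # missing rate is an error
  expect_error(flows_from_rates(st, list(city_mig = cm[cm$city != "A1", ],
                                         prov_mig = zr$prov_mig), geo),
               "missing migration rate")
})

test_that("flow signs equal rate signs wherever population is positive", {
  fx <- fx_baseline()
  fl <- flows_from_rates(fx$state, fx$rates, fx$geo)
  joined <- dplyr::inner_join(
    fl$city_net, fx$rates$city_mig,
    by = c("city", "sex", "age"))
  pop <- tibble::as_tibble(fx$state)
  joined <- dplyr::inner_join(joined, pop, by = c("city", "sex", "age"))
  pos <- joined$population > 0 & joined$rate != 0
  expect_true(all(sign(joined$net[pos]) == sign(joined$rate[pos])))
})

test_that("provincial balancing cuts back only the surplus side", {
  # already balanced: untouched
  fl <- balance_provinces(make_flows(c(P1 = 10, P2 = -10)))
  expect_equal(fl$prov_net_adj$net_adj, c(10, -10))

  # positive surplus scaled by 10/30
  fl <- balance_provinces(make_flows(c(P1 = 30, P2 = -10)))
  expect_equal(fl$prov_net_adj$net_adj, c(10, -10))
  expect_equal(sum(fl$prov_net_adj$net_adj), 0)

  # ratios within the scaled side are preserved
  fl <- balance_provinces(make_flows(c(P1 = 20, P2 = 10, P3 = -15)))
  expect_equal(fl$prov_net_adj$net_adj, c(10, 5, -15))

  # all-zero input passes through
  fl <- balance_provinces(make_flows(c(P1 = 0, P2 = 0)))
  expect_equal(fl$prov_net_adj$net_adj, c(0, 0))
})

test_that("balancing never flips signs, never grows magnitudes, and is idempotent", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n, 0, 50), 2)
    fl <- balance_provinces(make_flows(setNames(x, sprintf("P%02d", seq_len(n)))))
    adj <- fl$prov_net_adj$net_adj
    expect_true(all(sign(adj) == sign(x) | adj == 0))
    expect_true(all(abs(adj) <= abs(x) + 1e-9))
    expect_lt(abs(sum(adj)), 1e-9 * max(1, sum(abs(x))))
    # idempotence
    fl2 <- balance_provinces(make_flows(setNames(adj, sprintf("P%02d", seq_len(n)))))
    expect_equal(fl2$prov_net_adj$net_adj, adj)
    # brute-force oracle on small instances
    if (n <= 4) {
      expect_equal(adj, oracle_cutback(x), tolerance = 1e-9)
    }
  }
})

test_that("city reconciliation matches its provincial targets exactly", {
  geo2 <- load_geo(data.frame(city = c("c1", "c2"), province = "P1",
                              region = "east", tier = "T3"))

  # factor 1 when the city sum already equals the target
  fl <- make_flows(c(P1 = 40), c(c1 = 30, c2 = 10))
  fl <- balance_provinces(fl)
  fl$prov_net_adj$net_adj <- 40  # single province: force the target
  fl <- reconcile_cities(fl, geo2)
  expect_equal(fl$city_net_adj$net_adj, c(30, 10))

  # multiplicative scaling by T/C = 0.5
  fl <- make_flows(c(P1 = 20), c(c1 = 30, c2 = 10))
  fl <- balance_provinces(fl)
  fl$prov_net_adj$net_adj <- 20
  fl <- reconcile_cities(fl, geo2)
  expect_equal(fl$city_net_adj$net_adj, c(15, 5))

  # C = 0 with equal populations: additive split of the discrepancy
  w <- tibble::tibble(city = c("c1", "c2"), sex = "M", age = 30,
                      population = c(500, 500))
  fl <- make_flows(c(P1 = 6), c(c1 = 10, c2 = -10), weights = w)
  fl <- balance_provinces(fl)
  fl$prov_net_adj$net_adj <- 6
  fl <- reconcile_cities(fl, geo2)
  expect_equal(fl$city_net_adj$net_adj, c(13, -7))

  # zero population with a nonzero target cannot be redistributed
  w0 <- tibble::tibble(city = c("c1", "c2"), sex = "M", age = 30,
                       population = c(0, 0))
  fl <- make_flows(c(P1 = 6), c(c1 = 0, c2 = 0), weights = w0)
  fl <- balance_provinces(fl)
  fl$prov_net_adj$net_adj <- 6
  expect_error(reconcile_cities(fl, geo2), "zero population")
})

test_that("the composed balance satisfies both constraints on synthetic instances", {
  set.seed(99)
  for (i in 1:3) {
    np <- sample(3:6, 1)
    cp <- sample(3:5, 1)
    cfg <- synth_config(n_provinces = np, cities_per_province = cp,
                        total_population = 5e6, seed = 1000L + i)
    geo <- make_geo(cfg)
    base <- make_baseline(cfg, geo)
    fl <- apply_migration_balance(base$state, base$rates, geo)
    scale <- sum(abs(fl$prov_net$net)) + 1

    pa <- dplyr::summarise(fl$prov_net_adj,
                           s = sum(.data$net_adj), .by = c("sex", "age"))
    expect_lt(max(abs(pa$s)), 1e-9 * scale)

    ca <- fl$city_net_adj |>
      dplyr::left_join(geo$cities[c("city", "province")], by = "city") |>
      dplyr::summarise(s = sum(.data$net_adj),
                       .by = c("province", "sex", "age")) |>
      dplyr::inner_join(fl$prov_net_adj, by = c("province", "sex", "age"))
    expect_lt(max(abs(ca$s - ca$net_adj)), 1e-9 * scale)

    # national conservation: adjusted city flows sum to zero per (sex, age)
    cn <- dplyr::summarise(fl$city_net_adj, s = sum(.data$net_adj),
                           .by = c("sex", "age"))
    expect_lt(max(abs(cn$s)), 1e-9 * scale)
  }
})
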