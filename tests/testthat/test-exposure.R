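test_that("the dose equation is plain arithmetic with unit conversion", {
  # 600 ng/g is the benzophenone migration limit of 0.6 mg/kg
  expect_identical(add_point(600, 100, 1, 10), 6e-3)
  expect_identical(add_point(0, 123, 1, 45), 0)
  expect_equal(add_point(34, 50, 1, 17), 1e-4)
  expect_equal(add_point(c(1, 2), 10, 1, c(10, 10)), c(1e-6, 2e-6))
  expect_error(add_point(1, 1, 1, 0), class = "bpprisk_domain_error")
  expect_error(add_point(1, 1, 1.5, 10), class = "bpprisk_domain_error")
  expect_error(add_point(-1, 1, 1, 10), class = "bpprisk_domain_error")
})

test_that("degenerate distributions reduce the simulation to the point dose", {
  group <- make_group(
    bw_spec = dist_spec("normal", mean = 10, sd = 0),
    ir_specs = list(grain = dist_spec("lognormal", gm = 100, gsd = 1)))
  sc <- scenario_parametric(list(grain = dist_spec("point", value = 600)))
  res <- simulate_add(sc, group, "BP", n_iter = 500, seed = 1)
  expect_true(all(res$samples == 6e-3))
  expect_identical(res$p50, 6e-3)
  expect_identical(res$p97_5, 6e-3)
})

test_that("doses add across food categories at matched draws", {
  group2 <- make_group(
    bw_spec = dist_spec("normal", mean = 10, sd = 0),
    ir_specs = list(grain = dist_spec("lognormal", gm = 100, gsd = 1),
                    juice = dist_spec("lognormal", gm = 100, gsd = 1)))
  sc2 <- scenario_parametric(list(grain = dist_spec("point", value = 600),
                                  juice = dist_spec("point", value = 600)))
  res2 <- simulate_add(sc2, group2, "BP", n_iter = 200, seed = 1)
  expect_true(all(res2$samples == 2 * 6e-3))
})

test_that("doses scale linearly with concentration", {
  group <- make_group(
    bw_spec = dist_spec("normal", mean = 15, sd = 2),
    ir_specs = list(grain = dist_spec("lognormal", gm = 50, gsd = 1.8)))
  base <- scenario_parametric(list(grain = dist_spec("lognormal", gm = 20,
                                                     gsd = 1.5)))
  scaled <- scenario_parametric(list(grain = dist_spec("lognormal", gm = 20 * 7,
                                                       gsd = 1.5)))
  r1 <- simulate_add(base, group, "BP", n_iter = 1000, seed = 9)
  r7 <- simulate_add(scaled, group, "BP", n_iter = 1000, seed = 9)
  expect_equal(r7$samples, 7 * r1$samples)
})

test_that("the simulated tail matches the analytic lognormal quantile", {
  mu_c <- log(34); s_c <- 0.5
  mu_i <- log(50); s_i <- 0.4
  mu_b <- log(17); s_b <- 0.25
  group <- make_group(
    bw_spec = dist_spec("lognormal", meanlog = mu_b, sdlog = s_b),
    ir_specs = list(grain = dist_spec("lognormal", meanlog = mu_i, sdlog = s_i)))
  sc <- scenario_parametric(list(grain = dist_spec("lognormal", meanlog = mu_c,
                                                   sdlog = s_c)))
  res <- simulate_add(sc, group, "BP", n_iter = 100000, seed = 31)
  z <- qnorm(0.975)
  analytic <- exp(mu_c + mu_i - mu_b + z * sqrt(s_c^2 + s_i^2 + s_b^2)) * 1e-6
  expect_equal(res$p97_5, analytic, tolerance = 0.03)
})

test_that("simulation draws are reproducible and seed-sensitive", {
  cfg <- multi_config()
  occ <- generate_occurrence(cfg)
  pop <- generate_population(cfg)
  sc <- scenario_measured(occ, bound = "UB")
  a <- simulate_add(sc, pop[["19-65"]], "4-MBP", n_iter = 400, seed = 5)
  b <- simulate_add(sc, pop[["19-65"]], "4-MBP", n_iter = 400, seed = 5)
  d <- simulate_add(sc, pop[["19-65"]], "4-MBP", n_iter = 400, seed = 6)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, d$samples))
})

test_that("the regulatory scenario uses converted migration limits and excludes analytes without one", {
  group <- make_group(
    bw_spec = dist_spec("normal", mean = 10, sd = 0),
    ir_specs = list(grain = dist_spec("lognormal", gm = 100, gsd = 1)))
  res <- simulate_add(scenario_sml(), group, "BP", n_iter = 10, seed = 1)
  expect_true(all(res$samples == 6e-3))  # 0.6 mg/kg -> 600 ng/g
  expect_equal(res$bound, "not_applicable")
  expect_error(simulate_add(scenario_sml(), group, "2-OHBP", n_iter = 10),
               class = "bpprisk_config_error")
})

test_that("matched random streams keep lower-bound doses below upper-bound doses", {
  cfg <- multi_config()
  occ <- generate_occurrence(cfg)
  pop <- generate_population(cfg)
  for (source in c("fitted", "empirical")) {
    lb <- simulate_add(scenario_measured(occ, "LB", source = source),
                       pop[["0-3"]], "4-MBP", n_iter = 2000, seed = 77)
    ub <- simulate_add(scenario_measured(occ, "UB", source = source),
                       pop[["0-3"]], "4-MBP", n_iter = 2000, seed = 77)
    expect_true(all(lb$samples <= ub$samples))
    expect_lte(lb$p50, ub$p50)
    expect_lte(lb$p97_5, ub$p97_5)
  }
})

test_that("a fully detected analyte needs no censoring bound", {
  cfg <- multi_config()
  occ <- generate_occurrence(cfg)
  pop <- generate_population(cfg)
  lb <- simulate_add(scenario_measured(occ, "LB"), pop[["19-65"]], "BP",
                     n_iter = 300, seed = 2)
  ub <- simulate_add(scenario_measured(occ, "UB"), pop[["19-65"]], "BP",
                     n_iter = 300, seed = 2)
  expect_equal(lb$bound, "not_applicable")
  expect_identical(lb$samples, ub$samples)
})

test_that("exposure tables key on analyte, group, scenario and bound", {
  group <- make_group()
  sc <- scenario_parametric(list(grain = dist_spec("point", value = 10)))
  res <- purrr::map(c("BP", "4-MBP"), function(a)
    simulate_add(sc, group, a, n_iter = 50, seed = 3))
  tab <- assemble_exposure_table(res)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("analyte", "age_group", "scenario", "bound",
                      "p50_mg_kg_day", "p97_5_mg_kg_day", "n_iter", "seed"))
  expect_error(assemble_exposure_table(c(res, res[1])),
               class = "bpprisk_usage_error")
  expect_error(assemble_exposure_table(list()),
               class = "bpprisk_usage_error")
})

test_that("the P97.5 estimate is stable across seeds at 10,000 iterations", {
  cfg <- default_survey_config()
  occ <- generate_occurrence(cfg)
  pop <- generate_population(cfg)
  sc <- scenario_measured(occ, bound = "UB")
  p975 <- purrr::map_dbl(1:6, function(s)
    suppressWarnings(
      simulate_add(sc, pop[["19-65"]], "BP", n_iter = 10000, seed = s)$p97_5))
  expect_lt(sd(p975) / mean(p975), 0.05)
})
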