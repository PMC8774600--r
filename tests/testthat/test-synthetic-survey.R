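test_that("extreme detection rates force fully detected or fully censored surveys", {
  all_det <- generate_occurrence(tiny_config(detection_rate = 1, n_samples = 50L))
  expect_equal(nrow(all_det), 50L)
  expect_true(all(all_det$status == "detected"))
  expect_true(all(all_det$value_ng_per_g > 0))

  none_det <- generate_occurrence(tiny_config(detection_rate = 0, n_samples = 50L))
  expect_equal(nrow(none_det), 50L)
  expect_true(all(none_det$status %in% c("lt_lod", "lt_loq")))
  expect_true(all(is.na(none_det$value_ng_per_g)))
  expect_true(all(bounded_values(none_det, "LB") == 0))
})

test_that("each (category, analyte) spec yields exactly n_samples records", {
  cfg <- multi_config(n_samples = 25L)
  occ <- generate_occurrence(cfg)
  counts <- dplyr::count(occ, food_category, analyte)
  expect_equal(nrow(counts), nrow(cfg$analytes))
  expect_true(all(counts$n == 25L))
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- multi_config(seed = 99L)
  expect_identical(generate_occurrence(cfg), generate_occurrence(cfg))
  expect_false(identical(generate_occurrence(cfg),
                         generate_occurrence(cfg, seed = 100L)))
})

test_that("sample geometric mean and detection rate converge to their parameters", {
  cfg <- tiny_config(seed = 5L, n_samples = 10000L, detection_rate = 0.7,
                     gm = 34, gsd = 1.8)
  occ <- generate_occurrence(cfg)
  summ <- summarize_occurrence(occ)
  expect_equal(summ$gm, 34, tolerance = 0.02)
  # binomial tolerance: 4 standard errors at n = 10,000
  expect_lt(abs(summ$detection_rate / 100 - 0.7),
            4 * sqrt(0.7 * 0.3 / 10000))
})

test_that("detected values respect the LOQ truncation switch", {
  cfg <- tiny_config(seed = 3L, n_samples = 2000L, detection_rate = 1,
                     gm = 1, gsd = 2.5, lod = 0.3, loq = 0.8)
  occ <- generate_occurrence(cfg)
  expect_true(all(occ$value_ng_per_g >= 0.8))

  cfg_free <- tiny_config(seed = 3L, n_samples = 2000L, detection_rate = 1,
                          gm = 1, gsd = 2.5, lod = 0.3, loq = 0.8,
                          truncate_at_loq = FALSE)
  expect_true(any(generate_occurrence(cfg_free)$value_ng_per_g < 0.8))
})

test_that("censored records split between lt_lod and lt_loq as configured", {
  cfg <- tiny_config(seed = 13L, n_samples = 4000L, detection_rate = 0)
  occ <- generate_occurrence(cfg)
  frac_loq <- mean(occ$status == "lt_loq")
  expect_lt(abs(frac_loq - 0.5), 4 * sqrt(0.25 / 4000))

  cfg1 <- tiny_config(seed = 13L, n_samples = 500L, detection_rate = 0,
                      censor_split = 1)
  expect_true(all(generate_occurrence(cfg1)$status == "lt_loq"))
})

test_that("generate_population echoes the configured groups and distributions", {
  cfg <- default_survey_config()
  pop <- generate_population(cfg)
  expect_length(pop, 7L)
  expect_setequal(names(pop),
                  c("0-3", "3-6", "6-12", "12-16", "16-18", "19-65", ">65"))
  adult <- pop[["19-65"]]
  expect_s3_class(adult, "bpp_population_group")
  expect_equal(adult$bw_spec$family, "normal")
  expect_setequal(names(adult$ir_specs), cfg$categories$name)
  expect_true(all(purrr::map_chr(adult$ir_specs, "family") == "lognormal"))

  degenerate <- make_group(bw_spec = dist_spec("normal", mean = 10, sd = 0))
  expect_true(all(draw_dist(degenerate$bw_spec, 100) == 10))
})

test_that("invalid generator configurations fail loudly naming the offender", {
  expect_error(tiny_config(gsd = 0.9), class = "bpprisk_config_error")
  expect_error(tiny_config(detection_rate = 1.2), class = "bpprisk_config_error")
  expect_error(tiny_config(lod = 0.5, loq = 0.1), "lod",
               class = "bpprisk_config_error")
  cfg <- tiny_config()
  expect_error(
    survey_config(cfg$categories, cfg$analytes, cfg$population,
                  cfg$intake[0, ]),
    "intake", class = "bpprisk_config_error")
})

test_that("configurations round-trip through YAML", {
  cfg <- multi_config(seed = 21L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_survey_config(cfg, path)
  cfg2 <- read_survey_config(path)
  expect_identical(generate_occurrence(cfg), generate_occurrence(cfg2))
  expect_equal(cfg2$seed, cfg$seed)
})
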