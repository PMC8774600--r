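test_that("the margin of exposure is the POD-to-dose ratio", {
  expect_identical(compute_moe(3.1, 3.1e-4), 10000)
  expect_identical(compute_moe(0.03, 0.03), 1)
  expect_equal(compute_moe(18.5, 2.56e-4), 72265.625)
  expect_identical(compute_moe(3.1, 0), Inf)
  expect_error(compute_moe(0, 1), class = "bpprisk_domain_error")
  expect_error(compute_moe(1, -1), class = "bpprisk_domain_error")
  # antitone in dose, monotone in POD
  expect_true(all(diff(compute_moe(3.1, c(1e-4, 1e-3, 1e-2))) < 0))
  expect_true(all(diff(compute_moe(c(1, 10, 100), 1e-3)) > 0))
})

test_that("harmonic combination of MOEs satisfies its identities", {
  expect_identical(combine_moet(c(a = 100)), 100)
  expect_identical(combine_moet(c(a = 100, b = 100)), 50)
  expect_equal(combine_moet(c(a = 100, b = 200, c = 400)), 400 / 7)
  expect_error(combine_moet(numeric()), class = "bpprisk_usage_error")
  expect_error(combine_moet(c(1, -1)), class = "bpprisk_usage_error")
})

test_that("MOE_T never exceeds the smallest member and shrinks with new members", {
  withr::with_seed(404L, {
    for (i in 1:200) {
      moes <- exp(runif(sample(1:6, 1), log(10), log(1e6)))
      m <- combine_moet(moes)
      expect_lte(m, min(moes))
      if (length(moes) == 1) expect_identical(m, moes[[1]])
      expect_lt(combine_moet(c(moes, 500)), m)
    }
  })
})

test_that("RISK21 classification compares exposure and toxicity bands", {
  expect_identical(risk21_classify(1e-5, 2.56e-4, 3.1, 18.5, 100), "low")
  # even the median exposure reaches the toxicity band
  expect_identical(risk21_classify(3.1, 3.5, 3.1, 18.5, 100), "high")
  # protective exactly at the target margin
  expect_identical(risk21_classify(1e-3, 3.1 / 100, 3.1, 3.1, 100), "low")
  expect_identical(risk21_classify(0.1, 0.2, 3.1, 18.5, 100), "moderate")
  expect_error(risk21_classify(2, 1, 3.1, 18.5), class = "bpprisk_usage_error")
  expect_error(risk21_classify(1, 2, 18.5, 3.1), class = "bpprisk_usage_error")
})

test_that("TTC screening is a strict comparison against the threshold", {
  expect_identical(ttc_screen(3.52e-5, 0.0015), "below_threshold")
  expect_identical(ttc_screen(0.0015, 0.0015), "exceeds_threshold")
  expect_identical(ttc_screen(0, 0.0015), "below_threshold")
  expect_error(ttc_screen(1e-5, 0), class = "bpprisk_domain_error")
})

make_exposure_row <- function(analyte, age_group = "19-65", bound = "UB",
                              p50 = 1e-5, p975 = 1e-4, scenario = 2L) {
  tibble::tibble(analyte = analyte, age_group = age_group,
                 scenario = scenario, bound = bound,
                 p50_mg_kg_day = p50, p97_5_mg_kg_day = p975,
                 n_iter = 100L, seed = 1L)
}

test_that("risk tables join exposure against the registry correctly", {
  exposure <- dplyr::bind_rows(
    make_exposure_row("BP", bound = "not_applicable"),
    make_exposure_row("4-MBP", bound = "LB"),
    make_exposure_row("4-MBP", bound = "UB"),
    make_exposure_row("M2BB", bound = "LB"),
    make_exposure_row("M2BB", bound = "UB"),
    make_exposure_row("2-OHBP", bound = "UB", p975 = 3.52e-5))

  moe <- moe_table(exposure)
  # BP contributes noncarcinogen and carcinogen endpoints, two percentiles
  expect_equal(sum(moe$analyte == "BP"), 4L)
  expect_true(all(moe$verdict[moe$moe >= moe$target_moe] == "acceptable"))
  bp_975 <- dplyr::filter(moe, analyte == "BP", percentile == "P97.5",
                          endpoint_class == "noncarcinogen")
  expect_equal(bp_975$moe, 3.1 / 1e-4)
  # 2-OHBP has no POD: absent from the MOE table
  expect_false("2-OHBP" %in% moe$analyte)

  moet <- moet_table(exposure)
  expect_setequal(unique(moet$bound), c("LB", "UB"))
  expect_true(all(moet$members == "4-MBP+BP+M2BB"))
  row <- dplyr::filter(moet, bound == "UB", percentile == "P97.5")
  manual <- combine_moet(c(3.1 / 1e-4, 3.1 / 1e-4, 31.25 / 1e-4))
  expect_equal(row$moet, manual)
  expect_equal(row$target, 200)

  ttc <- ttc_table(exposure)
  expect_equal(nrow(ttc), 1L)
  expect_equal(ttc$analyte, "2-OHBP")
  expect_equal(ttc$threshold_mg_kg_day, 0.0015)
  expect_equal(ttc$verdict, "below_threshold")

  r21 <- risk21_table(exposure)
  bp <- dplyr::filter(r21, analyte == "BP")
  expect_equal(bp$tox_low, 3.1)
  expect_equal(bp$tox_high, 18.5)
  expect_equal(bp$classification, "low")
})

test_that("risk plots build without error", {
  exposure <- dplyr::bind_rows(
    make_exposure_row("BP", bound = "not_applicable"),
    make_exposure_row("2-OHBP", bound = "UB", p975 = 3.52e-5))
  expect_s3_class(plot_risk21(risk21_table(exposure)), "ggplot")
  expect_s3_class(plot_ttc(ttc_table(exposure)), "ggplot")
})
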