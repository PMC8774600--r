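# In-code fixtures: tiny generator configurations and hand-built occurrence
# records used across the suite.

tiny_config <- function(seed = 7L, n_samples = 40L, detection_rate = 0.8,
                        gm = 34, gsd = 1.8, lod = 0.003, loq = 0.01,
                        categories = "grain", analytes = "BP",
                        bw_mean = 60, bw_sd = 8,
                        ir_gm = 50, ir_gsd = 1.8,
                        age_groups = "19-65", ...) {
  cats <- tibble::tibble(name = categories, matrix_kind = "solid",
                         n_samples = n_samples)
  specs <- tidyr::expand_grid(food_category = categories, analyte = analytes)
  specs$detection_rate <- detection_rate
  specs$gm <- gm
  specs$gsd <- gsd
  specs$lod <- lod
  specs$loq <- loq
  pop <- tibble::tibble(age_group = age_groups, bw_mean = bw_mean,
                        bw_sd = bw_sd)
  intake <- tidyr::expand_grid(age_group = age_groups,
                               food_category = categories)
  intake$ir_gm <- ir_gm
  intake$ir_gsd <- ir_gsd
  survey_config(cats, specs, pop, intake, seed = seed, ...)
}

# a multi-analyte config resembling the reference survey in miniature
multi_config <- function(seed = 11L, n_samples = 60L) {
  specs <- tibble::tribble(
    ~food_category, ~analyte, ~detection_rate, ~gm, ~gsd,
    "grain", "BP",     1.0, 30,  1.8,
    "grain", "4-MBP",  0.6,  2,  2.0,
    "grain", "M2BB",   0.3,  1,  1.8,
    "juice", "BP",     1.0, 12,  1.6,
    "juice", "4-MBP",  0.9,  0.4, 1.9,
    "juice", "M2BB",   0.9,  0.5, 1.5,
    "juice", "2-OHBP", 0.4,  0.5, 2.0,
    "juice", "4-OHBP", 0.2,  0.8, 1.8,
    "juice", "PBZ",    0.5,  0.4, 1.9
  )
  specs$lod <- 0.03
  specs$loq <- 0.1
  cats <- tibble::tibble(name = c("grain", "juice"),
                         matrix_kind = c("solid", "liquid"),
                         n_samples = n_samples)
  pop <- tibble::tibble(age_group = c("0-3", "19-65"),
                        bw_mean = c(12.6, 64), bw_sd = c(1.9, 11))
  intake <- tidyr::expand_grid(age_group = pop$age_group,
                               food_category = cats$name)
  intake$ir_gm <- c(5, 20, 10, 30)
  intake$ir_gsd <- 1.9
  survey_config(cats, specs, pop, intake, seed = seed)
}

make_records <- function(values, status = rep("detected", length(values)),
                         lod = 0.05, loq = 0.29,
                         category = "grain", analyte = "BP") {
  tibble::tibble(
    food_category = category, analyte = analyte,
    value_ng_per_g = ifelse(status == "detected", values, NA_real_),
    status = status, lod_ng_per_g = lod, loq_ng_per_g = loq,
    packaging = "plastic")
}

# population group with explicit distribution specs (bypasses the generator)
make_group <- function(age_group = "adult",
                       bw_spec = dist_spec("normal", mean = 10, sd = 0),
                       ir_specs = list(grain = dist_spec("point", value = 100))) {
  structure(list(age_group = age_group, bw_spec = bw_spec,
                 ir_specs = ir_specs),
            class = "bpp_population_group")
}
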