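#' Generate a synthetic occurrence dataset
#'
#' Draws one synthetic market survey from a generator configuration.  For
#' each (food category, analyte) spec, `n_samples` records are produced:
#' each sample is detected with probability `detection_rate`, detected
#' concentrations are drawn from the configured lognormal body (left-
#' truncated at the LOQ when `truncate_at_loq` is set), and censored
#' records are split between `lt_loq` and `lt_lod` status according to
#' `censor_split`.  The generator is fully deterministic given the
#' configuration (including its seed).
#'
#' @param config a [survey_config()] object.
#' @param seed optional integer overriding `config$seed`.
#' @return A tibble of occurrence records with columns `food_category`,
#'   `analyte`, `value_ng_per_g` (`NA` when censored), `status`
#'   (`detected`, `lt_lod`, `lt_loq`), `lod_ng_per_g`, `loq_ng_per_g`,
#'   `packaging`.
#' @export
generate_occurrence <- function(config, seed = NULL) {
  stopifnot(inherits(config, "bpp_config"))
  validate_survey_config(config)
  seed <- seed %||% config$seed
  specs <- dplyr::inner_join(
    config$analytes,
    dplyr::rename(config$categories, food_category = "name"),
    by = "food_category"
  )
  # fixed generation order => reproducibility does not depend on row order
  specs <- dplyr::arrange(specs, .data$food_category, .data$analyte)

  packs <- c("plastic", "carton board", "aluminum foil", "glass")
  withr::with_seed(seed, {
    recs <- purrr::pmap(specs, function(food_category, analyte,
                                        detection_rate, gm, gsd, lod, loq,
                                        matrix_kind, n_samples, ...) {
      n <- n_samples
      detected <- runif(n) < detection_rate
      value <- rep(NA_real_, n)
      nd <- sum(detected)
      if (nd > 0) {
        if (config$truncate_at_loq) {
          lo <- plnorm(loq, log(gm), log(gsd))
          value[detected] <- qlnorm(runif(nd, lo, 1), log(gm), log(gsd))
        } else {
          value[detected] <- rlnorm(nd, log(gm), log(gsd))
        }
      }
      status <- rep("detected", n)
      nc <- n - nd
      if (nc > 0) {
        status[!detected] <- ifelse(runif(nc) < config$censor_split,
                                    "lt_loq", "lt_lod")
      }
      tibble::tibble(
        food_category = food_category, analyte = analyte,
        value_ng_per_g = value, status = status,
        lod_ng_per_g = lod, loq_ng_per_g = loq,
        packaging = packs[sample.int(length(packs), n, replace = TRUE)]
      )
    })
    dplyr::bind_rows(recs)
  })
}

#' Generate population groups from a configuration
#'
#' Echoes the configured age groups into fully parameterized
#' `bpp_population_group` objects: a normal body-weight spec and one
#' lognormal intake-rate spec per food category.  Deterministic (no random
#' draws happen here; draws occur in [simulate_add()]).
#'
#' @param config a [survey_config()] object.
#' @return A named list (class `bpp_population`) of groups, each a list
#'   with `age_group`, `bw_spec` and `ir_specs`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "bpp_config"))
  validate_survey_config(config)
  groups <- purrr::pmap(config$population, function(age_group, bw_mean, bw_sd) {
    ir <- dplyr::filter(config$intake, .data$age_group == !!age_group)
    ir_specs <- setNames(
      purrr::map2(ir$ir_gm, ir$ir_gsd,
                  function(gm, gsd) dist_spec("lognormal", gm = gm, gsd = gsd)),
      ir$food_category
    )
    structure(list(age_group = age_group,
                   bw_spec = dist_spec("normal", mean = bw_mean, sd = bw_sd),
                   ir_specs = ir_specs),
              class = "bpp_population_group")
  })
  structure(setNames(groups, config$population$age_group),
            class = "bpp_population")
}

#' Write the synthetic survey to CSV files
#'
#' Writes `occurrence.csv` (columns `food_category, analyte, value_ng_per_g,
#' status, lod_ng_per_g, loq_ng_per_g, packaging`) and `population.csv`
#' (columns `age_group, bw_mean_kg, bw_sd_kg, food_category, ir_gm_g_day,
#' ir_gsd`) under `out_dir`.
#'
#' @param config a [survey_config()] object.
#' @param out_dir output directory (created if missing).
#' @param seed optional integer overriding `config$seed`.
#' @return Invisibly, the paths of the two files written.
#' @export
simulate_survey <- function(config, out_dir, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  occ <- generate_occurrence(config, seed = seed)
  occ_path <- file.path(out_dir, "occurrence.csv")
  readr::write_csv(occ, occ_path, na = "")

  pop <- dplyr::inner_join(config$population, config$intake, by = "age_group")
  pop <- tibble::tibble(
    age_group = pop$age_group,
    bw_mean_kg = pop$bw_mean, bw_sd_kg = pop$bw_sd,
    food_category = pop$food_category,
    ir_gm_g_day = pop$ir_gm, ir_gsd = pop$ir_gsd
  )
  pop_path <- file.path(out_dir, "population.csv")
  readr::write_csv(pop, pop_path)
  invisible(c(occurrence = occ_path, population = pop_path))
}

#' Read an occurrence CSV
#'
#' Reads the CSV dialect written by [simulate_survey()] and validates the
#' record-level invariants (detected records carry a positive value,
#' censored records carry none; `lod <= loq`).
#'
#' @param path file path.
#' @return A tibble of occurrence records.
#' @export
read_occurrence <- function(path) {
  occ <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           value_ng_per_g = readr::col_double(),
                           .default = readr::col_guess()))
  validate_occurrence(occ)
  occ
}

validate_occurrence <- function(occ) {
  need <- c("food_category", "analyte", "value_ng_per_g", "status",
            "lod_ng_per_g", "loq_ng_per_g")
  miss <- setdiff(need, names(occ))
  if (length(miss))
    abort(paste("occurrence table missing columns:",
                paste(miss, collapse = ", ")),
          class = "bpprisk_data_error")
  if (!all(occ$status %in% c("detected", "lt_lod", "lt_loq")))
    abort("occurrence status must be detected / lt_lod / lt_loq",
          class = "bpprisk_data_error")
  det <- occ$status == "detected"
  if (any(is.na(occ$value_ng_per_g[det])) ||
      any(occ$value_ng_per_g[det] <= 0))
    abort("detected records must carry a positive concentration",
          class = "bpprisk_data_error")
  if (any(!is.na(occ$value_ng_per_g[!det])))
    abort("censored records must not carry a concentration",
          class = "bpprisk_data_error")
  if (any(occ$lod_ng_per_g > occ$loq_ng_per_g))
    abort("lod must not exceed loq", class = "bpprisk_data_error")
  invisible(occ)
}

#' Read a population CSV
#'
#' Reads the long-format population table written by [simulate_survey()]
#' and rebuilds the `bpp_population` structure.
#'
#' @param path file path.
#' @return A `bpp_population` list as from [generate_population()].
#' @export
read_population <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  population <- dplyr::distinct(tab, age_group = .data$age_group,
                                bw_mean = .data$bw_mean_kg,
                                bw_sd = .data$bw_sd_kg)
  intake <- tibble::tibble(age_group = tab$age_group,
                           food_category = tab$food_category,
                           ir_gm = tab$ir_gm_g_day, ir_gsd = tab$ir_gsd)
  categories <- dplyr::distinct(tab, name = .data$food_category)
  categories$matrix_kind <- "solid"; categories$n_samples <- 1L
  # ride on the config validator, then return only the population part
  cfg <- survey_config(categories,
                       tibble::tibble(food_category = character(),
                                      analyte = character(),
                                      detection_rate = numeric(),
                                      gm = numeric(), gsd = numeric(),
                                      lod = numeric(), loq = numeric()),
                       population, intake)
  generate_population(cfg)
}
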