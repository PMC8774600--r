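#' Average daily dose for a single deterministic draw
#'
#' The exposure model is `ADD = C * IR * AF / BW * 1e-6` with `C` the
#' concentration in food (ng/g), `IR` the intake rate (g/day), `AF` the
#' absorbed fraction and `BW` the body weight (kg); the factor `1e-6`
#' converts ng to mg, so the result is in mg/kg bw/day.  Vectorized.
#'
#' @param c concentration, ng/g (>= 0).
#' @param ir intake rate, g/day (>= 0).
#' @param af absorbed fraction in (0, 1]; the assessments in this package
#'   conservatively assume complete absorption (`af = 1`).
#' @param bw body weight, kg (> 0).
#' @return ADD in mg/kg bw/day.
#' @export
add_point <- function(c, ir, af = 1, bw) {
  if (any(bw <= 0))
    abort("body weight must be positive", class = "bpprisk_domain_error")
  if (any(c < 0) || any(ir < 0))
    abort("concentration and intake rate must be nonnegative",
          class = "bpprisk_domain_error")
  if (any(af <= 0) || any(af > 1))
    abort("absorbed fraction must lie in (0, 1]",
          class = "bpprisk_domain_error")
  c * ir * af / bw * 1e-6
}

#' Exposure scenarios
#'
#' A scenario tells the simulator where per-category concentrations come
#' from:
#' * `scenario_sml()` - regulatory worst case: every food category is
#'   assumed contaminated at the analyte's specific migration limit (SML).
#'   The default SMLs (mg/kg: BP 0.6, 4-MBP 0.05, M2BB 0.05, PBZ 0.01)
#'   follow the Swiss ordinance on materials in contact with food; no SMLs
#'   exist for 2-OHBP and 4-OHBP, which are therefore excluded from this
#'   scenario.  SMLs are converted mg/kg -> ng/g (x1000) before entering
#'   the dose equation.
#' * `scenario_measured()` - measured occurrence: concentrations come from
#'   occurrence records at the chosen censoring bound, either by drawing
#'   from the family selected by [fit_distribution()] (`source = "fitted"`,
#'   default) or by resampling the bounded values (`source = "empirical"`).
#' * `scenario_parametric()` - concentrations from explicit [dist_spec()]
#'   objects per food category (used for closed-form checks and custom
#'   what-if runs).
#'
#' @param smls named numeric vector of SMLs in mg/kg.
#' @param records occurrence tibble (all analytes; filtered per analyte at
#'   simulation time).
#' @param bound `"LB"` or `"UB"` censoring bound for `scenario_measured()`.
#' @param source `"fitted"` or `"empirical"` concentration sampling.
#' @param conc_specs named list (by food category) of [dist_spec()]s.
#' @param id scenario identifier carried into result tables.
#' @param af absorbed fraction in (0, 1].
#' @return An object of class `bpp_scenario`.
#' @export
scenario_sml <- function(smls = c("BP" = 0.6, "4-MBP" = 0.05,
                                  "M2BB" = 0.05, "PBZ" = 0.01),
                         id = 1L, af = 1) {
  stopifnot(is.numeric(smls), !is.null(names(smls)), all(smls > 0))
  structure(list(id = id, type = "sml", smls = smls, af = af,
                 bound = "not_applicable"),
            class = "bpp_scenario")
}

#' @rdname scenario_sml
#' @export
scenario_measured <- function(records, bound = c("UB", "LB"),
                              source = c("fitted", "empirical"),
                              id = 2L, af = 1) {
  bound <- match.arg(bound)
  source <- match.arg(source)
  validate_occurrence(records)
  structure(list(id = id, type = "measured", records = records,
                 bound = bound, source = source, af = af),
            class = "bpp_scenario")
}

#' @rdname scenario_sml
#' @export
scenario_parametric <- function(conc_specs, id = 2L, af = 1,
                                bound = "not_applicable") {
  stopifnot(is.list(conc_specs), !is.null(names(conc_specs)),
            all(purrr::map_lgl(conc_specs, inherits, "bpp_dist")))
  structure(list(id = id, type = "parametric", conc_specs = conc_specs,
                 bound = bound, af = af),
            class = "bpp_scenario")
}

# Resolve the per-category concentration samplers (bpp_dist specs) for one
# analyte under a scenario.  Returns list(specs = named list, bound = label).
resolve_concentration <- function(scenario, analyte, ir_categories) {
  switch(scenario$type,
    sml = {
      if (!analyte %in% names(scenario$smls))
        abort(paste0("no specific migration limit available for ", analyte,
                     "; it is excluded from this scenario"),
              class = "bpprisk_config_error")
      conc <- scenario$smls[[analyte]] * 1000  # mg/kg -> ng/g
      list(specs = setNames(
             replicate(length(ir_categories),
                       dist_spec("point", value = conc), simplify = FALSE),
             ir_categories),
           bound = "not_applicable")
    },
    measured = {
      recs <- dplyr::filter(scenario$records, .data$analyte == !!analyte)
      if (nrow(recs) == 0)
        abort(paste0("no occurrence records for ", analyte),
              class = "bpprisk_config_error")
      cats <- unique(recs$food_category)
      miss <- setdiff(cats, ir_categories)
      if (length(miss))
        abort(paste0("no intake-rate distribution for categories: ",
                     paste(miss, collapse = ", ")),
              class = "bpprisk_config_error")
      specs <- lapply(setNames(cats, cats), function(cc) {
        conc_sampler(recs[recs$food_category == cc, ],
                     scenario$bound, scenario$source)
      })
      fully_detected <- all(recs$status == "detected")
      list(specs = specs,
           bound = if (fully_detected) "not_applicable" else scenario$bound)
    },
    parametric = {
      miss <- setdiff(names(scenario$conc_specs), ir_categories)
      if (length(miss))
        abort(paste0("no intake-rate distribution for categories: ",
                     paste(miss, collapse = ", ")),
              class = "bpprisk_config_error")
      list(specs = scenario$conc_specs, bound = scenario$bound)
    }
  )
}

# Concentration sampler for one category's records under a censoring bound.
#
# Empirical source: resample the bounded values.  Fitted source: a
# detection mixture -- with probability (detected fraction) draw from the
# family selected by fit_distribution() on the *detected* values, otherwise
# resample the substituted censored values (0 under LB, LOD/LOQ under UB).
# Fitting the parametric body to the detected values only keeps the fit
# meaningful when censoring is heavy (a single two-parameter family cannot
# represent a zero-inflated LB sample) and, together with matched random
# streams, makes every LB dose draw <= its UB counterpart by construction.
# Short or degenerate detected bodies fall back to empirical resampling.
conc_sampler <- function(records, bound, source) {
  values <- bounded_values(records, bound)
  if (length(unique(values)) == 1L)
    return(dist_spec("point", value = values[[1]]))
  if (source == "empirical")
    return(dist_spec("empirical", values = values))
  det <- records$status == "detected"
  detected <- records$value_ng_per_g[det]
  if (!any(det))  # nothing detected: only the substituted values remain
    return(dist_spec("empirical", values = values))
  body <- if (length(unique(detected)) < 2L || length(detected) < 8)
    dist_spec("empirical", values = detected)
  else
    fit_distribution(detected)
  if (all(det)) return(body)
  censored <- values[!det]
  mixture_spec(p_body = mean(det), body = body,
               tail_values = censored)
}

# Two-component detection mixture: body with probability p_body, resampled
# tail values otherwise.  Always consumes the same RNG stream layout
# (uniforms, body draws, tail indices) so matched seeds across censoring
# bounds yield elementwise-comparable draws.
mixture_spec <- function(p_body, body, tail_values) {
  structure(list(family = "mixture", p_body = p_body, body = body,
                 tail_values = tail_values),
            class = "bpp_dist")
}

#' Monte Carlo simulation of the average daily dose
#'
#' Simulates the ADD of one analyte for one population group under a
#' scenario.  Each iteration represents one person: a single body weight is
#' drawn (normal, nonpositive draws rejected and redrawn) and shared across
#' all food categories, while one concentration and one intake rate are
#' drawn independently per category; the per-category doses are summed.
#' Negative concentration draws (possible under a fitted normal family) are
#' truncated at zero.  Empirical P50 and P97.5 are extracted with linear
#' interpolation between order statistics (type-7 quantiles).
#'
#' @param scenario a `bpp_scenario`.
#' @param group a `bpp_population_group` (from [generate_population()]).
#' @param analyte analyte name.
#' @param n_iter number of iterations (default 10,000).
#' @param seed optional integer seed; draws are reproducible given it.
#' @param keep_draws retain the per-iteration input draws (body weight and
#'   per-category concentration / intake draws) for sensitivity analysis.
#' @return An object of class `bpp_add`: list with `analyte`, `age_group`,
#'   `scenario`, `bound`, `samples` (mg/kg bw/day), `p50`, `p97_5`,
#'   `n_iter`, `seed`, and (if requested) `draws`.
#' @export
simulate_add <- function(scenario, group, analyte, n_iter = 10000L,
                         seed = NULL, keep_draws = FALSE) {
  stopifnot(inherits(scenario, "bpp_scenario"),
            inherits(group, "bpp_population_group"))
  if (n_iter < 1) abort("n_iter must be >= 1", class = "bpprisk_usage_error")
  resolved <- resolve_concentration(scenario, analyte,
                                    names(group$ir_specs))
  run <- function() {
    bw <- draw_positive_normal(group$bw_spec, n_iter)
    draws <- list(BW = bw)
    total <- numeric(n_iter)
    for (cat in names(resolved$specs)) {
      cdraw <- pmax(draw_dist(resolved$specs[[cat]], n_iter), 0)
      ir <- draw_dist(group$ir_specs[[cat]], n_iter)
      total <- total + add_point(cdraw, ir, scenario$af, bw)
      draws[[paste0("C:", cat)]] <- cdraw
      draws[[paste0("IR:", cat)]] <- ir
    }
    list(samples = total, draws = draws)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  q <- quantile(out$samples, c(0.5, 0.975), names = FALSE, type = 7)
  structure(
    list(analyte = analyte, age_group = group$age_group,
         scenario = scenario$id, bound = resolved$bound,
         samples = out$samples, p50 = q[[1]], p97_5 = q[[2]],
         n_iter = as.integer(n_iter),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         draws = if (keep_draws) out$draws),
    class = "bpp_add"
  )
}

#' @export
print.bpp_add <- function(x, ...) {
  cat(sprintf("<bpp_add> %s | %s | scenario %s | bound %s\n  P50 = %.4g, P97.5 = %.4g mg/kg bw/day (n_iter = %d)\n",
              x$analyte, x$age_group, x$scenario, x$bound,
              x$p50, x$p97_5, x$n_iter))
  invisible(x)
}

#' Assemble simulated doses into a long exposure table
#'
#' @param results list of `bpp_add` objects.
#' @return Tibble keyed by (`analyte`, `age_group`, `scenario`, `bound`)
#'   with `p50_mg_kg_day`, `p97_5_mg_kg_day`, `n_iter`, `seed`.
#' @export
assemble_exposure_table <- function(results) {
  if (length(results) == 0)
    abort("no simulation results supplied", class = "bpprisk_usage_error")
  stopifnot(all(purrr::map_lgl(results, inherits, "bpp_add")))
  tab <- purrr::map_dfr(results, function(r) {
    tibble::tibble(analyte = r$analyte, age_group = r$age_group,
                   scenario = r$scenario, bound = r$bound,
                   p50_mg_kg_day = r$p50, p97_5_mg_kg_day = r$p97_5,
                   n_iter = r$n_iter, seed = r$seed)
  })
  key <- paste(tab$analyte, tab$age_group, tab$scenario, tab$bound)
  if (anyDuplicated(key))
    abort(paste("duplicate exposure keys:",
                paste(unique(key[duplicated(key)]), collapse = "; ")),
          class = "bpprisk_usage_error")
  tab
}
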