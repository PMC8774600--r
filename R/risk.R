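#' Margin of exposure
#'
#' The margin of exposure (MOE) is the ratio of the critical point of
#' departure to the estimated exposure.  Values at or above the target MOE
#' are considered protective.  A zero exposure yields an infinite MOE
#' (flagged, not an error).  Vectorized.
#'
#' @param pod point of departure, mg/kg bw/day (> 0).
#' @param add estimated exposure, mg/kg bw/day (>= 0).
#' @return Numeric MOE values (possibly `Inf`).
#' @export
compute_moe <- function(pod, add) {
  if (any(pod <= 0))
    abort("point of departure must be positive",
          class = "bpprisk_domain_error")
  if (any(add < 0))
    abort("exposure must be nonnegative", class = "bpprisk_domain_error")
  pod / add
}

#' Combined margin of exposure for a common endpoint
#'
#' The cumulative margin of exposure MOE_T of chemicals sharing a toxic
#' endpoint is the reciprocal of the sum of reciprocals of the individual
#' MOEs (harmonic combination):
#' `MOE_T = 1 / (1/MOE_1 + ... + 1/MOE_k)`.
#' A single member returns itself; MOE_T never exceeds the smallest member.
#'
#' @param moes numeric vector (optionally named by analyte) of MOEs, all
#'   > 0; infinite members contribute nothing to the sum.
#' @return The combined MOE_T (scalar).
#' @export
combine_moet <- function(moes) {
  moes <- unlist(moes)
  if (length(moes) == 0)
    abort("MOE_T needs at least one member", class = "bpprisk_usage_error")
  if (any(is.na(moes)) || any(moes <= 0))
    abort("all member MOEs must be positive", class = "bpprisk_usage_error")
  if (length(moes) == 1L) return(unname(moes[[1]]))  # exact single-member identity
  1 / sum(1 / moes)
}

#' RISK21-style exposure/toxicity classification
#'
#' Juxtaposes an exposure band (P50 to P97.5 ADD) against a toxicity band
#' (the range of PODs for the analyte) and classifies the level of concern:
#' `"low"` when the upper exposure times the target MOE stays at or below
#' the lower toxicity bound (the margin is protective), `"high"` when even
#' the lower exposure reaches the toxicity band, `"moderate"` otherwise.
#' Vectorized over rows.
#'
#' @param exposure_low,exposure_high exposure band, mg/kg bw/day.
#' @param tox_low,tox_high toxicity band, mg/kg bw/day.
#' @param target_moe target margin of exposure (default 100).
#' @return Character vector of classifications.
#' @export
risk21_classify <- function(exposure_low, exposure_high,
                            tox_low, tox_high, target_moe = 100) {
  if (any(exposure_low > exposure_high) || any(tox_low > tox_high))
    abort("inverted exposure or toxicity band",
          class = "bpprisk_usage_error")
  if (any(tox_low <= 0))
    abort("toxicity band must be positive", class = "bpprisk_usage_error")
  dplyr::case_when(
    exposure_high * target_moe <= tox_low ~ "low",
    exposure_low >= tox_low ~ "high",
    .default = "moderate"
  )
}

#' Threshold-of-toxicological-concern screen
#'
#' Compares an exposure against a TTC threshold (both mg/kg bw/day); the
#' verdict is `"below_threshold"` only for exposures strictly below the
#' threshold.  Vectorized.
#'
#' @param add exposure, mg/kg bw/day.
#' @param threshold TTC threshold, mg/kg bw/day (> 0).
#' @return Character vector of verdicts.
#' @export
ttc_screen <- function(add, threshold) {
  if (any(threshold <= 0))
    abort("TTC threshold must be positive", class = "bpprisk_domain_error")
  ifelse(add < threshold, "below_threshold", "exceeds_threshold")
}

#' Risk tables from an exposure table
#'
#' `moe_table()` joins each exposure percentile against every MOE-eligible
#' hazard profile; `moet_table()` harmonically combines the noncarcinogenic
#' kidney-endpoint members (default BP, 4-MBP, M2BB) per age group, bound
#' and percentile against the most stringent member target (200);
#' `ttc_table()` screens TTC-only analytes (2-OHBP) at their Cramer-class
#' threshold; `risk21_table()` classifies each analyte's exposure band
#' against its POD band.
#'
#' @param exposure tibble from [assemble_exposure_table()].
#' @param registry a [load_hazard_registry()] object.
#' @param members analytes combined in MOE_T.
#' @param target combined target MOE_T.
#' @param ttc_bw body weight (kg) for the TTC conversion; defaults to the
#'   registry default (60 kg).
#' @param percentile which exposure percentile feeds the TTC screen.
#' @return A tibble (per function).
#' @export
moe_table <- function(exposure, registry = load_hazard_registry()) {
  profiles <- registry_profiles(registry, moe_only = TRUE)
  long <- tidyr::pivot_longer(
    exposure, cols = c("p50_mg_kg_day", "p97_5_mg_kg_day"),
    names_to = "percentile", values_to = "add_mg_kg_day")
  long$percentile <- ifelse(long$percentile == "p50_mg_kg_day",
                            "P50", "P97.5")
  out <- dplyr::inner_join(long, profiles, by = "analyte",
                           relationship = "many-to-many")
  out$moe <- compute_moe(out$pod_value, out$add_mg_kg_day)
  out$verdict <- ifelse(out$moe >= out$target_moe, "acceptable", "concern")
  dplyr::select(out, "analyte", "age_group", "scenario", "bound",
                "percentile", pod_type = "pod_type",
                pod_mg_kg_day = "pod_value", endpoint_class = "endpoint_class",
                add_mg_kg_day = "add_mg_kg_day", "moe",
                "target_moe", "verdict")
}

#' @rdname moe_table
#' @export
moet_table <- function(exposure, registry = load_hazard_registry(),
                       members = c("BP", "4-MBP", "M2BB"), target = 200) {
  moe <- moe_table(exposure, registry)
  moe <- dplyr::filter(moe, .data$endpoint_class == "noncarcinogen",
                       .data$analyte %in% members)
  bounds <- setdiff(unique(moe$bound), "not_applicable")
  if (length(bounds) == 0) bounds <- "not_applicable"
  grid <- tidyr::expand_grid(
    age_group = unique(moe$age_group),
    scenario = unique(moe$scenario),
    bound = bounds,
    percentile = unique(moe$percentile))
  purrr::pmap_dfr(grid, function(age_group, scenario, bound, percentile) {
    rows <- dplyr::filter(
      moe, .data$age_group == !!age_group, .data$scenario == !!scenario,
      .data$percentile == !!percentile,
      .data$bound %in% c(!!bound, "not_applicable"))
    if (nrow(rows) == 0) return(NULL)
    moet <- combine_moet(setNames(rows$moe, rows$analyte))
    tibble::tibble(age_group = age_group, scenario = scenario,
                   bound = bound, percentile = percentile,
                   members = paste(sort(rows$analyte), collapse = "+"),
                   moet = moet, target = target,
                   verdict = ifelse(moet >= target, "acceptable", "concern"))
  })
}

#' @rdname moe_table
#' @export
ttc_table <- function(exposure, registry = load_hazard_registry(),
                      ttc_bw = NULL, percentile = "P97.5") {
  ttc_analytes <- names(purrr::keep(registry$analytes,
                                    function(a) isTRUE(a$ttc_only)))
  rows <- dplyr::filter(exposure, .data$analyte %in% ttc_analytes)
  if (nrow(rows) == 0) {
    return(tibble::tibble(analyte = character(), age_group = character(),
                          scenario = integer(), bound = character(),
                          percentile = character(),
                          add_mg_kg_day = numeric(),
                          cramer_class = character(),
                          threshold_mg_kg_day = numeric(),
                          verdict = character()))
  }
  # screen the upper bound where both bounds exist (conservative side)
  if ("UB" %in% rows$bound)
    rows <- dplyr::filter(rows, .data$bound %in% c("UB", "not_applicable"))
  add <- if (percentile == "P97.5") rows$p97_5_mg_kg_day else rows$p50_mg_kg_day
  cls <- purrr::map_chr(rows$analyte,
                        function(a) registry$analytes[[a]]$cramer_class)
  thr <- purrr::map_dbl(cls, function(cl)
    ttc_threshold_per_bw(cl, bw = ttc_bw, registry = registry)$mg_kg_bw_day)
  tibble::tibble(analyte = rows$analyte, age_group = rows$age_group,
                 scenario = rows$scenario, bound = rows$bound,
                 percentile = percentile, add_mg_kg_day = add,
                 cramer_class = cls, threshold_mg_kg_day = thr,
                 verdict = ttc_screen(add, thr))
}

#' @rdname moe_table
#' @export
risk21_table <- function(exposure, registry = load_hazard_registry()) {
  profiles <- registry_profiles(registry, moe_only = TRUE)
  band <- profiles |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(tox_low = min(.data$pod_value),
                     tox_high = max(.data$pod_value),
                     target_moe = max(.data$target_moe), .groups = "drop")
  out <- dplyr::inner_join(exposure, band, by = "analyte")
  out$classification <- risk21_classify(
    out$p50_mg_kg_day, out$p97_5_mg_kg_day,
    out$tox_low, out$tox_high, out$target_moe)
  dplyr::select(out, "analyte", "age_group", "scenario", "bound",
                exposure_low = "p50_mg_kg_day",
                exposure_high = "p97_5_mg_kg_day",
                "tox_low", "tox_high", "target_moe", "classification")
}
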