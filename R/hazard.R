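#' Load the hazard registry
#'
#' Reads and validates the packaged registry of points of departure (POD),
#' health-based guidance values and TTC rules for the six benzophenone-type
#' photoinitiators.  Per analyte the registry carries one or more hazard
#' profiles (POD type, value in mg/kg bw/day, endpoint, endpoint class,
#' target margin of exposure) or, for 2-OHBP, a TTC-only flag with its
#' Cramer class.  The TTC block carries the person-level thresholds for
#' Cramer classes I-III (1800 / 540 / 90 ug/person/day) and the default
#' body weight used to convert them to body-weight scale.
#'
#' @param path optional path to a registry YAML; defaults to the packaged
#'   registry.
#' @return An object of class `bpp_hazard_registry`: list with `analytes`
#'   (named list of profile tibbles / TTC flags), `ttc` and `meta`.
#' @export
load_hazard_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hazard_registry.yaml",
                                package = "bpprisk", mustWork = TRUE)
  doc <- yaml::read_yaml(path)
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))

  ttc <- doc$ttc
  thr <- unlist(ttc$thresholds_ug_person_day)
  if (!setequal(names(thr), c("I", "II", "III")))
    note("ttc thresholds must cover Cramer classes I, II, III")
  if (!(is.numeric(ttc$default_bw_kg) && ttc$default_bw_kg > 0))
    note("ttc default_bw_kg must be positive")
  if (!(thr[["I"]] > thr[["II"]] && thr[["II"]] > thr[["III"]]))
    note("ttc thresholds must be strictly decreasing I > II > III")

  analytes <- purrr::imap(doc$analytes, function(entry, analyte) {
    if (isTRUE(entry$ttc_only)) {
      if (!entry$cramer_class %in% c("I", "II", "III"))
        note(analyte, ": invalid cramer_class")
      return(list(ttc_only = TRUE, cramer_class = entry$cramer_class,
                  note = entry$note))
    }
    profiles <- dplyr::bind_rows(purrr::map(entry$profiles, function(p) {
      tibble::tibble(
        analyte = analyte,
        pod_type = p$pod_type, pod_value = as.numeric(p$pod_value),
        endpoint = p$endpoint, endpoint_class = p$endpoint_class,
        target_moe = as.numeric(p$target_moe),
        use_for_moe = isTRUE(p$use_for_moe),
        source = gsub("\\s+", " ", trimws(p$source %||% ""))
      )
    }))
    if (any(!profiles$pod_type %in% c("TDI", "BMDL10", "NOAEL")))
      note(analyte, ": invalid pod_type")
    if (any(profiles$pod_value <= 0)) note(analyte, ": pod_value must be > 0")
    if (any(profiles$target_moe < 1)) note(analyte, ": target_moe must be >= 1")
    if (any(!profiles$endpoint_class %in% c("noncarcinogen", "carcinogen")))
      note(analyte, ": invalid endpoint_class")
    list(ttc_only = FALSE, profiles = profiles)
  })

  if (length(problems))
    abort(paste0("hazard registry failed validation:\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "bpprisk_registry_error")

  structure(list(analytes = analytes,
                 ttc = list(default_bw_kg = ttc$default_bw_kg,
                            thresholds_ug_person_day = thr),
                 meta = doc$meta),
            class = "bpp_hazard_registry")
}

#' @export
print.bpp_hazard_registry <- function(x, ...) {
  cat("<bpp_hazard_registry> analytes:",
      paste(names(x$analytes), collapse = ", "), "\n")
  invisible(x)
}

#' All margin-of-exposure profiles in a registry as one table
#'
#' @param registry a [load_hazard_registry()] object.
#' @param moe_only keep only profiles flagged for MOE use (drops guidance
#'   values such as the TDI, which are carried as metadata).
#' @return Tibble of hazard profiles.
#' @export
registry_profiles <- function(registry, moe_only = TRUE) {
  stopifnot(inherits(registry, "bpp_hazard_registry"))
  profiles <- dplyr::bind_rows(
    purrr::map(registry$analytes,
               function(a) if (!a$ttc_only) a$profiles))
  if (moe_only) profiles <- dplyr::filter(profiles, .data$use_for_moe)
  profiles
}

#' Convert a person-level TTC threshold to body-weight scale
#'
#' Divides the Cramer-class threshold (ug/person/day) by a body weight to
#' obtain ug/kg bw/day and mg/kg bw/day.  With the default 60 kg adult,
#' class III gives 1.5 ug/kg bw/day = 0.0015 mg/kg bw/day.
#'
#' @param cramer_class `"I"`, `"II"` or `"III"`.
#' @param bw body weight in kg (> 0); defaults to the registry's default.
#' @param registry a [load_hazard_registry()] object.
#' @return List with `ug_kg_bw_day` and `mg_kg_bw_day`.
#' @export
ttc_threshold_per_bw <- function(cramer_class = c("III", "II", "I"),
                                 bw = NULL,
                                 registry = load_hazard_registry()) {
  cramer_class <- match.arg(cramer_class)
  bw <- bw %||% registry$ttc$default_bw_kg
  if (!is.numeric(bw) || bw <= 0)
    abort("body weight must be positive", class = "bpprisk_domain_error")
  per_person <- registry$ttc$thresholds_ug_person_day[[cramer_class]]
  ug <- per_person / bw
  list(ug_kg_bw_day = ug, mg_kg_bw_day = ug / 1000)
}
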