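#' Lower-bound / upper-bound substitution for censored concentrations
#'
#' Left-censored occurrence data are bounded by substitution: at the lower
#' bound (LB) every value below the LOD or LOQ is set to zero; at the upper
#' bound (UB) it is set to the corresponding LOD or LOQ value.  Detected
#' values are unchanged under both bounds, so a fully detected sample has
#' identical LB and UB representations.
#'
#' `apply_bounds()` works on the records of a single (food category,
#' analyte) pair and returns both bounds; [bounded_values()] is the vector
#' helper used throughout the package.
#'
#' @param records occurrence tibble (one category, one analyte).
#' @return An object of class `bpp_bounded`: list with `food_category`,
#'   `analyte`, `lb_values`, `ub_values` (equal length, element-wise
#'   `lb <= ub`).
#' @export
apply_bounds <- function(records) {
  validate_occurrence(records)
  if (nrow(records) == 0)
    abort("no records supplied", class = "bpprisk_usage_error")
  if (dplyr::n_distinct(records$food_category) != 1 ||
      dplyr::n_distinct(records$analyte) != 1)
    abort("apply_bounds() expects records of one (category, analyte) pair",
          class = "bpprisk_usage_error")
  structure(
    list(food_category = records$food_category[[1]],
         analyte = records$analyte[[1]],
         lb_values = bounded_values(records, "LB"),
         ub_values = bounded_values(records, "UB")),
    class = "bpp_bounded"
  )
}

#' @rdname apply_bounds
#' @param bound `"LB"` or `"UB"`.
#' @export
bounded_values <- function(records, bound = c("LB", "UB")) {
  bound <- match.arg(bound)
  v <- records$value_ng_per_g
  if (bound == "LB") {
    ifelse(records$status == "detected", v, 0)
  } else {
    ifelse(records$status == "detected", v,
           ifelse(records$status == "lt_lod",
                  records$lod_ng_per_g, records$loq_ng_per_g))
  }
}

#' Summary statistics for occurrence records
#'
#' Computes survey-style summary rows per (food category, analyte):
#' sample size, detection rate (percent), and min / max / arithmetic mean /
#' SD / geometric mean over the *detected* values only.  With zero detects
#' the detection rate is 0 and all value statistics are `NA`.
#'
#' @param records occurrence tibble (any number of category/analyte pairs).
#' @return A tibble with columns `food_category`, `analyte`, `n`,
#'   `detection_rate` (percent), `min`, `max`, `am`, `sd`, `gm` (ng/g).
#' @export
summarize_occurrence <- function(records) {
  validate_occurrence(records)
  if (nrow(records) == 0)
    abort("no records supplied", class = "bpprisk_usage_error")
  records |>
    dplyr::group_by(.data$food_category, .data$analyte) |>
    dplyr::summarise(
      n = dplyr::n(),
      detection_rate = 100 * sum(.data$status == "detected") / dplyr::n(),
      min = if (any(.data$status == "detected"))
        min(.data$value_ng_per_g, na.rm = TRUE) else NA_real_,
      max = if (any(.data$status == "detected"))
        max(.data$value_ng_per_g, na.rm = TRUE) else NA_real_,
      am = mean(.data$value_ng_per_g[.data$status == "detected"]),
      sd = sd(.data$value_ng_per_g[.data$status == "detected"]),
      gm = exp(mean(log(.data$value_ng_per_g[.data$status == "detected"]))),
      .groups = "drop"
    )
}

#' Select a concentration distribution by Kolmogorov-Smirnov fit
#'
#' Fits normal and lognormal candidates by maximum likelihood
#' (via \pkg{fitdistrplus}) and keeps the family with the larger
#' Kolmogorov-Smirnov p-value against its own fit.  The KS comparison is a
#' selection heuristic (parameters are estimated from the same data; no
#' Lilliefors correction), not a formal goodness-of-fit test.  Ties are
#' broken toward the lognormal, the conventional family for concentration
#' data.  If any value is nonpositive the lognormal candidate is skipped
#' with a warning and the normal fit is returned.
#'
#' @param values numeric vector, length >= 8.
#' @return A `bpp_dist` spec (also class `bpp_distribution`) carrying
#'   `family`, `param1`/`param2` (mean/sd for normal, meanlog/sdlog for
#'   lognormal), `ks_statistic` and `ks_pvalue`.
#' @export
fit_distribution <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 8)
    abort("need at least 8 values to select a distribution",
          class = "bpprisk_usage_error")
  if (sd(values) == 0)
    abort("values are constant; no non-degenerate distribution can be fitted",
          class = "bpprisk_degenerate_error")

  fit_one <- function(distname) {
    fit <- fitdistrplus::fitdist(values, distname, method = "mle")
    p <- as.list(fit$estimate)
    ks <- suppressWarnings(switch(distname,
      norm = stats::ks.test(values, "pnorm", p$mean, p$sd),
      lnorm = stats::ks.test(values, "plnorm", p$meanlog, p$sdlog)))
    spec <- dist_spec(if (distname == "norm") "normal" else "lognormal",
                      mean = p$mean, sd = p$sd,
                      meanlog = p$meanlog, sdlog = p$sdlog)
    spec$ks_statistic <- unname(ks$statistic)
    spec$ks_pvalue <- ks$p.value
    class(spec) <- c("bpp_distribution", class(spec))
    spec
  }

  norm_fit <- fit_one("norm")
  if (any(values <= 0)) {
    warn("nonpositive values present; lognormal candidate skipped",
         class = "bpprisk_lognormal_skipped")
    return(norm_fit)
  }
  lnorm_fit <- fit_one("lnorm")
  # tie (or better) goes to the lognormal: concentration data convention
  if (lnorm_fit$ks_pvalue >= norm_fit$ks_pvalue) lnorm_fit else norm_fit
}
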