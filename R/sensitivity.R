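#' Contribution of stochastic inputs to output variance
#'
#' Quantifies how much each stochastic input (body weight, per-category
#' intake rates, per-category concentrations) drives the spread of the
#' simulated dose.  The method is the normalized squared Spearman rank
#' correlation: for input `i` with rank correlation `r_i` against the
#' output, `contribution_i = 100 * r_i^2 / sum_j r_j^2` percent.  This is
#' the "contribution to variance" convention of spreadsheet Monte Carlo
#' tools.  The sign of `r_i` is retained as metadata (body weight divides
#' the dose, so its correlation is expected negative).  Inputs with
#' `|r| < 0.01` are reported as 0% rather than as noise; constant inputs
#' get a warning and 0%.
#'
#' @param input_draws named list of equal-length numeric vectors.
#' @param output_draws numeric vector (the simulated doses); must have
#'   nonzero variance.
#' @return An object of class `bpp_sensitivity`: tibble with `input`,
#'   `rank_correlation`, `contribution_pct` (descending), with a `method`
#'   attribute.
#' @export
contribution_to_variance <- function(input_draws, output_draws) {
  if (!is.list(input_draws) || is.null(names(input_draws)) ||
      any(names(input_draws) == ""))
    abort("input_draws must be a fully named list",
          class = "bpprisk_usage_error")
  n <- length(output_draws)
  if (n < 100)
    abort("need at least 100 draws", class = "bpprisk_usage_error")
  if (any(lengths(input_draws) != n))
    abort("all inputs must match the output length",
          class = "bpprisk_usage_error")
  if (sd(output_draws) == 0)
    abort("output has zero variance; nothing to attribute",
          class = "bpprisk_usage_error")

  r <- purrr::map_dbl(input_draws, function(x) {
    if (sd(x) == 0) {
      warn("constant input reported with zero contribution",
           class = "bpprisk_constant_input")
      return(0)
    }
    cor(x, output_draws, method = "spearman")
  })
  r[abs(r) < 0.01] <- 0
  denom <- sum(r^2)
  contribution <- if (denom > 0) 100 * r^2 / denom else {
    warn("no input correlates with the output; all contributions zero",
         class = "bpprisk_no_signal")
    r * 0
  }
  out <- tibble::tibble(input = names(input_draws),
                        rank_correlation = unname(r),
                        contribution_pct = unname(contribution))
  out <- dplyr::arrange(out, dplyr::desc(.data$contribution_pct))
  attr(out, "method") <- "normalized squared Spearman rank correlation"
  class(out) <- c("bpp_sensitivity", class(out))
  out
}

#' Sensitivity analysis of a simulated dose
#'
#' Runs [contribution_to_variance()] on the retained input draws of a
#' [simulate_add()] result (`keep_draws = TRUE`).  Inputs that are constant
#' by construction (point-mass concentrations in the regulatory-limit
#' scenario) are dropped before attribution.
#'
#' @param add a `bpp_add` carrying draws.
#' @return A `bpp_sensitivity` tibble with `analyte` and `age_group`
#'   columns prepended.
#' @export
add_sensitivity <- function(add) {
  stopifnot(inherits(add, "bpp_add"))
  if (is.null(add$draws))
    abort("simulate_add() must be run with keep_draws = TRUE",
          class = "bpprisk_usage_error")
  draws <- purrr::keep(add$draws, function(x) sd(x) > 0)
  out <- contribution_to_variance(draws, add$samples)
  out <- tibble::add_column(out, analyte = add$analyte,
                            age_group = add$age_group, .before = 1)
  class(out) <- c("bpp_sensitivity", "tbl_df", "tbl", "data.frame")
  attr(out, "method") <- "normalized squared Spearman rank correlation"
  out
}
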