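#' Distribution specifications
#'
#' Light-weight parametric distribution descriptors used for body weights
#' (normal), intake rates and concentrations (lognormal), fixed regulatory
#' values (point mass) and empirical resampling.
#'
#' @param family one of `"normal"`, `"lognormal"`, `"point"`, `"empirical"`.
#' @param mean,sd natural-scale parameters for `family = "normal"`
#'   (`sd = 0` gives a degenerate point mass at `mean`).
#' @param meanlog,sdlog log-scale parameters for `family = "lognormal"`;
#'   alternatively supply `gm` and `gsd` (geometric mean / geometric
#'   standard deviation), which are converted as `meanlog = log(gm)`,
#'   `sdlog = log(gsd)`.
#' @param gm,gsd geometric-scale parameterization of the lognormal.
#' @param value the location of a point mass.
#' @param values the data vector resampled by `family = "empirical"`.
#'
#' @return An object of class `bpp_dist`: a list with `family`, `param1`,
#'   `param2` (and `values` for the empirical family).
#' @export
dist_spec <- function(family = c("normal", "lognormal", "point", "empirical"),
                      mean = NULL, sd = NULL, meanlog = NULL, sdlog = NULL,
                      gm = NULL, gsd = NULL, value = NULL, values = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    normal = {
      stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
      list(family = family, param1 = mean, param2 = sd)
    },
    lognormal = {
      gm_exact <- NULL
      if (!is.null(gm)) {
        stopifnot(gm > 0, gsd >= 1)
        meanlog <- log(gm); sdlog <- log(gsd)
        gm_exact <- gm  # keeps degenerate (gsd = 1) draws exact
      }
      stopifnot(is.numeric(meanlog), is.numeric(sdlog), sdlog >= 0)
      list(family = family, param1 = meanlog, param2 = sdlog,
           gm = gm_exact)
    },
    point = {
      stopifnot(is.numeric(value))
      list(family = family, param1 = value, param2 = 0)
    },
    empirical = {
      stopifnot(is.numeric(values), length(values) >= 1)
      list(family = family, param1 = NA_real_, param2 = NA_real_,
           values = values)
    }
  )
  structure(spec, class = "bpp_dist")
}

#' Draw from a distribution specification
#'
#' @param spec a [dist_spec()] object (or the fit returned by
#'   [fit_distribution()], which shares the same structure).
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "bpp_dist"), n >= 0)
  switch(spec$family,
    normal = if (spec$param2 == 0) rep(spec$param1, n)
             else rnorm(n, spec$param1, spec$param2),
    lognormal = if (spec$param2 == 0) rep(spec$gm %||% exp(spec$param1), n)
                else rlnorm(n, spec$param1, spec$param2),
    point = rep(spec$param1, n),
    empirical = spec$values[sample.int(length(spec$values), n, replace = TRUE)],
    mixture = {
      u <- runif(n)
      b <- draw_dist(spec$body, n)
      tail_draw <- spec$tail_values[
        sample.int(length(spec$tail_values), n, replace = TRUE)]
      ifelse(u < spec$p_body, b, tail_draw)
    }
  )
}

#' @export
print.bpp_dist <- function(x, ...) {
  cat("<bpp_dist ", x$family, "> ", sep = "")
  if (x$family == "empirical") {
    cat("n = ", length(x$values), "\n", sep = "")
  } else if (x$family == "mixture") {
    cat("p_body = ", signif(x$p_body, 3), ", body = ", x$body$family,
        ", tail n = ", length(x$tail_values), "\n", sep = "")
  } else {
    cat("param1 = ", signif(x$param1, 4), ", param2 = ",
        signif(x$param2, 4), "\n", sep = "")
  }
  if (!is.null(x$ks_pvalue))
    cat("  KS D = ", signif(x$ks_statistic, 3), ", p = ",
        signif(x$ks_pvalue, 3), "\n", sep = "")
  invisible(x)
}

# Positive draws from a (possibly degenerate) normal body-weight spec:
# nonpositive draws are rejected and redrawn, which is negligible mass for
# realistic anthropometric parameters.
draw_positive_normal <- function(spec, n, max_tries = 100L) {
  out <- draw_dist(spec, n)
  tries <- 0L
  while (any(bad <- out <= 0)) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort("body-weight distribution places too much mass at <= 0",
            class = "bpprisk_domain_error")
    out[bad] <- draw_dist(spec, sum(bad))
  }
  out
}
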