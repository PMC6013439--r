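#' Loss-on-ignition to organic-carbon conversion coefficients
#'
#' Quadratic coefficients for predicting fraction organic carbon (OC) from
#' fraction organic matter (OM) measured by loss on ignition:
#' \eqn{OC = a \cdot OM^2 + b \cdot OM + c}.
#'
#' Two sets are available. The default (`"consistent"`) uses a linear
#' coefficient of 0.421, which is internally consistent with the organic
#' self-packing density upper limit on carbon density
#' (\eqn{k_1 \times OC(1) \approx 0.098 \times 0.487 \approx 0.048}
#' gC cm\eqn{^{-3}}) and with Craft-type linear conversions near 0.40.
#' The `"printed"` set keeps the alternative linear coefficient 0.0421,
#' retained for reproducing calculations made with that value.
#'
#' @param set Either `"consistent"` (default) or `"printed"`.
#' @return Named numeric vector with elements `a`, `b`, `c`.
#' @export
#' @examples
#' oc_coefficients()
#' oc_coefficients("printed")
oc_coefficients <- function(set = c("consistent", "printed")) {
  set <- match.arg(set)
  switch(set,
    consistent = c(a = 0.074, b = 0.421,  c = -0.0080),
    printed    = c(a = 0.074, b = 0.0421, c = -0.0080)
  )
}

#' Convert organic-matter fraction to organic-carbon fraction
#'
#' Evaluates the quadratic LOI-to-OC conversion and clamps the result to
#' \[0, 1\]. The raw quadratic is slightly negative for OM below about 0.018,
#' which is unphysical; clamping at zero keeps downstream carbon densities
#' non-negative.
#'
#' @param om_fraction Numeric vector of organic-matter fractions in \[0, 1\].
#' @param coefs Coefficient vector `c(a, b, c)`; see [oc_coefficients()].
#' @param clamp Clamp output to \[0, 1\] (default `TRUE`).
#' @return Numeric vector of organic-carbon fractions. `NA` inputs propagate.
#' @export
#' @examples
#' om_to_oc(c(0, 0.5, 1))
om_to_oc <- function(om_fraction, coefs = oc_coefficients(), clamp = TRUE) {
  bad <- !is.na(om_fraction) & (om_fraction < 0 | om_fraction > 1)
  if (any(bad))
    stop("om_fraction must lie in [0, 1]; offending values: ",
         paste(utils::head(om_fraction[bad], 3), collapse = ", "))
  oc <- coefs[["a"]] * om_fraction^2 + coefs[["b"]] * om_fraction + coefs[["c"]]
  if (clamp) oc <- pmin(pmax(oc, 0), 1)
  oc
}

#' Carbon density from bulk density and organic fractions
#'
#' Carbon density (gC cm\eqn{^{-3}}) is bulk density times fraction organic
#' carbon. When an OM (loss-on-ignition) measurement is present, OC is always
#' recomputed from the quadratic conversion — even if a measured OC value also
#' exists — so that all cores share one conversion. Measured OC is used only
#' when OM is absent. If both fractions are missing the result is `NA`
#' (a missing-data signal, not an error).
#'
#' @param bulk_density Bulk density, g cm\eqn{^{-3}} (vector).
#' @param om_fraction Organic-matter fraction in \[0, 1\] or `NA`.
#' @param oc_fraction Measured organic-carbon fraction in \[0, 1\] or `NA`.
#' @param coefs LOI-to-OC conversion coefficients.
#' @return Numeric vector of carbon densities, gC cm\eqn{^{-3}}.
#' @export
#' @examples
#' compute_carbon_density(0.2, NA, 0.10)  # 0.020
compute_carbon_density <- function(bulk_density, om_fraction = NA,
                                   oc_fraction = NA,
                                   coefs = oc_coefficients()) {
  n <- max(length(bulk_density), length(om_fraction), length(oc_fraction))
  bd <- rep_len(bulk_density, n)
  om <- rep_len(om_fraction, n)
  oc <- rep_len(oc_fraction, n)
  if (any(bd < 0, na.rm = TRUE)) stop("bulk_density must be >= 0")
  oc_used <- ifelse(!is.na(om), om_to_oc(om, coefs), oc)
  bd * oc_used
}

# Length of overlap between [a1,a2) and [b1,b2)
.overlap <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

#' Aggregate a soil-core profile to standardized 10-cm increments
#'
#' Depth-weighted averaging of bulk density, organic matter and measured
#' organic carbon over half-open 10-cm slabs \[0,10), \[10,20), ... \[90,100)
#' cm, equivalent to normalizing the sampling intervals to 1-cm increments and
#' summing within each slab. If the deepest sample leaves a terminal slab
#' partially covered but measured data span more than 5 cm of it, the deepest
#' sample's values are carried to the slab bottom (flagged `extrapolated`);
#' a terminal slab with 5 cm or less of data is dropped as no-data.
#'
#' @param core A data frame with one row per measured interval; required
#'   columns `depth_top_cm`, `depth_bottom_cm`, `bulk_density_g_cm3`,
#'   `om_fraction`, `oc_fraction` (the latter three may be `NA`). Metadata
#'   columns `core_id`, `submitter_id`, `climate`, `sal_veg`,
#'   `position_quality` are carried through when present.
#' @param max_depth Bottom of the profile considered, cm (default 100).
#' @param threshold_om Organic/mineral classification threshold applied to
#'   slab OM (default 0.132; strictly greater than is organic).
#' @param coefs LOI-to-OC conversion coefficients for the slab carbon density.
#' @return Data frame with one row per populated slab: `increment_top`,
#'   `bulk_density`, `om_fraction`, `oc_fraction` (value used for carbon),
#'   `carbon_density`, `soil_class`, `coverage` (cm of measured data) and
#'   `extrapolated`, plus any carried metadata.
#' @export
aggregate_to_increments <- function(core, max_depth = 100,
                                    threshold_om = 0.132,
                                    coefs = oc_coefficients()) {
  req <- c("depth_top_cm", "depth_bottom_cm")
  if (!all(req %in% names(core))) stop("core lacks depth columns")
  if (nrow(core) < 1) stop("core has no samples")
  core <- core[order(core$depth_top_cm), , drop = FALSE]
  if (any(core$depth_bottom_cm <= core$depth_top_cm))
    stop("each sample must have depth_bottom > depth_top")
  if (nrow(core) > 1 &&
      any(core$depth_top_cm[-1] < core$depth_bottom_cm[-nrow(core)] - 1e-9))
    stop("overlapping sample intervals")

  bd <- if ("bulk_density_g_cm3" %in% names(core)) core$bulk_density_g_cm3 else rep(NA_real_, nrow(core))
  om <- if ("om_fraction" %in% names(core)) core$om_fraction else rep(NA_real_, nrow(core))
  oc <- if ("oc_fraction" %in% names(core)) core$oc_fraction else rep(NA_real_, nrow(core))

  core_bottom <- max(core$depth_bottom_cm)
  deepest <- which.max(core$depth_bottom_cm)
  tops <- seq(0, max_depth - 10, by = 10)

  wmean <- function(x, w) {
    ok <- !is.na(x) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }

  out <- vector("list", length(tops))
  for (i in seq_along(tops)) {
    lo <- tops[i]; hi <- lo + 10
    w <- .overlap(core$depth_top_cm, core$depth_bottom_cm, lo, hi)
    coverage <- sum(w)
    if (coverage <= 0) next
    extrapolated <- FALSE
    # terminal slab: core ends inside this slab
    if (core_bottom > lo && core_bottom < hi) {
      if (coverage > 5) {
        w[deepest] <- w[deepest] + (hi - core_bottom)
        extrapolated <- TRUE
      } else {
        next  # <= 50% terminal coverage: no-data slab
      }
    }
    slab_bd <- wmean(bd, w)
    slab_om <- wmean(om, w)
    slab_oc <- wmean(oc, w)
    oc_used <- if (!is.na(slab_om)) om_to_oc(slab_om, coefs) else slab_oc
    cd <- if (!is.na(slab_bd) && !is.na(oc_used)) slab_bd * oc_used else NA_real_
    soil <- if (is.na(slab_om)) "unknown" else if (slab_om > threshold_om) "organic" else "mineral"
    out[[i]] <- data.frame(
      increment_top = lo, bulk_density = slab_bd, om_fraction = slab_om,
      oc_fraction = oc_used, carbon_density = cd, soil_class = soil,
      coverage = coverage, extrapolated = extrapolated
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(increment_top = numeric(0), bulk_density = numeric(0),
                      om_fraction = numeric(0), oc_fraction = numeric(0),
                      carbon_density = numeric(0), soil_class = character(0),
                      coverage = numeric(0), extrapolated = logical(0))
  meta <- intersect(c("core_id", "submitter_id", "climate", "sal_veg",
                      "position_quality"), names(core))
  for (m in rev(meta)) out[[m]] <- rep(core[[m]][1], nrow(out))
  out[, c(meta, setdiff(names(out), meta))]
}

#' Aggregate every core in a dataset to 10-cm increments
#'
#' @param dataset Core table (one row per measured interval, multiple cores).
#' @param ... Passed to [aggregate_to_increments()].
#' @return Combined increment table with a `depth_increment` factor label
#'   (e.g. `"0-10"`).
#' @export
aggregate_cores <- function(dataset, ...) {
  stopifnot("core_id" %in% names(dataset))
  parts <- lapply(split(dataset, dataset$core_id),
                  aggregate_to_increments, ...)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out$depth_increment <- factor(
    sprintf("%d-%d", out$increment_top, out$increment_top + 10L),
    levels = sprintf("%d-%d", seq(0, 90, 10), seq(10, 100, 10))
  )
  out
}

#' Fit a probability distribution to carbon-density values
#'
#' Fits either a normal distribution truncated at zero (maximum likelihood,
#' support \[0, Inf)) or a log-normal distribution. For the log-normal family,
#' exact zeros are treated as below a detection limit and recast to
#' 0.01 kgC m\eqn{^{-3}} (= 1e-5 gC cm\eqn{^{-3}}) before fitting.
#' Log-likelihoods are reported so the two families can be compared on the
#' same data.
#'
#' @param values Non-negative carbon densities, gC cm\eqn{^{-3}}.
#' @param family `"truncated_normal"` or `"log_normal"`.
#' @return Object of class `carbon_distribution`: list with `family`, `mean`,
#'   `sd` (distribution parameters; for the log-normal these are the implied
#'   natural-scale mean and s.d.), `n`, `se` (= sd/sqrt(n)),
#'   `log_likelihood`, and the raw `params`.
#' @export
fit_carbon_distribution <- function(values,
                                    family = c("truncated_normal",
                                               "log_normal")) {
  family <- match.arg(family)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (any(values < 0)) stop("values must be non-negative")
  if (stats::sd(values) == 0) stop("degenerate fit: all values identical")

  if (family == "truncated_normal") {
    nll <- function(p) {
      mu <- p[1]; sigma <- exp(p[2])
      -sum(stats::dnorm(values, mu, sigma, log = TRUE) -
             stats::pnorm(0, mu, sigma, lower.tail = FALSE, log.p = TRUE))
    }
    opt <- stats::optim(c(mean(values), log(stats::sd(values))), nll,
                        method = "Nelder-Mead")
    mu <- opt$par[1]; sigma <- exp(opt$par[2])
    fit <- list(family = family, mean = mu, sd = sigma, n = n,
                se = sigma / sqrt(n), log_likelihood = -opt$value,
                params = c(mean = mu, sd = sigma))
  } else {
    v <- ifelse(values == 0, 1e-5, values)
    fd <- MASS::fitdistr(v, "lognormal")
    ml <- fd$estimate[["meanlog"]]; sl <- fd$estimate[["sdlog"]]
    m <- exp(ml + sl^2 / 2)
    s <- sqrt((exp(sl^2) - 1) * exp(2 * ml + sl^2))
    fit <- list(family = family, mean = m, sd = s, n = n, se = s / sqrt(n),
                log_likelihood = as.numeric(fd$loglik),
                params = c(meanlog = ml, sdlog = sl))
  }
  class(fit) <- "carbon_distribution"
  fit
}

#' @export
print.carbon_distribution <- function(x, ...) {
  cat(sprintf("%s fit: mean %.4g, sd %.4g gC cm^-3 (n = %d, se = %.3g)\n",
              x$family, x$mean, x$sd, x$n, x$se))
  cat(sprintf("log-likelihood: %.2f\n", x$log_likelihood))
  invisible(x)
}

#' Standard error of a mean
#'
#' @param sd Sample standard deviation.
#' @param n Sample size.
#' @return `sd / sqrt(n)`.
#' @export
#' @examples
#' standard_error(0.013, 8280)
standard_error <- function(sd, n) {
  stopifnot(n >= 1, sd >= 0)
  sd / sqrt(n)
}

#' Per-increment summary of depth profiles
#'
#' Mean, standard error and n of bulk density, organic matter and carbon
#' density for each 10-cm slab, in depth order. The standard error is
#' reported `NA` where only one observation is available.
#'
#' @param records Increment table from [aggregate_cores()].
#' @return Data frame with one row per populated slab, ordered 0-10 ... 90-100.
#' @export
summarize_depth_profiles <- function(records) {
  stopifnot("increment_top" %in% names(records))
  sumfun <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    c(mean = if (n) mean(x) else NA_real_,
      se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
      n = n)
  }
  tops <- sort(unique(records$increment_top))
  rows <- lapply(tops, function(t) {
    r <- records[records$increment_top == t, ]
    bd <- sumfun(r$bulk_density); om <- sumfun(r$om_fraction)
    cd <- sumfun(r$carbon_density)
    data.frame(increment_top = t,
               bd_mean = bd[1], bd_se = bd[2], bd_n = bd[3],
               om_mean = om[1], om_se = om[2], om_n = om[3],
               cd_mean = cd[1], cd_se = cd[2], cd_n = cd[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
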