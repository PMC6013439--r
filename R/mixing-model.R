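#' Ideal mixing model bulk density
#'
#' Bulk density as a function of organic-matter fraction under the ideal
#' mixing model, \eqn{BD = 1 / (OM/k_1 + (1-OM)/k_2)}, where \eqn{k_1} and
#' \eqn{k_2} are the self-packing densities of pure organic and pure mineral
#' matter (g cm\eqn{^{-3}}).
#'
#' @param om Organic-matter fraction in \[0, 1\].
#' @param k1,k2 Self-packing densities, g cm\eqn{^{-3}}.
#' @return Bulk density, g cm\eqn{^{-3}}.
#' @export
#' @examples
#' mixing_bd(c(0, 0.5, 1), k1 = 0.098, k2 = 1.67)
mixing_bd <- function(om, k1, k2) 1 / (om / k1 + (1 - om) / k2)

#' Fit the ideal mixing model
#'
#' Nonlinear least squares of bulk density on organic-matter fraction under
#' the ideal mixing model. Initialization at (k1, k2) = (0.1, 1.5), near
#' physically typical tidal-wetland values.
#'
#' @param om Organic-matter fractions in \[0, 1\] (or a data frame holding
#'   columns `om_fraction` and `bulk_density`).
#' @param bd Bulk densities, g cm\eqn{^{-3}}; ignored when `om` is a data
#'   frame.
#' @param start Named start values for the optimizer.
#' @return Object of class `mixing_fit`: `k1`, `k2`, `se_k1`, `se_k2`,
#'   `residual_sd` (s.d. of BD residuals, population denominator n),
#'   `n`, and the underlying `nls` fit.
#' @seealso [predict.mixing_fit()], [bootstrap_mixing_fit()], [predict_omd()]
#' @export
#' @examples
#' om <- seq(0.02, 0.95, length.out = 50)
#' fit <- mixing_model(om, mixing_bd(om, 0.098, 1.67))
#' coef(fit)
mixing_model <- function(om, bd = NULL, start = c(k1 = 0.1, k2 = 1.5)) {
  if (is.data.frame(om)) {
    bd <- om$bulk_density
    om <- om$om_fraction
  }
  keep <- !is.na(om) & !is.na(bd)
  om <- om[keep]; bd <- bd[keep]
  if (length(om) < 3) stop("need at least 3 complete OM-BD pairs")
  if (any(om < 0 | om > 1)) stop("OM must lie in [0, 1]")
  if (any(bd <= 0)) stop("BD must be positive")
  dat <- data.frame(om = om, bd = bd)
  fit <- tryCatch(
    minpack.lm::nlsLM(bd ~ 1 / (om / k1 + (1 - om) / k2),
                      data = dat, start = as.list(start),
                      lower = c(1e-4, 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("mixing model failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(k1 = NA_real_, k2 = NA_real_))
  res <- stats::residuals(fit)
  out <- list(k1 = unname(cf["k1"]), k2 = unname(cf["k2"]),
              se_k1 = unname(se["k1"]), se_k2 = unname(se["k2"]),
              ci_k1 = NULL, ci_k2 = NULL,
              residual_sd = sqrt(mean(res^2)),
              n = length(om), fit = fit)
  class(out) <- "mixing_fit"
  out
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat("Ideal mixing model fit\n")
  cat(sprintf("  k1 (organic): %.4g g cm^-3 (s.e. %.3g)\n", x$k1, x$se_k1))
  cat(sprintf("  k2 (mineral): %.4g g cm^-3 (s.e. %.3g)\n", x$k2, x$se_k2))
  if (!is.null(x$ci_k1))
    cat(sprintf("  95%% CI k1: [%.4g, %.4g]  k2: [%.4g, %.4g]\n",
                x$ci_k1[1], x$ci_k1[2], x$ci_k2[1], x$ci_k2[2]))
  cat(sprintf("  residual s.d.: %.4g g cm^-3 (n = %d)\n",
              x$residual_sd, x$n))
  invisible(x)
}

#' @export
coef.mixing_fit <- function(object, ...) c(k1 = object$k1, k2 = object$k2)

#' Predict bulk density or organic-matter density from a mixing fit
#'
#' @param object A `mixing_fit`.
#' @param newdata Numeric vector of OM fractions, or a data frame with an
#'   `om_fraction` column.
#' @param type `"bd"` for bulk density (the ideal mixing model) or `"omd"`
#'   for organic-matter density (OM times the mixing-model bulk density).
#' @param ... Unused.
#' @return Numeric vector, g cm\eqn{^{-3}} (g OM cm\eqn{^{-3}} for `"omd"`).
#' @export
predict.mixing_fit <- function(object, newdata, type = c("bd", "omd"), ...) {
  type <- match.arg(type)
  om <- if (is.data.frame(newdata)) newdata$om_fraction else newdata
  bd <- mixing_bd(om, object$k1, object$k2)
  if (type == "omd") om * bd else bd
}

#' Organic-matter density model
#'
#' Mass of organic matter per unit soil volume implied by the ideal mixing
#' model, \eqn{OMD = OM / (OM/k_1 + (1-OM)/k_2)}. OMD increases monotonically
#' with OM and approaches the organic self-packing density \eqn{k_1} at
#' OM = 1, which sets the theoretical upper limit on organic-matter (and
#' hence carbon) density in organic soils.
#'
#' @param om_fraction OM fraction in \[0, 1\].
#' @param fit A `mixing_fit`, or a named vector/list with `k1`, `k2`.
#' @return Organic-matter density, g OM cm\eqn{^{-3}}.
#' @export
#' @examples
#' predict_omd(1, c(k1 = 0.098, k2 = 1.67))  # = k1
predict_omd <- function(om_fraction, fit) {
  k1 <- if (inherits(fit, "mixing_fit")) fit$k1 else fit[["k1"]]
  k2 <- if (inherits(fit, "mixing_fit")) fit$k2 else fit[["k2"]]
  om_fraction * mixing_bd(om_fraction, k1, k2)
}

#' Bootstrap uncertainty for the mixing model
#'
#' Case-resampling bootstrap (appropriate for heteroscedastic field data) of
#' the ideal mixing model, returning percentile 95% confidence intervals for
#' k1 and k2. Deterministic given `seed`.
#'
#' @param om,bd OM-BD pairs (or a data frame, as in [mixing_model()]).
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A `mixing_fit` with `ci_k1`, `ci_k2` percentile intervals,
#'   bootstrap standard errors `se_k1`/`se_k2`, and the replicate draws in
#'   `boot` (matrix with columns k1, k2).
#' @export
bootstrap_mixing_fit <- function(om, bd = NULL, n_iter = 1000, seed = 1,
                                 conf = 0.95) {
  if (is.data.frame(om)) {
    bd <- om$bulk_density
    om <- om$om_fraction
  }
  keep <- !is.na(om) & !is.na(bd)
  om <- om[keep]; bd <- bd[keep]
  if (length(om) < 10) stop("need at least 10 pairs to bootstrap")
  base <- mixing_model(om, bd)
  n <- length(om)
  draws <- matrix(NA_real_, n_iter, 2, dimnames = list(NULL, c("k1", "k2")))
  rng <- .new_rng(seed)
  warm <- c(k1 = base$k1, k2 = base$k2)
  for (b in seq_len(n_iter)) {
    idx <- sample.int(n, n, replace = TRUE)
    f <- tryCatch(mixing_model(om[idx], bd[idx], start = warm),
                  error = function(e) NULL)
    if (!is.null(f)) draws[b, ] <- c(f$k1, f$k2)
  }
  .restore_rng(rng)
  fail <- mean(is.na(draws[, 1]))
  if (fail > 0.10)
    stop(sprintf("bootstrap unstable: %.0f%% of iterations failed", 100 * fail))
  a <- (1 - conf) / 2
  base$ci_k1 <- unname(stats::quantile(draws[, "k1"], c(a, 1 - a), na.rm = TRUE))
  base$ci_k2 <- unname(stats::quantile(draws[, "k2"], c(a, 1 - a), na.rm = TRUE))
  base$se_k1 <- stats::sd(draws[, "k1"], na.rm = TRUE)
  base$se_k2 <- stats::sd(draws[, "k2"], na.rm = TRUE)
  base$boot <- draws
  base$n_iter <- n_iter
  base
}

#' Fit the mixing model separately per 10-cm depth slab
#'
#' Independent ideal-mixing-model fits for each depth increment, plus a
#' Spearman rank correlation of each self-packing density against slab depth
#' as a simple trend diagnostic.
#'
#' @param increments Increment table (needs `increment_top`, `om_fraction`,
#'   `bulk_density`).
#' @param min_n Minimum pairs per slab; slabs below this are skipped with a
#'   warning.
#' @return List with `fits` (named list of `mixing_fit` per slab), `table`
#'   (data frame of k1/k2 per slab) and `trend` (Spearman rho of k1 and k2
#'   vs depth).
#' @export
fit_per_depth_slabs <- function(increments, min_n = 3) {
  tops <- sort(unique(increments$increment_top))
  fits <- list(); rows <- list()
  for (t in tops) {
    r <- increments[increments$increment_top == t, ]
    r <- r[!is.na(r$om_fraction) & !is.na(r$bulk_density), ]
    if (nrow(r) < min_n) {
      warning(sprintf("slab %d-%d cm has fewer than %d pairs; skipped",
                      t, t + 10, min_n))
      next
    }
    f <- mixing_model(r$om_fraction, r$bulk_density)
    fits[[sprintf("%d-%d", t, t + 10)]] <- f
    rows[[length(rows) + 1]] <- data.frame(increment_top = t, k1 = f$k1,
                                           k2 = f$k2, n = f$n)
  }
  tab <- do.call(rbind, rows)
  trend <- c(k1 = NA_real_, k2 = NA_real_)
  if (!is.null(tab) && nrow(tab) >= 3) {
    trend["k1"] <- stats::cor(tab$increment_top, tab$k1, method = "spearman")
    trend["k2"] <- stats::cor(tab$increment_top, tab$k2, method = "spearman")
  }
  list(fits = fits, table = tab, trend = trend)
}

# SSE profile of the continuous two-segment regression over a breakpoint grid.
# Returns the grid and SSE vector; ties in the minimum break toward smaller OM.
.segmented_sse <- function(x, y, grid) {
  sse <- vapply(grid, function(bp) {
    X <- cbind(1, x, pmax(x - bp, 0))
    f <- stats::lm.fit(X, y)
    sum(f$residuals^2)
  }, numeric(1))
  sse
}

#' Detect an organic/mineral threshold by segmented regression
#'
#' Fits a continuous two-segment linear model of carbon density on
#' organic-matter fraction, choosing the breakpoint by exhaustive grid search
#' (OM 0.02 to 0.90, step 0.001, ties toward the smaller OM) minimizing the
#' residual sum of squares. A case-resampling bootstrap gives a percentile
#' confidence interval. The variance explained by the resulting binary
#' organic/mineral classification (one-way ANOVA R-squared of carbon density
#' on the two-class factor) is reported at the fitted breakpoint and at the
#' conventional 0.20 and 0.35 thresholds.
#'
#' @param om OM fractions in \[0, 1\].
#' @param carbon_density Carbon densities, gC cm\eqn{^{-3}}.
#' @param n_boot Bootstrap iterations (default 500).
#' @param seed Integer seed.
#' @param grid Breakpoint candidate grid.
#' @return Object of class `threshold_fit` with `breakpoint_om`, `ci`,
#'   `r2_at_breakpoint`, `r2_at_020`, `r2_at_035`, the segment coefficients
#'   and bootstrap draws.
#' @export
fit_segmented_threshold <- function(om, carbon_density, n_boot = 500,
                                    seed = 1,
                                    grid = seq(0.02, 0.90, by = 0.001)) {
  keep <- !is.na(om) & !is.na(carbon_density)
  x <- om[keep]; y <- carbon_density[keep]
  if (length(x) < 20) stop("need at least 20 points")
  if (min(x) > 0.132 || max(x) < 0.132)
    warning("OM values do not span the organic/mineral region")

  pick <- function(x, y) {
    sse <- .segmented_sse(x, y, grid)
    grid[which.min(sse)]  # which.min takes the first = smallest OM on ties
  }
  bp <- pick(x, y)

  # interior-minimum check: SSE at the ends should not be the global minimum
  sse <- .segmented_sse(x, y, grid)
  if (which.min(sse) %in% c(1L, length(grid)))
    warning("no interior SSE minimum; breakpoint estimate is a boundary value")

  rng <- .new_rng(seed)
  n <- length(x)
  draws <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    pick(x[idx], y[idx])
  }, numeric(1))
  .restore_rng(rng)

  class_r2 <- function(thr) {
    cl <- factor(x > thr, levels = c(FALSE, TRUE))
    if (nlevels(droplevels(cl)) < 2) return(NA_real_)
    a <- stats::anova(stats::lm(y ~ cl))
    a[["Sum Sq"]][1] / sum(a[["Sum Sq"]])
  }

  X <- cbind(1, x, pmax(x - bp, 0))
  cf <- stats::lm.fit(X, y)$coefficients
  out <- list(breakpoint_om = bp,
              ci = unname(stats::quantile(draws, c(0.025, 0.975))),
              r2_at_breakpoint = class_r2(bp),
              r2_at_020 = class_r2(0.20),
              r2_at_035 = class_r2(0.35),
              coefficients = c(intercept = cf[1], slope1 = cf[2],
                               slope_change = cf[3]),
              boot = draws, n = n)
  class(out) <- "threshold_fit"
  out
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("Segmented threshold: OM = %.1f%% (95%% CI %.1f%% to %.1f%%)\n",
              100 * x$breakpoint_om, 100 * x$ci[1], 100 * x$ci[2]))
  cat(sprintf("Classification R^2: %.2f at breakpoint, %.2f at 20%%, %.2f at 35%%\n",
              x$r2_at_breakpoint, x$r2_at_020, x$r2_at_035))
  invisible(x)
}
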