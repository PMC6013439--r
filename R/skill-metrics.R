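#' Standardized model-skill scores
#'
#' Target-diagram skill metrics of modeled against reference values, all
#' normalized by the reference standard deviation \eqn{\sigma_r}:
#' normalized bias \eqn{B^* = (\mu_m - \mu_r)/\sigma_r}; correlation
#' \eqn{R}; normalized s.d. \eqn{\sigma^* = \sigma_m/\sigma_r}; unbiased
#' RMSE \eqn{RMSE^{*\prime} = \sqrt{1 + \sigma^{*2} - 2\sigma^* R}}; and
#' total \eqn{RMSE^* = \sqrt{RMSE^{*\prime 2} + B^{*2}}}. Standard
#' deviations use the population denominator \eqn{n}, consistent with the
#' \eqn{1/n} correlation definition; with that convention
#' \eqn{RMSE^{*\prime}} equals the direct standardized RMSE of the
#' mean-centred series, and a perfect model scores 0 on every error metric.
#' \eqn{RMSE^* < 1} means the model outperforms using the reference mean.
#'
#' @param modeled,reference Paired numeric vectors (n >= 2); the reference
#'   must have positive spread.
#' @return Object of class `skill_scores`: `bias_star`, `correlation`,
#'   `sigma_star`, `rmse_prime_star`, `rmse_star`, `sign_convention`
#'   (sign of \eqn{\sigma_m - \sigma_r}, used to sign the target-diagram
#'   x-axis) and `n`.
#' @export
#' @examples
#' skill_scores(1:10, 1:10)
skill_scores <- function(modeled, reference) {
  if (length(modeled) != length(reference))
    stop("modeled and reference must be paired vectors of equal length")
  keep <- !is.na(modeled) & !is.na(reference)
  m <- modeled[keep]; r <- reference[keep]
  n <- length(m)
  if (n < 2) stop("need at least 2 paired values")
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  mu_m <- mean(m); mu_r <- mean(r)
  s_m <- sd_pop(m); s_r <- sd_pop(r)
  if (s_r == 0) stop("reference standard deviation is zero")
  bias_star <- (mu_m - mu_r) / s_r
  R <- if (s_m == 0) 0 else mean((m - mu_m) * (r - mu_r)) / (s_m * s_r)
  sigma_star <- s_m / s_r
  rmse_prime <- sqrt(max(1 + sigma_star^2 - 2 * sigma_star * R, 0))
  out <- list(bias_star = bias_star, correlation = R,
              sigma_star = sigma_star, rmse_prime_star = rmse_prime,
              rmse_star = sqrt(rmse_prime^2 + bias_star^2),
              sign_convention = sign(s_m - s_r), n = n)
  class(out) <- "skill_scores"
  out
}

#' @export
print.skill_scores <- function(x, ...) {
  cat(sprintf(
    "skill: B* %.3f, R %.3f, sigma* %.3f, RMSE*' %.3f, RMSE* %.3f (n = %d)\n",
    x$bias_star, x$correlation, x$sigma_star, x$rmse_prime_star,
    x$rmse_star, x$n))
  invisible(x)
}

#' Evaluate a mapping strategy per depth slab
#'
#' Computes [skill_scores()] separately for each 10-cm depth increment and
#' flags the slabs where the strategy beats the reference-mean baseline
#' (\eqn{RMSE^* < 1}).
#'
#' @param modeled,reference Paired values.
#' @param increment_top Slab identifier per pair (cm, 0/10/.../90).
#' @param min_n Minimum pairs per slab to score it.
#' @return Object of class `strategy_skill`: data frame `table` with one row
#'   per scored slab (`increment_top`, the five scores, `signed_rmse_prime`
#'   for target-diagram x-coordinates, `n`, `better_than_mean`) and the
#'   per-slab `skill_scores` in `scores`.
#' @export
evaluate_strategy <- function(modeled, reference, increment_top,
                              min_n = 2) {
  stopifnot(length(modeled) == length(reference),
            length(modeled) == length(increment_top))
  tops <- sort(unique(increment_top))
  scores <- list(); rows <- list()
  for (t in tops) {
    i <- which(increment_top == t & !is.na(modeled) & !is.na(reference))
    if (length(i) < min_n) next
    s <- skill_scores(modeled[i], reference[i])
    scores[[as.character(t)]] <- s
    rows[[length(rows) + 1]] <- data.frame(
      increment_top = t, bias_star = s$bias_star,
      correlation = s$correlation, sigma_star = s$sigma_star,
      rmse_prime_star = s$rmse_prime_star, rmse_star = s$rmse_star,
      signed_rmse_prime = s$sign_convention * s$rmse_prime_star,
      n = s$n, better_than_mean = s$rmse_star < 1)
  }
  if (!length(rows)) stop("no slab with enough paired data")
  out <- list(table = do.call(rbind, rows), scores = scores)
  class(out) <- "strategy_skill"
  out
}

#' @export
print.strategy_skill <- function(x, ...) {
  print(x$table, digits = 3, row.names = FALSE)
  v <- classify_accuracy_precision(x)
  cat(v$verdict, "\n")
  invisible(x)
}

#' Qualitative accurate/precise classification of a strategy
#'
#' A strategy is accurate when \eqn{|B^*| < 1} for every scored depth
#' increment, and precise when \eqn{RMSE^{*\prime} < 1} for every scored
#' increment.
#'
#' @param per_slab_scores A `strategy_skill` or its `table` data frame.
#' @return List with logicals `accurate`, `precise` and a `verdict` string.
#' @export
classify_accuracy_precision <- function(per_slab_scores) {
  tab <- if (inherits(per_slab_scores, "strategy_skill"))
    per_slab_scores$table else per_slab_scores
  accurate <- all(abs(tab$bias_star) < 1)
  precise <- all(tab$rmse_prime_star < 1)
  verdict <- if (accurate && precise) "Accurate and precise"
  else if (accurate) "Accurate but not precise"
  else {
    dir <- if (mean(tab$bias_star) > 0) "Positively biased"
    else "Negatively biased"
    if (precise) paste(dir, "but precise") else paste(dir, "and not precise")
  }
  list(accurate = accurate, precise = precise, verdict = verdict)
}

#' Target-diagram coordinates
#'
#' X is the unbiased RMSE* signed by whether the modeled or the reference
#' series has the larger standard deviation; Y is the normalized bias.
#'
#' @param strategy_skill A `strategy_skill`.
#' @return Data frame `increment_top`, `x`, `y`, `rmse_star`.
#' @export
target_diagram_coords <- function(strategy_skill) {
  tab <- strategy_skill$table
  data.frame(increment_top = tab$increment_top,
             x = tab$signed_rmse_prime, y = tab$bias_star,
             rmse_star = tab$rmse_star)
}
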