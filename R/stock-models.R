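#' Fit a random-intercept mixed model of carbon density
#'
#' Linear mixed model of carbon density (gC cm\eqn{^{-3}}) on categorical
#' predictors with a random intercept for the data submitter, fitted by
#' maximum likelihood (not REML) so that information-criterion comparisons
#' across fixed-effect structures are valid. The submitter intercept absorbs
#' laboratory-specific measurement bias shared by all cores of one submitter.
#'
#' @param records Increment table with a `carbon_density` column, the
#'   grouping column, and the covariate columns named in `fixed_terms`.
#' @param fixed_terms Character vector of fixed-effect terms, e.g.
#'   `c("climate", "soil_class", "climate:soil_class")`. Empty for an
#'   intercept-only model.
#' @param response,group Column names of the response and the random-intercept
#'   grouping factor.
#' @return Object of class `carbon_lmm`: the `lmerMod` in `$model` plus
#'   `fixed_terms`, `submitter_intercept_sd`, `residual_sd`, `log_likelihood`,
#'   `k_params`, `n`, `aicc`, `pseudo_r2_marginal`, `pseudo_r2_conditional`
#'   and `singular`.
#' @export
fit_mixed_model <- function(records, fixed_terms = character(),
                            response = "carbon_density",
                            group = "submitter_id") {
  need <- c(response, group, .term_factors(fixed_terms))
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  records <- records[stats::complete.cases(records[, need, drop = FALSE]), ,
                     drop = FALSE]
  if (length(unique(records[[group]])) < 2)
    stop("need at least 2 grouping levels")
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fml <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", response, rhs, group))
  fit <- suppressMessages(
    lme4::lmer(fml, data = records, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular random-effect variance; reported as 0")
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_group <- vc$sdcor[vc$grp == group & is.na(vc$var2) &
                         vc$var1 == "(Intercept)"][1]
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  r2 <- pseudo_r2(fit)
  out <- list(model = fit, fixed_terms = fixed_terms,
              response = response, group = group,
              submitter_intercept_sd = sd_group,
              residual_sd = stats::sigma(fit),
              log_likelihood = ll, k_params = k, n = n,
              aicc = aicc(ll, k, n),
              pseudo_r2_marginal = r2[["marginal"]],
              pseudo_r2_conditional = r2[["conditional"]],
              singular = singular)
  class(out) <- "carbon_lmm"
  out
}

# Factors appearing in a vector of terms ("a", "a:b" -> a, b)
.term_factors <- function(terms) unique(unlist(strsplit(terms, ":", fixed = TRUE)))

#' @export
print.carbon_lmm <- function(x, ...) {
  rhs <- if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ")
         else "1"
  cat(sprintf("Mixed model (ML): %s ~ %s + (1 | %s)\n",
              x$response, rhs, x$group))
  cat(sprintf("  n = %d, k = %d, AICc = %.1f\n", x$n, x$k_params, x$aicc))
  cat(sprintf("  submitter intercept s.d.: %.3g; residual s.d.: %.3g\n",
              x$submitter_intercept_sd, x$residual_sd))
  cat(sprintf("  pseudo-R2: marginal %.2f, conditional %.2f\n",
              x$pseudo_r2_marginal, x$pseudo_r2_conditional))
  invisible(x)
}

#' @export
coef.carbon_lmm <- function(object, ...) lme4::fixef(object$model)

#' @export
summary.carbon_lmm <- function(object, ...) summary(object$model)

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = AIC + 2k(k+1)/(n-k-1)} with \eqn{AIC = -2\ell + 2k}.
#'
#' @param log_likelihood Maximized log-likelihood (or a `carbon_lmm`).
#' @param k_params Number of estimated parameters.
#' @param n Number of observations; must exceed `k_params + 1`.
#' @return AICc value.
#' @export
#' @examples
#' aicc(-47, 3, 10)  # AIC 100 -> 104
aicc <- function(log_likelihood, k_params, n) {
  if (inherits(log_likelihood, "carbon_lmm")) return(log_likelihood$aicc)
  if (n <= k_params + 1) stop("AICc undefined for n <= k + 1")
  -2 * log_likelihood + 2 * k_params +
    2 * k_params * (k_params + 1) / (n - k_params - 1)
}

# All subsets of candidate terms respecting marginality: an interaction may
# enter only when every lower-order term over its factors is also present.
.marginal_subsets <- function(candidate_terms) {
  nt <- length(candidate_terms)
  if (nt > 12) stop("more than 2^12 candidate structures; refusing")
  canon <- function(t) paste(sort(strsplit(t, ":", fixed = TRUE)[[1]]),
                             collapse = ":")
  canon_all <- vapply(candidate_terms, canon, character(1))
  # canonical lower-order requirements of each candidate term
  lower_of <- lapply(candidate_terms, function(t) {
    f <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(f) == 1) return(character())
    unlist(lapply(seq_len(length(f) - 1), function(k)
      utils::combn(f, k, function(z) paste(sort(z), collapse = ":"),
                   simplify = FALSE)), use.names = FALSE)
  })
  keep <- list()
  for (mask in 0:(2^nt - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(nt) - 1)) > 0
    s_canon <- canon_all[sel]
    ok <- all(vapply(which(sel), function(i)
      all(lower_of[[i]] %in% s_canon), logical(1)))
    if (ok) keep[[length(keep) + 1]] <- candidate_terms[sel]
  }
  keep
}

#' Rank all marginality-respecting fixed-effect structures by AICc
#'
#' Enumerates every subset of the candidate fixed-effect terms in which an
#' interaction appears only together with all its lower-order terms, fits each
#' structure by maximum likelihood with the submitter random intercept, and
#' ranks the fits by AICc with Akaike weights.
#'
#' @param records Increment table.
#' @param candidate_terms Character vector of candidate terms (main effects
#'   and `:`-interactions). At most 12 terms.
#' @param ... Passed to [fit_mixed_model()].
#' @return Object of class `model_ranking`: data frame `table` (structure,
#'   k, log-likelihood, AICc, delta, Akaike weight) in AICc order, the fitted
#'   models in `fits`, and the top model in `top`.
#' @export
dredge_models <- function(records, candidate_terms, ...) {
  subsets <- .marginal_subsets(candidate_terms)
  fits <- lapply(subsets, function(s)
    fit_mixed_model(records, fixed_terms = s, ...))
  tab <- data.frame(
    structure = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = " + ") else "1", character(1)),
    k = vapply(fits, function(f) f$k_params, numeric(1)),
    log_likelihood = vapply(fits, function(f) f$log_likelihood, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1))
  )
  ord <- order(tab$aicc)
  tab <- tab[ord, ]; fits <- fits[ord]; subsets <- subsets[ord]
  tab$delta <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  out <- list(table = tab, fits = fits, structures = subsets,
              top = fits[[1]])
  class(out) <- "model_ranking"
  out
}

#' @export
print.model_ranking <- function(x, n = 10, ...) {
  cat(sprintf("AICc model ranking (%d structures)\n", nrow(x$table)))
  print(utils::head(x$table, n), digits = 4)
  invisible(x)
}

#' Adjusted effect size from ANOVA sums of squares
#'
#' \eqn{\omega^2 = (SS_{term} - df_{term} \cdot MS_{error}) /
#' (SS_{total} + MS_{error})}.
#'
#' @param ss_term,df_term Sum of squares and degrees of freedom of the term.
#' @param ms_error Residual mean square.
#' @param ss_total Total sum of squares.
#' @return Adjusted effect size (can be slightly negative for null effects).
#' @export
#' @examples
#' omega_squared_stat(80, 1, 1, 100)  # ~0.782
omega_squared_stat <- function(ss_term, df_term, ms_error, ss_total) {
  if (ss_total <= 0) stop("omega squared undefined for zero total SS")
  (ss_term - df_term * ms_error) / (ss_total + ms_error)
}

#' Per-term adjusted effect sizes for a mixed model
#'
#' Computes \eqn{\omega^2} for each fixed-effect term from Type-III sums of
#' squares of the fixed-effects design, with the random submitter intercept
#' profiled out by subtracting each observation's predicted group effect
#' (BLUP) from the response before the ANOVA. This is an approximation to
#' effect sizes on the mixed model itself, adequate for ranking terms.
#'
#' @param fit A `carbon_lmm`.
#' @return Named numeric vector of \eqn{\omega^2} per fixed term.
#' @export
omega_squared <- function(fit) {
  stopifnot(inherits(fit, "carbon_lmm"))
  if (!length(fit$fixed_terms)) return(stats::setNames(numeric(0), character(0)))
  mf <- stats::model.frame(fit$model)
  y <- mf[[fit$response]]
  # remove the conditional group effect
  re <- lme4::ranef(fit$model)[[fit$group]]
  grp <- as.character(mf[[fit$group]])
  y_adj <- y - re[grp, "(Intercept)"]
  dat <- mf
  dat$.y_adj <- y_adj
  rhs <- paste(fit$fixed_terms, collapse = " + ")
  lm_fit <- stats::lm(stats::as.formula(paste(".y_adj ~", rhs)), data = dat,
                      contrasts = .sum_contrasts(dat, fit$fixed_terms))
  a <- car::Anova(lm_fit, type = 3, singular.ok = TRUE)
  ss <- a[["Sum Sq"]]; df <- a[["Df"]]
  terms_a <- rownames(a)
  resid_i <- which(terms_a == "Residuals")
  ms_err <- ss[resid_i] / df[resid_i]
  ss_total <- sum((y_adj - mean(y_adj))^2)
  keep <- setdiff(seq_along(terms_a), c(which(terms_a == "(Intercept)"), resid_i))
  out <- vapply(keep, function(i)
    omega_squared_stat(ss[i], df[i], ms_err, ss_total), numeric(1))
  stats::setNames(out, terms_a[keep])
}

.sum_contrasts <- function(dat, terms) {
  f <- .term_factors(terms)
  f <- f[vapply(f, function(v) is.factor(dat[[v]]) || is.character(dat[[v]]),
                logical(1))]
  stats::setNames(rep(list("contr.sum"), length(f)), f)
}

#' Marginal and conditional pseudo-R-squared for a mixed model
#'
#' Variance-components decomposition in the Nakagawa-Schielzeth convention:
#' marginal \eqn{R^2} is the fixed-effects variance over the total of fixed,
#' random and residual variances; conditional \eqn{R^2} adds the random
#' variance to the numerator.
#'
#' @param fit A `carbon_lmm` or `lmerMod`.
#' @return Named vector `c(marginal, conditional)`.
#' @seealso [pseudo_r2_components()] for the plug-in formula.
#' @export
pseudo_r2 <- function(fit) {
  m <- if (inherits(fit, "carbon_lmm")) fit$model else fit
  var_fixed <- stats::var(as.numeric(stats::model.matrix(m) %*% lme4::fixef(m)))
  vc <- as.data.frame(lme4::VarCorr(m))
  var_random <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- stats::sigma(m)^2
  pseudo_r2_components(var_fixed, var_random, var_resid)
}

#' @rdname pseudo_r2
#' @param var_fixed,var_random,var_resid Variance components.
#' @export
#' @examples
#' pseudo_r2_components(2, 1, 1)  # marginal 0.5, conditional 0.75
pseudo_r2_components <- function(var_fixed, var_random, var_resid) {
  tot <- var_fixed + var_random + var_resid
  c(marginal = var_fixed / tot,
    conditional = (var_fixed + var_random) / tot)
}

#' Fixed-effects-only prediction from a mixed model
#'
#' Predicts carbon density using only the fixed effects (random submitter
#' intercept set to zero), so predictions apply equally to submitters seen in
#' training and to new data. Used for both model validation (true covariates)
#' and model application (mapped covariates).
#'
#' @param fit A `carbon_lmm`.
#' @param newdata Data frame of covariates; every factor level must have been
#'   seen in training.
#' @return Numeric vector of predicted carbon densities, gC cm\eqn{^{-3}}.
#' @export
predict_fixed <- function(fit, newdata) {
  stopifnot(inherits(fit, "carbon_lmm"))
  mf <- stats::model.frame(fit$model)
  for (v in .term_factors(fit$fixed_terms)) {
    seen <- unique(as.character(mf[[v]]))
    new_lv <- setdiff(unique(as.character(newdata[[v]])), seen)
    if (length(new_lv))
      stop(sprintf("unseen level(s) in '%s': %s", v,
                   paste(new_lv, collapse = ", ")))
  }
  unname(stats::predict(fit$model, newdata = newdata, re.form = NA))
}
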