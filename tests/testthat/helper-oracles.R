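# Independent brute-force oracles used across the test files. These
# deliberately re-derive results by fine discretization / direct formulas,
# not by calling the implementation under test.

# 1-mm midpoint discretization of a core profile to 10-cm slabs, including
# the terminal >50% extrapolation rule. Sample boundaries are assumed to lie
# on (at worst) a 0.5 cm grid so midpoint membership is exact.
oracle_aggregate <- function(core, max_depth = 100) {
  mids <- seq(0.05, max_depth - 0.05, by = 0.1)  # 1-mm cell midpoints, in cm
  idx <- rep(NA_integer_, length(mids))
  for (i in seq_len(nrow(core))) {
    hit <- mids > core$depth_top_cm[i] & mids < core$depth_bottom_cm[i]
    idx[hit] <- i
  }
  slab <- floor(mids / 10)
  core_bottom <- max(core$depth_bottom_cm)
  deepest <- which.max(core$depth_bottom_cm)
  out <- list()
  for (k in sort(unique(slab))) {
    cells <- which(slab == k)
    covered <- !is.na(idx[cells])
    coverage <- sum(covered) * 0.1
    if (coverage <= 0) next
    use <- idx[cells]
    terminal <- core_bottom > k * 10 && core_bottom < (k + 1) * 10
    if (terminal) {
      if (coverage > 5) {
        use[!covered & mids[cells] > core_bottom] <- deepest
      } else next
    }
    wmean <- function(v) {
      ok <- !is.na(use) & !is.na(v[use])
      if (!any(ok)) return(NA_real_)
      mean(v[use[ok]])
    }
    out[[length(out) + 1]] <- data.frame(
      increment_top = k * 10,
      bulk_density = wmean(core$bulk_density_g_cm3),
      om_fraction = wmean(core$om_fraction),
      coverage = coverage)
  }
  do.call(rbind, out)
}

# Direct-formula skill metrics (population sd), independent of skill_scores()
oracle_skill <- function(m, r) {
  sdp <- function(x) sqrt(mean((x - mean(x))^2))
  bias <- (mean(m) - mean(r)) / sdp(r)
  rmse_prime <- sqrt(mean(((m - mean(m)) - (r - mean(r)))^2)) / sdp(r)
  list(bias_star = bias, rmse_prime_star = rmse_prime,
       rmse_star = sqrt(bias^2 + rmse_prime^2))
}

# Random core with interval boundaries on a 0.5-cm grid
random_core <- function(seed, max_bottom = 104) {
  set.seed(seed)
  bottom <- sample(seq(8, max_bottom, by = 0.5), 1)
  cuts <- sort(sample(seq(0.5, bottom - 0.5, by = 0.5),
                      sample(2:12, 1)))
  tops <- c(0, cuts); bots <- c(cuts, bottom)
  data.frame(core_id = sprintf("c%03d", seed),
             depth_top_cm = tops, depth_bottom_cm = bots,
             bulk_density_g_cm3 = runif(length(tops), 0.05, 1.6),
             om_fraction = runif(length(tops), 0.01, 0.9),
             oc_fraction = NA_real_)
}

# Exhaustive 2-D grid search for the mixing model (independent of nls)
oracle_mixing_grid <- function(om, bd, k1_grid, k2_grid) {
  best <- c(NA, NA); best_sse <- Inf
  for (k1 in k1_grid) for (k2 in k2_grid) {
    sse <- sum((bd - 1 / (om / k1 + (1 - om) / k2))^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(k1, k2) }
  }
  c(k1 = best[1], k2 = best[2])
}
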