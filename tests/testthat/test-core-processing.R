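test_that("LOI-to-OC quadratic evaluates and clamps correctly", {
  # raw constant term is negative; clamp keeps OC physical at OM = 0
  expect_equal(om_to_oc(0, clamp = FALSE), -0.0080)
  expect_equal(om_to_oc(0), 0)
  # full-organic endpoint under both coefficient sets
  expect_equal(om_to_oc(1), 0.074 + 0.421 - 0.0080)          # 0.487
  expect_equal(om_to_oc(1, oc_coefficients("printed")),
               0.074 + 0.0421 - 0.0080)                      # 0.1081
  expect_error(om_to_oc(1.2), "0, 1")
  expect_true(is.na(om_to_oc(NA)))
})

test_that("carbon density prefers the LOI conversion over measured OC", {
  # OM present and measured OC present: the conversion wins
  expect_equal(compute_carbon_density(0.3, om_fraction = 0.5,
                                      oc_fraction = 0.9),
               0.3 * om_to_oc(0.5))
  # measured OC used only when OM is absent
  expect_equal(compute_carbon_density(0.2, NA, 0.10), 0.020)
  expect_equal(compute_carbon_density(0, 0.5, NA), 0)
  expect_true(is.na(compute_carbon_density(0.3, NA, NA)))
  expect_error(compute_carbon_density(-1, 0.5), ">= 0")
})

test_that("depth-weighted aggregation matches hand-computed slabs", {
  core <- data.frame(core_id = "a",
                     depth_top_cm = c(0, 4), depth_bottom_cm = c(4, 12),
                     bulk_density_g_cm3 = c(0.2, 0.4),
                     om_fraction = c(0.1, 0.3), oc_fraction = NA_real_)
  out <- aggregate_to_increments(core)
  expect_equal(out$bulk_density[out$increment_top == 0],
               (4 * 0.2 + 6 * 0.4) / 10)
  expect_equal(out$om_fraction[out$increment_top == 0],
               (4 * 0.1 + 6 * 0.3) / 10)

  # single sample spanning exactly one slab passes through unchanged
  one <- data.frame(core_id = "b", depth_top_cm = 0, depth_bottom_cm = 10,
                    bulk_density_g_cm3 = 0.5, om_fraction = 0.2,
                    oc_fraction = NA_real_)
  out1 <- aggregate_to_increments(one)
  expect_equal(nrow(out1), 1)
  expect_equal(out1$bulk_density, 0.5)
  expect_equal(out1$om_fraction, 0.2)
  expect_equal(out1$carbon_density, 0.5 * om_to_oc(0.2))

  expect_error(aggregate_to_increments(
    data.frame(core_id = "c", depth_top_cm = c(0, 3),
               depth_bottom_cm = c(5, 8),
               bulk_density_g_cm3 = 0.3, om_fraction = 0.1,
               oc_fraction = NA_real_)), "overlap")
})

test_that("terminal slab extrapolates above 50% coverage and drops at or below", {
  mk <- function(bottom) data.frame(
    core_id = "t", depth_top_cm = c(0, 90), depth_bottom_cm = c(90, bottom),
    bulk_density_g_cm3 = c(0.3, 0.6), om_fraction = c(0.2, 0.4),
    oc_fraction = NA_real_)
  # 6 cm coverage (> 5): extrapolated, value = deepest sample carried to 100
  out6 <- aggregate_to_increments(mk(96))
  last6 <- out6[out6$increment_top == 90, ]
  expect_equal(nrow(last6), 1)
  expect_true(last6$extrapolated)
  expect_equal(last6$bulk_density, 0.6)   # carried values fill 96-100
  expect_equal(last6$coverage, 6)
  # exactly 5 cm coverage: no-data, slab omitted
  out5 <- aggregate_to_increments(mk(95))
  expect_false(90 %in% out5$increment_top)
  # mixed terminal slab: extrapolation extends only the deepest sample
  core <- data.frame(core_id = "m", depth_top_cm = c(85, 93),
                     depth_bottom_cm = c(93, 96),
                     bulk_density_g_cm3 = c(0.2, 0.5),
                     om_fraction = c(0.1, 0.1), oc_fraction = NA_real_)
  out <- aggregate_to_increments(core)
  last <- out[out$increment_top == 90, ]
  expect_equal(last$bulk_density, (3 * 0.2 + (3 + 4) * 0.5) / 10)
})

test_that("aggregation equals 1-mm brute-force discretization on random cores", {
  for (s in 1:50) {
    core <- random_core(s)
    got <- aggregate_to_increments(core)
    want <- oracle_aggregate(core)
    expect_equal(got$increment_top, want$increment_top, info = paste("seed", s))
    expect_equal(got$bulk_density, want$bulk_density, tolerance = 1e-10,
                 info = paste("seed", s))
    expect_equal(got$om_fraction, want$om_fraction, tolerance = 1e-10,
                 info = paste("seed", s))
    expect_equal(got$coverage, want$coverage, tolerance = 1e-10,
                 info = paste("seed", s))
  }
})

test_that("aggregating a constant profile is idempotent and bounded", {
  core <- data.frame(core_id = "k", depth_top_cm = seq(0, 95, 5),
                     depth_bottom_cm = seq(5, 100, 5),
                     bulk_density_g_cm3 = 0.42, om_fraction = 0.37,
                     oc_fraction = NA_real_)
  out <- aggregate_to_increments(core)
  expect_equal(nrow(out), 10)
  expect_equal(out$bulk_density, rep(0.42, 10))
  expect_equal(out$om_fraction, rep(0.37, 10))
  # carbon density is non-negative and cannot exceed bulk density
  expect_true(all(out$carbon_density >= 0 &
                    out$carbon_density <= out$bulk_density))
})

test_that("standard error formula and distribution fits behave", {
  expect_equal(standard_error(0.013, 8280), 0.013 / sqrt(8280))
  expect_equal(round(standard_error(0.013, 8280), 5), 0.00014)

  set.seed(31)
  v <- qnorm(runif(1e5, pnorm(0, 0.027, 0.013), 1), 0.027, 0.013)
  fit <- fit_carbon_distribution(v, "truncated_normal")
  expect_equal(fit$mean, 0.027, tolerance = 3 * 0.013 / sqrt(1e5) / 0.027)
  expect_equal(fit$sd, 0.013, tolerance = 0.02)
  expect_equal(fit$se, fit$sd / sqrt(fit$n))

  # zeros are recast to the 0.01 kgC m^-3 detection floor for the log-normal
  set.seed(32)
  w <- c(0, rlnorm(500, log(0.02), 0.5))
  ln <- fit_carbon_distribution(w, "log_normal")
  expect_true(is.finite(ln$log_likelihood))
  expect_error(fit_carbon_distribution(rep(0.02, 10)), "degenerate")
  expect_error(fit_carbon_distribution(0.02), "at least 2")
})

test_that("depth-profile summary reflects generator trends and handles n = 1", {
  cfg <- generator_config(n_cores = 150, seed = 5)
  inc <- aggregate_cores(generate_core_dataset(cfg))
  s <- summarize_depth_profiles(inc)
  expect_equal(s$increment_top, sort(s$increment_top))
  # generator builds OM declining and BD rising downcore
  expect_lt(s$om_mean[s$increment_top == 90], s$om_mean[s$increment_top == 0])
  expect_gt(s$bd_mean[s$increment_top == 90], s$bd_mean[s$increment_top == 0])

  one <- data.frame(increment_top = 0, bulk_density = 0.3, om_fraction = 0.1,
                    carbon_density = 0.01)
  s1 <- summarize_depth_profiles(one)
  expect_true(is.na(s1$bd_se))
  dup <- rbind(one, one)
  expect_equal(summarize_depth_profiles(dup)$bd_se, 0)
})
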