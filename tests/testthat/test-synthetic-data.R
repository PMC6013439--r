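test_that("generator config validates its invariants", {
  expect_error(generator_config(class_mix = c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(generator_config(k1_true = 2, k2_true = 1), "k1_true < k2_true")
  expect_error(generator_config(submitter_sd = -1), ">= 0")
  expect_error(generator_config(organic_fraction_of_cores = 1.2), "\\[0, 1\\]")
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_cores = 40, seed = 123)
  expect_identical(generate_core_dataset(cfg), generate_core_dataset(cfg))
  m1 <- generate_map_unit_table(cfg, 2, 0.1, n_map_units = 30)
  m2 <- generate_map_unit_table(cfg, 2, 0.1, n_map_units = 30)
  expect_identical(m1, m2)
  # a different seed changes the draw
  cfg2 <- generator_config(n_cores = 40, seed = 124)
  expect_false(identical(generate_core_dataset(cfg), generate_core_dataset(cfg2)))
})

test_that("zero-noise generation lies exactly on the mixing curve", {
  cfg <- generator_config(n_cores = 50, seed = 9, submitter_sd = 0,
                          noise_sd_bd = 0)
  d <- generate_core_dataset(cfg)
  expect_equal(d$bulk_density_g_cm3,
               mixing_bd(d$om_fraction, cfg$k1_true, cfg$k2_true),
               tolerance = 1e-12)
})

test_that("class counts match the configured mix within sampling error", {
  cfg <- generator_config(n_cores = 1959, seed = 2)
  d <- generate_core_dataset(cfg)
  cores <- d[!duplicated(d$core_id), ]
  counts <- table(factor(cores$sal_veg, names(cfg$class_mix)))
  expected <- cfg$class_mix * 1959
  # each count within 4 multinomial standard deviations
  sds <- sqrt(1959 * cfg$class_mix * (1 - cfg$class_mix))
  expect_true(all(abs(counts - expected) < 4 * sds))
  # dominant class is estuarine emergent, as in the emulated synthesis
  expect_equal(names(which.max(counts)), "estuarine_emergent")
})

test_that("carbon densities hit the configured mean and sd targets", {
  cfg <- generator_config(n_cores = 1200, seed = 8)
  d <- generate_core_dataset(cfg)
  inc <- aggregate_cores(d)
  cd <- inc$carbon_density[!is.na(inc$carbon_density)]
  expect_gt(length(cd), 1000)
  # cluster-aware standard error: submitter intercepts correlate increments,
  # so the se of the dataset mean is governed by the submitter level
  sub_means <- tapply(inc$carbon_density, inc$submitter_id, mean,
                      na.rm = TRUE)
  se_mean <- sd(sub_means) / sqrt(length(sub_means))
  expect_lt(abs(mean(cd) - 0.027), 3 * se_mean)
  expect_lt(abs(sd(cd) - 0.013), 0.003)
})

test_that("submitter effect is an additive intercept on carbon density", {
  # with no measurement noise, the carbon-density anomaly from the mixing
  # curve is constant within a submitter and varies between submitters
  cfg <- generator_config(n_cores = 120, seed = 4, noise_sd_bd = 0,
                          om_within_core_sd = 0, submitter_sd = 0.01,
                          n_submitters = 6, om_mineral_mean = 0.10,
                          om_mineral_sd = 0.02)
  d <- generate_core_dataset(cfg)
  oc <- om_to_oc(d$om_fraction)
  d <- d[oc >= 0.02, ]  # below the OC floor the shift is attenuated
  anomaly <- d$bulk_density_g_cm3 * om_to_oc(d$om_fraction) -
    mixing_bd(d$om_fraction, cfg$k1_true, cfg$k2_true) * om_to_oc(d$om_fraction)
  within <- tapply(anomaly, d$submitter_id, sd)
  between <- sd(tapply(anomaly, d$submitter_id, mean))
  expect_true(all(within < 1e-10))
  expect_gt(between, 0.001)
})

test_that("map-unit generator injects the configured k1 bias and flips", {
  cfg <- generator_config(n_cores = 10, seed = 21, submitter_sd = 0)
  mt <- generate_map_unit_table(cfg, k1_map_bias = 2.7,
                                misclassification_rate = 0,
                                n_map_units = 250)
  agg <- aggregate_map_units(mt)
  fit <- mixing_model(agg$om_fraction, agg$bulk_density)
  # truth 0.098 scaled by 2.7 -> ~0.26, the reported soil-survey range
  expect_gt(fit$k1, 0.24 * 0.85)
  expect_lt(fit$k1, 0.30 * 1.15)

  # identity case: no bias, no flips
  mt0 <- generate_map_unit_table(cfg, 1, 0, n_map_units = 250)
  agg0 <- aggregate_map_units(mt0)
  fit0 <- mixing_model(agg0$om_fraction, agg0$bulk_density)
  expect_equal(fit0$k1, cfg$k1_true, tolerance = 0.15)
  expect_true(all(mt0$map_units$soil_class == mt0$map_units$soil_class_true))

  # flips are counted directly in the table
  mtf <- generate_map_unit_table(cfg, 1, 0.4, n_map_units = 400)
  flipped <- mean(mtf$map_units$soil_class != mtf$map_units$soil_class_true)
  expect_equal(flipped, 0.4, tolerance = 0.1)
  # component percents sum to 100 within each unit
  sums <- tapply(mtf$components$component_percent,
                 mtf$components$map_unit_id, sum)
  expect_true(all(sums == 100))
  expect_error(generate_map_unit_table(cfg, k1_map_bias = 0), "> 0")
})

test_that("calibration/reference split is a clean core-level partition", {
  cfg <- generator_config(n_cores = 100, seed = 6)
  d <- generate_core_dataset(cfg)
  s <- split_calibration_reference(d, 0.5, seed = 77)
  cal_ids <- unique(s$calibration$core_id)
  ref_ids <- unique(s$reference$core_id)
  expect_equal(length(cal_ids), 50)
  expect_length(intersect(cal_ids, ref_ids), 0)
  # no core's rows are divided between the subsets
  expect_true(all(table(d$core_id[d$core_id %in% cal_ids]) ==
                    table(s$calibration$core_id)))
  # reference screens out unusable-position cores
  expect_false(any(s$reference$position_quality == "unusable"))
  expect_true(all(setdiff(unique(d$core_id), c(cal_ids, ref_ids)) %in%
                    d$core_id[d$position_quality == "unusable"]))
  # determinism
  s2 <- split_calibration_reference(d, 0.5, seed = 77)
  expect_identical(s, s2)
  expect_error(split_calibration_reference(d, 0), "\\(0, 1\\)")
})

test_that("CSV round-trips preserve the core and map schemas", {
  cfg <- generator_config(n_cores = 12, seed = 14)
  d <- generate_core_dataset(cfg)
  f <- tempfile(fileext = ".csv")
  write_core_csv(d, f)
  back <- read_core_csv(f)
  expect_equal(back$bulk_density_g_cm3, d$bulk_density_g_cm3)
  expect_equal(back$om_fraction, d$om_fraction)
  expect_identical(back$core_id, d$core_id)

  mt <- generate_map_unit_table(cfg, 1.5, 0.1, n_map_units = 8)
  dir <- tempfile()
  write_map_unit_csvs(mt, dir)
  back_mt <- read_map_unit_csvs(dir)
  expect_equal(back_mt$horizons$bulk_density_g_cm3,
               mt$horizons$bulk_density_g_cm3)
  expect_identical(back_mt$map_units$soil_class, mt$map_units$soil_class)
})
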