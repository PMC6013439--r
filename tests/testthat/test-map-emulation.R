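test_that("horizon aggregation applies survey missing-data rules", {
  h <- data.frame(depth_top_cm = c(0, 6), depth_bottom_cm = c(6, 10),
                  bulk_density_g_cm3 = c(0.1, 0.3),
                  om_fraction = c(0.2, 0.4))
  out <- aggregate_horizons(h)
  expect_equal(out$bulk_density, (6 * 0.1 + 4 * 0.3) / 10)  # 0.18
  expect_equal(out$om_fraction, (6 * 0.2 + 4 * 0.4) / 10)

  # OM missing with BD present: OM treated as zero over that span
  h2 <- data.frame(depth_top_cm = 0, depth_bottom_cm = 10,
                   bulk_density_g_cm3 = 0.5, om_fraction = NA_real_)
  expect_equal(aggregate_horizons(h2)$om_fraction, 0)
  # BD missing: the span is no-data
  h3 <- data.frame(depth_top_cm = c(0, 0), depth_bottom_cm = c(10, 10),
                   bulk_density_g_cm3 = c(NA, NA), om_fraction = c(0.3, 0.3))
  expect_equal(nrow(suppressWarnings(aggregate_horizons(h3))), 0)
  # horizons tiling a slab with equal values return that value
  h4 <- data.frame(depth_top_cm = c(0, 3, 7), depth_bottom_cm = c(3, 7, 10),
                   bulk_density_g_cm3 = 0.25, om_fraction = 0.15)
  out4 <- aggregate_horizons(h4)
  expect_equal(out4$bulk_density, 0.25)
  expect_equal(out4$om_fraction, 0.15)
  expect_error(aggregate_horizons(
    data.frame(depth_top_cm = 5, depth_bottom_cm = 5,
               bulk_density_g_cm3 = 1, om_fraction = 0.1)), "exceed")
})

test_that("component aggregation weights by percent and renormalizes", {
  slab <- function(bd, om) data.frame(increment_top = 0, bulk_density = bd,
                                      om_fraction = om, coverage = 10)
  out <- aggregate_components(list(slab(0.2, 0.1), slab(0.2, 0.3)),
                              c(60, 40))
  expect_equal(out$om_fraction, 0.6 * 0.1 + 0.4 * 0.3)  # 0.18
  # single component: identity
  expect_equal(aggregate_components(list(slab(0.33, 0.22)), 100)$om_fraction,
               0.22)
  # a no-data component drops out; weights renormalize to the other
  empty <- data.frame(increment_top = numeric(0), bulk_density = numeric(0),
                      om_fraction = numeric(0), coverage = numeric(0))
  out2 <- aggregate_components(list(slab(0.2, 0.1), empty), c(60, 40))
  expect_equal(out2$om_fraction, 0.1)
  # zero-percent components are ignored entirely
  out3 <- aggregate_components(list(slab(0.2, 0.1), slab(9, 0.9)), c(100, 0))
  expect_equal(out3$om_fraction, 0.1)
})

test_that("horizon aggregation equals brute-force discretization", {
  set.seed(99)
  for (s in 1:25) {
    h <- random_core(s + 500)
    names(h)[names(h) == "bulk_density_g_cm3"] <- "bulk_density_g_cm3"
    got <- aggregate_horizons(h)
    want <- oracle_aggregate(h)
    # horizons have no terminal extrapolation; compare full-coverage slabs
    full <- want[want$coverage >= 10 - 1e-9, ]
    gf <- got[got$increment_top %in% full$increment_top, ]
    expect_equal(gf$bulk_density, full$bulk_density, tolerance = 1e-10)
    expect_equal(gf$om_fraction, full$om_fraction, tolerance = 1e-10)
  }
})

test_that("van Bemmelen carbon density and slab stocks", {
  expect_equal(map_carbon_density(0.2, 0.5), 0.058)
  expect_equal(map_carbon_density(0.7, 0), 0)
  expect_equal(slab_stock_kg_m2(0.058), 5.8)
  expect_error(map_carbon_density(0.2, 1.5), "om")
})

test_that("soil classification uses a strict threshold", {
  expect_equal(classify_soil(0.15), "organic")
  expect_equal(classify_soil(0.10), "mineral")
  expect_equal(classify_soil(0.132), "mineral")  # boundary falls to mineral
  expect_equal(classify_soil(0.25, threshold = 0.35), "mineral")
  expect_true(is.na(classify_soil(NA)))
})

test_that("accuracy assessment computes the three accuracy families", {
  mapped <- c(rep("organic", 10), rep("mineral", 10))
  ref <- c(rep("organic", 8), rep("mineral", 2),
           rep("organic", 3), rep("mineral", 7))
  acc <- accuracy_assessment(mapped, ref)
  expect_equal(unname(acc$total_accuracy), 0.75)
  expect_equal(unname(acc$users_accuracy["organic"]), 0.8)
  expect_equal(unname(acc$users_accuracy["mineral"]), 0.7)
  expect_equal(unname(acc$producers_accuracy["organic"]), 8 / 11)
  perfect <- accuracy_assessment(ref, ref)
  expect_equal(unname(perfect$total_accuracy), 1)
  expect_true(all(perfect$users_accuracy == 1))
  expect_error(accuracy_assessment(character(), character()), "empty")
})

test_that("generated label flips surface as commission error", {
  cfg <- generator_config(n_cores = 10, seed = 50)
  mt <- generate_map_unit_table(cfg, 1, misclassification_rate = 0.4,
                                n_map_units = 500)
  acc <- accuracy_assessment(mt$map_units$soil_class,
                             mt$map_units$soil_class_true)
  # with balanced classes, commission error of each class tracks the rate
  expect_equal(unname(1 - acc$users_accuracy["mineral"]), 0.4,
               tolerance = 0.12)
  expect_equal(unname(acc$total_accuracy), 0.6, tolerance = 0.08)
})

test_that("bias correction transfers map residuals onto the empirical curve", {
  set.seed(17)
  n <- 400
  om <- runif(n, 0.02, 0.95)
  emp <- data.frame(om_fraction = om,
                    bulk_density = pmax(mixing_bd(om, 0.098, 1.67) +
                                          rnorm(n, 0, 0.04), 0.01))
  om_m <- runif(n, 0.02, 0.95)
  map <- data.frame(om_fraction = om_m,
                    bulk_density = pmax(mixing_bd(om_m, 0.098 * 2.7, 1.67) +
                                          rnorm(n, 0, 0.08), 0.01))
  out <- bias_correct_bd(map, emp)
  fit_c <- attr(out, "empirical_fit")
  # corrected data refit close to the empirical self-packing densities
  refit <- mixing_model(out$om_fraction, out$corrected_bd)
  expect_equal(refit$k1, fit_c$k1, tolerance = 0.10)
  expect_equal(refit$residual_sd, fit_c$residual_sd, tolerance = 0.10)
  # rank order of standardized residuals is preserved
  resid_after <- out$corrected_bd - predict(fit_c, out$om_fraction)
  expect_equal(order(out$std_residual), order(resid_after))

  # a zero-residual point lands exactly on the empirical curve
  fit_s <- attr(out, "map_fit")
  on_curve <- data.frame(om_fraction = 0.5,
                         bulk_density = predict(fit_s, 0.5))
  both <- rbind(map, on_curve)
  out2 <- bias_correct_bd(both, emp)
  expect_equal(out2$corrected_bd[n + 1],
               predict(attr(out2, "empirical_fit"), 0.5), tolerance = 1e-6)
})

test_that("corrected bulk densities below zero get the pre-correction minimum", {
  set.seed(18)
  om <- seq(0.05, 0.95, length.out = 60)
  emp <- data.frame(om_fraction = om,
                    bulk_density = mixing_bd(om, 0.098, 1.67) +
                      rnorm(60, 0, 0.001))
  # adversarial map table: one extreme negative outlier whose standardized
  # residual drives the corrected value negative
  map <- data.frame(om_fraction = c(om, 0.9),
                    bulk_density = c(mixing_bd(om, 0.26, 1.67) +
                                       rnorm(60, 0, 0.02), 0.011))
  map$bulk_density[61] <- 0.011
  emp_big <- emp
  emp_big$bulk_density <- emp_big$bulk_density +
    rnorm(60, 0, 0.3)  # large calibration residual sd amplifies the shift
  emp_big$bulk_density <- pmax(emp_big$bulk_density, 0.01)
  out <- bias_correct_bd(map, emp_big)
  expect_true(any(out$corrected_bd == min(map$bulk_density)))
  expect_true(all(out$corrected_bd >= 0))
})
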