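#' Default pipeline configuration
#'
#' Named list of every knob of [run_pipeline()]: generator parameters (see
#' [generator_config()]), the calibration/reference split fraction, bootstrap
#' iteration counts, map-emulation parameters, candidate fixed-effect sets
#' for the two dredges, the LOI-to-OC coefficient set, and area scenarios in
#' hectares (the full coastal-wetland map and the smaller area with soil
#' survey coverage).
#'
#' @param ... Overrides of the defaults.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_cores = 1959,
    seed = 1L,
    split_fraction = 0.5,
    n_boot_mixing = 1000,
    n_boot_threshold = 500,
    k1_map_bias = 2.7,
    misclassification_rate = 0.2,
    n_map_units = 200,
    oc_coefficient_set = "consistent",
    model1_terms = c("climate", "sal_veg", "soil_class",
                     "climate:sal_veg", "climate:soil_class",
                     "sal_veg:soil_class"),
    model2_terms = c("climate", "sal_veg", "depth_increment",
                     "climate:sal_veg"),
    areas_ha = c(ccap_nwi = 2.67e6, ccap_nwi_ssurgo = 1.97e6),
    depth_m = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full soil-carbon analysis pipeline
#'
#' Generate -> process -> fit -> evaluate -> account, on synthetic data:
#' generates a soil-core dataset and a map-unit table, aggregates cores to
#' 10-cm increments, splits calibration/reference at the core level, fits the
#' carbon-density distribution, the ideal mixing model (with bootstrap), the
#' per-slab mixing fits and the segmented organic/mineral threshold on the
#' calibration set, selects mixed models with and without soil class by AICc,
#' scores every mapping strategy (empirical mean, model validation and
#' application, soil-survey map, bias-corrected map) with target-diagram
#' skill metrics against the reference set, and produces the scenario stock
#' table. Writes a report directory (CSV tables, a JSON summary and a log)
#' when `out_dir` is given.
#'
#' @param config List from [pipeline_config()], or a path to a YAML file of
#'   overrides.
#' @param out_dir Optional report directory.
#' @return (Invisibly) a list with every intermediate object: the datasets,
#'   fits, skill tables, accuracy matrix and scenario table.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  coefs <- oc_coefficients(config$oc_coefficient_set)

  gcfg <- generator_config(n_cores = config$n_cores, seed = config$seed)
  cores <- generate_core_dataset(gcfg)
  map_table <- generate_map_unit_table(
    gcfg, k1_map_bias = config$k1_map_bias,
    misclassification_rate = config$misclassification_rate,
    n_map_units = config$n_map_units)
  say("generated %d cores (%d intervals), %d map units",
      length(unique(cores$core_id)), nrow(cores), nrow(map_table$map_units))

  split <- split_calibration_reference(cores, config$split_fraction,
                                       seed = config$seed + 2L)
  cal_inc <- aggregate_cores(split$calibration, coefs = coefs)
  ref_inc <- aggregate_cores(split$reference, coefs = coefs)
  cal_inc$soil_class_true <- split$calibration$soil_class_true[
    match(cal_inc$core_id, split$calibration$core_id)]
  ref_inc$soil_class_true <- split$reference$soil_class_true[
    match(ref_inc$core_id, split$reference$core_id)]
  say("increments: %d calibration, %d reference", nrow(cal_inc), nrow(ref_inc))

  cd <- cal_inc$carbon_density[!is.na(cal_inc$carbon_density)]
  dist_tn <- fit_carbon_distribution(cd, "truncated_normal")
  dist_ln <- fit_carbon_distribution(cd, "log_normal")
  say("carbon density: mean %.4f sd %.4f gC cm^-3 (n = %d); logLik tn %.0f vs ln %.0f",
      mean(cd), stats::sd(cd), length(cd),
      dist_tn$log_likelihood, dist_ln$log_likelihood)

  mix <- bootstrap_mixing_fit(cal_inc, n_iter = config$n_boot_mixing,
                              seed = config$seed + 3L)
  say("mixing model: k1 %.3f [%.3f, %.3f], k2 %.2f [%.2f, %.2f]",
      mix$k1, mix$ci_k1[1], mix$ci_k1[2], mix$k2, mix$ci_k2[1], mix$ci_k2[2])
  slabs <- fit_per_depth_slabs(cal_inc)
  thr <- fit_segmented_threshold(cal_inc$om_fraction, cal_inc$carbon_density,
                                 n_boot = config$n_boot_threshold,
                                 seed = config$seed + 4L)
  say("threshold: %.1f%% OM [%.1f%%, %.1f%%]", 100 * thr$breakpoint_om,
      100 * thr$ci[1], 100 * thr$ci[2])

  fit_dat <- cal_inc[cal_inc$soil_class != "unknown" &
                       !is.na(cal_inc$carbon_density), ]
  m1 <- dredge_models(fit_dat, config$model1_terms)
  m2 <- dredge_models(fit_dat, config$model2_terms)
  sigma_c <- stats::sd(fit_dat$carbon_density)
  say("model 1 top: %s (AICc %.0f, pseudo-R2 %.2f, random %.2g = %.2f sigma_c)",
      m1$table$structure[1], m1$table$aicc[1], m1$top$pseudo_r2_conditional,
      m1$top$submitter_intercept_sd, m1$top$submitter_intercept_sd / sigma_c)
  say("model 2 top: %s (AICc %.0f)", m2$table$structure[1], m2$table$aicc[1])
  omega1 <- omega_squared(m1$top)

  # --- validation (true covariates) and application (mapped covariates) ---
  ref_ok <- ref_inc[ref_inc$soil_class != "unknown" &
                      !is.na(ref_inc$carbon_density), ]
  mu_slabs <- aggregate_map_units(map_table)
  units <- map_table$map_units
  rng <- .new_rng(config$seed + 5L)
  ref_cores <- unique(ref_ok[, c("core_id", "soil_class_true")])
  assign_unit <- vapply(ref_cores$soil_class_true, function(cl) {
    pool <- units$map_unit_id[units$soil_class_true == cl]
    if (!length(pool)) pool <- units$map_unit_id
    sample(pool, 1)
  }, character(1))
  .restore_rng(rng)
  ref_cores$map_unit_id <- assign_unit
  ref_ok <- merge(ref_ok, ref_cores, by = c("core_id", "soil_class_true"))
  ref_ok$mapped_soil <- units$soil_class[match(ref_ok$map_unit_id,
                                               units$map_unit_id)]
  key <- paste(ref_ok$map_unit_id, ref_ok$increment_top)
  mkey <- paste(mu_slabs$map_unit_id, mu_slabs$increment_top)
  ref_ok$ssurgo_cd <- mu_slabs$carbon_density[match(key, mkey)]

  corr <- bias_correct_bd(
    data.frame(om_fraction = mu_slabs$om_fraction,
               bulk_density = mu_slabs$bulk_density),
    data.frame(om_fraction = cal_inc$om_fraction,
               bulk_density = cal_inc$bulk_density))
  mu_slabs$corrected_cd <- map_carbon_density(corr$corrected_bd,
                                              mu_slabs$om_fraction)
  ref_ok$ssurgo_corrected_cd <- mu_slabs$corrected_cd[match(key, mkey)]

  mean_cd <- mean(cd)
  preds <- list(
    average = rep(mean_cd, nrow(ref_ok)),
    model1_validation = predict_fixed(m1$top, ref_ok),
    model2_validation = predict_fixed(m2$top, ref_ok),
    model1_application = {
      app <- ref_ok; app$soil_class <- app$mapped_soil
      predict_fixed(m1$top, app)
    },
    ssurgo = ref_ok$ssurgo_cd,
    ssurgo_corrected = ref_ok$ssurgo_corrected_cd
  )
  skill <- lapply(preds, evaluate_strategy, reference = ref_ok$carbon_density,
                  increment_top = ref_ok$increment_top)
  verdicts <- lapply(skill, classify_accuracy_precision)
  for (s in names(skill))
    say("%-20s RMSE* %.2f-%.2f: %s", s, min(skill[[s]]$table$rmse_star),
        max(skill[[s]]$table$rmse_star), verdicts[[s]]$verdict)

  acc <- accuracy_assessment(ref_ok$mapped_soil, ref_ok$soil_class_true)
  say("map classification total accuracy %.1f%%", 100 * acc$total_accuracy)

  dens <- function(x) 1000 * mean(x, na.rm = TRUE)  # gC cm^-3 -> kgC m^-3
  strategies <- list(
    average = list(mean_density_kg_m3 = dens(preds$average),
                   verdict = verdicts$average$verdict),
    model1 = list(mean_density_kg_m3 = c(
      ccap_nwi = NA_real_, ccap_nwi_ssurgo = dens(preds$model1_application)),
      verdict = verdicts$model1_application$verdict),
    model2 = list(mean_density_kg_m3 = dens(preds$model2_validation),
                  verdict = verdicts$model2_validation$verdict),
    ssurgo = list(mean_density_kg_m3 = c(
      ccap_nwi = NA_real_, ccap_nwi_ssurgo = dens(preds$ssurgo)),
      verdict = verdicts$ssurgo$verdict),
    ssurgo_corrected = list(mean_density_kg_m3 = c(
      ccap_nwi = NA_real_, ccap_nwi_ssurgo = dens(preds$ssurgo_corrected)),
      verdict = verdicts$ssurgo_corrected$verdict)
  )
  stocks <- scenario_table(strategies, config$areas_ha, config$depth_m)

  result <- list(config = config, cores = cores, map_table = map_table,
                 calibration = cal_inc, reference = ref_inc,
                 distribution = list(truncated_normal = dist_tn,
                                     log_normal = dist_ln),
                 mixing_fit = mix, slab_fits = slabs, threshold = thr,
                 model1 = m1, model2 = m2, omega_squared_model1 = omega1,
                 skill = skill, verdicts = verdicts, accuracy = acc,
                 bias_correction = corr, stocks = stocks, log = log_lines)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_core_csv(cores, file.path(out_dir, "cores.csv"))
    utils::write.csv(rbind(cal_inc, ref_inc),
                     file.path(out_dir, "increments.csv"), row.names = FALSE)
    write_map_unit_csvs(map_table, file.path(out_dir, "map_tables"))
    utils::write.csv(mu_slabs, file.path(out_dir, "map_unit_slabs.csv"),
                     row.names = FALSE)
    skl <- do.call(rbind, lapply(names(skill), function(s)
      cbind(strategy = s, skill[[s]]$table)))
    utils::write.csv(skl, file.path(out_dir, "skill_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(m1$table, file.path(out_dir, "model1_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(m2$table, file.path(out_dir, "model2_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(stocks),
                     file.path(out_dir, "stock_scenarios.csv"),
                     row.names = FALSE)
    summary <- list(
      carbon_density_mean_g_cm3 = mean(cd),
      carbon_density_sd_g_cm3 = stats::sd(cd),
      k1 = mix$k1, k2 = mix$k2,
      k1_ci = mix$ci_k1, k2_ci = mix$ci_k2,
      threshold_om = thr$breakpoint_om, threshold_ci = thr$ci,
      model1_structure = m1$table$structure[1],
      model1_aicc = m1$table$aicc[1],
      model2_aicc = m2$table$aicc[1],
      omega_squared_model1 = as.list(omega1),
      total_accuracy = acc$total_accuracy,
      verdicts = lapply(verdicts, `[[`, "verdict"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(result)
}
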