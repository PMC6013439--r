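#' Configuration for the synthetic soil-core generator
#'
#' Builds and validates the parameter set controlling [generate_core_dataset()]
#' and [generate_map_unit_table()]. Defaults emulate the statistical structure
#' of a national tidal-wetland soil-core synthesis: 1959 cores dominated by
#' estuarine emergent wetlands, an ideal-mixing-model OM-BD relationship with
#' self-packing densities (k1, k2) = (0.098, 1.67) g cm\eqn{^{-3}},
#' submitter-level (laboratory) random intercepts on carbon density, a mean
#' core length near 55 cm with a median near 24 cm, and organic-matter
#' fractions that decline with depth (so bulk density rises with depth).
#'
#' @param n_cores Number of cores.
#' @param class_mix Named proportions over salinity-vegetation classes
#'   (`estuarine_emergent`, `palustrine_emergent`, `estuarine_forested_scrub`,
#'   `palustrine_forested_scrub`, `unknown`); must sum to 1.
#' @param climate_mix Named proportions over the four climate zones; sum to 1.
#' @param organic_fraction_of_cores Proportion of cores drawn from the organic
#'   soil class (OM above the 13.2% threshold region).
#' @param k1_true,k2_true Generating self-packing densities, g cm\eqn{^{-3}}
#'   (`k1_true < k2_true`).
#' @param submitter_sd Standard deviation of submitter random intercepts on
#'   carbon density, gC cm\eqn{^{-3}}.
#' @param noise_sd_bd Gaussian noise s.d. added to mixing-model bulk density,
#'   g cm\eqn{^{-3}} (clamped below at 0.01 g cm\eqn{^{-3}}).
#' @param core_length_mean Target mean core length, cm.
#' @param seed Integer seed; one pseudo-random stream per generator call.
#' @param n_submitters Number of distinct data submitters.
#' @param om_mineral_mean,om_mineral_sd Truncated-normal OM parameters for the
#'   mineral class (support \[0, 0.132\]).
#' @param om_organic_mean,om_organic_sd Truncated-normal OM parameters for the
#'   organic class (support (0.132, 1\]).
#' @param om_depth_decline Proportional decline of OM from the surface to
#'   100 cm depth (0.45 reproduces a roughly 29% to 15% downcore OM profile).
#' @param om_within_core_sd Within-core OM sampling noise (fraction units).
#' @param unusable_position_rate Proportion of cores flagged with unusable
#'   location quality (excluded from reference splits).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_cores = 1959,
                             class_mix = c(estuarine_emergent = 1533,
                                           palustrine_emergent = 157,
                                           estuarine_forested_scrub = 46,
                                           palustrine_forested_scrub = 87,
                                           unknown = 134) / 1957,
                             climate_mix = c(mediterranean = 0.10,
                                             subtropical = 0.35,
                                             temperate_warm = 0.30,
                                             temperate_cool = 0.25),
                             organic_fraction_of_cores = 0.5,
                             k1_true = 0.098, k2_true = 1.67,
                             submitter_sd = 0.006,
                             noise_sd_bd = 0.05,
                             core_length_mean = 55,
                             seed = 1L,
                             n_submitters = 49,
                             om_mineral_mean = 0.10, om_mineral_sd = 0.04,
                             om_organic_mean = 0.30, om_organic_sd = 0.25,
                             om_depth_decline = 0.45,
                             om_within_core_sd = 0.02,
                             unusable_position_rate = 0.05) {
  cfg <- list(n_cores = as.integer(n_cores), class_mix = class_mix,
              climate_mix = climate_mix,
              organic_fraction_of_cores = organic_fraction_of_cores,
              k1_true = k1_true, k2_true = k2_true,
              submitter_sd = submitter_sd, noise_sd_bd = noise_sd_bd,
              core_length_mean = core_length_mean, seed = as.integer(seed),
              n_submitters = as.integer(n_submitters),
              om_mineral_mean = om_mineral_mean, om_mineral_sd = om_mineral_sd,
              om_organic_mean = om_organic_mean, om_organic_sd = om_organic_sd,
              om_depth_decline = om_depth_decline,
              om_within_core_sd = om_within_core_sd,
              unusable_position_rate = unusable_position_rate)
  for (mix in c("class_mix", "climate_mix")) {
    p <- cfg[[mix]]
    if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-8)
      stop(mix, " proportions must lie in [0, 1] and sum to 1")
  }
  if (cfg$organic_fraction_of_cores < 0 || cfg$organic_fraction_of_cores > 1)
    stop("organic_fraction_of_cores must lie in [0, 1]")
  if (!(cfg$k1_true > 0 && cfg$k1_true < cfg$k2_true))
    stop("require 0 < k1_true < k2_true")
  if (cfg$submitter_sd < 0 || cfg$noise_sd_bd < 0)
    stop("standard deviations must be >= 0")
  if (cfg$n_cores < 1) stop("n_cores must be >= 1")
  class(cfg) <- "generator_config"
  cfg
}

# Floor below which generated bulk density is clamped (g cm^-3): keeps BD
# physically positive and avoids division by ~0 downstream.
.BD_FLOOR <- 0.01

# OC floor used when translating a submitter carbon-density intercept into a
# bulk-density shift (delta_CD = delta_BD * OC); prevents blow-up at low OM.
.OC_FLOOR <- 0.02

.SAL_VEG_LEVELS <- c("estuarine_emergent", "estuarine_forested_scrub",
                     "palustrine_emergent", "palustrine_forested_scrub",
                     "unknown")
.CLIMATE_LEVELS <- c("mediterranean", "subtropical", "temperate_warm",
                     "temperate_cool")
.POSITION_LEVELS <- c("gps", "map_figure", "site_description", "unusable")

#' Generate a synthetic soil-core dataset
#'
#' Draws a core table with the schema used throughout the package: one row per
#' measured depth interval per core with provenance metadata. Each core gets a
#' soil-class-dependent mean OM level (mineral cores on \[0, 0.132\], organic
#' cores on (0.132, 1\]); per-sample OM adds within-core noise and a downcore
#' decline; bulk density is the ideal mixing model evaluated at the sampled OM
#' plus Gaussian noise, clamped at 0.01 g cm\eqn{^{-3}}; a submitter-level
#' intercept perturbs carbon density identically for all samples of one
#' submitter (carried through bulk density as
#' \eqn{\Delta BD = u_s / \max(OC, 0.02)} so the downstream carbon density
#' shifts additively by \eqn{u_s}). Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return Data frame with columns `core_id`, `submitter_id`, `climate`,
#'   `sal_veg`, `position_quality`, `soil_class_true`, `depth_top_cm`,
#'   `depth_bottom_cm`, `bulk_density_g_cm3`, `om_fraction`, `oc_fraction`.
#' @export
generate_core_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  rng <- .new_rng(config$seed)
  on.exit(.restore_rng(rng))

  n <- config$n_cores
  sal_veg <- sample(names(config$class_mix), n, replace = TRUE,
                    prob = config$class_mix)
  climate <- sample(names(config$climate_mix), n, replace = TRUE,
                    prob = config$climate_mix)
  position <- sample(.POSITION_LEVELS, n, replace = TRUE,
                     prob = c(1 - config$unusable_position_rate - 0.25,
                              0.15, 0.10, config$unusable_position_rate))
  organic <- stats::runif(n) < config$organic_fraction_of_cores
  submitter <- sprintf("sub%02d", sample.int(config$n_submitters, n,
                                             replace = TRUE))
  u_sub <- stats::rnorm(config$n_submitters, 0, config$submitter_sd)
  names(u_sub) <- sprintf("sub%02d", seq_len(config$n_submitters))

  # core-level mean OM by soil class
  om_core <- ifelse(organic,
                    .rtruncnorm(n, config$om_organic_mean,
                                config$om_organic_sd, 0.132 + 1e-6, 1),
                    .rtruncnorm(n, config$om_mineral_mean,
                                config$om_mineral_sd, 0, 0.132))

  # lengths: lognormal with median ~ 24 cm scaled so the mean matches target
  sdlog <- 1.29
  meanlog <- log(config$core_length_mean) - sdlog^2 / 2
  lengths <- pmin(pmax(stats::rlnorm(n, meanlog, sdlog), 5), 1550)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    len <- min(lengths[i], 110)  # only the top metre (plus margin) is sampled
    thick <- sample(c(1, 2, 2.5, 5, 10), 1, prob = c(0.1, 0.3, 0.1, 0.3, 0.2))
    tops <- seq(0, len - 1e-9, by = thick)
    bots <- pmin(tops + thick, len)
    mid <- (tops + bots) / 2
    om <- om_core[i] * (1 - config$om_depth_decline * pmin(mid, 100) / 100) +
      stats::rnorm(length(tops), 0, config$om_within_core_sd)
    om <- pmin(pmax(om, 0.001), 1)
    oc <- om_to_oc(om)
    bd <- mixing_bd(om, config$k1_true, config$k2_true) +
      u_sub[[submitter[i]]] / pmax(oc, .OC_FLOOR) +
      stats::rnorm(length(tops), 0, config$noise_sd_bd)
    bd <- pmax(bd, .BD_FLOOR)
    # roughly a quarter of cores also report a measured OC value
    has_oc <- stats::runif(1) < 0.25
    rows[[i]] <- data.frame(
      core_id = sprintf("core%05d", i), submitter_id = submitter[i],
      climate = climate[i], sal_veg = sal_veg[i],
      position_quality = position[i],
      soil_class_true = ifelse(organic[i], "organic", "mineral"),
      depth_top_cm = tops, depth_bottom_cm = bots,
      bulk_density_g_cm3 = bd, om_fraction = om,
      oc_fraction = if (has_oc) oc else NA_real_
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a soil-survey-style map-unit table
#'
#' Emulates the map unit -> component -> horizon hierarchy of a soil survey
#' database. Horizon organic matter is drawn from the same class-dependent
#' distributions as the core generator (using each unit's true soil class);
#' horizon bulk density is the ideal mixing model evaluated with
#' `k1_true * k1_map_bias` (injecting a positive mapped-BD bias when
#' `k1_map_bias > 1`) plus Gaussian noise. A fraction `misclassification_rate`
#' of units has its mapped soil-class label flipped relative to the true
#' class, emulating thematic classification error.
#'
#' @param config A [generator_config()]; the map generator draws its own
#'   stream from `config$seed + 1`.
#' @param k1_map_bias Multiplier (> 0) on the organic self-packing density
#'   used for mapped bulk densities.
#' @param misclassification_rate Proportion of units with flipped class label.
#' @param n_map_units Number of map units.
#' @return List of class `map_unit_table` with data frames `map_units`
#'   (`map_unit_id`, `soil_class_true`, `soil_class`), `components`
#'   (`component_id`, `map_unit_id`, `hydric`, `component_percent`) and
#'   `horizons` (`component_id`, `depth_top_cm`, `depth_bottom_cm`,
#'   `bulk_density_g_cm3`, `om_fraction`).
#' @export
generate_map_unit_table <- function(config = generator_config(),
                                    k1_map_bias = 1,
                                    misclassification_rate = 0,
                                    n_map_units = 200) {
  stopifnot(inherits(config, "generator_config"))
  if (k1_map_bias <= 0) stop("k1_map_bias must be > 0")
  if (misclassification_rate < 0 || misclassification_rate > 1)
    stop("misclassification_rate must lie in [0, 1]")
  rng <- .new_rng(config$seed + 1L)
  on.exit(.restore_rng(rng))

  k1_map <- config$k1_true * k1_map_bias
  organic <- stats::runif(n_map_units) < config$organic_fraction_of_cores
  flip <- stats::runif(n_map_units) < misclassification_rate
  true_cl <- ifelse(organic, "organic", "mineral")
  mapped_cl <- ifelse(flip, ifelse(organic, "mineral", "organic"), true_cl)

  units <- data.frame(map_unit_id = sprintf("mu%04d", seq_len(n_map_units)),
                      soil_class_true = true_cl, soil_class = mapped_cl)
  comp_rows <- list(); hor_rows <- list(); cid <- 0L
  for (i in seq_len(n_map_units)) {
    ncomp <- sample.int(3, 1)
    pct <- as.numeric(stats::rmultinom(1, 100, rep(1, ncomp)))
    om_unit <- if (organic[i])
      .rtruncnorm(1, config$om_organic_mean, config$om_organic_sd,
                  0.132 + 1e-6, 1)
    else
      .rtruncnorm(1, config$om_mineral_mean, config$om_mineral_sd, 0, 0.132)
    for (j in seq_len(ncomp)) {
      cid <- cid + 1L
      id <- sprintf("comp%05d", cid)
      hydric <- j == 1 || stats::runif(1) > 0.1
      comp_rows[[cid]] <- data.frame(component_id = id,
                                     map_unit_id = units$map_unit_id[i],
                                     hydric = hydric,
                                     component_percent = pct[j])
      breaks <- sort(unique(c(0, sample(seq(10, 90, 10),
                                        sample.int(4, 1)), 100)))
      tops <- utils::head(breaks, -1); bots <- breaks[-1]
      mid <- (tops + bots) / 2
      om <- pmin(pmax(om_unit * (1 - config$om_depth_decline * mid / 100) +
                        stats::rnorm(length(tops), 0, config$om_within_core_sd),
                      0.001), 1)
      bd <- pmax(mixing_bd(om, k1_map, config$k2_true) +
                   stats::rnorm(length(tops), 0, config$noise_sd_bd),
                 .BD_FLOOR)
      hor_rows[[cid]] <- data.frame(component_id = id, depth_top_cm = tops,
                                    depth_bottom_cm = bots,
                                    bulk_density_g_cm3 = bd, om_fraction = om)
    }
  }
  out <- list(map_units = units,
              components = do.call(rbind, comp_rows),
              horizons = do.call(rbind, hor_rows))
  rownames(out$components) <- rownames(out$horizons) <- NULL
  class(out) <- "map_unit_table"
  out
}

#' @export
print.map_unit_table <- function(x, ...) {
  cat(sprintf("map_unit_table: %d map units, %d components, %d horizons\n",
              nrow(x$map_units), nrow(x$components), nrow(x$horizons)))
  invisible(x)
}

#' Split cores into calibration and reference subsets
#'
#' Core-level random partition (a core's samples are never split). The
#' reference subset is additionally screened to exclude cores whose position
#' quality is `"unusable"`, mirroring the exclusion of low-quality
#' latitude-longitude records from accuracy assessment.
#'
#' @param dataset Core table (rows are measured intervals).
#' @param fraction Proportion of cores assigned to calibration (0 < f < 1).
#' @param seed Integer seed.
#' @return List with data frames `calibration` and `reference`.
#' @export
split_calibration_reference <- function(dataset, fraction = 0.5, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ids <- unique(dataset$core_id)
  n_cal <- round(length(ids) * fraction)
  if (n_cal == 0 || n_cal == length(ids))
    stop("split leaves an empty partition")
  rng <- .new_rng(seed)
  cal_ids <- sample(ids, n_cal)
  .restore_rng(rng)
  cal <- dataset[dataset$core_id %in% cal_ids, , drop = FALSE]
  ref <- dataset[!dataset$core_id %in% cal_ids, , drop = FALSE]
  if ("position_quality" %in% names(ref))
    ref <- ref[ref$position_quality != "unusable", , drop = FALSE]
  list(calibration = cal, reference = ref)
}

#' Write / read the core-table CSV schema
#'
#' Plain CSV with empty fields for missing values.
#'
#' @param dataset Core table.
#' @param path File path.
#' @return `read_core_csv` returns the core table.
#' @export
write_core_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_core_csv
#' @export
read_core_csv <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"))
}

#' Write / read the three-CSV map-unit schema
#'
#' Writes `map_units.csv`, `components.csv` and `horizons.csv` under `dir`,
#' keyed by `map_unit_id` / `component_id`.
#'
#' @param map_table A `map_unit_table`.
#' @param dir Directory.
#' @return `read_map_unit_csvs` returns a `map_unit_table`.
#' @export
write_map_unit_csvs <- function(map_table, dir) {
  stopifnot(inherits(map_table, "map_unit_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("map_units", "components", "horizons"))
    utils::write.csv(map_table[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_map_unit_csvs
#' @export
read_map_unit_csvs <- function(dir) {
  out <- lapply(c("map_units", "components", "horizons"), function(nm)
    utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                    na.strings = c("", "NA")))
  names(out) <- c("map_units", "components", "horizons")
  class(out) <- "map_unit_table"
  out
}
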