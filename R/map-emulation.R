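#' Depth-weighted horizon aggregation for one soil-map component
#'
#' Averages horizon bulk density and organic matter over standardized 10-cm
#' slabs, weighting by the overlap length of each horizon with the slab.
#' Survey conventions are applied: a horizon with bulk density present but
#' organic matter missing is treated as 0% organic matter; a horizon with
#' missing bulk density is a no-data span and contributes to neither average.
#'
#' @param horizons Data frame with `depth_top_cm`, `depth_bottom_cm`,
#'   `bulk_density_g_cm3`, `om_fraction`.
#' @param max_depth Profile bottom, cm (default 100).
#' @return Data frame with one row per slab having data: `increment_top`,
#'   `bulk_density`, `om_fraction`, `coverage` (cm of usable data).
#' @export
aggregate_horizons <- function(horizons, max_depth = 100) {
  stopifnot(all(c("depth_top_cm", "depth_bottom_cm") %in% names(horizons)))
  if (any(horizons$depth_bottom_cm <= horizons$depth_top_cm))
    stop("horizon depth_bottom must exceed depth_top")
  bd <- horizons$bulk_density_g_cm3
  om <- ifelse(is.na(horizons$om_fraction) & !is.na(bd), 0,
               horizons$om_fraction)
  usable <- !is.na(bd)
  tops <- seq(0, max_depth - 10, by = 10)
  rows <- lapply(tops, function(lo) {
    w <- .overlap(horizons$depth_top_cm, horizons$depth_bottom_cm, lo, lo + 10)
    w[!usable] <- 0
    if (sum(w) <= 0) return(NULL)
    data.frame(increment_top = lo,
               bulk_density = sum(bd[usable] * w[usable]) / sum(w),
               om_fraction = sum(om[usable] * w[usable]) / sum(w),
               coverage = sum(w))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(increment_top = numeric(0), bulk_density = numeric(0),
                      om_fraction = numeric(0), coverage = numeric(0))
  out
}

#' Component-percent-weighted aggregation to the map-unit scale
#'
#' Combines per-component slab values into map-unit values as the weighted
#' average over hydric components, weights proportional to component percent
#' and renormalized per slab over the components that have data there.
#'
#' @param component_slabs List of per-component slab tables (as returned by
#'   [aggregate_horizons()]).
#' @param percents Component percents (0-100), one per component.
#' @return Data frame `increment_top`, `bulk_density`, `om_fraction`, or a
#'   zero-row frame when no component has data.
#' @export
aggregate_components <- function(component_slabs, percents) {
  stopifnot(length(component_slabs) == length(percents))
  keep <- percents > 0
  component_slabs <- component_slabs[keep]
  percents <- percents[keep]
  tops <- sort(unique(unlist(lapply(component_slabs,
                                    function(s) s$increment_top))))
  rows <- lapply(tops, function(t) {
    vals <- lapply(seq_along(component_slabs), function(i) {
      s <- component_slabs[[i]]
      r <- s[s$increment_top == t, , drop = FALSE]
      if (nrow(r) == 0) return(NULL)
      c(w = percents[i], bd = r$bulk_density[1], om = r$om_fraction[1])
    })
    vals <- do.call(rbind, vals[!vapply(vals, is.null, logical(1))])
    if (is.null(vals)) return(NULL)
    w <- vals[, "w"] / sum(vals[, "w"])
    data.frame(increment_top = t,
               bulk_density = sum(w * vals[, "bd"]),
               om_fraction = sum(w * vals[, "om"]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(increment_top = numeric(0), bulk_density = numeric(0),
                      om_fraction = numeric(0))
  out
}

#' Soil-survey carbon density (van Bemmelen conversion)
#'
#' Carbon density for mapped data as BD x OM x 0.58, the van Bemmelen factor
#' (g organic carbon per g organic matter) conventionally recommended for
#' soil-survey tables. Deliberately distinct from the empirical quadratic
#' LOI conversion used for soil cores.
#'
#' @param bd Bulk density, g cm\eqn{^{-3}}.
#' @param om Organic-matter fraction in \[0, 1\].
#' @return Carbon density, gC cm\eqn{^{-3}}.
#' @export
#' @examples
#' map_carbon_density(0.2, 0.5)  # 0.058
map_carbon_density <- function(bd, om) {
  stopifnot(all(bd >= 0, na.rm = TRUE),
            all(om >= 0 & om <= 1, na.rm = TRUE))
  bd * om * 0.58
}

#' Carbon stock of a depth slab
#'
#' Converts a slab carbon density to areal stock:
#' gC cm\eqn{^{-3}} x thickness (cm) gives gC cm\eqn{^{-2}}, times 10 gives
#' kgC m\eqn{^{-2}}.
#'
#' @param carbon_density gC cm\eqn{^{-3}}.
#' @param thickness_cm Slab thickness, cm (default 10).
#' @return Stock in kgC m\eqn{^{-2}}.
#' @export
#' @examples
#' slab_stock_kg_m2(0.058)  # 5.8 kgC m^-2 per 10 cm
slab_stock_kg_m2 <- function(carbon_density, thickness_cm = 10) {
  carbon_density * thickness_cm * 10
}

#' Binary organic/mineral soil classification
#'
#' Organic if the organic-matter fraction strictly exceeds the threshold
#' (default the empirically detected 13.2%); a value exactly at the threshold
#' is mineral.
#'
#' @param om_fraction OM fraction in \[0, 1\].
#' @param threshold Classification threshold (default 0.132).
#' @return Character vector `"organic"`/`"mineral"` (`NA` propagates).
#' @export
classify_soil <- function(om_fraction, threshold = 0.132) {
  stopifnot(all(om_fraction >= 0 & om_fraction <= 1, na.rm = TRUE))
  ifelse(is.na(om_fraction), NA_character_,
         ifelse(om_fraction > threshold, "organic", "mineral"))
}

#' Thematic classification accuracy assessment
#'
#' Confusion matrix of mapped against reference organic/mineral classes with
#' user's accuracy (1 - commission error, per mapped class), producer's
#' accuracy (1 - omission error, per reference class) and total accuracy.
#'
#' @param mapped,reference Equal-length class vectors over
#'   `{"organic", "mineral"}`.
#' @return Object of class `accuracy_matrix`: `confusion` (mapped rows x
#'   reference columns), `users_accuracy`, `producers_accuracy`,
#'   `total_accuracy`.
#' @export
accuracy_assessment <- function(mapped, reference) {
  if (length(mapped) == 0) stop("empty input")
  if (length(mapped) != length(reference)) stop("inputs must be paired")
  lv <- c("organic", "mineral")
  cm <- table(mapped = factor(mapped, lv), reference = factor(reference, lv))
  out <- list(confusion = cm,
              users_accuracy = diag(cm) / rowSums(cm),
              producers_accuracy = diag(cm) / colSums(cm),
              total_accuracy = sum(diag(cm)) / sum(cm))
  class(out) <- "accuracy_matrix"
  out
}

#' @export
print.accuracy_matrix <- function(x, ...) {
  cat("Confusion matrix (mapped x reference):\n")
  print(x$confusion)
  cat(sprintf("total accuracy: %.3f\n", x$total_accuracy))
  cat("user's accuracy:     ")
  cat(sprintf("%s %.3f  ", names(x$users_accuracy), x$users_accuracy), "\n")
  cat("producer's accuracy: ")
  cat(sprintf("%s %.3f  ", names(x$producers_accuracy), x$producers_accuracy),
      "\n")
  invisible(x)
}

#' Aggregate a full map-unit table to per-unit slab carbon densities
#'
#' Runs [aggregate_horizons()] per hydric component and
#' [aggregate_components()] per map unit, then derives carbon density (van
#' Bemmelen) and an OM-derived soil class per slab.
#'
#' @param map_table A `map_unit_table` (see [generate_map_unit_table()] and
#'   [read_map_unit_csvs()]).
#' @param threshold Organic/mineral threshold for the derived class.
#' @return Data frame with `map_unit_id`, `increment_top`, `bulk_density`,
#'   `om_fraction`, `carbon_density`, `soil_class_om`.
#' @export
aggregate_map_units <- function(map_table, threshold = 0.132) {
  stopifnot(inherits(map_table, "map_unit_table"))
  comps <- map_table$components
  hors <- split(map_table$horizons, map_table$horizons$component_id)
  rows <- lapply(map_table$map_units$map_unit_id, function(mu) {
    cc <- comps[comps$map_unit_id == mu & comps$hydric, , drop = FALSE]
    if (nrow(cc) == 0) return(NULL)
    slabs <- lapply(cc$component_id, function(cid) {
      h <- hors[[cid]]
      if (is.null(h)) return(data.frame(increment_top = numeric(0),
                                        bulk_density = numeric(0),
                                        om_fraction = numeric(0),
                                        coverage = numeric(0)))
      aggregate_horizons(h)
    })
    agg <- aggregate_components(slabs, cc$component_percent)
    if (nrow(agg) == 0) return(NULL)
    agg$map_unit_id <- mu
    agg
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no hydric component with data in any map unit")
  out$carbon_density <- map_carbon_density(out$bulk_density, out$om_fraction)
  out$soil_class_om <- classify_soil(out$om_fraction, threshold)
  rownames(out) <- NULL
  out[, c("map_unit_id", "increment_top", "bulk_density", "om_fraction",
          "carbon_density", "soil_class_om")]
}

#' Bias-correct mapped bulk densities against empirical data
#'
#' Standardized-residual transfer: the ideal mixing model is fitted to the
#' mapped OM-BD pairs, giving survey self-packing densities and residuals;
#' residuals are standardized by the survey residual s.d.; the mixing model
#' is fitted to the empirical calibration pairs; corrected bulk density is
#' the empirical-curve prediction at each mapped point's OM plus the
#' standardized survey residual rescaled by the calibration residual s.d.
#' The mapped data thus mimic the calibration mean-variance structure while
#' keeping the relative pattern of survey anomalies. Any corrected value
#' falling below zero is assigned the minimum pre-correction mapped BD.
#'
#' @param map_pairs Data frame with `om_fraction` and `bulk_density`
#'   (mapped values).
#' @param empirical_pairs Data frame with `om_fraction` and `bulk_density`
#'   (calibration values).
#' @return `map_pairs` with added columns `residual`, `std_residual` and
#'   `corrected_bd`; attributes `map_fit` and `empirical_fit` hold the two
#'   `mixing_fit` objects.
#' @export
bias_correct_bd <- function(map_pairs, empirical_pairs) {
  fit_s <- mixing_model(map_pairs$om_fraction, map_pairs$bulk_density)
  fit_c <- mixing_model(empirical_pairs$om_fraction,
                        empirical_pairs$bulk_density)
  pred_s <- predict(fit_s, map_pairs$om_fraction)
  r <- map_pairs$bulk_density - pred_s
  sigma_s <- fit_s$residual_sd
  r_star <- if (sigma_s == 0) rep(0, length(r)) else r / sigma_s
  corrected <- predict(fit_c, map_pairs$om_fraction) +
    r_star * fit_c$residual_sd
  min_bd <- min(map_pairs$bulk_density, na.rm = TRUE)
  corrected[corrected < 0] <- min_bd
  out <- map_pairs
  out$residual <- r
  out$std_residual <- r_star
  out$corrected_bd <- corrected
  attr(out, "map_fit") <- fit_s
  attr(out, "empirical_fit") <- fit_c
  out
}
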