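#' Total carbon stock from mean density, area and depth
#'
#' \eqn{Pg\,C = density\ (kgC\,m^{-3}) \times depth\ (m) \times area\ (ha)
#' \times 10^4 / 10^{12}}. One gC cm\eqn{^{-3}} equals exactly
#' 1000 kgC m\eqn{^{-3}}.
#'
#' @param mean_density_kg_m3 Mean carbon density, kgC m\eqn{^{-3}}.
#' @param area_ha Area, hectares.
#' @param depth_m Accounting depth, m (default 1).
#' @return Total stock, Pg C.
#' @export
#' @examples
#' total_stock(27.0, 2.67e6)  # ~0.72 Pg C
total_stock <- function(mean_density_kg_m3, area_ha, depth_m = 1) {
  stopifnot(all(mean_density_kg_m3 >= 0), all(area_ha >= 0),
            all(depth_m >= 0))
  mean_density_kg_m3 * depth_m * area_ha * 1e4 / 1e12
}

#' Scenario comparison table of carbon-stock strategies
#'
#' One row per strategy and area scenario: mean carbon density
#' (kgC m\eqn{^{-3}}), total stock (Pg C) and the strategy's qualitative
#' accuracy/precision verdict. A strategy lacking coverage of a scenario
#' (density `NA`) has that cell omitted.
#'
#' @param strategies Named list; each element a list with
#'   `mean_density_kg_m3` (a single value, or a named vector with one value
#'   per scenario) and optionally `verdict`.
#' @param areas_ha Named vector of scenario areas in hectares.
#' @param depth_m Accounting depth (default 1 m).
#' @return Data frame `strategy`, `scenario`, `area_ha`,
#'   `mean_density_kg_m3`, `total_pg`, `verdict`, with presentation rounding
#'   applied by [print.scenario_table()] (densities to 1 decimal, Pg to 2).
#' @export
scenario_table <- function(strategies, areas_ha, depth_m = 1) {
  rows <- list()
  for (s in names(strategies)) {
    st <- strategies[[s]]
    for (a in names(areas_ha)) {
      dens <- if (length(st$mean_density_kg_m3) > 1)
        st$mean_density_kg_m3[[a]] else st$mean_density_kg_m3
      if (is.null(dens) || is.na(dens)) next
      rows[[length(rows) + 1]] <- data.frame(
        strategy = s, scenario = a, area_ha = unname(areas_ha[[a]]),
        mean_density_kg_m3 = unname(dens),
        total_pg = total_stock(unname(dens), unname(areas_ha[[a]]), depth_m),
        verdict = if (is.null(st$verdict)) NA_character_ else st$verdict)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scenario_table", class(out))
  out
}

#' @export
print.scenario_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$mean_density_kg_m3 <- round(y$mean_density_kg_m3, 1)
  y$total_pg <- round(y$total_pg, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Assign a climate zone from state, latitude and coast
#'
#' Rules follow national greenhouse-gas-inventory conventions:
#' mediterranean is California south of 40 deg latitude; subtropical is the
#' Gulf coast, plus the Atlantic coast of Florida south of 30 deg;
#' temperate warm is the Atlantic coast between 30 and 40 deg; temperate
#' cool is the Pacific (outside Mediterranean California) and the Atlantic
#' north of 40 deg. Boundary latitudes (exactly 30 or 40) fall to the
#' cooler class, since "south of" is strict.
#'
#' @param state State name, e.g. `"California"`.
#' @param latitude Degrees north.
#' @param coast One of `"atlantic"`, `"gulf"`, `"pacific"`.
#' @return One of `"mediterranean"`, `"subtropical"`, `"temperate_warm"`,
#'   `"temperate_cool"`.
#' @export
#' @examples
#' climate_zone("California", 37.8, "pacific")
climate_zone <- function(state, latitude, coast) {
  if (length(state) > 1 || length(latitude) > 1 || length(coast) > 1)
    return(mapply(climate_zone, state, latitude, coast, USE.NAMES = FALSE))
  coast <- match.arg(tolower(coast), c("atlantic", "gulf", "pacific"))
  if (coast == "gulf") return("subtropical")
  if (coast == "pacific") {
    if (identical(state, "California") && latitude < 40)
      return("mediterranean")
    return("temperate_cool")
  }
  # atlantic
  if (latitude >= 40) return("temperate_cool")
  if (latitude >= 30) return("temperate_warm")
  if (identical(state, "Florida")) return("subtropical")
  stop(sprintf("unclassifiable combination: %s / %.1f / %s",
               state, latitude, coast))
}
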