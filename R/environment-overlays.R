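# Static exposure overlays: population-weighted urban greenness (NDVI) and
# population living below an elevation threshold.

#' Urban greenness classification parameters
#'
#' @param class_breaks ascending NDVI cut-points separating
#'   very low / low / moderate / high greenness (defaults 0.2, 0.3, 0.4).
#' @param moderate_or_above_cut NDVI value at or above which a centre counts
#'   as moderately green (default 0.4; the comparison is `>=`).
#' @return object of class `greenness_params`.
#' @export
greenness_params <- function(class_breaks = c(0.2, 0.3, 0.4),
                             moderate_or_above_cut = 0.4) {
  if (any(diff(class_breaks) <= 0) || any(abs(class_breaks) > 1))
    stop("class_breaks must be strictly ascending within [-1, 1]")
  structure(list(class_breaks = class_breaks,
                 moderate_or_above_cut = moderate_or_above_cut),
            class = "greenness_params")
}

#' Population-weighted urban greenness
#'
#' Per urban centre, the population-weighted mean NDVI over its cells;
#' centres with zero population are missing. Summarised by the share of
#' centres at or above the moderate cut and the population-weighted global
#' mean over centres.
#'
#' @param regions a [region_table()] with urban_centre_id and ndvi.
#' @param pop a [population_grid()] (all-age weights).
#' @param params a [greenness_params()].
#' @return an [indicator_table()] with per-centre NDVI, the share of
#'   moderately green centres, and the global mean.
#' @export
urban_greenness <- function(regions, pop, params = greenness_params()) {
  has_centre <- !is.na(regions$urban_centre_id)
  if (!any(has_centre)) stop("no urban centres in the region table")
  pw <- colSums(matrix(pop$counts, nrow = length(pop$age_groups)))
  centre <- regions$urban_centre_id[has_centre]
  vals <- weighted_regional_mean(regions$ndvi[has_centre], pw[has_centre], centre)
  ok <- !is.na(vals)
  share_mod <- mean(vals[ok] >= params$moderate_or_above_cut)
  pop_by_centre <- tapply(pw[has_centre], centre, sum)[names(vals)]
  global_mean <- sum(vals[ok] * pop_by_centre[ok]) / sum(pop_by_centre[ok])
  bind_indicators(
    indicator_table("urban_ndvi", paste0("centre_", names(vals)[ok]), "annual",
                    vals[ok], "ndvi"),
    indicator_table("urban_ndvi_mean", "GLOBAL", "annual", global_mean, "ndvi"),
    indicator_table("urban_moderately_green_share", "GLOBAL", "annual",
                    100 * share_mod, "%")
  )
}

#' Population living below an elevation threshold
#'
#' Sums population over land cells with elevation strictly below
#' `threshold_m` ("less than"), per country and globally.
#'
#' @param regions a [region_table()].
#' @param pop a [population_grid()].
#' @param threshold_m elevation threshold in metres (default 1).
#' @return an [indicator_table()] of persons below the threshold.
#' @export
population_below_elevation <- function(regions, pop, threshold_m = 1) {
  pw <- colSums(matrix(pop$counts, nrow = length(pop$age_groups)))
  low <- regions$is_land & !is.na(regions$elevation_m) &
    regions$elevation_m < threshold_m
  by_country <- tapply(pw * low, regions$country_code, sum)
  by_country <- by_country[!is.na(by_country)]
  bind_indicators(
    indicator_table("population_below_elevation", names(by_country),
                    sprintf("<%gm", threshold_m), by_country, "persons"),
    indicator_table("population_below_elevation", "GLOBAL",
                    sprintf("<%gm", threshold_m), sum(pw[low]), "persons")
  )
}
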