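# Semi-quantification via internal-standard response factors, migration
# conversion, calibration for confirmed compounds, and system-suitability
# statistics.
#
# Units: concentrations in the extract are ng/mL unless stated; migration
# is mg per kg of food under the conventional 6 dm2/kg food-contact
# surface ratio.

#' Extract geometry and food-contact convention
#'
#' @param film_area extracted film area, dm2 (default 0.25, i.e. a
#'   5 cm x 5 cm portion).
#' @param extract_volume final extract volume, mL (default 1).
#' @param food_contact_ratio conventional food contact surface-to-mass
#'   ratio, dm2 per kg of food (default 6).
#' @return list of class `extract_geometry`.
#' @export
extract_geometry <- function(film_area = 0.25, extract_volume = 1.0,
                             food_contact_ratio = 6) {
  stopifnot(film_area > 0, extract_volume > 0, food_contact_ratio > 0)
  structure(list(film_area = film_area, extract_volume = extract_volume,
                 food_contact_ratio = food_contact_ratio),
            class = "extract_geometry")
}

#' Average internal-standard response factor
#'
#' Mean over internal standards and replicates of (peak area /
#' spiked concentration). This single factor converts any compound's area
#' to a semi-quantitative concentration estimate, deliberately ignoring
#' compound-specific response differences.
#'
#' @param standards data.frame as returned by [read_internal_standards()]
#'   (columns `name`, `spiked_conc_ng_ml`, list-column `areas`).
#' @return response factor, area units per (ng/mL).
#' @export
average_response_factor <- function(standards) {
  stopifnot(is.data.frame(standards), nrow(standards) >= 1L)
  if (any(standards$spiked_conc_ng_ml <= 0)) {
    stop("spiked concentration must be positive")
  }
  ratios <- unlist(lapply(seq_len(nrow(standards)), function(i) {
    standards$areas[[i]] / standards$spiked_conc_ng_ml[i]
  }))
  if (length(ratios) == 0L || any(!is.finite(ratios))) {
    stop("no finite area/concentration ratios")
  }
  mean(ratios)
}

#' Estimate concentration from peak area
#'
#' @param area peak area (arbitrary units, >= 0); vectorised.
#' @param rf average response factor (area per ng/mL, > 0).
#' @return estimated concentration, ng/mL.
#' @export
estimate_concentration <- function(area, rf) {
  if (!is.finite(rf) || rf <= 0) stop("response factor must be positive")
  if (any(area < 0)) stop("area must be non-negative")
  area / rf
}

#' Convert extract concentration to estimated migration
#'
#' `migration = conc (mg/mL) * extract_volume / film_area *
#' food_contact_ratio`: mass in the extract, per film area, scaled by the
#' conventional 6 dm2 of contact surface per kg of food.
#'
#' @param conc_mg_ml concentration in the extract, mg/mL; vectorised.
#'   (Divide ng/mL values by 1e6.)
#' @param geom an [extract_geometry()].
#' @return estimated migration, mg per kg of food.
#' @export
concentration_to_migration <- function(conc_mg_ml, geom = extract_geometry()) {
  stopifnot(inherits(geom, "extract_geometry"))
  if (any(conc_mg_ml < 0)) stop("concentration must be non-negative")
  conc_mg_ml * geom$extract_volume / geom$film_area * geom$food_contact_ratio
}

#' Semi-quantify identified compounds
#'
#' Convenience chain: area -> concentration (average response factor) ->
#' migration (extract geometry). Results are marked
#' `method = "response_factor"` so semi-quantitative values are never
#' confused with calibrated ones.
#'
#' @param identifications data.frame with columns `compound` and `area`
#'   (e.g. from [build_identification_table()]).
#' @param standards internal-standard table for
#'   [average_response_factor()].
#' @param geom an [extract_geometry()].
#' @return `identifications` with `est_conc_ng_ml`, `migration_mg_kg`,
#'   `quant_method` columns added.
#' @export
semi_quantify <- function(identifications, standards,
                          geom = extract_geometry()) {
  stopifnot("area" %in% names(identifications))
  rf <- average_response_factor(standards)
  conc <- estimate_concentration(identifications$area, rf)
  identifications$est_conc_ng_ml <- conc
  identifications$migration_mg_kg <-
    concentration_to_migration(conc / 1e6, geom)
  identifications$quant_method <- "response_factor"
  identifications
}

#' Calibrate with standards and quantify a sample
#'
#' Ordinary least-squares line of area ratio (analyte/internal standard)
#' versus concentration, inverted at the sample's area ratio. A sample
#' response outside the calibrated range is still inverted but flagged as
#' extrapolated.
#'
#' @param curve data.frame with columns `conc` (ng/mL) and `area_ratio`
#'   (>= 3 points, not all at one concentration).
#' @param sample_area_ratio observed area ratio of the sample.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return list with `conc` (ng/mL), `extrapolated` flag, `slope`,
#'   `intercept`, `r_squared`.
#' @export
calibrate_and_quantify <- function(curve, sample_area_ratio,
                                   weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(curve), all(c("conc", "area_ratio") %in% names(curve)))
  if (nrow(curve) < 3L) stop("calibration needs at least 3 points")
  if (length(unique(curve$conc)) < 2L) {
    stop("calibration is singular: all points at one concentration")
  }
  w <- if (weighting == "1/x") 1 / curve$conc else rep(1, nrow(curve))
  fit <- stats::lm(area_ratio ~ conc, data = curve, weights = w)
  b <- stats::coef(fit)[[1]]; m <- stats::coef(fit)[[2]]
  if (m == 0) stop("calibration slope is zero")
  conc <- (sample_area_ratio - b) / m
  ss_res <- sum(w * stats::residuals(fit)^2)
  ss_tot <- sum(w * (curve$area_ratio -
                       stats::weighted.mean(curve$area_ratio, w))^2)
  list(conc = conc,
       extrapolated = sample_area_ratio < min(curve$area_ratio) ||
         sample_area_ratio > max(curve$area_ratio),
       slope = m, intercept = b,
       r_squared = 1 - ss_res / ss_tot)
}

#' System-suitability report for internal standards
#'
#' Relative standard deviations of base-peak area and retention time over
#' replicate injections, and mass accuracy of each internal standard
#' against the theoretical radical-cation m/z of its formula.
#'
#' @param replicates data.frame with one row per (standard, replicate):
#'   columns `name`, `area`, `rt_min`, `observed_mz`, `formula`.
#' @param max_abs_ppm pass/fail bound on |mass accuracy| (default 2 ppm).
#' @return data.frame with one row per standard: `name`, `rsd_area_pct`,
#'   `rsd_rt_pct`, `delta_mass_ppm` (mean signed), `mass_ok`.
#' @export
system_suitability <- function(replicates, max_abs_ppm = 2) {
  req <- c("name", "area", "rt_min", "observed_mz", "formula")
  stopifnot(all(req %in% names(replicates)))
  out <- do.call(rbind, lapply(split(replicates, replicates$name), function(g) {
    if (nrow(g) < 2L) stop("standard '", g$name[1],
                           "': at least 2 replicates required")
    theo <- monoisotopic_mass(parse_formula(g$formula[1]),
                              as_radical_cation = TRUE)
    dppm <- mean(ppm_error(g$observed_mz, theo))
    data.frame(
      name = g$name[1],
      rsd_area_pct = 100 * stats::sd(g$area) / mean(g$area),
      rsd_rt_pct = 100 * stats::sd(g$rt_min) / mean(g$rt_min),
      delta_mass_ppm = dppm,
      mass_ok = abs(dppm) <= max_abs_ppm,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
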