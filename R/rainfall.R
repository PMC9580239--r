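#' Past rainfall from a speleothem oxygen-isotope anomaly
#'
#' Adjusts present-day mean annual rainfall using the calibration between
#' precipitation d18O and rainfall amount: a 1 permil *decrease* in
#' precipitation d18O corresponds to roughly a 200 mm/yr *increase* in
#' annual rainfall. The anomaly is signed as past minus present, so a
#' negative `delta_d18o` (isotopically lighter past precipitation) yields a
#' wetter past.
#'
#' @param present_mm Present-day annual rainfall, mm/yr (> 0).
#' @param delta_d18o Speleothem d18O anomaly, permil, past minus present.
#' @param floor_mm Lower clamp applied to the result so extreme anomalies
#'   cannot produce non-physical rainfall; default 1 mm.
#' @return Past annual rainfall estimate in mm/yr:
#'   `max(present_mm - 200 * delta_d18o, floor_mm)`. Vectorised.
#' @examples
#' speleothem_adjust(280, -1)   # 480: 1 permil lighter -> 200 mm wetter
#' speleothem_adjust(280, 0.5)  # 180: heavier past -> drier
#' @export
speleothem_adjust <- function(present_mm, delta_d18o, floor_mm = 1) {
  if (!all(is.finite(present_mm)) || !all(is.finite(delta_d18o))) {
    abort("`present_mm` and `delta_d18o` must be finite.")
  }
  if (any(present_mm <= 0)) abort("`present_mm` must be > 0.")
  pmax(present_mm - 200 * delta_d18o, floor_mm)
}

#' Past rainfall range from pollen-derived seasonal anomalies
#'
#' Builds a past-rainfall range from extreme monthly rainfall anomalies
#' (mm/month, past minus present) reconstructed from pollen, separately for
#' summer and winter. Each seasonal extreme is scaled by six months, the two
#' seasons are summed to give minimum and maximum deviations from modern
#' rainfall, and the point estimate is the average of the two bounds.
#'
#' @param present_mm Present-day annual rainfall, mm/yr (> 0).
#' @param summer_extreme_min,summer_extreme_max Most extreme summer monthly
#'   anomalies, mm/month; `min <= max`.
#' @param winter_extreme_min,winter_extreme_max As above for winter.
#' @param floor_mm Lower clamp for non-physical negative rainfall.
#' @return A one-row tibble with columns `min_mm`, `mean_mm`, `max_mm`
#'   satisfying `min_mm <= mean_mm <= max_mm` (vectorised inputs give one
#'   row each).
#' @examples
#' pollen_anomaly_range(700, -5, 10, -10, 5)  # min 610, mean 700, max 790
#' @export
pollen_anomaly_range <- function(present_mm,
                                 summer_extreme_min, summer_extreme_max,
                                 winter_extreme_min, winter_extreme_max,
                                 floor_mm = 1) {
  args <- list(present_mm, summer_extreme_min, summer_extreme_max,
               winter_extreme_min, winter_extreme_max)
  if (!all(vapply(args, function(a) all(is.finite(a)), logical(1)))) {
    abort("All inputs must be finite.")
  }
  if (any(present_mm <= 0)) abort("`present_mm` must be > 0.")
  if (any(summer_extreme_min > summer_extreme_max)) {
    abort("`summer_extreme_min` must be <= `summer_extreme_max`.")
  }
  if (any(winter_extreme_min > winter_extreme_max)) {
    abort("`winter_extreme_min` must be <= `winter_extreme_max`.")
  }
  min_mm <- pmax(present_mm + 6 * (summer_extreme_min + winter_extreme_min),
                 floor_mm)
  max_mm <- pmax(present_mm + 6 * (summer_extreme_max + winter_extreme_max),
                 floor_mm)
  tibble::tibble(min_mm = min_mm,
                 mean_mm = (min_mm + max_mm) / 2,
                 max_mm = max_mm)
}
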