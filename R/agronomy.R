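#' Plant density from planting geometry
#'
#' Plants per square metre for a rectangular planting grid:
#' `1 / (distance_m * row_spacing_m)`. Inputs are in centimetres as planting
#' plans are written; the trial kept row spacing fixed at 150 cm.
#'
#' @param planting_distance In-row distance between plants (cm), > 0.
#' @param row_spacing Distance between rows (cm), > 0 (default 150).
#' @return Plants per m2 (full precision; report rounded to 1 decimal).
#' @examples
#' plant_density(30, 150)   # 2.22... -> reported 2.2
#' plant_density(100, 100)  # 1 plant on a 1 m2 grid cell
#' @export
plant_density <- function(planting_distance, row_spacing = 150) {
  if (any(planting_distance <= 0) || any(row_spacing <= 0)) {
    abort("planting_distance and row_spacing must be > 0.")
  }
  1 / ((planting_distance / 100) * (row_spacing / 100))
}

#' Projected plant count per 10 a
#'
#' Number of plants on 10 a (= 1,000 m2) at the given grid, rounded to the
#' nearest whole plant. Rounding happens once, on the final count, so exact
#' fractional distances (e.g. 100/3 cm) reproduce planning-table counts.
#'
#' @inheritParams plant_density
#' @return Integer plant count per 10 a.
#' @examples
#' plants_per_10a(30, 150)    # 2222
#' plants_per_10a(22.5, 150)  # 2963
#' @export
plants_per_10a <- function(planting_distance, row_spacing = 150) {
  round(1000 * plant_density(planting_distance, row_spacing))
}

#' Irrigation water productivity
#'
#' WP = Y / V_ir: total fruit yield divided by total irrigation water
#' supplied, in kg per m3. Both quantities are per the same ground area
#' (here, per 10 a).
#'
#' @param total_yield Total fruit yield (kg/10a), >= 0.
#' @param irrigation_volume Irrigation water supplied (m3/10a), > 0.
#' @return kg/m3 (full precision; report rounded to 1 decimal).
#' @examples
#' water_productivity(1000, 500)  # 2
#' @export
water_productivity <- function(total_yield, irrigation_volume) {
  if (any(irrigation_volume <= 0)) {
    abort("irrigation_volume must be > 0.")
  }
  if (any(total_yield < 0)) abort("total_yield must be >= 0.")
  total_yield / irrigation_volume
}

#' Planting geometry table
#'
#' Computes plant density and projected plants per 10 a for pairs of planting
#' distances and row spacings, in one tibble.
#'
#' @inheritParams plant_density
#' @return A tibble with `planting_distance`, `row_spacing`,
#'   `plants_per_m2`, `plants_per_10a`.
#' @export
planting_geometry <- function(planting_distance, row_spacing = 150) {
  tibble(
    planting_distance = planting_distance,
    row_spacing = row_spacing,
    plants_per_m2 = plant_density(planting_distance, row_spacing),
    plants_per_10a = plants_per_10a(planting_distance, row_spacing)
  )
}
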