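#' Packaged trial reference tables
#'
#' Loads the small reference tables shipped with the package, transcribed from
#' the hydroponic netted-melon factorial trial they describe:
#'
#' * `"treatment_summary"` (alias `"table1"`): per-treatment total yield
#'   (kg/10a), water productivity (kg/m3), fertilizer and substrate cost
#'   (USD/10a), with Tukey letter groups for yield and water productivity.
#' * `"market_prices"` (alias `"table3"`): wholesale melon price (USD/kg) per
#'   market grade tier (Premium, Superior, Medium, Inferior): mean, max, min,
#'   sd. Converted from KRW at 1382 KRW/USD (stored as attribute
#'   `krw_per_usd`).
#' * `"planting_geometry"` (alias `"table4"`): planting distance per substrate
#'   volume x plants-per-slab combination. Distances that are truncated
#'   decimals of exact fractions (33.3 cm is 100/3) are stored as
#'   numerator/denominator pairs; `planting_distance` is the exact quotient.
#' * `"production_costs"`: seven-component production cost (USD/10a) per
#'   cultivation system (substrate volume x planting density).
#' * `"trial_calibration"`: per-treatment mean fruit weight, Brix, panel net
#'   score, fruit dimensions, fruit count, yield and water productivity used
#'   to calibrate the synthetic trial generator (see
#'   [default_effect_spec()]). Means not printed in the source tables are
#'   synthetic calibration values.
#'
#' All per-area quantities use 10 a = 1,000 m2.
#'
#' @param name Fixture name or alias (see above).
#' @return A tibble.
#' @examples
#' load_fixture("table3")
#' load_fixture("treatment_summary")
#' @export
load_fixture <- function(name) {
  aliases <- c(
    table1 = "treatment_summary",
    table3 = "market_prices",
    table4 = "planting_geometry"
  )
  if (name %in% names(aliases)) name <- aliases[[name]]
  known <- c(
    "treatment_summary", "market_prices", "planting_geometry",
    "production_costs", "trial_calibration"
  )
  if (!is.character(name) || length(name) != 1L || !name %in% known) {
    abort(paste0(
      "Unknown fixture '", paste(name, collapse = ","),
      "'. Available: ", paste(known, collapse = ", ")
    ))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "melonopt",
                      mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (name == "planting_geometry") {
    out <- mutate(out,
      planting_distance = .data$distance_num_cm / .data$distance_den
    )
  }
  if (name == "market_prices") {
    out$grade <- factor(out$grade, levels = grade_levels)
    attr(out, "krw_per_usd") <- krw_per_usd
  }
  out
}

#' Per-treatment irrigation volumes implied by yield and water productivity
#'
#' Irrigation volumes are not part of the reference tables; they are recovered
#' from the identity WP = Y / V_ir, i.e. V_ir = Y / WP, so that
#' [water_productivity()] applied to the result returns the tabulated WP
#' exactly.
#'
#' @param summary A tibble with columns `total_yield` and
#'   `water_productivity`; defaults to `load_fixture("treatment_summary")`.
#' @return The input with an `irrigation_volume` column (m3/10a).
#' @export
irrigation_volumes <- function(summary = load_fixture("treatment_summary")) {
  stopifnot(all(c("total_yield", "water_productivity") %in% names(summary)))
  if (any(summary$water_productivity <= 0)) {
    abort("water_productivity must be > 0 to recover irrigation volumes.")
  }
  mutate(summary,
    irrigation_volume = .data$total_yield / .data$water_productivity
  )
}
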