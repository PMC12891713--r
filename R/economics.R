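#' Revenue from grade-dependent pricing
#'
#' Sum over market tiers of production (kg/10a) times the tier's wholesale
#' price (USD/kg). Tiers absent from `production` contribute nothing; a tier
#' in `production` that is not priced is an error.
#'
#' @param production Tibble with columns `grade` and `production_kg`
#'   (kg/10a, >= 0), or a named numeric vector of kg by tier.
#' @param prices Price table as from `load_fixture("market_prices")`.
#' @param price_stat Which price statistic to apply: `"mean"` (default),
#'   `"min"` or `"max"`.
#' @return Revenue in USD/10a.
#' @examples
#' revenue(c(Premium = 1000))  # 7380
#' @export
revenue <- function(production, prices = load_fixture("market_prices"),
                    price_stat = c("mean", "min", "max")) {
  price_stat <- match.arg(price_stat)
  if (is.numeric(production) && !is.null(names(production))) {
    production <- tibble(grade = names(production),
                         production_kg = unname(production))
  }
  stopifnot(all(c("grade", "production_kg") %in% names(production)))
  if (any(production$production_kg < 0)) {
    abort("production_kg must be >= 0.")
  }
  unknown <- setdiff(as.character(production$grade),
                     as.character(prices$grade))
  if (length(unknown) > 0) {
    abort(paste0("Unknown grade tier(s): ", paste(unknown, collapse = ", ")))
  }
  price <- setNames(prices[[price_stat]], as.character(prices$grade))
  sum(production$production_kg * price[as.character(production$grade)])
}

#' Total production cost
#'
#' Sum of the seven cost components (USD/10a): substrate, seedlings, labor,
#' maintenance, energy, fertilizer, fixed. Any component may be zero, none
#' negative.
#'
#' @param costs Named numeric vector or one-row tibble/list with the seven
#'   components (missing components count as 0).
#' @return Total cost in USD/10a.
#' @export
total_cost <- function(costs) {
  components <- c("substrate", "seedlings", "labor", "maintenance",
                  "energy", "fertilizer", "fixed")
  if (is.data.frame(costs)) {
    if (nrow(costs) != 1) abort("costs must describe a single system.")
    costs <- unlist(costs[intersect(components, names(costs))])
  }
  costs <- unlist(costs)
  extra <- setdiff(names(costs), components)
  if (length(extra) > 0) {
    abort(paste0("Unknown cost component(s): ", paste(extra, collapse = ", ")))
  }
  if (any(costs < 0)) abort("Cost components must be >= 0.")
  sum(costs)
}

#' Return on investment
#'
#' `100 * (revenue - cost) / cost`: net profit as a percentage of total
#' production cost.
#'
#' @param total_revenue Revenue, USD/10a.
#' @param total_cost Total cost, USD/10a, > 0.
#' @return ROI in percent (full precision; report to 1 decimal).
#' @examples
#' roi(20000, 10000)  # 100
#' @export
roi <- function(total_revenue, total_cost) {
  if (any(total_cost <= 0)) abort("total_cost must be > 0.")
  100 * (total_revenue - total_cost) / total_cost
}

#' Percent change relative to a reference
#'
#' `100 * (comparison - reference) / reference`.
#'
#' @param reference Baseline value, > 0.
#' @param comparison New value.
#' @return Percent change (full precision; report to 1 decimal).
#' @examples
#' percent_change(1085.4, 1392.9)  # 28.3...
#' @export
percent_change <- function(reference, comparison) {
  if (any(reference <= 0)) abort("reference must be > 0.")
  100 * (comparison - reference) / reference
}

#' Per-treatment economics from a graded trial
#'
#' For each treatment, splits total yield across market tiers according to
#' the fruit-level grade distribution, prices each tier, subtracts the
#' system's production cost and reports net profit and ROI.
#'
#' @param records Fruit table.
#' @param yields Tibble with treatment columns and `total_yield` (kg/10a);
#'   defaults to the packaged trial summary.
#' @param prices Price table (USD/kg by tier).
#' @param costs Cost table with one row per cultivation system
#'   (`substrate_volume`, `plants_per_slab` + the seven components);
#'   defaults to the packaged cost fixture.
#' @param by Grade fruits by `"brix"` (default) or `"net"`.
#' @param price_stat Price statistic passed to [revenue()].
#' @param thresholds [brix_thresholds()].
#' @return Tibble of class `melon_economics`: one row per treatment with
#'   `total_revenue`, `total_cost`, `net_profit`, `roi`.
#' @export
economic_summary <- function(records,
                             yields = load_fixture("treatment_summary"),
                             prices = load_fixture("market_prices"),
                             costs = load_fixture("production_costs"),
                             by = "brix",
                             price_stat = "mean",
                             thresholds = brix_thresholds()) {
  dist <- grade_distribution(records, by = by, thresholds = thresholds)
  cost_cols <- c("substrate", "seedlings", "labor", "maintenance",
                 "energy", "fertilizer", "fixed")
  out <- dist %>%
    left_join(select(yields, "cultivar", "substrate_volume",
                     "plants_per_slab", "total_yield"),
              by = c("cultivar", "substrate_volume", "plants_per_slab")) %>%
    mutate(production_kg = .data$total_yield * .data$pct / 100) %>%
    group_by(.data$cultivar, .data$substrate_volume, .data$plants_per_slab,
             .data$total_yield) %>%
    summarise(
      total_revenue = revenue(
        tibble(grade = grade, production_kg = production_kg),
        prices = prices, price_stat = price_stat
      ),
      .groups = "drop"
    ) %>%
    left_join(costs, by = c("substrate_volume", "plants_per_slab")) %>%
    mutate(
      total_cost = rowSums(dplyr::pick(dplyr::all_of(cost_cols))),
      net_profit = .data$total_revenue - .data$total_cost,
      roi = roi(.data$total_revenue, .data$total_cost)
    ) %>%
    select(-dplyr::all_of(cost_cols))
  class(out) <- c("melon_economics", class(out))
  out
}
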