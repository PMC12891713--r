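#' Brix grade thresholds
#'
#' Lower cut points (degrees Brix) of the market tiers. A fruit is Premium
#' when brix >= premium, Superior in [superior, premium), Medium in
#' [medium, superior), Inferior below medium. Intervals are closed at the
#' lower bound: 14.0 is Premium, 12.0 Superior, 10.0 Medium.
#'
#' @param premium,superior,medium Strictly decreasing cut points;
#'   defaults 14, 12, 10.
#' @return Named numeric vector of class `"brix_thresholds"`.
#' @export
brix_thresholds <- function(premium = 14, superior = 12, medium = 10) {
  cuts <- c(premium = premium, superior = superior, medium = medium)
  if (any(diff(cuts) >= 0)) {
    abort("Thresholds must be strictly decreasing: premium > superior > medium.")
  }
  structure(cuts, class = "brix_thresholds")
}

#' Classify fruits into market tiers by sugar content
#'
#' @param brix Soluble solids (degrees Brix), > 0. Vectorized.
#' @param thresholds A [brix_thresholds()] object.
#' @return Factor with levels Premium, Superior, Medium, Inferior.
#' @examples
#' brix_grade(c(14.5, 12, 10.3, 9.9))
#' @export
brix_grade <- function(brix, thresholds = brix_thresholds()) {
  if (any(brix <= 0, na.rm = TRUE)) abort("brix must be > 0.")
  cut(brix,
    breaks = c(-Inf, rev(unname(thresholds)), Inf),
    labels = rev(grade_levels),
    right = FALSE
  ) |>
    factor(levels = grade_levels)
}

#' Classify fruits into market tiers by panel netting score
#'
#' The panel scale runs 1 (excellent) to 5 (bad). Continuous scores are
#' rounded to the nearest panel step and mapped 1 -> Premium, 2 -> Superior,
#' 3 -> Medium, >= 4 -> Inferior by default.
#'
#' @param net_score Panel netting score in [1, 5]. Vectorized.
#' @param map Named integer cut points: a rounded score `<= map["premium"]`
#'   is Premium, and so on.
#' @return Factor with levels Premium, Superior, Medium, Inferior.
#' @export
net_grade <- function(net_score, map = c(premium = 1, superior = 2, medium = 3)) {
  if (any(net_score < 1 | net_score > 5, na.rm = TRUE)) {
    abort("net_score must be in [1, 5].")
  }
  if (any(diff(map) <= 0)) abort("map cut points must be increasing.")
  r <- round(net_score)
  cut(r,
    breaks = c(-Inf, unname(map), Inf),
    labels = grade_levels,
    right = TRUE
  )
}

clamp_to_bounds <- function(observed, bounds, what) {
  out_of_range <- observed < bounds[1] | observed > bounds[2]
  if (any(out_of_range, na.rm = TRUE)) {
    warn(paste0(
      sum(out_of_range, na.rm = TRUE), " ", what,
      " value(s) outside bounds [", bounds[1], ", ", bounds[2],
      "]; clamped."
    ))
    observed <- pmin(pmax(observed, bounds[1]), bounds[2])
  }
  observed
}

check_bounds <- function(bounds, on_degenerate) {
  if (length(bounds) != 2 || any(is.na(bounds)) || bounds[2] < bounds[1]) {
    abort("bounds must be c(min, max) with max >= min.")
  }
  if (bounds[2] == bounds[1]) {
    if (on_degenerate == "error") {
      abort("Degenerate bounds (max == min): score undefined.")
    }
    warn("Degenerate bounds (max == min): returning 0.")
    return(FALSE)
  }
  TRUE
}

#' Min-max normalized sugar score
#'
#' Maps observed Brix onto 0-100 relative to the observed range:
#' `(observed - min) / (max - min) * 100`. Values outside the bounds are
#' clamped with a warning.
#'
#' @param observed Observed Brix value(s).
#' @param bounds `c(min, max)` of the observed set.
#' @param on_degenerate What to do when max == min: `"error"` (default for
#'   direct calls) or `"zero"` (matrix contexts).
#' @return Score(s) in [0, 100].
#' @examples
#' normalize_sugar(12.5, c(10, 15))  # 50
#' @export
normalize_sugar <- function(observed, bounds,
                            on_degenerate = c("error", "zero")) {
  on_degenerate <- match.arg(on_degenerate)
  if (!check_bounds(bounds, on_degenerate)) return(rep(0, length(observed)))
  observed <- clamp_to_bounds(observed, bounds, "Brix")
  (observed - bounds[1]) / (bounds[2] - bounds[1]) * 100
}

#' Reverse min-max normalized netting score
#'
#' Panel netting scores rank 1 best, so normalization is inverted:
#' `(max - observed) / (max - min) * 100`; the best (lowest) score maps
#' to 100.
#'
#' @inheritParams normalize_sugar
#' @return Score(s) in [0, 100].
#' @examples
#' reverse_normalize_net(3, c(1, 5))  # 50
#' @export
reverse_normalize_net <- function(observed, bounds,
                                  on_degenerate = c("error", "zero")) {
  on_degenerate <- match.arg(on_degenerate)
  if (!check_bounds(bounds, on_degenerate)) return(rep(0, length(observed)))
  observed <- clamp_to_bounds(observed, bounds, "net score")
  (bounds[2] - observed) / (bounds[2] - bounds[1]) * 100
}

#' Market-channel weighting of sugar and netting
#'
#' Weighting factors alpha (sugar) and beta (netting) for the composite
#' market grade. The premium channel (department-store / gift market) weighs
#' external netting more (0.7/0.3); the public channel (direct retail, where
#' fruit ships in protective mesh) leans on sugar (0.8/0.2).
#'
#' @param channel `"premium"` or `"public"`, or `"custom"` with explicit
#'   `alpha`.
#' @param alpha Optional custom sugar weight in [0, 1]; beta is `1 - alpha`.
#' @return List with `alpha`, `beta`, `channel`.
#' @export
market_weights <- function(channel = c("premium", "public", "custom"),
                           alpha = NULL) {
  channel <- match.arg(channel)
  if (channel == "custom") {
    if (is.null(alpha)) abort("Custom channel requires alpha.")
  } else {
    alpha <- c(premium = 0.7, public = 0.8)[[channel]]
  }
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1].")
  list(alpha = alpha, beta = 1 - alpha, channel = channel)
}

check_weights <- function(weights) {
  if (!all(c("alpha", "beta") %in% names(weights))) {
    abort("weights must have alpha and beta (see market_weights()).")
  }
  if (abs(weights$alpha + weights$beta - 1) > 1e-8 ||
      weights$alpha < 0 || weights$beta < 0) {
    abort("weights must satisfy alpha + beta = 1 with both in [0, 1].")
  }
  invisible(weights)
}

#' Composite market grade score
#'
#' `alpha * sugar_score + beta * netting_score` on the 0-100 scale, with
#' channel-specific weights.
#'
#' @param sugar_score Normalized sugar score(s), 0-100.
#' @param net_score_norm Reverse-normalized netting score(s), 0-100.
#' @param weights A [market_weights()] list.
#' @return Composite score(s) in [0, 100].
#' @examples
#' market_grade_score(100, 0, market_weights("premium"))  # 70
#' @export
market_grade_score <- function(sugar_score, net_score_norm,
                               weights = market_weights("premium")) {
  check_weights(weights)
  if (any(sugar_score < 0 | sugar_score > 100, na.rm = TRUE) ||
      any(net_score_norm < 0 | net_score_norm > 100, na.rm = TRUE)) {
    abort("Scores must already be on the 0-100 scale.")
  }
  weights$alpha * sugar_score + weights$beta * net_score_norm
}

#' Per-treatment grade distribution
#'
#' Percentage of fruits per market tier within each treatment, graded either
#' by sugar content or by panel netting score. Treatments with no fruits are
#' dropped with a warning.
#'
#' @param records Fruit table (see [fruit_table_schema()]).
#' @param by `"brix"` or `"net"`.
#' @param thresholds [brix_thresholds()] for `by = "brix"`.
#' @param net_map Tier map for `by = "net"` (see [net_grade()]).
#' @return Tibble with treatment columns, `grade`, `n` and `pct`; `pct` sums
#'   to 100 within a treatment.
#' @export
grade_distribution <- function(records, by = c("brix", "net"),
                               thresholds = brix_thresholds(),
                               net_map = c(premium = 1, superior = 2, medium = 3)) {
  by <- match.arg(by)
  records <- validate_fruit_table(records)
  grade <- switch(by,
    brix = brix_grade(records$brix, thresholds),
    net  = net_grade(records$net_score, net_map)
  )
  records$grade <- factor(grade, levels = grade_levels)
  records %>%
    group_by(.data$cultivar, .data$substrate_volume, .data$plants_per_slab,
             .data$grade, .drop = FALSE) %>%
    summarise(n = dplyr::n(), .groups = "drop_last") %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    filter(!is.nan(.data$pct))
}

#' Composite quality score per treatment
#'
#' Aggregates fruit records to treatment means, then scores each treatment on
#' 0-100: sugar normalized over the range of treatment-mean Brix, netting
#' reverse-normalized over the range of treatment-mean panel scores (bounds
#' taken jointly over the whole trial), combined with channel weights.
#' The treatment holding both trial maxima scores 100.
#'
#' @param records Fruit table.
#' @param weights [market_weights()]; the premium channel is the default
#'   used for quality-score reporting.
#' @return Tibble of treatments with `mean_brix`, `mean_net`, `sugar_score`,
#'   `net_score_norm` and `quality_score`.
#' @export
treatment_quality_score <- function(records,
                                    weights = market_weights("premium")) {
  records <- validate_fruit_table(records)
  means <- records %>%
    group_by(.data$cultivar, .data$substrate_volume, .data$plants_per_slab) %>%
    summarise(
      mean_brix = mean(.data$brix),
      mean_net = mean(.data$net_score),
      .groups = "drop"
    )
  quality_scores(means, weights = weights)
}

#' Composite quality score from treatment-level means
#'
#' Same scoring as [treatment_quality_score()], starting from a summary table
#' that already holds `mean_brix` and `mean_net` per treatment (for instance
#' `load_fixture("trial_calibration")`).
#'
#' @param summaries Tibble with `mean_brix` and `mean_net` columns.
#' @param weights [market_weights()].
#' @return `summaries` with `sugar_score`, `net_score_norm`, `quality_score`.
#' @export
quality_scores <- function(summaries, weights = market_weights("premium")) {
  check_weights(weights)
  stopifnot(all(c("mean_brix", "mean_net") %in% names(summaries)))
  brix_bounds <- range(summaries$mean_brix)
  net_bounds <- range(summaries$mean_net)
  summaries %>%
    mutate(
      sugar_score = normalize_sugar(.data$mean_brix, brix_bounds,
                                    on_degenerate = "zero"),
      net_score_norm = reverse_normalize_net(.data$mean_net, net_bounds,
                                             on_degenerate = "zero"),
      quality_score = market_grade_score(.data$sugar_score,
                                         .data$net_score_norm, weights)
    )
}
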