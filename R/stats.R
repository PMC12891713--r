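p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "NS"
  )
}

#' Balanced three-way factorial ANOVA on fruit records
#'
#' Classical fixed-effects decomposition for the cultivar (C) x substrate
#' volume (S) x planting density (D) factorial: sums of squares for the three
#' main effects, all interactions and the residual, with F tests against the
#' residual mean square and the usual significance stars (*, **, *** at
#' 0.05/0.01/0.001). Requires a balanced complete factorial (equal cell
#' counts, >= 2 per cell); for unbalanced data aggregate to cell means first.
#' Fitting is delegated to [stats::aov()].
#'
#' @param records Fruit table.
#' @param response Name of the response column (e.g. `"brix"`).
#' @return Tibble with `term` (C, S, D, C:S, C:D, S:D, C:S:D, Residuals),
#'   `df`, `sumsq`, `meansq`, `statistic`, `p.value`, `stars`; attribute
#'   `response`.
#' @export
three_way_anova <- function(records, response) {
  records <- validate_fruit_table(records)
  if (!response %in% names(records)) {
    abort(paste0("Unknown response '", response, "'."))
  }
  cells <- count(records, .data$cultivar, .data$substrate_volume,
                 .data$plants_per_slab)
  n_cells <- dplyr::n_distinct(records$cultivar) *
    dplyr::n_distinct(records$substrate_volume) *
    dplyr::n_distinct(records$plants_per_slab)
  if (nrow(cells) != n_cells || dplyr::n_distinct(cells$n) != 1) {
    abort(paste0(
      "Design is not a balanced complete factorial (unequal or missing ",
      "cells). Aggregate to cell means before testing."
    ))
  }
  if (cells$n[1] < 2) abort("Need >= 2 observations per cell.")
  d <- tibble(
    y = records[[response]],
    C = factor(records$cultivar),
    S = factor(records$substrate_volume),
    D = factor(records$plants_per_slab)
  )
  fit <- aov(y ~ C * S * D, data = d)
  tab <- summary(fit)[[1]]
  out <- tibble(
    term = trimws(rownames(tab)),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
  out$stars <- ifelse(out$term == "Residuals", "", p_stars(out$p.value))
  attr(out, "response") <- response
  out
}

# Greedy insert-absorb compact letter display: start from one letter covering
# everything; for each significant pair sharing a letter, split that letter
# into two (each excluding one member), then absorb letters whose group is a
# subset of another's.
cld_letters <- function(group_names, sig_pairs) {
  sets <- list(group_names)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$g1[k]
    b <- sig_pairs$g2[k]
    hit <- which(vapply(sets, function(s) a %in% s && b %in% s, logical(1)))
    if (length(hit) == 0) next
    split <- purrr::flatten(purrr::map(sets[hit], function(s) {
      list(setdiff(s, a), setdiff(s, b))
    }))
    sets <- c(sets[-hit], split)
    sets <- sets[lengths(sets) > 0]
    # absorb any set contained in another (duplicates keep first occurrence)
    drop <- rep(FALSE, length(sets))
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i == j || drop[i] || drop[j]) next
        if (all(sets[[i]] %in% sets[[j]]) &&
            (length(sets[[i]]) < length(sets[[j]]) || j < i)) {
          drop[i] <- TRUE
          break
        }
      }
    }
    sets <- sets[!drop]
  }
  # stable letter order: by first (best-ranked) member of each set
  ord <- order(vapply(sets, function(s) min(match(s, group_names)), integer(1)))
  sets <- sets[ord]
  vapply(group_names, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
}

#' Tukey HSD pairwise tests with compact letter display
#'
#' All-pairs mean separation by the studentized range (Tukey's Honest
#' Significant Difference, via [stats::TukeyHSD()]) followed by a greedy
#' compact letter display: two groups share no letter if and only if their
#' difference is significant at `alpha`. Letters are assigned in descending
#' order of the group means, so `"a"` marks the top group.
#'
#' @param df Tibble in long form.
#' @param value Name of the numeric value column.
#' @param group Name of the grouping column.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List of class `tukey_cld` with `letters` (group, mean, n, letters)
#'   and `pairs` (g1, g2, estimate, p.adj, significant).
#' @export
tukey_hsd <- function(df, value, group, alpha = 0.05) {
  x <- df[[value]]
  g <- factor(df[[group]])
  sizes <- table(g)
  if (length(sizes) < 2) abort("Need >= 2 groups.")
  if (any(sizes < 2)) abort("Every group needs >= 2 values.")
  fit <- aov(x ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- tibble(
    g1 = vapply(nm, `[`, character(1), 1),
    g2 = vapply(nm, `[`, character(1), 2),
    estimate = unname(tk[, "diff"]),
    p.adj = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"] < alpha)
  )
  means <- sort(tapply(x, g, mean), decreasing = TRUE)
  lt <- cld_letters(names(means), pairs[pairs$significant, ])
  out <- list(
    letters = tibble(
      group = names(means),
      mean = as.numeric(means),
      n = as.integer(sizes[names(means)]),
      letters = unname(lt)
    ),
    pairs = pairs,
    alpha = alpha
  )
  class(out) <- "tukey_cld"
  out
}

#' @export
print.tukey_cld <- function(x, ...) {
  cat("Tukey HSD at alpha =", x$alpha, "\n")
  print(x$letters)
  invisible(x)
}

#' @method tidy tukey_cld
#' @export
tidy.tukey_cld <- function(x, ...) x$letters

#' Pearson correlation matrix of treatment-level metrics
#'
#' Pairwise Pearson correlations across treatments for the selected metric
#' columns. With only a dozen treatments these are descriptive; no p-values
#' are attached. A constant metric yields `NA` entries and a warning, never a
#' silent 0.
#'
#' @param summaries Tibble, one row per treatment.
#' @param metrics Character vector of numeric metric columns; default all
#'   numeric columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(summaries, metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  }
  stopifnot(all(metrics %in% names(summaries)))
  if (nrow(summaries) < 3) abort("Need >= 3 treatments.")
  m <- as.matrix(summaries[metrics])
  constant <- apply(m, 2, function(v) diff(range(v)) == 0)
  if (any(constant)) {
    warn(paste0("Constant metric(s): ",
                paste(metrics[constant], collapse = ", "),
                "; correlations undefined (NA)."))
  }
  suppressWarnings(r <- cor(m, method = "pearson"))
  diag(r) <- ifelse(constant, NA_real_, 1)
  r
}

#' Normalized treatment performance matrix
#'
#' The six-metric treatment scoreboard: composite quality score, total yield,
#' water productivity, ROI, mean flesh thickness and mean fruit weight, each
#' min-max normalized to 0-100 across treatments (all maximize-sense), so
#' every non-degenerate column attains both 0 and 100.
#'
#' @param summaries Tibble with one row per treatment holding
#'   `quality_score`, `total_yield`, `water_productivity`, `roi`,
#'   `mean_flesh`, `mean_weight` (or a custom `metrics` selection).
#' @param metrics Metric columns to normalize.
#' @return Tibble of class `melon_performance`: treatment columns plus the
#'   normalized metrics.
#' @export
performance_matrix <- function(summaries,
                               metrics = c("quality_score", "total_yield",
                                           "water_productivity", "roi",
                                           "mean_flesh", "mean_weight")) {
  missing <- setdiff(metrics, names(summaries))
  if (length(missing) > 0) {
    abort(paste0("Missing metric(s): ", paste(missing, collapse = ", ")))
  }
  out <- minmax_normalize(as_tibble(summaries), objectives = metrics,
                          sense = "maximize")
  structure(out, metrics = metrics,
            class = c("melon_performance", class(out)))
}
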