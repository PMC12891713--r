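sim_responses <- c("weight", "brix", "net_score", "length", "diameter",
                   "flesh_thickness")

# calibration column holding each response's treatment means
calib_cols <- c(
  weight = "mean_weight", brix = "mean_brix", net_score = "mean_net",
  length = "mean_length", diameter = "mean_diameter",
  flesh_thickness = "mean_flesh"
)

#' Effect specification for the synthetic factorial trial
#'
#' Builds the generator's effect structure from a table of per-treatment
#' response means: for each response the cell means are decomposed into a
#' grand mean, cultivar/substrate/density main effects (marginal deviations)
#' and an interaction remainder, so the implied treatment-mean surface
#' reproduces the calibration table exactly while the main effects stay
#' interpretable.
#'
#' @param calibration Tibble with the treatment columns, `n_fruits`,
#'   `total_yield`, `water_productivity` and a mean column per response (see
#'   `load_fixture("trial_calibration")`).
#' @param residual_sd Named numeric: within-treatment standard deviation per
#'   response, all >= 0. The source trial reports no within-treatment
#'   variances, so these are generator parameters, not estimates.
#' @param block_sd Standard deviation of the zero-mean Gaussian block effect
#'   shared by all responses of a block (default 0).
#' @return An object of class `effect_spec`.
#' @seealso [default_effect_spec()], [simulate_trial()]
#' @export
effect_spec <- function(calibration,
                        residual_sd = c(weight = 0.12, brix = 0.6,
                                        net_score = 0.15, length = 0.5,
                                        diameter = 0.4,
                                        flesh_thickness = 1.8),
                        block_sd = 0) {
  needed <- c("cultivar", "substrate_volume", "plants_per_slab", "n_fruits",
              "total_yield", "water_productivity", unname(calib_cols))
  missing <- setdiff(needed, names(calibration))
  if (length(missing) > 0) {
    abort(paste0("calibration lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(calibration[c("cultivar", "substrate_volume",
                                  "plants_per_slab")])) {
    abort("Treatments must be unique in the calibration table.")
  }
  if (!all(sim_responses %in% names(residual_sd))) {
    abort("residual_sd must name every response.")
  }
  if (any(residual_sd < 0) || block_sd < 0) {
    abort("Standard deviations must be >= 0.")
  }
  if (any(calibration$n_fruits < 1)) abort("n_fruits must be >= 1.")

  treatments <- calibration %>%
    mutate(irrigation_volume = .data$total_yield / .data$water_productivity)
  effects <- purrr::map(sim_responses, function(resp) {
    y <- calibration[[calib_cols[[resp]]]]
    mu <- mean(y)
    eff <- function(f) tapply(y, f, mean) - mu
    a <- eff(calibration$cultivar)
    b <- eff(calibration$substrate_volume)
    d <- eff(calibration$plants_per_slab)
    additive <- mu + a[as.character(calibration$cultivar)] +
      b[as.character(calibration$substrate_volume)] +
      d[as.character(calibration$plants_per_slab)]
    list(grand = mu, cultivar = a, substrate = b, density = d,
         interaction = y - unname(additive))
  })
  structure(
    list(
      treatments = treatments,
      effects = setNames(effects, sim_responses),
      residual_sd = residual_sd[sim_responses],
      block_sd = block_sd
    ),
    class = "effect_spec"
  )
}

#' Default effect specification
#'
#' The packaged calibration: a 3 cultivar x 2 substrate volume x 2 planting
#' density trial whose implied treatment means match the packaged
#' calibration table, and whose per-treatment irrigation volumes are set to
#' yield / water-productivity so the tabulated water productivity is
#' recovered exactly.
#'
#' @param n_fruits Optional override of the per-treatment fruit count: a
#'   single number (recycled) or one count per treatment.
#' @param ... Passed to [effect_spec()] (`residual_sd`, `block_sd`).
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function(n_fruits = NULL, ...) {
  calibration <- load_fixture("trial_calibration")
  if (!is.null(n_fruits)) {
    calibration$n_fruits <- rep(n_fruits, length.out = nrow(calibration))
  }
  effect_spec(calibration, ...)
}

#' Treatment means implied by an effect specification
#'
#' Reconstructs the per-treatment mean surface (grand mean + main effects +
#' interaction) for every response.
#'
#' @param spec An [effect_spec()].
#' @return Tibble: treatments plus one column per response.
#' @export
implied_means <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  out <- spec$treatments[c("cultivar", "substrate_volume", "plants_per_slab")]
  for (resp in sim_responses) {
    e <- spec$effects[[resp]]
    out[[resp]] <- as.numeric(
      e$grand +
        e$cultivar[as.character(out$cultivar)] +
        e$substrate[as.character(out$substrate_volume)] +
        e$density[as.character(out$plants_per_slab)] +
        e$interaction
    )
  }
  out
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("Synthetic trial effect spec:", nrow(x$treatments), "treatments,",
      sum(x$treatments$n_fruits), "fruits\n")
  cat("residual sd:",
      paste(names(x$residual_sd), signif(x$residual_sd, 3),
            sep = "=", collapse = ", "),
      "\nblock sd:", x$block_sd, "\n")
  invisible(x)
}

#' Randomization plan for the synthetic trial
#'
#' @param seed Integer RNG seed. The default, 20200129, is the trial's sowing
#'   date written as yyyymmdd; it is a documented constant, nothing more.
#' @param n_blocks Number of complete blocks (replicates), >= 1; default 3.
#' @return A list with `seed` and `n_blocks`.
#' @export
random_plan <- function(seed = 20200129, n_blocks = 3) {
  if (n_blocks < 1) abort("n_blocks must be >= 1.")
  list(seed = as.integer(seed), n_blocks = as.integer(n_blocks))
}

#' Simulate a randomized complete block factorial trial
#'
#' Draws per-fruit measurements as treatment mean + block effect + Gaussian
#' residual, independently per response. Fruits are allocated to blocks as
#' evenly as possible; counts are exact. Panel net scores are generated
#' continuous and clamped to the 1-5 scale (optionally rounded to integer
#' panel steps). Identical `(spec, plan)` gives bit-identical output.
#'
#' @param spec An [effect_spec()].
#' @param plan A [random_plan()].
#' @param round_net Round net scores to whole panel steps? Default `FALSE`
#'   (panel treatment means are non-integer).
#' @return A fruit-record tibble (see [fruit_table_schema()]) with attribute
#'   `"irrigation"`, a per-treatment tibble of irrigation volumes (m3/10a),
#'   also available via [irrigation_volumes()] on `spec$treatments`.
#' @export
simulate_trial <- function(spec, plan = random_plan(), round_net = FALSE) {
  stopifnot(inherits(spec, "effect_spec"))
  means <- implied_means(spec)
  n_t <- nrow(means)
  counts <- spec$treatments$n_fruits
  withr::with_seed(plan$seed, {
    block_eff <- matrix(
      rnorm(plan$n_blocks * length(sim_responses), 0, spec$block_sd),
      nrow = plan$n_blocks,
      dimnames = list(NULL, sim_responses)
    )
    rows <- purrr::map(seq_len(n_t), function(i) {
      n <- counts[i]
      base <- n %/% plan$n_blocks
      extra <- n %% plan$n_blocks
      blocks <- rep(seq_len(plan$n_blocks),
                    times = base + (seq_len(plan$n_blocks) <= extra))
      rec <- tibble(
        cultivar = means$cultivar[i],
        substrate_volume = means$substrate_volume[i],
        plants_per_slab = means$plants_per_slab[i],
        block = blocks
      )
      for (resp in sim_responses) {
        rec[[resp]] <- means[[resp]][i] + block_eff[blocks, resp] +
          rnorm(n, 0, spec$residual_sd[[resp]])
      }
      rec
    })
  })
  out <- bind_rows(rows)
  out$net_score <- pmin(pmax(out$net_score, 1), 5)
  if (round_net) out$net_score <- round(out$net_score)
  out <- select(out, dplyr::all_of(fruit_table_schema()$column))
  attr(out, "irrigation") <- spec$treatments[
    c("cultivar", "substrate_volume", "plants_per_slab", "irrigation_volume")
  ]
  invisible(validate_fruit_table(out, call_label = "simulated trial"))
  out
}
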