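# Small builders and independent oracles used across the suite.

make_fruit_df <- function(n = 12,
                          cultivar = "Dalgona",
                          substrate_volume = 10,
                          plants_per_slab = 3,
                          block = 1,
                          weight = 1.4, length = 14, diameter = 13.5,
                          flesh_thickness = 40, brix = 13, net_score = 1.5) {
  tibble::tibble(
    cultivar = rep_len(cultivar, n),
    substrate_volume = rep_len(substrate_volume, n),
    plants_per_slab = rep_len(plants_per_slab, n),
    block = rep_len(block, n),
    weight = rep_len(weight, n),
    length = rep_len(length, n),
    diameter = rep_len(diameter, n),
    flesh_thickness = rep_len(flesh_thickness, n),
    brix = rep_len(brix, n),
    net_score = rep_len(net_score, n)
  )
}

# A balanced factorial of fruit records with iid noise, for ANOVA fixtures.
random_balanced_trial <- function(n_per_cell = 4, sd = 1, seed = 42) {
  withr::with_seed(seed, {
    grid <- expand.grid(
      cultivar = c("Dalgona", "Hero", "Kingstar"),
      substrate_volume = c(10, 20),
      plants_per_slab = c(3, 4),
      rep = seq_len(n_per_cell),
      stringsAsFactors = FALSE
    )
    tibble::tibble(
      cultivar = grid$cultivar,
      substrate_volume = grid$substrate_volume,
      plants_per_slab = grid$plants_per_slab,
      block = grid$rep,
      weight = abs(rnorm(nrow(grid), 1.5, 0.2)) + 0.01,
      length = rnorm(nrow(grid), 15, sd),
      diameter = rnorm(nrow(grid), 14, sd),
      flesh_thickness = rnorm(nrow(grid), 40, sd),
      brix = rnorm(nrow(grid), 12, sd),
      net_score = pmin(pmax(rnorm(nrow(grid), 2, 0.4), 1), 5)
    )
  })
}

# Brute-force non-dominated flags: nested loops, no shared code with
# pareto_front(). Maximize-sense matrix in, logical vector out.
oracle_front <- function(m) {
  n <- nrow(m)
  flags <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      geq <- TRUE
      strict <- FALSE
      for (k in seq_len(ncol(m))) {
        if (m[j, k] < m[i, k]) geq <- FALSE
        if (m[j, k] > m[i, k]) strict <- TRUE
      }
      if (geq && strict) {
        flags[i] <- FALSE
        break
      }
    }
  }
  flags
}

# Direct cell-means sums-of-squares decomposition for a balanced three-way
# factorial, independent of stats::aov.
oracle_three_way_ss <- function(records, response) {
  y <- records[[response]]
  A <- factor(records$cultivar)
  B <- factor(records$substrate_volume)
  D <- factor(records$plants_per_slab)
  n <- nrow(records) / (nlevels(A) * nlevels(B) * nlevels(D))
  g <- mean(y)
  mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  mD <- tapply(y, D, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAD <- tapply(y, list(A, D), mean)
  mBD <- tapply(y, list(B, D), mean)
  mABD <- tapply(y, list(A, B, D), mean)
  ss_A <- n * nlevels(B) * nlevels(D) * sum((mA - g)^2)
  ss_B <- n * nlevels(A) * nlevels(D) * sum((mB - g)^2)
  ss_D <- n * nlevels(A) * nlevels(B) * sum((mD - g)^2)
  ss_AB <- n * nlevels(D) *
    sum((mAB - outer(mA, rep(0, nlevels(B)), "+") -
           outer(rep(0, nlevels(A)), mB, "+") + g)^2)
  ss_AD <- n * nlevels(B) *
    sum((mAD - outer(mA, rep(0, nlevels(D)), "+") -
           outer(rep(0, nlevels(A)), mD, "+") + g)^2)
  ss_BD <- n * nlevels(A) *
    sum((mBD - outer(mB, rep(0, nlevels(D)), "+") -
           outer(rep(0, nlevels(B)), mD, "+") + g)^2)
  full <- array(0, dim = c(nlevels(A), nlevels(B), nlevels(D)))
  for (i in seq_len(nlevels(A))) for (j in seq_len(nlevels(B))) {
    for (k in seq_len(nlevels(D))) {
      full[i, j, k] <- mABD[i, j, k] -
        mAB[i, j] - mAD[i, k] - mBD[j, k] +
        mA[i] + mB[j] + mD[k] - g
    }
  }
  ss_ABD <- n * sum(full^2)
  cell_mean <- mABD[cbind(as.integer(A), as.integer(B), as.integer(D))]
  ss_res <- sum((y - cell_mean)^2)
  c(C = ss_A, S = ss_B, D = ss_D, `C:S` = ss_AB, `C:D` = ss_AD,
    `S:D` = ss_BD, `C:S:D` = ss_ABD, Residuals = ss_res)
}

# Studentized-range Tukey decision for a balanced one-way layout, computed
# straight from ptukey (independent of stats::TukeyHSD).
oracle_tukey_p <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  ni <- table(g)
  mse <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / (length(x) - k)
  df <- length(x) - k
  means <- tapply(x, g, mean)
  out <- list()
  cmb <- utils::combn(levels(g), 2)
  for (c_i in seq_len(ncol(cmb))) {
    a <- cmb[1, c_i]; b <- cmb[2, c_i]
    se <- sqrt(mse / 2 * (1 / ni[[a]] + 1 / ni[[b]]))
    q <- abs(means[[a]] - means[[b]]) / se
    out[[paste(a, b, sep = "|")]] <- ptukey(q, k, df, lower.tail = FALSE)
  }
  unlist(out)
}
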