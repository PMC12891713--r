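test_that("three-way ANOVA matches the cell-means oracle exactly", {
  d <- random_balanced_trial(n_per_cell = 5, seed = 101)
  for (resp in c("brix", "weight", "flesh_thickness")) {
    got <- three_way_anova(d, resp)
    ss <- setNames(got$sumsq, got$term)
    want <- oracle_three_way_ss(d, resp)
    expect_equal(ss[names(want)], want, tolerance = 1e-10)
    # SS additivity on the balanced design
    total <- sum((d[[resp]] - mean(d[[resp]]))^2)
    expect_equal(sum(got$sumsq), total, tolerance = 1e-8 * total)
    expect_equal(sum(got$df), nrow(d) - 1)
  }
})

test_that("a constant response yields zero sums of squares", {
  d <- random_balanced_trial(n_per_cell = 3)
  d$brix <- 12
  a <- three_way_anova(d, "brix")
  expect_equal(a$sumsq, rep(0, nrow(a)), tolerance = 1e-20)
})

test_that("a pure cultivar effect loads only the cultivar term", {
  d <- random_balanced_trial(n_per_cell = 3)
  d$brix <- c(Dalgona = 14, Hero = 12, Kingstar = 10)[d$cultivar]
  a <- three_way_anova(d, "brix")
  expect_gt(a$sumsq[a$term == "C"], 0)
  others <- a$sumsq[a$term != "C"]
  expect_equal(others, rep(0, length(others)), tolerance = 1e-18)
})

test_that("unbalanced designs are rejected with guidance", {
  d <- random_balanced_trial(n_per_cell = 3)
  expect_error(three_way_anova(d[-1, ], "brix"), "balanced")
  expect_error(three_way_anova(d, "no_such"), "Unknown response")
  d1 <- random_balanced_trial(n_per_cell = 1)
  expect_error(three_way_anova(d1, "brix"), ">= 2")
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_equal(melonopt:::p_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
               c("NS", "*", "**", "***", ""))
})

test_that("Tukey decisions agree with the studentized-range oracle", {
  withr::with_seed(55, {
    d <- tibble::tibble(
      g = rep(c("a1", "a2", "a3"), each = 8),
      y = rnorm(24) + rep(c(0, 0.5, 3), each = 8)
    )
  })
  tk <- tukey_hsd(d, "y", "g")
  want <- oracle_tukey_p(d$y, d$g)
  for (i in seq_len(nrow(tk$pairs))) {
    key1 <- paste(tk$pairs$g1[i], tk$pairs$g2[i], sep = "|")
    key2 <- paste(tk$pairs$g2[i], tk$pairs$g1[i], sep = "|")
    p <- want[[if (key1 %in% names(want)) key1 else key2]]
    expect_equal(tk$pairs$p.adj[i], p, tolerance = 1e-6)
  }
})

test_that("compact letters separate exactly the significant pairs", {
  # two clearly identical groups share a letter; a distant one does not
  withr::with_seed(4, {
    d <- tibble::tibble(
      g = rep(c("lo1", "lo2", "hi"), each = 10),
      y = c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1), rnorm(10, 50, 0.1))
    )
  })
  tk <- tukey_hsd(d, "y", "g")
  lt <- setNames(tk$letters$letters, tk$letters$group)
  share <- function(a, b) {
    any(strsplit(lt[[a]], "")[[1]] %in% strsplit(lt[[b]], "")[[1]])
  }
  expect_true(share("lo1", "lo2"))
  expect_false(share("hi", "lo1"))
  expect_false(share("hi", "lo2"))
})

test_that("letter sharing is consistent with pairwise decisions", {
  withr::with_seed(321, {
    for (rep in 1:5) {
      k <- sample(3:6, 1)
      d <- tibble::tibble(
        g = rep(paste0("g", seq_len(k)), each = 6),
        y = rnorm(6 * k) + rep(runif(k, 0, 4), each = 6)
      )
      tk <- tukey_hsd(d, "y", "g")
      lt <- setNames(strsplit(tk$letters$letters, ""), tk$letters$group)
      for (i in seq_len(nrow(tk$pairs))) {
        shared <- length(intersect(lt[[tk$pairs$g1[i]]],
                                   lt[[tk$pairs$g2[i]]])) > 0
        expect_equal(shared, !tk$pairs$significant[i])
      }
    }
  })
  expect_error(tukey_hsd(tibble::tibble(g = c("a", "a"), y = 1:2), "y", "g"),
               ">= 2 groups")
  expect_error(
    tukey_hsd(tibble::tibble(g = c("a", "a", "b"), y = 1:3), "y", "g"),
    ">= 2 values"
  )
})

test_that("Pearson matrices are symmetric, unit-diagonal and PSD", {
  withr::with_seed(12, {
    s <- tibble::tibble(a = rnorm(12), b = rnorm(12))
    s$c <- -s$a
    r <- pearson_matrix(s)
    expect_equal(r, t(r))
    expect_equal(diag(r), c(a = 1, b = 1, c = 1))
    expect_equal(r["a", "c"], -1)
    expect_true(all(eigen(r, only.values = TRUE)$values > -1e-10))
    # against the direct covariance formula
    manual <- sum((s$a - mean(s$a)) * (s$b - mean(s$b))) /
      sqrt(sum((s$a - mean(s$a))^2) * sum((s$b - mean(s$b))^2))
    expect_equal(r["a", "b"], manual)
  })
  expect_warning(
    r2 <- pearson_matrix(tibble::tibble(a = rnorm(5), k = rep(1, 5))),
    "Constant"
  )
  expect_true(is.na(r2["k", "k"]))
  expect_error(pearson_matrix(tibble::tibble(a = 1:2)), ">= 3")
})

test_that("the performance matrix is column-normalized to the 0-100 span", {
  withr::with_seed(9, {
    s <- tibble::tibble(
      cultivar = rep(c("Dalgona", "Hero", "Kingstar"), each = 4),
      substrate_volume = rep(c(10, 10, 20, 20), 3),
      plants_per_slab = rep(c(3, 4), 6),
      quality_score = runif(12, 40, 95),
      total_yield = runif(12, 2400, 4400),
      water_productivity = runif(12, 3, 6),
      roi = runif(12, 40, 270),
      mean_flesh = runif(12, 35, 43),
      mean_weight = runif(12, 1.1, 1.7)
    )
  })
  pm <- performance_matrix(s)
  for (m in attr(pm, "metrics")) {
    expect_equal(range(pm[[m]]), c(0, 100))
  }
  # best-ROI treatment scores 100 in the ROI column
  expect_equal(pm$roi[which.max(s$roi)], 100)
  # delegation: identical to minmax_normalize applied directly
  direct <- minmax_normalize(s, objectives = attr(pm, "metrics"))
  expect_equal(pm$roi, direct$roi)
  expect_error(performance_matrix(s[, -4]), "Missing metric")
})
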