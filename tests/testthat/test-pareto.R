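test_that("min-max normalization spans 0-100 and respects sense", {
  expect_equal(minmax_normalize(tibble::tibble(y = c(10, 20)))$y, c(0, 100))
  expect_warning(
    z <- minmax_normalize(tibble::tibble(y = c(5, 5, 5))),
    "constant"
  )
  expect_equal(z$y, c(0, 0, 0))
  # a mid value on the trial's yield span
  yields <- load_fixture("table1")$total_yield
  n <- minmax_normalize(tibble::tibble(y = yields))$y
  expect_equal(round(n[yields == 3466], 1), 53.1)
  # minimize-sense flips the ends
  m <- minmax_normalize(tibble::tibble(y = c(1, 3)), sense = "minimize")
  expect_equal(m$y, c(100, 0))
  expect_error(minmax_normalize(tibble::tibble(y = c(1, NA))), "Missing")
})

test_that("every non-degenerate normalized column attains 0 and 100", {
  withr::with_seed(21, {
    for (i in 1:10) {
      df <- tibble::as_tibble(as.data.frame(matrix(rnorm(60), ncol = 3)))
      sense <- sample(c("maximize", "minimize"), 3, replace = TRUE)
      z <- minmax_normalize(df, sense = sense)
      for (j in names(z)) {
        expect_equal(range(z[[j]]), c(0, 100))
      }
    }
  })
})

test_that("dominance follows the strict component-wise definition", {
  expect_true(dominates(c(2, 2, 2), c(1, 1, 1)))
  expect_true(dominates(c(2, 1), c(1, 1)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("dominance is a strict partial order", {
  withr::with_seed(77, {
    vecs <- replicate(40, sample(0:3, 3, replace = TRUE), simplify = FALSE)
    for (a in vecs) expect_false(dominates(a, a))
    for (i in seq_along(vecs)) {
      for (j in seq_along(vecs)) {
        if (dominates(vecs[[i]], vecs[[j]])) {
          expect_false(dominates(vecs[[j]], vecs[[i]]))
        }
      }
    }
    # transitivity on random triples
    for (r in 1:200) {
      idx <- sample(seq_along(vecs), 3)
      a <- vecs[[idx[1]]]; b <- vecs[[idx[2]]]; c <- vecs[[idx[3]]]
      if (dominates(a, b) && dominates(b, c)) {
        expect_true(dominates(a, c))
      }
    }
  })
})

test_that("frontier handles singletons and exact ties", {
  one <- pareto_front(tibble::tibble(x = 1, y = 2))
  expect_equal(one$.frontier, TRUE)
  dup <- pareto_front(tibble::tibble(x = c(1, 1, 0), y = c(2, 2, 0)))
  expect_equal(dup$.frontier, c(TRUE, TRUE, FALSE))
  expect_error(pareto_front(tibble::tibble(x = numeric(0))), "one candidate")
})

test_that("frontier matches the brute-force oracle on random matrices", {
  withr::with_seed(2024, {
    sizes <- list(c(10, 2), c(50, 3), c(120, 4), c(200, 6))
    for (s in sizes) {
      m <- matrix(rnorm(s[1] * s[2]), ncol = s[2])
      df <- tibble::as_tibble(as.data.frame(m))
      pf <- pareto_front(df)
      expect_equal(pf$.frontier, oracle_front(m))
      expect_true(any(pf$.frontier))  # never empty
      # ties-by-duplication: duplicate rows never change others' status
      df2 <- dplyr::bind_rows(df, df[1, ])
      pf2 <- pareto_front(df2)
      expect_equal(pf2$.frontier[seq_len(s[1])], pf$.frontier)
    }
  })
})

test_that("the frontier is invariant under strictly increasing transforms", {
  withr::with_seed(13, {
    df <- tibble::as_tibble(as.data.frame(matrix(runif(90, 1, 9), ncol = 3)))
    base <- pareto_front(df)$.frontier
    trans <- list(function(x) 3 * x + 7, exp, function(x) x^3,
                  function(x) rank(x, ties.method = "min"))
    for (f in trans) {
      df2 <- dplyr::mutate(df, dplyr::across(dplyr::everything(), f))
      expect_equal(pareto_front(df2)$.frontier, base)
    }
    # including the 0-100 normalization itself
    expect_equal(pareto_front(minmax_normalize(df))$.frontier, base)
  })
})

test_that("minimize-sense via negation matches manual pre-negation", {
  withr::with_seed(3, {
    df <- tibble::as_tibble(as.data.frame(matrix(rnorm(45), ncol = 3)))
    a <- pareto_front(df, sense = c("maximize", "minimize", "maximize"))
    b <- pareto_front(dplyr::mutate(df, V2 = -V2))
    expect_equal(a$.frontier, b$.frontier)
  })
})

test_that("per-group frontiers are extracted within each group only", {
  df <- tibble::tibble(
    g = c("a", "a", "b", "b"),
    x = c(1, 2, 0.5, 0.4),
    y = c(1, 2, 0.5, 0.4)
  )
  pf <- pareto_front(df, objectives = c("x", "y"), within = "g")
  expect_equal(pf$.frontier, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("projections carry frontier flags without recomputation", {
  withr::with_seed(8, {
    df <- tibble::as_tibble(as.data.frame(matrix(rnorm(150), ncol = 3)))
    pf <- pareto_front(df)
    pr <- frontier_projection(pf, c("V1", "V3"))
    expect_equal(pr$.frontier, pf$.frontier)
    expect_error(frontier_projection(pf, c("V1", "nope")), "Unknown axis")
    two <- pareto_front(tibble::tibble(x = c(1, 0), y = c(0, 1)))
    expect_equal(frontier_projection(two, c("x", "y"))$.frontier,
                 c(TRUE, TRUE))
  })
})

test_that("tidy and glance summarise a frontier object", {
  pf <- pareto_front(tibble::tibble(x = c(1, 2), y = c(2, 1)))
  expect_s3_class(tidy(pf), "tbl_df")
  g <- glance(pf)
  expect_equal(g$n_candidates, 2)
  expect_equal(g$n_frontier, 2)
})
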