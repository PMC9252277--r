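ex <- example1_fixture()

test_that("index selection picks the enumeration optimum on the worked example", {
  # all 6 pairs enumerated by the oracle; steep weights favour the
  # high-trait-2 pair, equal weights the high-total pair
  opt1 <- oracle_index_optima(ex$values, c(0.1, 0.9), 2)
  expect_length(opt1, 1)
  expect_equal(index_select(ex$values, c(0.1, 0.9), 2)$selected, opt1[[1]])
  expect_equal(index_select(ex$values, c(0.1, 0.9), 2)$ids, c("i1", "i2"))

  opt2 <- oracle_index_optima(ex$values, c(0.5, 0.5), 2)
  expect_equal(index_select(ex$values, c(0.5, 0.5), 2)$selected, opt2[[1]])
  expect_equal(index_select(ex$values, c(0.5, 0.5), 2)$ids, c("i3", "i4"))
})

test_that("single-trait index selection is truncation by value", {
  set.seed(21)
  v <- genetic_values(matrix(rnorm(15), 15, 1))
  for (S in c(1, 3, 5)) {
    res <- index_select(v, 1, S)
    expect_setequal(res$selected, order(-unclass(v)[, 1])[seq_len(S)])
  }
  expect_error(index_select(v, 1, 16), "more individuals")
})

test_that("index selection respects score ties lexicographically", {
  v <- genetic_values(matrix(c(1, 1, 0.5), 3, 1,
                             dimnames = list(c("b", "a", "c"), "t")))
  expect_equal(index_select(v, 1, 1)$ids, "a")
})

test_that("the max-min objective matches the printed example and is
          homogeneous of degree -1 in the weights", {
  # cross c3 = {i1, i4}: sums (0.49, 0.39), equal weights -> 0.39/0.5 = 0.78
  expect_equal(lshaped_objective(c("i1", "i4"), ex$values, c(0.5, 0.5)), 0.78)
  # symmetric case: equal trait sums t and uniform weights 1/K give K * t
  vsym <- genetic_values(matrix(0.2, 4, 3), normalized = TRUE)
  expect_equal(lshaped_objective(1:2, vsym, rep(1 / 3, 3)), 3 * 0.4)
  set.seed(22)
  vn <- rand_values(8, 2, normalized = TRUE)
  w <- c(0.3, 0.7)
  o1 <- lshaped_objective(c(2, 5), vn, w)
  expect_equal(lshaped_objective(c(2, 5), vn, 5 * w), o1 / 5)
})

test_that("L-shaped selection solves the worked example for both weight sets", {
  res <- lshaped_select(ex$values, c(0.5, 0.5), 2)
  expect_equal(res$ids, c("i1", "i4"))     # cross c3
  expect_equal(res$objective, 0.78)
  # constructive weights of cross c2 recover c2
  expect_equal(lshaped_select(ex$values, c(0.35, 0.48), 2)$ids, c("i1", "i3"))
})

test_that("L-shaped selection equals index selection for a single trait", {
  set.seed(23)
  vn <- rand_values(10, 1, normalized = TRUE)
  for (S in c(1, 2, 4)) {
    expect_equal(lshaped_select(vn, 1, S)$selected,
                 index_select(vn, 1, S)$selected)
  }
})

test_that("L-shaped selection matches the enumeration oracle on random instances", {
  set.seed(24)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    K <- sample(2:3, 1)
    S <- sample(1:min(3, n), 1)
    vn <- rand_values(n, K, normalized = TRUE)
    w <- stats::runif(K, 0.1, 2)
    res <- lshaped_select(vn, w, S)
    oracle <- oracle_lshaped_optima(vn, w, S)
    expect_equal(res$objective, oracle$value, tolerance = 1e-12)
    expect_true(any(vapply(oracle$subsets,
                           function(s) identical(sort(s), res$selected),
                           logical(1))))
  }
})

test_that("oversized instances raise a capacity error, not a heuristic answer", {
  set.seed(25)
  vn <- rand_values(30, 2, normalized = TRUE)
  expect_error(lshaped_select(vn, c(1, 1), 2, enumeration_cap = 100),
               "capacity|too large")
})

test_that("constructive weights equal the subset's normalized trait sums", {
  w2 <- weights_for_solution(c("i1", "i3"), ex$values)
  expect_equal(unname(unclass(w2)), c(0.35, 0.48))
  w6 <- weights_for_solution(c("i3", "i4"), ex$values)
  expect_equal(unname(unclass(w6)), c(0.74, 0.21))
  expect_true(all(unclass(w6) > 0))
})

test_that("weighted-sum optima are Pareto optimal among subset sums", {
  # guarantee of index selection under strictly positive weights
  set.seed(26)
  for (rep in 1:60) {
    n <- sample(4:10, 1)
    K <- sample(2:3, 1)
    S <- sample(1:min(3, n), 1)
    v <- rand_values(n, K)
    w <- stats::runif(K, 0.05, 3)
    res <- index_select(v, w, S)
    enum <- oracle_subset_sums(v, S)
    pick <- which(vapply(enum$subsets,
                         function(s) identical(sort(s), res$selected),
                         logical(1)))
    expect_true(pick %in% oracle_pareto(enum$sums))
  }
})

test_that("every Pareto-optimal subset is a max-min optimum under its own sums", {
  # constructive recovery guarantee, checked exhaustively on small instances
  set.seed(27)
  for (rep in 1:30) {
    n <- sample(5:9, 1)
    K <- sample(2:3, 1)
    S <- sample(2:3, 1)
    vn <- rand_values(n, K, normalized = TRUE)
    enum <- oracle_subset_sums(vn, S)
    for (p in oracle_pareto(enum$sums)) {
      w <- enum$sums[p, ]
      objs <- vapply(seq_along(enum$subsets),
                     function(i) min(enum$sums[i, ] / w), numeric(1))
      expect_equal(objs[p], 1)                     # attains value 1 ...
      expect_lte(max(objs), 1 + 1e-12)             # ... which is the maximum
    }
  }
})

test_that("L-shaped selection is invariant under per-trait unit changes", {
  set.seed(28)
  for (rep in 1:100) {
    n <- sample(5:9, 1)
    v <- rand_values(n, 2)
    a <- stats::runif(2, 0.05, 50)
    off <- stats::rnorm(2, 0, 10)
    v2 <- genetic_values(sweep(sweep(unclass(v), 2, a, `*`), 2, off, `+`))
    sel1 <- lshaped_select(normalize_values(v, compute_bounds(v)), c(1, 1), 2)
    sel2 <- lshaped_select(normalize_values(v2, compute_bounds(v2)), c(1, 1), 2)
    expect_identical(sel1$selected, sel2$selected)
  }
})

test_that("raw-value index selection can change its winner under unit changes", {
  # two candidates, one trait rescaled tenfold flips the weighted-sum ranking
  v <- genetic_values(matrix(c(1.0, 1.5,
                               2.0, 1.4), 2, 2,
                             dimnames = list(c("a", "b"), NULL)))
  w <- c(0.5, 0.5)
  before <- index_select(v, w, 1)$ids
  v10 <- genetic_values(sweep(unclass(v), 2, c(10, 1), `*`))
  after <- index_select(v10, w, 1)$ids
  expect_equal(before, "a")
  expect_equal(after, "b")
  # whereas the normalized max-min pipeline is unaffected
  expect_identical(
    lshaped_select(normalize_values(v, compute_bounds(v)), w, 1)$ids,
    lshaped_select(normalize_values(v10, compute_bounds(v10)), w, 1)$ids)
})

test_that("rescaling all weights by a constant changes no selection", {
  set.seed(29)
  vn <- rand_values(9, 2, normalized = TRUE)
  v <- rand_values(9, 2)
  w <- c(0.25, 0.75)
  for (c0 in c(0.1, 3, 1000)) {
    expect_identical(lshaped_select(vn, c0 * w, 2)$selected,
                     lshaped_select(vn, w, 2)$selected)
    expect_identical(index_select(v, c0 * w, 2)$selected,
                     index_select(v, w, 2)$selected)
  }
})
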