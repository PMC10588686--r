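test_that("d' hits its endpoints on perfectly specialized and neutral matrices", {
  perfect <- matrix(c(5, 0, 0, 5), 2, 2)
  expect_equal(specialization_d(perfect)$d_prime, c(1, 1))

  neutral <- matrix(1, 2, 2)
  res <- specialization_d(neutral)
  expect_equal(res$d, c(0, 0))
  expect_equal(res$d_prime, c(0, 0))
})

test_that("greedy d_max equals the exhaustive integer-allocation maximum", {
  set.seed(4)
  for (rep in 1:30) {
    A <- matrix(rpois(12, 1), 3, 4)
    if (sum(A) == 0 || sum(A) > 12) next
    res <- specialization_d(A)
    q <- colSums(A) / sum(A)
    for (i in 1:3) {
      r <- sum(A[i, ])
      if (r == 0) next
      expect_equal(res$d_max[i], brute_d_max(r, q), tolerance = 1e-12)
    }
  }
})

test_that("d' stays in [0,1] and zero rows are flagged, not fatal", {
  set.seed(11)
  for (rep in 1:1000) {
    A <- matrix(rpois(20, 2), 4, 5)
    if (sum(A) == 0) next
    res <- specialization_d(A)
    ok <- !is.na(res$d_prime)
    expect_true(all(res$d_prime[ok] >= 0 & res$d_prime[ok] <= 1))
    expect_true(all(is.na(res$d_prime[res$degree == 0])))
  }
})

test_that("Barber modularity evaluates its formula and is permutation invariant", {
  expect_equal(barber_modularity(diag(2), c(1, 2), c(1, 2)), 0.5)
  expect_equal(barber_modularity(matrix(1, 3, 4), rep(1, 3), rep(1, 4)), 0)

  set.seed(2)
  A <- matrix(rpois(20, 3) + 1, 4, 5)
  rm_ <- c(1, 2, 1, 2); cm_ <- c(1, 1, 2, 2, 1)
  q0 <- barber_modularity(A, rm_, cm_)
  pr <- sample(4); pc <- sample(5)
  expect_equal(barber_modularity(A[pr, pc], rm_[pr], cm_[pc]), q0)
  expect_error(barber_modularity(A, c(1, 2), cm_), "length")
})

test_that("DIRTLPAwb+ recovers planted blocks and is self-consistent", {
  A <- planted_partition_matrix(3, 4, 4, 20, 0, seed = 5)
  mp <- dirt_lpawb_plus(A, n_runs = 10, seed = 2)
  expect_equal(mp$n_modules, 3)
  expect_equal(unname(mp$row_modules), attr(A, "row_groups"))
  expect_equal(unname(mp$col_modules), attr(A, "col_groups"))
  expect_equal(mp$Q,
               barber_modularity(A, attr(A, "row_groups"),
                                 attr(A, "col_groups")),
               tolerance = 1e-12)

  # single cell: one module, Q = 0
  one <- dirt_lpawb_plus(matrix(5, 1, 1), n_runs = 3, seed = 1)
  expect_equal(one$n_modules, 1)
  expect_equal(one$Q, 0)

  # single group in its uniform limit: one module, nothing to split
  A1 <- matrix(10, 4, 4)
  expect_equal(dirt_lpawb_plus(A1, n_runs = 5, seed = 1)$n_modules, 1)

  # returned Q is never below the trivial one-module partition, and always
  # equals Barber Q recomputed from the returned labels
  set.seed(8)
  for (rep in 1:10) {
    A <- matrix(rpois(30, 2), 5, 6)
    if (sum(A) == 0) next
    mp <- dirt_lpawb_plus(A, n_runs = 5, seed = rep)
    expect_gte(mp$Q, 0)
    expect_equal(mp$Q,
                 barber_modularity(A, mp$row_modules, mp$col_modules),
                 tolerance = 1e-12)
  }
  expect_error(dirt_lpawb_plus(diag(2), n_runs = 0), "n_runs")
})

test_that("module search is bit-reproducible under a fixed seed", {
  A <- planted_partition_matrix(3, 5, 4, 8, 1, seed = 6)
  expect_identical(dirt_lpawb_plus(A, n_runs = 8, seed = 42),
                   dirt_lpawb_plus(A, n_runs = 8, seed = 42))
  expect_identical(patefield_sample(rowSums(A), colSums(A), n = 3, seed = 9),
                   patefield_sample(rowSums(A), colSums(A), n = 3, seed = 9))
})

test_that("Patefield draws conserve margins and match 2x2 enumeration", {
  set.seed(10)
  for (rep in 1:10) {
    r <- rpois(4, 20) + 1; cmarg <- rmultinom(1, sum(r), rep(1, 5))[, 1]
    tabs <- patefield_sample(r, cmarg, n = 20, seed = rep)
    for (tb in tabs) {
      expect_identical(rowSums(tb), as.numeric(r))
      expect_identical(colSums(tb), as.numeric(cmarg))
    }
  }
  expect_error(patefield_sample(c(2, 2), c(1, 2)), "equal totals")

  # margins (1,1)/(1,1): exactly two feasible tables, each ~50%
  draws <- patefield_sample(c(1, 1), c(1, 1), n = 10000, seed = 77)
  p_diag <- mean(vapply(draws, function(tb) tb[1, 1] == 1, logical(1)))
  expect_lt(abs(p_diag - 0.5), 0.02)

  # hypergeometric cell expectation r_i c_j / F within 3 Monte-Carlo SEs
  r <- c(6, 10, 4); cmarg <- c(8, 7, 5)
  draws <- patefield_sample(r, cmarg, n = 20000, seed = 5)
  arr <- simplify2array(draws)
  for (i in 1:3) for (j in 1:3) {
    expval <- r[i] * cmarg[j] / sum(r)
    se <- sd(arr[i, j, ]) / sqrt(dim(arr)[3])
    expect_lt(abs(mean(arr[i, j, ]) - expval), 3 * se + 1e-9)
  }
})

test_that("modularity z-score separates planted structure from its own null", {
  # planted modules: strong z in nearly all seeds
  z_planted <- vapply(1:20, function(s) {
    A <- planted_partition_matrix(3, 4, 4, 20, 0.2, seed = s)
    modularity_zscore(A, n_null = 30, n_runs = 5, seed = s)$z
  }, numeric(1))
  expect_gte(mean(z_planted > 3), 0.95)

  # a fresh Patefield draw from its own margins is typically unremarkable
  r <- c(40, 30, 20, 15, 10, 8, 5, 4); cmarg <- rep(22, 6)
  z_null <- vapply(1:50, function(s) {
    A <- patefield_sample(r, cmarg, seed = 1000 + s)
    modularity_zscore(A, n_null = 30, n_runs = 5, seed = s)$z
  }, numeric(1))
  expect_gte(mean(abs(z_null) <= 3), 0.90)

  expect_error(modularity_zscore(diag(2), n_null = 0), "n_null")
})

test_that("degenerate null ensembles report an infinite z with a warning", {
  # a 1x2 network with margins (2),(1,1) has a single feasible table
  A <- matrix(c(1, 1), 1, 2)
  expect_warning(res <- modularity_zscore(A, n_null = 10, n_runs = 2,
                                          seed = 1),
                 "zero spread")
  expect_identical(res$z, Inf)
})

test_that("core-periphery matches exhaustive search and CPness bookkeeping", {
  set.seed(21)
  for (rep in 1:12) {
    A <- matrix(rpois(16, 3), 4, 4)
    if (sum(A) == 0 || any(rowSums(A) == 0) || any(colSums(A) == 0)) next
    cp <- core_periphery(A)
    ll <- brute_cp_loglik(A, unname(cp$row_core), unname(cp$col_core))
    expect_equal(ll, brute_cp_optimum(A), tolerance = 1e-9)
    expect_equal(sum(cp$E), sum(A))
    expect_gte(cp$cpness, 0)
    expect_lte(cp$cpness, 1)
  }
})

test_that("CPness is 1 when the periphery-periphery block is empty", {
  # all weight inside a 2x2 corner; remaining species interact not at all
  # beyond a trace link keeping their degrees positive
  A <- matrix(0, 4, 4)
  A[1:2, 1:2] <- 20
  A[3, 3] <- 1; A[4, 4] <- 1
  cp <- core_periphery(A)
  expect_true(all(cp$row_core[1:2]))
  expect_true(all(cp$col_core[1:2]))
  expect_lt(1 - cp$cpness, 0.05)

  full <- matrix(5, 3, 3)
  cp_full <- core_periphery(full)
  expect_equal(sum(cp_full$E), 45)

  # single-species guild is all-core by convention
  cp1 <- core_periphery(matrix(c(3, 1), 1, 2))
  expect_true(all(cp1$row_core))
})
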