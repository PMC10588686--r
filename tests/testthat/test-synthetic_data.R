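test_that("scenario validation enforces its invariants", {
  expect_s3_class(make_scenario(), "synthetic_scenario")
  expect_error(make_scenario(weight_neutral = 0.5, weight_match = 0.5,
                             weight_dominance = 0.5), "sum to 1")
  expect_error(make_scenario(dyad_observability = 1.2), "0, 1")
  expect_error(make_scenario(steepness = -1), "steepness")
  expect_error(make_scenario(total_contests = -5), "nonnegative")
  expect_error(make_scenario(latent_dominance = 1:3), "length")
  expect_error(make_scenario(hummingbird_abundance = rep(0, 13)),
               "positive")
})

test_that("tournament generator honours its deterministic limits", {
  # no contests: all-zero matrix
  sc0 <- make_scenario(total_contests = 0, seed = 3)
  expect_true(all(simulate_tournament(sc0) == 0))

  # infinitely steep hierarchy with strictly ordered scores: the higher
  # species wins every contest, so the matrix is upper triangular
  sci <- make_scenario(steepness = Inf, dyad_observability = 1,
                       total_contests = 300, seed = 4)
  W <- simulate_tournament(sci)
  expect_true(all(W[lower.tri(W)] == 0))
  expect_equal(sum(W), 300)

  # no observable dyads but contests demanded: explicit error
  scx <- make_scenario(dyad_observability = 0, total_contests = 10)
  expect_error(simulate_tournament(scx), "observable")
})

test_that("unobserved-dyad proportion matches its binomial expectation", {
  # observability 0.45 with ~14 contests per observable dyad: essentially
  # all observable dyads are seen, so E[prop unknown] ~ 0.55
  props <- vapply(1:200, function(s) {
    sc <- make_scenario(dyad_observability = 0.45, total_contests = 477,
                        seed = s)
    tournament_summary(simulate_tournament(sc))$prop_unknown
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.55), 0.02)
})

test_that("generators are bit-reproducible for a fixed seed", {
  sc <- make_scenario(seed = 99)
  expect_identical(simulate_tournament(sc), simulate_tournament(sc))
  tr <- simulate_traits(sc)
  expect_identical(tr, simulate_traits(sc))
  expect_identical(simulate_visitation(sc, tr), simulate_visitation(sc, tr))
  expect_identical(planted_partition_matrix(2, 3, 3, 9, 1, seed = 5),
                   planted_partition_matrix(2, 3, 3, 9, 1, seed = 5))
  # different seed, different draw
  sc2 <- make_scenario(seed = 100)
  expect_false(identical(simulate_tournament(sc), simulate_tournament(sc2)))
})

test_that("neutral visitation follows the abundance-product multinomial", {
  # goodness of fit against the exact multinomial expectation, alpha = 0.01
  sc <- make_scenario(n_hummingbirds = 6, n_plants = 5,
                      latent_dominance = seq(1, -1, length.out = 6),
                      hummingbird_abundance = c(8, 10, 12, 14, 16, 18),
                      plant_flower_abundance = c(30, 40, 50, 60, 70),
                      weight_neutral = 1, weight_match = 0,
                      weight_dominance = 0, total_visits = 10000)
  p <- outer(sc$hummingbird_abundance, sc$plant_flower_abundance)
  p <- as.vector(p / sum(p))
  rejections <- sum(vapply(1:100, function(s) {
    sc$seed <- s
    V <- simulate_visitation(sc, simulate_traits(sc))
    stats::chisq.test(as.vector(V), p = p)$p.value < 0.01
  }, logical(1)))
  expect_lte(rejections, 5)

  # zero effort: zero matrix
  sc0 <- make_scenario(total_visits = 0)
  expect_true(all(simulate_visitation(sc0, simulate_traits(sc0)) == 0))
})

test_that("row margins concentrate on abundance shares at large effort", {
  sc <- make_scenario(n_hummingbirds = 5, n_plants = 4,
                      latent_dominance = seq(1, -1, length.out = 5),
                      hummingbird_abundance = c(20, 25, 30, 35, 40),
                      plant_flower_abundance = c(50, 60, 70, 80),
                      weight_neutral = 1, weight_match = 0,
                      weight_dominance = 0,
                      total_visits = 100000, seed = 12)
  V <- simulate_visitation(sc, simulate_traits(sc))
  share <- rowSums(V) / sum(V)
  truth <- sc$hummingbird_abundance / sum(sc$hummingbird_abundance)
  expect_lt(max(abs(share - truth) / truth), 0.02)
})

test_that("pure dominance driver sends the top species to the richest plant", {
  hits <- vapply(1:200, function(s) {
    sc <- make_scenario(weight_neutral = 0, weight_match = 0,
                        weight_dominance = 1, total_visits = 2272,
                        seed = s)
    tr <- simulate_traits(sc)
    # one plant offers 10x the calories of any other
    cal <- calories_per_flower(tr$plants$nectar_volume,
                               tr$plants$nectar_concentration)
    rich <- which.max(cal)
    tr$plants$nectar_volume[rich] <-
      10 * max(calories_per_flower(tr$plants$nectar_volume[-rich],
                                   tr$plants$nectar_concentration[-rich])) /
      (brix_to_molarity(tr$plants$nectar_concentration[rich]) * 1.34)
    V <- simulate_visitation(sc, tr)
    top <- which.max(sc$latent_dominance)
    which.max(V[top, ]) == rich
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("planted-partition fixtures expose their ground truth", {
  A <- planted_partition_matrix(3, 2, 2, 8, 0, seed = 2)
  expect_equal(dim(A), c(6, 6))
  # between_mean = 0: strictly block diagonal
  for (i in 1:6) for (j in 1:6) {
    if (attr(A, "row_groups")[i] != attr(A, "col_groups")[j])
      expect_equal(A[i, j], 0)
  }
  expect_error(planted_partition_matrix(0, 2, 2, 5, 1), "positive")
  expect_error(planted_partition_matrix(2, 2, 2, 1, 2), "within_mean")
})

test_that("David's score recovers the latent hierarchy in a strong regime", {
  rho <- vapply(1:50, function(s) {
    sc <- make_scenario(steepness = 2.5, dyad_observability = 1,
                        total_contests = 600,
                        latent_dominance = seq(2, -2, length.out = 13) * 1.5,
                        seed = s)
    W <- simulate_tournament(sc)
    cor(davids_score(W), sc$latent_dominance, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho), 0.9)
})
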