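test_that("nectar energetics follow the volume x molarity x 1.34 rule", {
  expect_equal(calories_per_flower(0, 20), 0)
  expect_equal(calories_per_flower(10, molarity = 0.5), 6.7)
  # Brix 34.23 converts to exactly 1 molar sucrose (warned: beyond the
  # refractometer range)
  expect_warning(mol <- brix_to_molarity(34.23), "range")
  expect_equal(mol, 1)
  expect_error(calories_per_flower(-1, 20), "nonnegative")
  expect_error(calories_per_flower(1, molarity = -2), "nonnegative")

  expect_equal(calories_per_species(6.7, 100), 670)
  expect_equal(calories_per_species(5, 0), 0)
  expect_equal(calories_per_species(1, 1), 1)
})

test_that("morphological match is a z-scored Euclidean distance", {
  hb <- data.frame(species = c("A", "B"), bill_length = c(10, 20),
                   bill_curvature = c(5, 15))
  pl <- data.frame(species = c("X", "Y"), corolla_length = c(10, 20),
                   corolla_curvature = c(5, 15))
  D <- morphological_match(hb, pl)
  # identical standardized positions match perfectly
  expect_equal(D["A", "X"], 0)
  expect_equal(D["B", "Y"], 0)
  # z-scoring makes the distance invariant to affine trait rescaling
  pl2 <- transform(pl, corolla_length = corolla_length * 7 + 3)
  expect_equal(morphological_match(hb, pl2), D)

  # hand-checkable offsets on standardized axes
  hb3 <- data.frame(species = c("A", "B", "C"), bill_length = c(1, 2, 3),
                    bill_curvature = c(1, 2, 3))
  pl3 <- data.frame(species = c("X", "Y", "Z"), corolla_length = c(1, 2, 3),
                    corolla_curvature = c(1, 1, 1))
  expect_warning(D3 <- morphological_match(hb3, pl3), "zero variance")
  # B is at z = (0, 0); X at z = (-1, 0): one unit on one axis
  expect_equal(D3["B", "X"], 1)
  # A at (-1, -1), Y at (0, 0): sqrt(2) apart
  expect_equal(D3["A", "Y"], sqrt(2))

  # exchanging which guild supplies which axis values leaves D transposed
  hb_sw <- data.frame(species = pl3$species,
                      bill_length = pl3$corolla_length,
                      bill_curvature = pl3$corolla_curvature)
  pl_sw <- data.frame(species = hb3$species,
                      corolla_length = hb3$bill_length,
                      corolla_curvature = hb3$bill_curvature)
  expect_warning(D3_sw <- morphological_match(hb_sw, pl_sw), "zero variance")
  expect_equal(D3_sw, t(D3))
})

test_that("abundance proportions pool surveys and normalize", {
  expect_equal(abundance_proportions(c(10, 30, 60)), c(0.1, 0.3, 0.6))
  expect_equal(abundance_proportions(100), 1)
  expect_equal(abundance_proportions(rep(7, 5)), rep(0.2, 5))
  # matrix input: species x survey counts pooled before normalizing
  m <- cbind(c(1, 2), c(3, 4))
  expect_equal(abundance_proportions(m), c(0.4, 0.6))
  expect_error(abundance_proportions(c(0, 0)), "positive")
})

test_that("the pair table is full-factorial and lossless", {
  sc <- make_scenario(seed = 8)
  tr <- simulate_traits(sc)
  V <- simulate_visitation(sc, tr)
  pair <- build_pair_table(V, tr$hummingbirds, tr$plants)

  expect_equal(nrow(pair), 13 * 10)
  expect_equal(sum(pair$visits), sum(V))
  # structural zeros are retained
  expect_true(any(pair$visits == 0))
  # proportions each sum to 1 over their own guild
  expect_equal(sum(unique(pair[c("hummingbird",
                                 "hummingbird_abundance_prop")])[[2]]), 1)
  expect_equal(sum(unique(pair[c("plant", "flower_abundance_prop")])[[2]]),
               1)
  # matrix reconstructable from the table
  V2 <- xtabs(visits ~ hummingbird + plant, pair)
  expect_equal(unclass(V2)[rownames(V), colnames(V)], unclass(V)[, ],
               ignore_attr = TRUE)

  bad <- tr$hummingbirds[-3, ]
  expect_error(build_pair_table(V, bad, tr$plants),
               tr$hummingbirds$species[3])
})

test_that("the NB-GAM finds no consistent structure in constant-mean data", {
  fits <- lapply(1:10, function(s) {
    set.seed(s)
    tab <- neutral_pair_table(s)
    tab$visits <- rnbinom(nrow(tab), size = 2, mu = 15)  # constant mean
    fit_nb_gam(tab, predictors = c("hummingbird_abundance_prop",
                                   "flower_abundance_prop", "noise_trait"))
  })
  dev <- vapply(fits, function(f) f$deviance_explained, numeric(1))
  edf <- vapply(fits, function(f) median(f$smooth_table$edf), numeric(1))
  sig <- t(vapply(fits, function(f) f$smooth_table$p_value < 0.05,
                  logical(3)))
  expect_lt(mean(dev), 10)             # no real structure to absorb
  expect_lt(median(edf), 1.5)          # smooths collapse toward linear
  expect_true(all(colMeans(sig) <= 0.2))  # nothing consistently "detected"
  expect_error(fit_nb_gam(transform(neutral_pair_table(1),
                                    visits = visits + 0.5)),
               "integer")
})

test_that("neutral datasets recover abundance effects, not noise", {
  res <- t(vapply(1:10, function(s) {
    f <- fit_nb_gam(neutral_pair_table(s + 100),
                    predictors = c("hummingbird_abundance_prop",
                                   "flower_abundance_prop", "noise_trait"))
    p <- setNames(f$smooth_table$p_value, f$smooth_table$term)
    c(hb = p[["hummingbird_abundance_prop"]] < 0.05,
      fl = p[["flower_abundance_prop"]] < 0.05,
      noise = p[["noise_trait"]] < 0.05, theta = f$theta)
  }, numeric(4)))
  expect_gte(mean(res[, "hb"]), 0.9)
  expect_gte(mean(res[, "fl"]), 0.9)
  expect_lte(mean(res[, "noise"]), 0.2)
  # dispersion recovered near its generating value of 2
  expect_gt(median(res[, "theta"]), 0.8)
  expect_lt(median(res[, "theta"]), 5)
})

test_that("the large-theta fit agrees with a Poisson GAM and conserves totals", {
  tab <- neutral_pair_table(23, theta = 50)
  f <- fit_nb_gam(tab, predictors = c("hummingbird_abundance_prop",
                                      "flower_abundance_prop"),
                  theta_range = c(2000, 2001))
  oracle <- mgcv::gam(
    visits ~ s(hummingbird_abundance_prop, bs = "ps", k = 10, m = c(2, 2)) +
      s(flower_abundance_prop, bs = "ps", k = 10, m = c(2, 2)),
    data = tab, family = poisson(), method = "GCV.Cp", gamma = 1.4)
  expect_lt(max(abs(f$fitted - fitted(oracle)) / (fitted(oracle) + 1e-9)),
            0.01)
  # log-link stationarity: fitted total matches the observed total in the
  # Poisson limit
  expect_lt(abs(sum(f$fitted) - sum(tab$visits)) / sum(tab$visits), 0.001)
})
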