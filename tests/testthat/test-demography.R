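test_that("density estimation counts individuals per window area", {
  d0 <- estimate_density(numeric(0), numeric(0), c(5, 5), 1)
  expect_true(all(d0 == 0))

  d1 <- estimate_density(2.5, 3.5, c(5, 5), 1)
  expect_equal(d1[4, 3], 1)
  expect_equal(sum(d1), 1)

  # Poisson-count oracle: 1000 uniform individuals on 50 x 50, window 5
  set.seed(1)
  x <- runif(1000, 0, 50); y <- runif(1000, 0, 50)
  d <- estimate_density(x, y, c(50, 50), 5)
  interior <- d[6:45, 6:45]
  # windowed means are spatially correlated: ~(40/5)^2 = 64 effectively
  # independent windows, each with variance 0.4/25
  expect_lt(abs(mean(interior) - 0.4), 3 * sqrt(0.4 / 25 / 64))
})

test_that("mate search respects radius, eligibility, and weighting", {
  # no partner within radius -> unpaired
  p0 <- find_mating_pairs(c(0.5, 9.5), c(0.5, 9.5), c(TRUE, TRUE),
                          radius = 2)
  expect_equal(nrow(p0), 0)

  # exactly one eligible partner in radius -> always that pair
  for (i in 1:5) {
    p1 <- find_mating_pairs(c(1, 2, 9), c(1, 1, 9), c(TRUE, TRUE, TRUE),
                            radius = 2)
    expect_equal(p1, cbind(1L, 2L), ignore_attr = TRUE)
  }

  # dioecious mode requires opposite sexes
  p2 <- find_mating_pairs(c(1, 1.5), c(1, 1), c(TRUE, TRUE),
                          sex = c(0L, 0L), radius = 2, dioecious = TRUE)
  expect_equal(nrow(p2), 0)

  # inverse-distance weighting at x = 0, 1, 2: chooser 1 picks its d = 1
  # partner w.p. 2/3 (weights 1/d). Propagating all three choosers'
  # weighted picks (2/3, 1/2, 2/3 toward the middle) through pair
  # deduplication and the random-order one-mating-per-individual pass gives
  # P(pair {1,2} formed) = 41/108 = 0.3796 by exact enumeration of the
  # choice x order outcomes.
  set.seed(2)
  picks <- vapply(seq_len(4000), function(i) {
    pp <- find_mating_pairs(c(0, 1, 2), c(0, 0, 0), c(TRUE, TRUE, TRUE),
                            radius = 5, weighting = "inverse_distance")
    any(pp[, 1] == 1L & pp[, 2] == 2L)
  }, logical(1))
  expect_lt(abs(mean(picks) - 0.3796), 3.5 * sqrt(0.38 * 0.62 / 4000))

  # nearest-neighbour mode always takes the closest partner
  pn <- find_mating_pairs(c(0, 1, 2.5), c(0, 0, 0), c(TRUE, TRUE, TRUE),
                          radius = 5, weighting = "nearest")
  expect_true(any(pn[, 1] == 1 & pn[, 2] == 2))

  # at most one mating per individual per timestep
  set.seed(3)
  x <- runif(200, 0, 5); y <- runif(200, 0, 5)
  pm <- find_mating_pairs(x, y, rep(TRUE, 200), radius = 3)
  expect_false(any(duplicated(c(pm))))
})

test_that("mating decisions are Bernoulli(b)", {
  pairs <- cbind(1:10000, 10001:20000)
  expect_equal(nrow(decide_matings(pairs, 0)), 0)
  expect_equal(nrow(decide_matings(pairs, 1)), 10000)
  set.seed(4)
  frac <- nrow(decide_matings(pairs, 0.3)) / 10000
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("offspring numbers follow the fixed or Poisson rule", {
  expect_true(all(draw_n_offspring(50, 2, fixed = TRUE) == 2L))
  expect_true(all(draw_n_offspring(50, 0) == 0L))
  set.seed(5)
  n <- draw_n_offspring(1e4, 4)
  expect_lt(abs(mean(n) - 4), 3 * sqrt(4 / 1e4))
})

test_that("density mortality follows the logistic balance", {
  beta <- 0.3
  expect_equal(p_death_density(2, 2, r = 0.5, beta = beta), beta)
  expect_equal(p_death_density(1, 2, r = 0.5, beta = 0.3), 0.05)
  expect_equal(p_death_density(4, 2, r = 0.5, beta = 0.3), 0.8)
  # clamping and the K = 0 rule
  expect_equal(p_death_density(10, 1, r = 2, beta = 0.9), 0.999)
  expect_equal(p_death_density(0.001, 100, r = 2, beta = 0.1), 0.001)
  expect_equal(p_death_density(1, 0, r = 0.5, beta = 0.3), 0.999)
})

test_that("trait fitness penalises phenotype-environment mismatch", {
  expect_equal(fitness_trait(0.4, 0.4, phi = 0.3), 1)
  expect_equal(fitness_trait(0.1, 0.9, phi = 0), 1)
  expect_equal(fitness_trait(0, 1, phi = 0.05, gamma = 1), 0.95)
  expect_equal(fitness_trait(0.5, 1, phi = 0.2, gamma = 2), 1 - 0.2 * 0.25)
  z <- runif(50); e <- runif(50)
  w <- fitness_trait(z, e, phi = 0.4)
  expect_true(all(w >= 0.6 & w <= 1))
})

test_that("total death probability composes density and selection", {
  expect_equal(p_death_total(0.37), 0.37)
  expect_equal(p_death_total(0.2, matrix(0.9, 1, 1)), 0.28)
  m <- 4; phi <- 0.1
  expect_equal(p_death_total(0.2, matrix(1 - phi, 1, m)),
               1 - 0.8 * (1 - phi)^m)
  # monotone: non-decreasing in P_dxy, non-increasing in each omega
  p1 <- p_death_total(seq(0, 1, 0.1), matrix(0.9, 11, 1))
  expect_true(all(diff(p1) >= 0))
  p2 <- vapply(seq(0.5, 1, 0.05), function(w) {
    p_death_total(0.3, matrix(c(w, 0.9), 1, 2))
  }, numeric(1))
  expect_true(all(diff(p2) <= 0))
})

test_that("mortality is Bernoulli with deterministic max-age deaths", {
  expect_true(all(apply_mortality(rep(0, 100))))
  expect_false(any(apply_mortality(rep(1, 100))))
  set.seed(6)
  surv <- apply_mortality(rep(0.25, 1e4))
  expect_lt(abs(sum(!surv) - 2500), 3 * sqrt(1e4 * 0.25 * 0.75))
  expect_false(any(apply_mortality(rep(0, 5), age = rep(9L, 5), max_age = 8)))
})

test_that("deleterious loci multiply fitness down by (1 - s g)", {
  a <- gl_genarch(6)
  a$delet_s <- c(`2` = 0.5, `5` = 0.2)
  ch1 <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L), 1)
  ch2 <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L), 1)
  # locus 2: g = 0.5 -> 1 - 0.25; locus 5: g = 1 -> 1 - 0.2
  expect_equal(deleterious_factors(ch1, ch2, a), 0.75 * 0.8)
})
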