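test_that("von Mises draws concentrate at the mode and flatten at kappa = 0", {
  set.seed(1)
  th <- rvonmises(200, mu = 1.2, kappa = 1e6)
  expect_true(all(abs(th - 1.2) < 0.01))

  # kappa = 0: uniform on the circle (Rayleigh statistic small)
  th0 <- rvonmises(1e4, mu = 0, kappa = 0)
  expect_true(all(th0 >= 0 & th0 < 2 * pi))
  rbar <- sqrt(mean(cos(th0))^2 + mean(sin(th0))^2)
  # under uniformity 2 n rbar^2 ~ chi^2_2; reject threshold at alpha = 1e-3
  expect_lt(2 * 1e4 * rbar^2, stats::qchisq(0.999, 2))

  # circular mean of moderately concentrated draws matches mu
  th2 <- rvonmises(2e4, mu = 4, kappa = 3)
  mu_hat <- atan2(mean(sin(th2)), mean(cos(th2))) %% (2 * pi)
  expect_lt(abs(mu_hat - 4), 0.05)
})

test_that("Wald draws have the inverse-Gaussian mean and variance", {
  set.seed(2)
  d <- rwald(1e5, mean = 2, shape = 3)
  expect_true(all(d > 0))
  expect_lt(abs(mean(d) - 2), 3 * sqrt(8 / 3 / 1e5))
  expect_lt(abs(stats::var(d) - 8 / 3), 0.15)
  expect_error(rwald(1, -1, 1), "> 0")
})

test_that("unimodal surfaces point at the highest-valued neighbour", {
  # gradient increasing with x: E, NE, SE tie at the max and the fixed
  # neighbour ordering (N, NE, E, ...) breaks the tie toward NE
  g <- make_gradient_raster(c(5, 5), "x")
  set.seed(3)
  s <- build_movement_surface(g, kappa = 1e6, M = 50, mode = "unimodal")
  interior <- landgen:::coords_to_cell(2.5, 2.5, c(5, 5))$cell
  th <- s$cols[, interior]
  expect_true(all(abs(th - 7 * pi / 4) < 0.02))

  # all-equal neighbourhood: tie broken by fixed order (N first), and the
  # result is deterministic under a seed
  u <- matrix(0.5, 5, 5)
  set.seed(4); s1 <- build_movement_surface(u, kappa = 1e6, M = 10,
                                            mode = "unimodal")
  set.seed(4); s2 <- build_movement_surface(u, kappa = 1e6, M = 10,
                                            mode = "unimodal")
  expect_identical(s1$cols, s2$cols)
  north <- (3 * pi / 2)  # N neighbour: dr = -1 in row/col space
  expect_true(all(abs(s1$cols[, interior] - north) < 0.02))
})

test_that("mixture surfaces weight components by neighbour values", {
  # single positive neighbour reduces to unimodal toward it
  m <- matrix(0, 3, 3); m[2, 3] <- 1  # only E neighbour of center positive
  set.seed(5)
  s <- suppressWarnings(build_movement_surface(m, kappa = 1e6, M = 100))
  center <- landgen:::coords_to_cell(1.5, 1.5, c(3, 3))$cell
  th <- s$cols[, center]
  expect_true(all(pmin(th, 2 * pi - th) < 0.02))

  # equal neighbours: each of 8 components drawn ~ 1/8 of the time
  u <- matrix(1, 5, 5)
  set.seed(6)
  M <- 8000
  su <- build_movement_surface(u, kappa = 1e6, M = M)
  interior <- landgen:::coords_to_cell(2.5, 2.5, c(5, 5))$cell
  comp <- round(su$cols[, interior] / (pi / 4)) %% 8
  counts <- table(factor(comp, levels = 0:7))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)

  # two opposite neighbours at 0.5/0.5: bimodal with about equal mass
  b <- matrix(0, 3, 3); b[2, 1] <- 0.5; b[2, 3] <- 0.5
  set.seed(7)
  sb <- suppressWarnings(build_movement_surface(b, kappa = 1e6, M = 2000))
  thb <- sb$cols[, center]
  east <- sum(pmin(thb, 2 * pi - thb) < 0.1)
  west <- sum(abs(thb - pi) < 0.1)
  expect_equal(east + west, 2000)
  expect_lt(abs(east - 1000), 3.5 * sqrt(2000 * 0.25))

  # all-zero neighbourhoods fall back to uniform directions with a warning
  z <- matrix(0, 4, 4)
  set.seed(8)
  expect_warning(sz <- build_movement_surface(z, kappa = 5, M = 3000),
                 "uniform")
  rbar <- sqrt(mean(cos(sz$cols[, 6]))^2 + mean(sin(sz$cols[, 6]))^2)
  expect_lt(2 * 3000 * rbar^2, stats::qchisq(0.999, 2))
})

test_that("direction draws resample the stored column", {
  set.seed(9)
  s <- build_movement_surface(matrix(1, 3, 3), kappa = 2, M = 1)
  d <- draw_directions(s, rep(4L, 20))
  expect_true(all(d == s$cols[1, 4]))

  sM <- build_movement_surface(matrix(1, 3, 3), kappa = 2, M = 40)
  d2 <- draw_directions(sM, rep(2L, 5000))
  expect_true(all(d2 %in% sM$cols[, 2]))
  expect_error(draw_directions(sM, 10L), "out of bounds")

  # determinism: identical generator state gives identical draws
  st <- .Random.seed
  a <- draw_directions(sM, 1:9)
  .Random.seed <<- st
  b <- draw_directions(sM, 1:9)
  expect_identical(a, b)
})

test_that("moves stay strictly inside the landscape and are isotropic without a surface", {
  set.seed(10)
  dims <- c(10, 10)
  x <- runif(2000, 0, 10); y <- runif(2000, 0, 10)
  for (i in 1:5) {
    nxt <- move_positions(x, y, NULL, list(mean = 2, shape = 0.5), dims)
    x <- nxt$x; y <- nxt$y
    expect_true(all(x > 0 & x < 10 & y > 0 & y < 10))
  }

  # zero-distance moves leave positions unchanged
  same <- move_positions(c(1, 2), c(3, 4), NULL, list(mean = 0, shape = 1),
                         dims)
  expect_equal(same$x, c(1, 2)); expect_equal(same$y, c(3, 4))

  # isotropy: mean displacement ~ 0 away from borders
  x0 <- rep(5, 2e4); y0 <- rep(5, 2e4)
  mv <- move_positions(x0, y0, NULL, list(mean = 0.5, shape = 2), dims)
  expect_lt(abs(mean(mv$x - 5)), 0.02)
  expect_lt(abs(mean(mv$y - 5)), 0.02)
})

test_that("movement on a barrier layer prefers high-suitability cells", {
  set.seed(11)
  # half the cells low-suitability so the layer median separates the zones
  lay <- make_barrier_raster(c(20, 20), 6:15, inside = 0.02, outside = 1)
  s <- build_movement_surface(lay, kappa = 12, M = 400)
  x <- 2.5; y <- 10.5
  vals <- numeric(3000)
  for (i in seq_len(3000)) {
    nxt <- move_positions(x, y, s, list(mean = 0.5, shape = 0.5), c(20, 20))
    x <- nxt$x; y <- nxt$y
    cc <- landgen:::coords_to_cell(x, y, c(20, 20))
    vals[i] <- lay[cc$row, cc$col]
  }
  expect_gt(mean(vals > stats::median(lay)), 0.9)
})

test_that("offspring disperse from the parental midpoint", {
  expect_equal(
    disperse_positions(0.5, 0.5, 2.5, 2.5, NULL, list(mean = 0, shape = 1),
                       c(10, 10)),
    list(x = 1.5, y = 1.5))

  # isotropic dispersal bearings are uniform
  set.seed(12)
  off <- disperse_positions(rep(5, 1e4), rep(5, 1e4), rep(5, 1e4),
                            rep(5, 1e4), NULL, list(mean = 0.5, shape = 2),
                            c(10, 10))
  th <- atan2(off$y - 5, off$x - 5)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(2 * 1e4 * rbar^2, stats::qchisq(0.999, 2))
})

test_that("large approximation columns converge to the mixture distribution", {
  set.seed(13)
  lay <- matrix(runif(9), 3, 3)
  lay <- lay / max(lay)
  s_ref <- build_movement_surface(lay, kappa = 4, M = 1e5)
  s_apx <- build_movement_surface(lay, kappa = 4, M = 1e4)
  center <- landgen:::coords_to_cell(1.5, 1.5, c(3, 3))$cell
  ks <- suppressWarnings(stats::ks.test(s_apx$cols[, center],
                                        s_ref$cols[, center]))
  expect_gt(ks$p.value, 1e-3)
})
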