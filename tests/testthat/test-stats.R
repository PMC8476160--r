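test_that("heterozygosity gives observed and expected values per locus", {
  ch1 <- matrix(1L, 6, 3); ch2 <- matrix(1L, 6, 3)
  h <- heterozygosity(ch1, ch2)
  expect_equal(h$H_obs, rep(0, 3))
  expect_equal(h$p, rep(1, 3))
  expect_equal(h$H_exp, rep(0, 3))

  h2 <- heterozygosity(matrix(0L, 6, 3), matrix(1L, 6, 3))
  expect_equal(h2$H_obs, rep(1, 3))
  expect_equal(h2$H_exp, rep(0.5, 3))

  set.seed(1)
  a <- gl_genarch(400)
  g <- init_genomes(a, 200)
  h3 <- heterozygosity(g$ch1, g$ch2)
  expect_lt(abs(mean(h3$H_obs) - 0.5), 3 * sqrt(0.25 / (200 * 400)))
})

test_that("FST estimators separate identical and fixed-different demes", {
  set.seed(2)
  a <- gl_genarch(100)
  g <- init_genomes(a, 40)
  deme <- list(ch1 = g$ch1, ch2 = g$ch2)
  expect_equal(unname(fst(list(deme, deme))), c(0, 0))

  d1 <- list(ch1 = matrix(0L, 20, 10), ch2 = matrix(0L, 20, 10))
  d2 <- list(ch1 = matrix(1L, 20, 10), ch2 = matrix(1L, 20, 10))
  expect_equal(unname(fst(list(d1, d2))), c(1, 1))

  # hand-computed two-deme case at p = 0.3 / 0.7 (equal sizes):
  # pbar = 0.5, HT = 0.5, HS = 2*0.3*0.7 = 0.42 -> FST_het = 0.16;
  # var = 0.04, pq = 0.25 -> FST_var = 0.16
  mk <- function(p, n = 500, L = 1) {
    list(ch1 = matrix(rbinom(n * L, 1, p), n, L),
         ch2 = matrix(rbinom(n * L, 1, p), n, L))
  }
  set.seed(3)
  f <- fst(list(mk(0.3, 5000, 20), mk(0.7, 5000, 20)))
  expect_lt(abs(f[["fst_het"]] - 0.16), 0.02)
  expect_lt(abs(f[["fst_var"]] - 0.16), 0.02)
})

test_that("windowed nucleotide diversity equals the brute-force pairwise mean", {
  mono <- list(ch1 = matrix(0L, 5, 10), ch2 = matrix(0L, 5, 10))
  expect_equal(nucleotide_diversity(mono$ch1, mono$ch2, window = 10)$pi, 0)

  # brute force over all chromatid pairs on a small random case
  set.seed(4)
  ch1 <- matrix(rbinom(40, 1, 0.4), 4, 10)
  ch2 <- matrix(rbinom(40, 1, 0.4), 4, 10)
  hap <- rbind(ch1, ch2)
  n <- nrow(hap)
  diffs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    diffs <- diffs + sum(hap[i, ] != hap[j, ])
  }
  pi_brute <- diffs / choose(n, 2) / 10
  pi_pkg <- nucleotide_diversity(ch1, ch2, window = 10)$pi
  expect_equal(pi_pkg, pi_brute)
})

test_that("PCA genetic distances behave like Euclidean genotype distances", {
  g <- matrix(0L, 6, 20)
  gd <- genetic_distances_pca(g, g)
  expect_true(all(gd$dist == 0))

  ch1 <- rbind(matrix(0L, 3, 20), matrix(1L, 3, 20))
  gd2 <- genetic_distances_pca(ch1, ch1)
  expect_true(all(gd2$dist[1:3, 1:3] == 0))
  expect_true(all(gd2$dist[1:3, 4:6] > 0))

  set.seed(5)
  a <- gl_genarch(30)
  g3 <- init_genomes(a, 15)
  d_a <- genetic_distances_pca(g3$ch1, g3$ch2)$dist
  perm <- sample(30)
  d_b <- genetic_distances_pca(g3$ch1[, perm], g3$ch2[, perm])$dist
  expect_equal(d_a, d_b, tolerance = 1e-9)
  expect_equal(ncol(genetic_distances_pca(g3$ch1, g3$ch2, k = 3)$scores), 3)
})

test_that("partial Mantel matches the brute-force residual correlation", {
  set.seed(6)
  pts <- matrix(runif(10), 5, 2)
  A <- as.matrix(dist(pts))
  B <- as.matrix(dist(pts + rnorm(10, sd = 0.2)))
  C <- as.matrix(dist(matrix(runif(10), 5, 2)))
  pm <- partial_mantel(A, B, C, n_perm = 99)
  lt <- lower.tri(A)
  ra <- resid(lm(A[lt] ~ C[lt])); rb <- resid(lm(B[lt] ~ C[lt]))
  expect_equal(pm$r, cor(ra, rb), tolerance = 1e-10)

  # self-correlation with an uncorrelated control
  pm2 <- partial_mantel(A, A, C, n_perm = 99)
  expect_gt(pm2$r, 0.999)

  # null: independent matrices give small r and a non-extreme p
  set.seed(7)
  rs <- replicate(20, {
    X <- as.matrix(dist(runif(12))); Y <- as.matrix(dist(runif(12)))
    Z <- as.matrix(dist(runif(12)))
    partial_mantel(X, Y, Z, n_perm = 99)$p
  })
  expect_gt(mean(rs > 0.05), 0.7)   # about alpha-level type-I error
})

test_that("MMRR recovers constructed linear relations between matrices", {
  set.seed(8)
  X <- as.matrix(dist(runif(15)))
  fit <- suppressWarnings(mmrr(2 * X, list(X = X), n_perm = 49))
  expect_equal(unname(fit$coefficients["X"]), 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  X2 <- as.matrix(dist(runif(15)))
  noise <- matrix(rnorm(225, sd = 0.05), 15); noise <- noise + t(noise)
  diag(noise) <- 0
  Y <- X + 0.5 * X2 + noise
  fit2 <- mmrr(Y, list(X1 = X, X2 = X2), n_perm = 99)
  expect_lt(abs(fit2$coefficients[["X1"]] - 1), 0.15)
  expect_lt(abs(fit2$coefficients[["X2"]] - 0.5), 0.15)
  expect_lt(fit2$p_model, 0.05)

  # independent response: R^2 near zero
  Y0 <- as.matrix(dist(runif(15)))
  expect_lt(mmrr(Y0, list(X = X), n_perm = 49)$r_squared, 0.35)

  td <- tidy(fit2); gl <- glance(fit2)
  expect_equal(td$term, c("(Intercept)", "X1", "X2"))
  expect_equal(gl$r.squared, fit2$r_squared)
})

test_that("crossing rates count zone traversals per timestep", {
  # never enters the zone columns
  h0 <- tibble::tibble(id = 1, t = 0:10, x = seq(0, 5, length.out = 11))
  expect_equal(crossing_rate(h0, c(8, 9))$rate, 0)

  # scripted track crossing twice in 10 steps
  xs <- c(2, 2, 6, 6, 6, 2, 2, 2, 2, 2, 2)
  h1 <- tibble::tibble(id = 1, t = 0:10, x = xs)
  expect_equal(crossing_rate(h1, c(4, 4.5))$rate, 0.2)

  # brute-force segment-intersection oracle on randomized fast tracks
  set.seed(9)
  zone <- c(4, 6)
  for (rep in 1:5) {
    x <- runif(21, 0, 10)
    x[x >= zone[1] & x <= zone[2]] <- 1   # keep every point outside the zone
    h <- tibble::tibble(id = 1, t = 0:20, x = x)
    segs <- sum((x[-21] < zone[1] & x[-1] > zone[2]) |
                  (x[-21] > zone[2] & x[-1] < zone[1]))
    expect_equal(crossing_rate(h, zone)$crossings, segs)
  }
})

test_that("stepping-stone FST increases with inter-island distance", {
  rhos <- t(vapply(1:2, function(s) {
    m <- suppressWarnings(build_model(scenario_stepping_stone(T = 150),
                                      seed = s + 40))
    m <- run_model(m)
    demes <- island_demes(m)
    prs <- t(utils::combn(6, 2))
    fsts <- apply(prs, 1, function(pr) fst(demes[pr]))
    drank <- abs(prs[, 1] - prs[, 2])
    c(het = stats::cor(fsts[1, ], drank, method = "spearman"),
      var = stats::cor(fsts[2, ], drank, method = "spearman"))
  }, numeric(2)))
  expect_true(all(rhos > 0))
})

test_that("mismatch and fitness series summarise the run log", {
  lg <- tibble::tibble(phase = "main", t = 1:3, N = c(10L, 11L, 12L),
                       births = 0L, deaths = 0L,
                       mean_fitness = c(1, 1, 1),
                       mean_mismatch = c(0, 0.3, 0.2), crossings = 0L)
  s <- mismatch_and_fitness_series(lg)
  expect_equal(names(s), c("t", "mean_mismatch", "mean_fitness"))
  expect_equal(nrow(s), 3)
  expect_equal(mean(c(0.2, 0.4)), 0.3)  # two-individual mismatch average
})

test_that("logistic pseudo-R2 and the GEA scan find real associations", {
  set.seed(10)
  e <- rep(c(0, 1), each = 100)
  z <- plogis(qlogis(0.02 + 0.96 * e) + rnorm(200, sd = 0.3))
  fit <- logistic_pseudo_r2(z, e)
  expect_gt(fit$pseudo_r2, 0.5)
  expect_lt(fit$p, 1e-6)

  z0 <- runif(200)
  expect_lt(logistic_pseudo_r2(z0, e)$pseudo_r2, 0.05)

  # scan: a locus tracking the environment beats unlinked loci
  ch1 <- matrix(rbinom(200 * 10, 1, 0.5), 200, 10)
  ch2 <- matrix(rbinom(200 * 10, 1, 0.5), 200, 10)
  ch1[, 4] <- e; ch2[, 4] <- rbinom(200, 1, 0.2 + 0.6 * e)
  scan <- gea_scan(ch1, ch2, e)
  expect_equal(which.min(scan$p), 4L)
  expect_lt(scan$p_bonferroni[4], 0.05)
  expect_gt(min(scan$p_bonferroni[-4]), 0.05)
})
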