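test_that("genome initialisation follows the per-locus start frequencies", {
  a0 <- tiny_arch(L = 8, start_freq = 0)
  g0 <- init_genomes(a0, 5)
  expect_true(all(g0$ch1 == 0) && all(g0$ch2 == 0))

  a1 <- tiny_arch(L = 8, start_freq = 1)
  g1 <- init_genomes(a1, 5)
  expect_true(all(g1$ch1 == 1) && all(g1$ch2 == 1))

  set.seed(11)
  a <- tiny_arch(L = 1000)
  g <- init_genomes(a, 100)
  phat <- mean(c(g$ch1, g$ch2))
  se <- sqrt(0.25 / (2 * 100 * 1000))
  expect_lt(abs(phat - 0.5), 3 * se)
  expect_error(init_genomes(a, 0), "positive")
})

test_that("recombination paths reproduce the map's per-gap switch rates", {
  set.seed(21)
  a0 <- tiny_arch(L = 6, rate = 0)
  p0 <- generate_recomb_paths(a0, 100)
  expect_true(all(apply(p0$paths, 1, function(r) length(unique(r)) == 1)))

  R <- 4000
  a5 <- tiny_arch(L = 6, rate = 0.5)
  p5 <- generate_recomb_paths(a5, R)
  sw <- abs(diff(t(p5$paths)))           # gaps x paths
  freq <- rowMeans(sw)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / R)))

  # heterogeneous map, Monte-Carlo oracle over 10^4 paths
  set.seed(22)
  rates <- runif(40, 0, 0.5)
  ah <- gl_genarch(41, recomb_rates = rates)
  ph <- generate_recomb_paths(ah, 10000)
  fh <- rowMeans(abs(diff(t(ph$paths))))
  se <- sqrt(pmax(rates * (1 - rates), 1e-6) / 10000)
  expect_true(all(abs(fh - rates) < 4.5 * pmax(se, 1e-4)))
  expect_gt(cor(fh, rates), 0.99)
  expect_error(gl_genarch(3, recomb_rates = c(0.2, 0.7)), "0, 0.5")
})

test_that("the path deck draws without replacement and reshuffles", {
  set.seed(31)
  a <- tiny_arch(L = 4, rate = 0.5)
  rp <- generate_recomb_paths(a, 3)
  draws <- draw_path_indices(rp, 6)
  expect_equal(sort(draws[1:3]), 1:3)
  expect_equal(sort(draws[4:6]), 1:3)
  expect_equal(as.vector(table(draws)), c(2L, 2L, 2L))

  rp1 <- generate_recomb_paths(tiny_arch(L = 4), 1)
  expect_equal(draw_path_indices(rp1, 5), rep(1L, 5))

  # consecutive decks are independently ordered: over many reshuffles every
  # path appears in every deck position about equally often
  rp3 <- generate_recomb_paths(a, 3)
  n_decks <- 600
  firsts <- vapply(seq_len(n_decks), function(i) draw_path_indices(rp3, 3)[1],
                   integer(1))
  counts <- table(factor(firsts, levels = 1:3))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("gametes copy the path-selected chromatid exactly", {
  ch1 <- c(0L, 0L, 0L, 0L); ch2 <- c(1L, 1L, 1L, 1L)
  expect_equal(make_gamete(ch1, ch2, c(0L, 0L, 1L, 1L)), c(0L, 0L, 1L, 1L))
  expect_equal(make_gamete(ch1, ch2, rep(0L, 4)), ch1)
  hom <- c(1L, 0L, 1L, 0L)
  expect_equal(make_gamete(hom, hom, c(0L, 1L, 0L, 1L)), hom)
  expect_error(make_gamete(ch1, ch2, c(0L, 1L)), "length")

  # allele conservation: every gamete allele is one of the parent's two
  set.seed(41)
  a <- tiny_arch(L = 30, rate = 0.3)
  g <- init_genomes(a, 20)
  rp <- generate_recomb_paths(a, 100)
  idx <- draw_path_indices(rp, 50)
  par <- sample.int(20, 50, replace = TRUE)
  gam <- landgen:::make_gametes(g$ch1, g$ch2, par, rp$paths[idx, ])
  ok <- gam == g$ch1[par, ] | gam == g$ch2[par, ]
  expect_true(all(ok))
})

test_that("on-the-fly recombination matches the path mechanism distributionally", {
  set.seed(51)
  a <- tiny_arch(L = 21, rate = 0)
  het1 <- matrix(0L, 1, 21); het2 <- matrix(1L, 1, 21)
  g0 <- recombine_on_the_fly(het1, het2, rep(1L, 50), rate = 0)
  expect_true(all(apply(g0, 1, function(r) length(unique(r)) == 1)))

  n <- 4000
  g5 <- recombine_on_the_fly(het1, het2, rep(1L, n), rate = 0.5)
  sw_freq <- colMeans(abs(g5[, -1] - g5[, -21]))
  expect_true(all(abs(sw_freq - 0.5) < 4 * sqrt(0.25 / n)))

  # chi-square two-sample check against the path mechanism at rate 0.2
  rate <- 0.2
  a2 <- tiny_arch(L = 21, rate = rate)
  rp <- generate_recomb_paths(a2, n)
  sw_paths <- colSums(abs(rp$paths[, -1] - rp$paths[, -21]))
  gf <- recombine_on_the_fly(het1, het2, rep(1L, n), rate = rate)
  sw_otf <- colSums(abs(gf[, -1] - gf[, -21]))
  pvals <- vapply(seq_len(20), function(j) {
    suppressWarnings(stats::prop.test(c(sw_paths[j], sw_otf[j]),
                                      c(n, n))$p.value)
  }, numeric(1))
  # under the null the per-gap p-values are uniform; combine with Fisher
  fisher <- -2 * sum(log(pmax(pvals, 1e-12)))
  expect_gt(stats::pchisq(fisher, df = 40, lower.tail = FALSE), 0.01)
  expect_error(recombine_on_the_fly(het1, het2, 1L, rate = c(0.1, 0.2)),
               "homogeneous")
})

test_that("mutations flip alleles at the configured class rates", {
  set.seed(61)
  a <- tiny_arch(L = 20)
  gam <- matrix(0L, 30, 20)
  out <- apply_mutations(gam, a)
  expect_identical(out$gametes, gam)
  expect_equal(nrow(out$records), 0)

  # forced neutral mutation: every neutral locus flips in every gamete
  af <- gl_genarch(10, mu_neutral = 1)
  gf <- matrix(0L, 4, 10)
  outf <- apply_mutations(gf, af)
  expect_true(all(outf$gametes[, af$neutral_loci] == 1L))

  # binomial oracle: ~ n_gametes * pool * mu total flips
  ab <- gl_genarch(1000, mu_neutral = 1e-3)
  gb <- matrix(0L, 1000, 1000)
  outb <- apply_mutations(gb, ab)
  n_mut <- sum(outb$gametes)
  expect_lt(abs(n_mut - 1000), 3 * sqrt(1000 * (1 - 1e-3)))

  # deleterious mutations register a selection coefficient in (0, 1]
  ad <- gl_genarch(50, mu_deleterious = 0.02, prop_deleterious = 1)
  outd <- apply_mutations(matrix(0L, 200, 50), ad)
  expect_gt(length(outd$arch$delet_s), 0)
  expect_true(all(outd$arch$delet_s > 0 & outd$arch$delet_s <= 1))

  # exhausted trait pool is skipped with a warning
  tr <- gl_trait(1:2, phi = 0.1, layer = "env", mu = 0.9, name = "t")
  at <- gl_genarch(5, traits = list(tr))
  expect_warning(apply_mutations(matrix(0L, 50, 5), at), "exhausted")
})

test_that("phenotypes follow the additive model with baseline centering", {
  dom0 <- rep(0, 20)
  # polygenic all-heterozygous baseline
  tr10 <- gl_trait(1:10, phi = 0.1, layer = "env", name = "p")
  arch <- gl_genarch(20, traits = list(tr10))
  ch1 <- matrix(0L, 1, 20); ch2 <- matrix(1L, 1, 20)
  expect_equal(compute_phenotype(ch1, ch2, tr10, arch), 0.5)

  # monogenic alpha = 1 maps genotype scores to {0, 0.5, 1}
  tr1 <- gl_trait(3, phi = 0.1, layer = "env", name = "m")
  arch1 <- gl_genarch(20, traits = list(tr1))
  g00 <- matrix(0L, 1, 20)
  g11 <- matrix(1L, 1, 20)
  expect_equal(compute_phenotype(g00, g00, tr1, arch1), 0)
  expect_equal(compute_phenotype(g00, g11, tr1, arch1), 0.5)
  expect_equal(compute_phenotype(g11, g11, tr1, arch1), 1)

  # 10-locus trait, equal effects 1/10, all homozygous 1 -> z = 1
  expect_equal(compute_phenotype(matrix(1L, 1, 20), matrix(1L, 1, 20),
                                 tr10, arch), 1)

  # uncentered literal form: z = sum alpha g + g0
  tru <- gl_trait(1:10, phi = 0.1, layer = "env", centered = FALSE,
                  name = "u")
  archu <- gl_genarch(20, traits = list(tru))
  expect_equal(compute_phenotype(matrix(1L, 1, 20), matrix(1L, 1, 20),
                                 tru, archu), 1.5)

  # dominant loci score 1 when heterozygous
  archd <- gl_genarch(20, dominance = 1, traits = list(tr1))
  expect_equal(compute_phenotype(g00, g11, tr1, archd), 1)

  # phenotypes stay in [0, 1] under the default effect-size rule
  set.seed(71)
  archp <- gl_genarch(30, traits = list(gl_trait(1:10, phi = 0.1,
                                                 layer = "env", name = "r")))
  g <- init_genomes(archp, 200)
  z <- compute_phenotype(g$ch1, g$ch2, archp$traits[[1]], archp)
  expect_true(all(z >= 0 & z <= 1))
})

test_that("neutral allele frequency is a martingale in a well-mixed run", {
  set.seed(81)
  deltas <- vapply(1:6, function(s) {
    p <- tiny_params(L = 40, T = 12, K = 3)
    m <- quiet_build(p, seed = s)
    m <- run_model(m, track_allele_freq = TRUE)
    mean(m$allele_freq[nrow(m$allele_freq), ] - m$allele_freq[1, ])
  }, numeric(1))
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 4 * max(se, 1e-3))
})
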