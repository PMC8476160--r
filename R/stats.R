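#' Summary statistics and spatial-genetic analyses
#'
#' Heterozygosity, two FST estimators, windowed nucleotide diversity,
#' PCA-based genetic distances, partial Mantel tests, multiple matrix
#' regression on distance matrices (MMRR), barrier-crossing rates, and the
#' mean phenotype-environment mismatch / mean fitness time series.
#'
#' @name gstats
NULL

#' Observed and expected heterozygosity per locus
#'
#' Observed = fraction of heterozygous individuals; expected = `2 p (1 - p)`
#' with `p` the pooled allele frequency.
#'
#' @param ch1,ch2 N x L chromatid matrices.
#' @return tibble with `locus`, `p`, `H_obs`, `H_exp`.
#' @export
heterozygosity <- function(ch1, ch2) {
  p <- (colSums(ch1) + colSums(ch2)) / (2 * nrow(ch1))
  tibble::tibble(locus = seq_len(ncol(ch1)), p = p,
                 H_obs = colMeans(ch1 != ch2),
                 H_exp = 2 * p * (1 - p))
}

#' FST between demes, by heterozygosity and by allele-frequency variance
#'
#' Heterozygosity-based: `(H_T - mean(H_S)) / H_T` averaged over polymorphic
#' loci, with `H_T` the expected heterozygosity of the pooled population and
#' `H_S` the within-deme expected heterozygosities. Variance-based: the
#' among-deme variance of allele frequencies divided by `p(1-p)` of the
#' pooled frequency, averaged over polymorphic loci. Both lie in [0, 1].
#'
#' @param demes list of `list(ch1=, ch2=)` genome pairs, one per deme.
#' @return named numeric: `fst_het`, `fst_var`.
#' @export
fst <- function(demes) {
  k <- length(demes)
  if (k < 2) stop("need at least two demes")
  freqs <- vapply(demes, function(d) {
    (colSums(d$ch1) + colSums(d$ch2)) / (2 * nrow(d$ch1))
  }, numeric(ncol(demes[[1]]$ch1)))
  if (is.null(dim(freqs))) freqs <- matrix(freqs, 1)
  ns <- vapply(demes, function(d) nrow(d$ch1), numeric(1))
  pbar <- as.numeric(freqs %*% ns) / sum(ns)
  ht <- 2 * pbar * (1 - pbar)
  hs <- 2 * freqs * (1 - freqs)
  hs_bar <- as.numeric(hs %*% ns) / sum(ns)
  poly <- ht > 0
  fst_het <- if (any(poly)) mean((ht[poly] - hs_bar[poly]) / ht[poly]) else 0
  vp <- apply(freqs, 1, function(f) mean((f - mean(f))^2))
  denom <- pbar * (1 - pbar)
  fst_var <- if (any(poly)) mean(vp[poly] / denom[poly]) else 0
  c(fst_het = min(max(fst_het, 0), 1), fst_var = min(max(fst_var, 0), 1))
}

#' Windowed nucleotide diversity
#'
#' Mean pairwise difference per site within sliding windows: for each locus,
#' `pi_l = 2 p (1 - p) * 2n / (2n - 1)` (the unbiased per-site mean pairwise
#' difference over the 2n chromatids), averaged within each window.
#'
#' @param ch1,ch2 N x L chromatid matrices.
#' @param window window width in loci.
#' @param step window step (default = window, non-overlapping).
#' @return tibble with window `start`, `end`, `mid`, `pi`.
#' @export
nucleotide_diversity <- function(ch1, ch2, window = 10, step = window) {
  L <- ncol(ch1)
  n2 <- 2 * nrow(ch1)
  p <- (colSums(ch1) + colSums(ch2)) / n2
  pi_l <- 2 * p * (1 - p) * n2 / (n2 - 1)
  starts <- seq(1, max(L - window + 1, 1), by = step)
  tibble::tibble(
    start = starts, end = pmin(starts + window - 1, L),
    mid = (starts + pmin(starts + window - 1, L)) / 2,
    pi = vapply(starts, function(s) {
      mean(pi_l[s:min(s + window - 1, L)])
    }, numeric(1)))
}

#' PCA-based pairwise genetic distances
#'
#' Centers the genotype matrix (0/0.5/1 genotype scores), computes principal
#' components, and returns Euclidean distances in component-score space
#' (all components by default, so the distance equals the Euclidean distance
#' between centered genotype rows) plus the first `k` scores for mapping.
#'
#' @param ch1,ch2 N x L chromatid matrices.
#' @param k number of leading component scores to return.
#' @return list: `dist` (N x N matrix), `scores` (N x k), `sdev`.
#' @export
genetic_distances_pca <- function(ch1, ch2, k = 3) {
  g <- (ch1 + ch2) / 2
  g <- scale(g, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(g, center = FALSE)
  k <- min(k, ncol(pc$x))
  d <- as.matrix(stats::dist(pc$x))
  dimnames(d) <- NULL
  list(dist = d, scores = pc$x[, seq_len(k), drop = FALSE], sdev = pc$sdev)
}

#' Pairwise geographic / environmental / phenotypic distance matrices
#'
#' @param x,y positions (geographic distance is Euclidean).
#' @param env matrix or vector of environmental values at individuals'
#'   locations (Euclidean distance across columns).
#' @param pheno optional phenotype matrix/vector for phenotypic distance.
#' @return list of symmetric zero-diagonal matrices: `geo`, `env`, and
#'   optionally `pheno`.
#' @export
distance_matrices <- function(x, y, env, pheno = NULL) {
  out <- list(geo = as.matrix(stats::dist(cbind(x, y))),
              env = as.matrix(stats::dist(as.matrix(env))))
  if (!is.null(pheno)) out$pheno <- as.matrix(stats::dist(as.matrix(pheno)))
  lapply(out, function(m) { dimnames(m) <- NULL; m })
}

#' Partial Mantel test
#'
#' Permutation correlation between distance matrices A and B controlling for
#' C (rows and columns permuted jointly); delegates to
#' [vegan::mantel.partial()].
#'
#' @param A,B,C symmetric distance matrices.
#' @param n_perm permutations for the significance test.
#' @return object of class `gl_partial_mantel`: list with `r`, `p`,
#'   `n_perm`, `n`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 999) {
  fit <- vegan::mantel.partial(stats::as.dist(A), stats::as.dist(B),
                               stats::as.dist(C), permutations = n_perm)
  structure(list(r = unname(fit$statistic), p = fit$signif,
                 n_perm = n_perm, n = nrow(as.matrix(A))),
            class = "gl_partial_mantel")
}

#' @export
print.gl_partial_mantel <- function(x, ...) {
  cat(sprintf("Partial Mantel: r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

#' Multiple matrix regression with randomization (MMRR)
#'
#' Ordinary least squares on the vectorized off-diagonals of the response
#' distance matrix against predictor distance matrices; significance of the
#' coefficients and of the full model by joint row/column permutation of the
#' response matrix.
#'
#' @param Y response distance matrix.
#' @param predictors named list of predictor distance matrices.
#' @param n_perm permutations.
#' @return object of class `gl_mmrr`: coefficients, R^2, t-statistics,
#'   permutation p-values.
#' @export
mmrr <- function(Y, predictors, n_perm = 999) {
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("X", seq_along(predictors))
  }
  n <- nrow(Y)
  lt <- lower.tri(Y)
  yv <- Y[lt]
  Xv <- vapply(predictors, function(m) m[lt], numeric(sum(lt)))
  fit <- stats::lm(yv ~ Xv)
  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", names(predictors))
  r2 <- summary(fit)$r.squared
  tstats <- summary(fit)$coefficients[, "t value"]
  fstat <- summary(fit)$fstatistic[1]
  t_perm <- matrix(0, n_perm, length(coefs))
  f_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    ord <- sample.int(n)
    yp <- Y[ord, ord][lt]
    fp <- stats::lm(yp ~ Xv)
    sm <- summary(fp)
    t_perm[i, ] <- sm$coefficients[, "t value"]
    f_perm[i] <- sm$fstatistic[1]
  }
  p_coef <- vapply(seq_along(coefs), function(j) {
    (sum(abs(t_perm[, j]) >= abs(tstats[j])) + 1) / (n_perm + 1)
  }, numeric(1))
  names(p_coef) <- names(coefs)
  p_model <- (sum(f_perm >= fstat) + 1) / (n_perm + 1)
  structure(list(coefficients = coefs, r_squared = unname(r2),
                 t_statistics = stats::setNames(tstats, names(coefs)),
                 p_values = p_coef, p_model = unname(p_model),
                 n = n, n_perm = n_perm),
            class = "gl_mmrr")
}

#' @export
print.gl_mmrr <- function(x, ...) {
  cat(sprintf("MMRR: R^2 = %.4f, model p = %.4g (%d permutations, n = %d)\n",
              x$r_squared, x$p_model, x$n_perm, x$n))
  print(round(rbind(coefficient = x$coefficients, t = x$t_statistics,
                    p = x$p_values), 4))
  invisible(x)
}

#' Tidy methods for fitted matrix-regression objects
#'
#' @param x a `gl_mmrr` or `gl_partial_mantel`.
#' @param ... unused.
#' @return a tibble of terms (tidy) or model summaries (glance).
#' @export
tidy.gl_mmrr <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 statistic = unname(x$t_statistics),
                 p.value = unname(x$p_values))
}

#' @rdname tidy.gl_mmrr
#' @export
glance.gl_mmrr <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_model,
                 n = x$n, n_perm = x$n_perm)
}

#' @rdname tidy.gl_mmrr
#' @export
tidy.gl_partial_mantel <- function(x, ...) {
  tibble::tibble(term = "partial Mantel r", estimate = x$r,
                 p.value = x$p)
}

#' @rdname tidy.gl_mmrr
#' @export
glance.gl_partial_mantel <- function(x, ...) {
  tibble::tibble(statistic = x$r, p.value = x$p, n = x$n, n_perm = x$n_perm)
}

#' Generic tidiers
#'
#' broom-style generics for the package's fitted objects.
#'
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Barrier-crossing rate from a position history
#'
#' Counts transitions whose displacement segment takes an individual from one
#' side of a column zone `[x0, x1]` to the other. An individual lingering
#' inside the zone keeps its last side until it emerges: emerging on the
#' opposite side counts one crossing. The rate is total crossings divided by
#' the number of timesteps.
#'
#' @param history tibble with columns `id`, `t`, `x` (one row per individual
#'   per timestep).
#' @param zone c(x0, x1) column range.
#' @return list: `rate`, `crossings`, `timesteps`.
#' @export
crossing_rate <- function(history, zone) {
  ts <- sort(unique(history$t))
  if (length(ts) < 2) return(list(rate = 0, crossings = 0L,
                                  timesteps = length(ts)))
  crossings <- 0L
  h <- history[order(history$id, history$t), ]
  for (one in split(h, h$id)) {
    s <- zone_side(one$x, zone)
    last <- 0L
    for (v in s) {
      if (v != 0L) {
        if (last != 0L && v == -last) crossings <- crossings + 1L
        last <- v
      }
    }
  }
  T_steps <- length(ts) - 1L
  list(rate = crossings / T_steps, crossings = crossings,
       timesteps = T_steps)
}

#' Mean mismatch and mean fitness time series from a run log
#'
#' @param model a run `gl_model` (or its [run_log()] tibble).
#' @return tibble with `t`, `mean_mismatch`, `mean_fitness`.
#' @export
mismatch_and_fitness_series <- function(model) {
  lg <- if (inherits(model, "gl_model")) run_log(model, "main") else model
  dplyr::select(lg, "t", "mean_mismatch", "mean_fitness")
}

#' McFadden-style pseudo R^2 of a logistic regression
#'
#' Fits `response ~ predictor` with a quasibinomial logit link (the response
#' may be any value in [0, 1], e.g. a phenotype) and returns
#' `1 - deviance / null deviance` plus the Wald p-value of the slope.
#'
#' @param response values in [0, 1].
#' @param predictor numeric covariate.
#' @return list: `pseudo_r2`, `p`, `coef`.
#' @export
logistic_pseudo_r2 <- function(response, predictor) {
  fit <- stats::glm(response ~ predictor, family = stats::quasibinomial())
  sm <- summary(fit)
  list(pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
       p = sm$coefficients[2, 4],
       coef = unname(stats::coef(fit)[2]))
}

#' Locus-wise genotype-environment logistic association scan
#'
#' For each locus, regresses the genotype score (0/0.5/1) on the
#' environmental value with a quasibinomial logit link and records the slope
#' p-value; p-values are Bonferroni-corrected across loci.
#'
#' @param ch1,ch2 N x L chromatid matrices.
#' @param env environmental values at individuals' locations.
#' @return tibble with `locus`, `p`, `p_bonferroni`.
#' @export
gea_scan <- function(ch1, ch2, env) {
  L <- ncol(ch1)
  pvals <- vapply(seq_len(L), function(l) {
    g <- (ch1[, l] + ch2[, l]) / 2
    if (stats::sd(g) == 0) return(1)
    fit <- suppressWarnings(
      stats::glm(g ~ env, family = stats::quasibinomial()))
    sm <- suppressWarnings(summary(fit))
    if (nrow(sm$coefficients) < 2) 1 else sm$coefficients[2, 4]
  }, numeric(1))
  tibble::tibble(locus = seq_len(L), p = pvals,
                 p_bonferroni = pmin(pvals * L, 1))
}
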