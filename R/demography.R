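#' Density estimation, mating, and mortality
#'
#' Mortality combines logistic density dependence with multi-trait selection:
#' an individual dies with probability
#' `P = 1 - (1 - P_dxy) * prod_p omega_ip * prod_l (1 - s_l g_l)`, where the
#' density-dependent component at its cell is
#' `P_dxy = clamp(beta - r (1 - N/K))` with `beta = b * lambda / 2` the
#' per-capita expected birth rate, and the trait fitness is
#' `omega = 1 - phi * |e - z|^gamma`.
#'
#' @name demography
NULL

#' Species-level demographic and life-history parameters
#'
#' @param r intrinsic (logistic) growth rate per timestep.
#' @param b intrinsic birth rate: per-pair Bernoulli mating probability.
#' @param lambda_offspring mean offspring per mating event (Poisson), or the
#'   fixed count when `fixed_offspring = TRUE`.
#' @param fixed_offspring use a fixed offspring count instead of Poisson.
#' @param mating_radius mate-search radius (cell widths).
#' @param pair_weighting `"uniform"`, `"inverse_distance"`, or
#'   `"nearest"` mate choice among in-radius partners.
#' @param repro_age minimum age for mating eligibility.
#' @param max_age maximum age (deterministic death beyond it), or NULL.
#' @param sex_ratio probability an offspring is female.
#' @param dioecious require opposite-sex pairs (FALSE = hermaphroditic).
#' @param density_window side of the square density-estimation window
#'   (cells).
#' @param K_layer name of the carrying-capacity layer.
#' @param K_factor multiplier applied to the K layer to obtain per-cell K.
#' @param p_min,p_max clamp bounds on the density mortality probability.
#' @export
gl_species_params <- function(r = 0.5, b = 0.2, lambda_offspring = 2,
                              fixed_offspring = FALSE, mating_radius = 5,
                              pair_weighting = c("uniform", "inverse_distance",
                                                 "nearest"),
                              repro_age = 1, max_age = NULL, sex_ratio = 0.5,
                              dioecious = FALSE, density_window = 5,
                              K_layer = NULL, K_factor = 1,
                              p_min = 0.001, p_max = 0.999) {
  pair_weighting <- match.arg(pair_weighting)
  if (b < 0 || b > 1) stop("b must lie in [0, 1]")
  if (lambda_offspring < 0) stop("lambda_offspring must be >= 0")
  if (mating_radius <= 0 || density_window < 1) stop("radii must be positive")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]")
  structure(list(r = r, b = b, lambda_offspring = lambda_offspring,
                 fixed_offspring = fixed_offspring,
                 mating_radius = mating_radius,
                 pair_weighting = pair_weighting, repro_age = repro_age,
                 max_age = max_age, sex_ratio = sex_ratio,
                 dioecious = dioecious, density_window = density_window,
                 K_layer = K_layer, K_factor = K_factor,
                 p_min = p_min, p_max = p_max),
            class = "gl_species_params")
}

#' Estimate per-cell population density
#'
#' Counts individuals in a square window centered on each cell and divides by
#' the (boundary-clipped) window area, giving per-cell density.
#'
#' @param x,y individual positions.
#' @param dims c(nrows, ncols).
#' @param window window side in cells (>= 1).
#' @return matrix of per-cell densities.
#' @export
estimate_density <- function(x, y, dims, window = 1) {
  if (window < 1) stop("window must be >= 1")
  counts <- cell_counts(x, y, dims)
  window_mean(counts, window)
}

#' Per-cell individual counts
#' @keywords internal
cell_counts <- function(x, y, dims) {
  cc <- coords_to_cell(x, y, dims)
  matrix(tabulate(cc$cell, nbins = prod(dims)), dims[1], dims[2])
}

# windowed mean via a summed-area table; windows are clipped at the borders
window_mean <- function(m, window) {
  h <- (window - 1) %/% 2
  if (h == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  sat <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- t(sat)
  satp <- matrix(0, nr + 1, nc + 1)
  satp[-1, -1] <- sat
  r1 <- pmax(seq_len(nr) - h, 1); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1); c2 <- pmin(seq_len(nc) + h, nc)
  R1 <- matrix(r1, nr, nc); R2 <- matrix(r2, nr, nc)
  C1 <- matrix(c1, nr, nc, byrow = TRUE); C2 <- matrix(c2, nr, nc, byrow = TRUE)
  tot <- satp[cbind(as.vector(R2 + 1), as.vector(C2 + 1))] -
    satp[cbind(as.vector(R1), as.vector(C2 + 1))] -
    satp[cbind(as.vector(R2 + 1), as.vector(C1))] +
    satp[cbind(as.vector(R1), as.vector(C1))]
  area <- (R2 - R1 + 1) * (C2 - C1 + 1)
  matrix(tot, nr, nc) / area
}

#' Find mating pairs within the search radius
#'
#' Each eligible individual draws at most one mate from the eligible partners
#' within its mate-search radius, with uniform, inverse-distance, or strict
#' nearest-neighbour weighting; pairs are deduplicated and each individual
#' takes part in at most one pair per timestep.
#'
#' @param x,y positions.
#' @param eligible logical or integer index of mating-eligible individuals.
#' @param sex integer sex codes (0/1), used when `dioecious`.
#' @param radius mate-search radius.
#' @param weighting `"uniform"`, `"inverse_distance"`, or `"nearest"`.
#' @param dioecious require opposite sexes.
#' @return two-column integer matrix of individual indices (one row per pair).
#' @export
find_mating_pairs <- function(x, y, eligible, sex = NULL, radius,
                              weighting = "uniform", dioecious = FALSE) {
  idx <- if (is.logical(eligible)) which(eligible) else as.integer(eligible)
  n <- length(idx)
  if (n < 2) return(matrix(integer(0), 0, 2))
  xs <- x[idx]; ys <- y[idx]
  # spatial binning at the search radius: all partners of an individual lie
  # in its own or the 8 adjacent bins
  bx <- as.integer(floor(xs / radius))
  by <- as.integer(floor(ys / radius))
  B <- max(max(bx) - min(bx), max(by) - min(by)) + 3L
  key <- (bx - min(bx) + 1L) * B + (by - min(by) + 1L)
  uk <- sort(unique(key))
  grp <- match(key, uk)
  ord <- order(grp)
  cnt <- tabulate(grp, length(uk))
  starts <- c(0L, cumsum(cnt))
  acc_i <- vector("list", 9); acc_j <- vector("list", 9); k <- 0L
  for (dxb in -1:1) for (dyb in -1:1) {
    ng <- match(key + dxb * B + dyb, uk)
    has <- which(!is.na(ng))
    if (length(has) == 0) next
    k <- k + 1L
    reps <- cnt[ng[has]]
    acc_i[[k]] <- rep.int(has, reps)
    acc_j[[k]] <- ord[sequence(reps, from = starts[ng[has]] + 1L)]
  }
  ii <- unlist(acc_i, use.names = FALSE)
  jj <- unlist(acc_j, use.names = FALSE)
  if (is.null(ii)) return(matrix(integer(0), 0, 2))
  keep <- ii != jj
  if (dioecious) keep <- keep & (sex[idx][ii] != sex[idx][jj])
  ii <- ii[keep]; jj <- jj[keep]
  d <- sqrt((xs[ii] - xs[jj])^2 + (ys[ii] - ys[jj])^2)
  inr <- d <= radius
  ii <- ii[inr]; jj <- jj[inr]; d <- d[inr]
  if (length(ii) == 0) return(matrix(integer(0), 0, 2))
  # sample one partner per chooser: exponential-race trick gives a draw
  # proportional to the weights without per-group sample() calls
  race <- if (weighting == "nearest") d else if
    (weighting == "inverse_distance") stats::rexp(length(d)) *
      pmax(d, 1e-12) else stats::rexp(length(d))
  o <- order(ii, race)
  first <- o[!duplicated(ii[o])]
  ci <- idx[ii[first]]; cj <- idx[jj[first]]
  a <- pmin(ci, cj); b <- pmax(ci, cj)
  dup <- duplicated(cbind(a, b))
  a <- a[!dup]; b <- b[!dup]
  # greedy enforcement: at most one mating per individual per timestep,
  # processed in random order
  rord <- sample.int(length(a))
  seen <- logical(max(b))
  keep2 <- logical(length(a))
  for (t in rord) {
    at <- a[t]; bt <- b[t]
    if (!seen[at] && !seen[bt]) {
      seen[at] <- TRUE; seen[bt] <- TRUE
      keep2[t] <- TRUE
    }
  }
  cbind(a[keep2], b[keep2], deparse.level = 0)
}

#' Bernoulli mating decisions
#'
#' Each candidate pair mates independently with probability equal to the
#' intrinsic birth rate.
#'
#' @param pairs two-column pair matrix.
#' @param b intrinsic birth rate in [0, 1].
#' @return the mating subset of `pairs`.
#' @export
decide_matings <- function(pairs, b) {
  if (b < 0 || b > 1) stop("b must lie in [0, 1]")
  if (nrow(pairs) == 0) return(pairs)
  pairs[stats::runif(nrow(pairs)) < b, , drop = FALSE]
}

#' Offspring number per mating event
#'
#' @param n_events number of mating events.
#' @param lambda mean (Poisson) or fixed offspring count.
#' @param fixed use the fixed count.
#' @export
draw_n_offspring <- function(n_events, lambda, fixed = FALSE) {
  if (fixed) rep(as.integer(lambda), n_events) else
    stats::rpois(n_events, lambda)
}

#' Density-dependent death probability
#'
#' From the logistic model `dN/dt = r N (1 - N/K)` and expected births
#' `E[N_b] = beta * N` (with `beta = b * lambda / 2` expected births per
#' capita), the expected per-capita death probability is
#' `P = beta - r (1 - N/K)`, clamped to `[p_min, p_max]`. At `N = K` births
#' balance deaths exactly (`P = beta`); cells with `K = 0` take `p_max`.
#'
#' @param N_hat estimated local density.
#' @param K local carrying capacity.
#' @param r intrinsic growth rate.
#' @param beta expected per-capita births.
#' @param p_min,p_max clamp bounds.
#' @export
p_death_density <- function(N_hat, K, r, beta, p_min = 0.001, p_max = 0.999) {
  p <- ifelse(K > 0, beta - r * (1 - N_hat / pmax(K, .Machine$double.eps)),
              p_max)
  pmin(pmax(p, p_min), p_max)
}

#' Trait fitness from phenotype-environment mismatch
#'
#' `omega = 1 - phi * |e - z|^gamma`, bounded in `[1 - phi, 1]`: a perfect
#' match costs nothing, the maximal mismatch of 1 costs the full selection
#' coefficient.
#'
#' @param z phenotype(s) in [0, 1].
#' @param e selection-layer value(s) at the individual's cell.
#' @param phi selection coefficient(s) in [0, 1].
#' @param gamma fitness-curve curvature (> 0).
#' @export
fitness_trait <- function(z, e, phi, gamma = 1) {
  1 - phi * abs(e - z)^gamma
}

#' Total death probability combining density dependence and selection
#'
#' `P = 1 - (1 - P_dxy) * prod_p omega_p * prod_l (1 - s_l g_l)`.
#'
#' @param p_dxy density-dependent component (vector over individuals).
#' @param trait_fitnesses matrix (individuals x traits) of omega values, or
#'   NULL when selection is off.
#' @param deleterious_factors per-individual product of `(1 - s_l g_l)` over
#'   registered deleterious loci, or NULL.
#' @export
p_death_total <- function(p_dxy, trait_fitnesses = NULL,
                          deleterious_factors = NULL) {
  w <- rep(1, length(p_dxy))
  if (!is.null(trait_fitnesses)) {
    tf <- as.matrix(trait_fitnesses)
    w <- w * apply(tf, 1, prod)
  }
  if (!is.null(deleterious_factors)) w <- w * deleterious_factors
  pmin(pmax(1 - (1 - p_dxy) * w, 0), 1)
}

#' Per-individual deleterious fitness factor
#'
#' Product over registered deleterious loci of `(1 - s_l * g_l)` with `g_l`
#' the genotype score.
#'
#' @param ch1,ch2 chromatid matrices.
#' @param arch a `gl_genarch` with a (possibly empty) deleterious registry.
#' @export
deleterious_factors <- function(ch1, ch2, arch) {
  if (length(arch$delet_s) == 0) return(rep(1, nrow(ch1)))
  loci <- as.integer(names(arch$delet_s))
  g <- genotype_scores(ch1, ch2, loci, arch$dominance)
  f <- 1 - g * matrix(arch$delet_s, nrow(ch1), length(loci), byrow = TRUE)
  apply(f, 1, prod)
}

#' Bernoulli mortality
#'
#' Each individual dies independently with its total death probability;
#' individuals beyond `max_age` die deterministically.
#'
#' @param p_total per-individual death probabilities.
#' @param age ages.
#' @param max_age maximum age or NULL.
#' @return logical survival vector.
#' @export
apply_mortality <- function(p_total, age = NULL, max_age = NULL) {
  survive <- stats::runif(length(p_total)) >= p_total
  if (!is.null(max_age) && !is.null(age)) survive <- survive & (age <= max_age)
  survive
}
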