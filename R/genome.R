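#' Genomic architecture, genotypes, recombination, mutation, phenotypes
#'
#' Genomes are diploid and diallelic: an individual's genome is an L x 2
#' binary matrix (two homologous chromatids), stored population-wide as two
#' N x L matrices. Recombination between neighbouring loci is modeled through
#' pre-generated "recombination paths": genome-length binary arrays that
#' switch chromatid at an inter-locus gap with probability equal to that gap's
#' recombination rate. Paths are shuffled and drawn through like a deck of
#' cards; the number of paths sets the smallest recombination-rate difference
#' that can be represented (1/R).
#'
#' @name genome
NULL

#' Define a phenotypic trait
#'
#' A trait is controlled by a set of loci with additive effect sizes. Its
#' phenotype is, by default, the centered additive form
#' `z = g0 + sum_l alpha_l * (g_l - g0)` with baseline `g0 = 0` for monogenic
#' and `g0 = 0.5` for polygenic traits, so that equal effect sizes `1/n` span
#' phenotypes on [0, 1]. The literal uncentered form
#' `z = sum_l alpha_l * g_l + g0` is available via `centered = FALSE`.
#'
#' @param loci integer locus positions (1-based, distinct).
#' @param effect_sizes per-locus effect sizes; default `1/length(loci)` for
#'   polygenic traits and 1 for monogenic traits.
#' @param phi selection coefficient (scalar in [0, 1], or the name of a
#'   selection layer holding per-cell phi values).
#' @param gamma fitness-curve curvature (> 0).
#' @param layer name of the selection layer the trait tracks.
#' @param mu per-locus per-gamete trait-affecting mutation rate.
#' @param centered use the centered additive phenotype (default TRUE).
#' @param name trait name.
#' @export
gl_trait <- function(loci, effect_sizes = NULL, phi = 0.05, gamma = 1,
                     layer = NULL, mu = 0, centered = TRUE, name = "trait") {
  loci <- as.integer(loci)
  if (anyDuplicated(loci)) stop("trait loci must be distinct")
  n <- length(loci)
  if (is.null(effect_sizes)) effect_sizes <- if (n == 1) 1 else rep(1 / n, n)
  if (length(effect_sizes) != n) stop("one effect size per locus")
  if (gamma <= 0) stop("gamma must be > 0")
  if (is.numeric(phi) && (phi < 0 || phi > 1)) stop("phi must lie in [0, 1]")
  structure(list(name = name, loci = loci, effect_sizes = effect_sizes,
                 phi = phi, gamma = gamma, layer = layer, mu = mu,
                 baseline = if (n == 1) 0 else 0.5, centered = centered),
            class = "gl_trait")
}

#' Define a genomic architecture
#'
#' @param L locus count.
#' @param recomb_rates inter-locus recombination rates: scalar or length L-1
#'   vector, each in [0, 0.5].
#' @param dominance per-locus dominance: 0 = codominant (genotype score is the
#'   mean of the two alleles), 1 = dominant (score 1 if any allele is 1).
#'   Scalar or length-L vector.
#' @param mu_neutral,mu_deleterious per-locus per-gamete mutation rates for
#'   the neutral and deleterious classes.
#' @param traits list of [gl_trait()]s; their loci must lie in 1..L.
#' @param start_freq starting 1-allele frequency per locus (scalar or
#'   length-L).
#' @param prop_deleterious fraction of non-trait loci eligible for
#'   deleterious mutations (the rest are neutral).
#' @param delet_mean_s mean of the exponential distribution deleterious
#'   selection coefficients are drawn from (capped at 1).
#' @param trait_effect_sd std. dev. of effect sizes drawn for trait-affecting
#'   mutations at not-yet-active loci.
#' @export
gl_genarch <- function(L, recomb_rates = 0.5, dominance = 0,
                       mu_neutral = 0, mu_deleterious = 0,
                       traits = list(), start_freq = 0.5,
                       prop_deleterious = 0, delet_mean_s = 0.01,
                       trait_effect_sd = NULL) {
  L <- as.integer(L)
  if (length(recomb_rates) == 1) recomb_rates <- rep(recomb_rates, max(L - 1L, 0L))
  if (length(recomb_rates) != L - 1L) stop("recomb_rates must have length L - 1")
  if (any(recomb_rates < 0 | recomb_rates > 0.5)) {
    stop("recombination rates must lie in [0, 0.5]")
  }
  if (length(dominance) == 1) dominance <- rep(dominance, L)
  if (any(c(mu_neutral, mu_deleterious) < 0 |
          c(mu_neutral, mu_deleterious) > 1)) {
    stop("mutation rates must lie in [0, 1]")
  }
  if (inherits(traits, "gl_trait")) traits <- list(traits)
  trait_loci <- unlist(lapply(traits, `[[`, "loci"))
  if (anyDuplicated(trait_loci)) stop("a locus may underlie only one trait")
  if (length(trait_loci) && (min(trait_loci) < 1 || max(trait_loci) > L)) {
    stop("trait loci must lie in 1..L")
  }
  if (length(start_freq) == 1) start_freq <- rep(start_freq, L)
  if (any(start_freq < 0 | start_freq > 1)) stop("start_freq must lie in [0, 1]")
  non_trait <- setdiff(seq_len(L), trait_loci)
  n_del <- round(prop_deleterious * length(non_trait))
  delet_loci <- if (n_del > 0) non_trait[seq_len(n_del)] else integer()
  neutral_loci <- setdiff(non_trait, delet_loci)
  if (length(traits)) {
    names(traits) <- vapply(traits, `[[`, character(1), "name")
  }
  structure(list(L = L, recomb_rates = recomb_rates, dominance = dominance,
                 mu_neutral = mu_neutral, mu_deleterious = mu_deleterious,
                 traits = traits, start_freq = start_freq,
                 neutral_loci = neutral_loci, delet_loci = delet_loci,
                 delet_s = stats::setNames(numeric(0), character(0)),
                 delet_mean_s = delet_mean_s,
                 trait_effect_sd = trait_effect_sd,
                 # trait loci all carry their effects from the start unless a
                 # positive trait mutation rate makes them mutation-activated
                 trait_active = lapply(traits, function(tr) {
                   rep(TRUE, length(tr$loci))
                 })),
            class = "gl_genarch")
}

#' Randomly initialise genomes from the architecture
#'
#' Alleles are independent Bernoulli(start_freq_l) draws; the population
#' starts with no pedigree and no spatial genetic structure.
#'
#' @param arch a `gl_genarch`.
#' @param n number of individuals (> 0).
#' @return list with `ch1`, `ch2`: n x L integer matrices.
#' @export
init_genomes <- function(arch, n) {
  if (n <= 0) stop("n must be positive")
  p <- rep(arch$start_freq, each = n)
  list(ch1 = matrix(stats::rbinom(n * arch$L, 1L, p), n, arch$L),
       ch2 = matrix(stats::rbinom(n * arch$L, 1L, p), n, arch$L))
}

# ---- recombination paths -----------------------------------------------

#' Pre-generate recombination paths
#'
#' Each path starts on a Bernoulli(0.5) chromatid and flips at inter-locus
#' gap j with probability `recomb_rates[j]`, independently across gaps and
#' paths.
#'
#' @param arch a `gl_genarch`.
#' @param R number of paths (>= 2); 1/R is the smallest representable
#'   recombination-rate difference.
#' @return a `gl_recomb_paths` holding the R x L binary path matrix and the
#'   shuffle-and-draw cursor state.
#' @export
generate_recomb_paths <- function(arch, R) {
  if (R < 1) stop("R must be >= 1")
  L <- arch$L
  init <- stats::rbinom(R, 1L, 0.5)
  if (L > 1) {
    sw <- matrix(stats::rbinom(R * (L - 1L), 1L,
                               rep(arch$recomb_rates, each = R)), R, L - 1L)
    cum <- sw
    if (L > 2) {
      for (j in 2:(L - 1L)) cum[, j] <- cum[, j - 1L] + cum[, j]
    }
    paths <- cbind(init, init + cum) %% 2L
  } else {
    paths <- matrix(init, R, 1L)
  }
  dimnames(paths) <- NULL
  deck <- new.env(parent = emptyenv())
  deck$order <- sample.int(R)
  deck$cursor <- 0L
  structure(list(paths = paths, R = R, deck = deck),
            class = "gl_recomb_paths")
}

#' Draw path indices from the shuffled deck
#'
#' Draws without replacement from a shuffled order, reshuffling when the deck
#' is exhausted: any window of R consecutive draws contains each path exactly
#' once.
#'
#' @param rp a `gl_recomb_paths`.
#' @param n number of paths to draw.
#' @return integer row indices into `rp$paths`.
#' @export
draw_path_indices <- function(rp, n) {
  out <- integer(n); got <- 0L
  deck <- rp$deck
  while (got < n) {
    if (deck$cursor >= rp$R) {
      deck$order <- sample.int(rp$R)
      deck$cursor <- 0L
    }
    take <- min(n - got, rp$R - deck$cursor)
    out[(got + 1L):(got + take)] <-
      deck$order[(deck$cursor + 1L):(deck$cursor + take)]
    deck$cursor <- deck$cursor + take
    got <- got + take
  }
  out
}

#' Produce a gamete from a genome and a recombination path
#'
#' `gamete[l] = chromatid[path[l] + 1][l]`: the path selects, per locus, which
#' of the parent's two chromatids contributes the allele.
#'
#' @param ch1,ch2 the parent's two chromatids (length-L binary vectors).
#' @param path length-L binary path.
#' @export
make_gamete <- function(ch1, ch2, path) {
  if (length(path) != length(ch1)) stop("path length must equal genome length")
  ifelse(path == 0L, ch1, ch2)
}

#' Vectorised gamete production for many parents at once
#'
#' @param ch1,ch2 N x L chromatid matrices.
#' @param parents length-G parent row indices (one per gamete).
#' @param pathmat G x L binary path matrix.
#' @return G x L gamete matrix.
#' @keywords internal
make_gametes <- function(ch1, ch2, parents, pathmat) {
  gam <- ch1[parents, , drop = FALSE]
  alt <- ch2[parents, , drop = FALSE]
  sel <- pathmat == 1L
  gam[sel] <- alt[sel]
  gam
}

#' On-the-fly recombination for homogeneous maps
#'
#' Generates a fresh path per gamete at a single uniform rate instead of
#' drawing from the pre-generated deck; distributionally identical to the
#' path mechanism at that rate, trading memory for per-gamete runtime.
#'
#' @param ch1,ch2 N x L chromatid matrices.
#' @param parents length-G parent row indices.
#' @param rate uniform inter-locus recombination rate in [0, 0.5].
#' @return G x L gamete matrix.
#' @export
recombine_on_the_fly <- function(ch1, ch2, parents, rate) {
  if (length(rate) != 1) stop("on-the-fly recombination needs a homogeneous rate")
  if (rate < 0 || rate > 0.5) stop("rate must lie in [0, 0.5]")
  G <- length(parents); L <- ncol(ch1)
  init <- stats::rbinom(G, 1L, 0.5)
  if (L > 1) {
    sw <- matrix(stats::rbinom(G * (L - 1L), 1L, rate), G, L - 1L)
    cum <- sw
    if (L > 2) for (j in 2:(L - 1L)) cum[, j] <- cum[, j - 1L] + cum[, j]
    pathmat <- cbind(init, init + cum) %% 2L
  } else {
    pathmat <- matrix(init, G, 1L)
  }
  make_gametes(ch1, ch2, parents, pathmat)
}

# ---- mutation ----------------------------------------------------------

#' Apply neutral, deleterious, and trait-affecting mutations to gametes
#'
#' Loci are partitioned into neutral, deleterious-eligible, and trait-mapped
#' pools. Per gamete, mutation counts are Binomial(pool size, class rate).
#' Neutral mutations flip an allele at a neutral locus; deleterious mutations
#' flip an allele and register a selection coefficient `s ~ Exp(mean s)`
#' (capped at 1) for the locus; trait-affecting mutations set the allele at a
#' previously unmutated (inactive) trait-mapped locus and activate its effect
#' size (drawn Normal(0, sd) unless preset). An exhausted trait pool skips
#' the mutation with a warning.
#'
#' @param gametes G x L binary gamete matrix.
#' @param arch a `gl_genarch`.
#' @return list with `gametes` (mutated), `arch` (updated deleterious registry
#'   and trait activations) and `records` (tibble of mutations).
#' @export
apply_mutations <- function(gametes, arch) {
  G <- nrow(gametes)
  recs <- list()
  if (G > 0) {
    flip_class <- function(pool, mu) {
      if (mu <= 0 || length(pool) == 0) return(NULL)
      ncell <- G * length(pool)
      k <- stats::rbinom(1L, ncell, mu)
      if (k == 0) return(NULL)
      cells <- sample.int(ncell, k)
      data.frame(gamete = ((cells - 1L) %/% length(pool)) + 1L,
                 locus = pool[((cells - 1L) %% length(pool)) + 1L])
    }
    nm <- flip_class(arch$neutral_loci, arch$mu_neutral)
    if (!is.null(nm)) {
      idx <- cbind(nm$gamete, nm$locus)
      gametes[idx] <- 1L - gametes[idx]
      recs[[length(recs) + 1L]] <-
        tibble::tibble(class = "neutral", gamete = nm$gamete, locus = nm$locus,
                       s = NA_real_, alpha = NA_real_)
    }
    dm <- flip_class(arch$delet_loci, arch$mu_deleterious)
    if (!is.null(dm)) {
      idx <- cbind(dm$gamete, dm$locus)
      gametes[idx] <- 1L - gametes[idx]
      new_s <- rep(NA_real_, nrow(dm))
      for (i in seq_len(nrow(dm))) {
        key <- as.character(dm$locus[i])
        if (!(key %in% names(arch$delet_s))) {
          arch$delet_s[key] <- min(stats::rexp(1, 1 / arch$delet_mean_s), 1)
        }
        new_s[i] <- arch$delet_s[key]
      }
      recs[[length(recs) + 1L]] <-
        tibble::tibble(class = "deleterious", gamete = dm$gamete,
                       locus = dm$locus, s = new_s, alpha = NA_real_)
    }
    for (p in seq_along(arch$traits)) {
      tr <- arch$traits[[p]]
      if (tr$mu <= 0) next
      inactive <- tr$loci[!arch$trait_active[[p]]]
      k <- stats::rbinom(1L, G * length(tr$loci), tr$mu)
      if (k == 0) next
      if (length(inactive) == 0) {
        warning("trait-mutation pool exhausted for trait '", tr$name,
                "'; mutation skipped")
        next
      }
      k_eff <- min(k, length(inactive))
      if (k_eff < k) {
        warning("trait-mutation pool exhausted for trait '", tr$name,
                "'; ", k - k_eff, " mutation(s) skipped")
      }
      loci_hit <- sample(inactive, k_eff)
      gam_hit <- sample.int(G, k_eff, replace = TRUE)
      gametes[cbind(gam_hit, loci_hit)] <- 1L
      li <- match(loci_hit, tr$loci)
      arch$trait_active[[p]][li] <- TRUE
      sd_a <- if (is.null(arch$trait_effect_sd)) 1 / length(tr$loci) else
        arch$trait_effect_sd
      drawn <- stats::rnorm(k_eff, 0, sd_a)
      preset <- !is.na(tr$effect_sizes[li]) & tr$effect_sizes[li] != 0
      tr$effect_sizes[li][!preset] <- drawn[!preset]
      arch$traits[[p]] <- tr
      recs[[length(recs) + 1L]] <-
        tibble::tibble(class = "trait", gamete = gam_hit, locus = loci_hit,
                       s = NA_real_, alpha = tr$effect_sizes[li])
    }
  }
  records <- if (length(recs)) dplyr::bind_rows(recs) else
    tibble::tibble(class = character(), gamete = integer(), locus = integer(),
                   s = numeric(), alpha = numeric())
  list(gametes = gametes, arch = arch, records = records)
}

# ---- phenotypes --------------------------------------------------------

#' Per-locus genotype scores for a set of loci
#'
#' Codominant loci score the mean of the two alleles (0, 0.5, 1); dominant
#' loci score 1 if either allele is 1.
#'
#' @param ch1,ch2 N x L chromatid matrices.
#' @param loci locus positions.
#' @param dominance per-locus dominance flags (length L).
#' @return N x length(loci) score matrix.
#' @keywords internal
genotype_scores <- function(ch1, ch2, loci, dominance) {
  a <- ch1[, loci, drop = FALSE]
  b <- ch2[, loci, drop = FALSE]
  g <- (a + b) / 2
  dom <- dominance[loci] == 1
  if (any(dom)) {
    gd <- pmax(a[, dom, drop = FALSE], b[, dom, drop = FALSE])
    g[, dom] <- gd
  }
  g
}

#' Compute phenotypes for one trait across individuals
#'
#' Centered form (default): `z = g0 + sum_l alpha_l (g_l - g0)` with `g0 = 0`
#' (monogenic) or `0.5` (polygenic); with the default equal effect sizes
#' `1/n`, phenotypes span [0, 1]. Uncentered literal form:
#' `z = sum_l alpha_l g_l + g0`. Only activated trait loci contribute.
#'
#' @param ch1,ch2 N x L chromatid matrices.
#' @param trait a `gl_trait`.
#' @param arch the `gl_genarch` (for dominance and activation flags).
#' @return numeric vector of phenotypes (length N).
#' @export
compute_phenotype <- function(ch1, ch2, trait, arch) {
  p_idx <- match(trait$name, names(arch$traits))
  active <- if (!is.na(p_idx)) arch$trait_active[[p_idx]] else
    rep(TRUE, length(trait$loci))
  loci <- trait$loci[active]
  alpha <- trait$effect_sizes[active]
  if (length(loci) == 0) return(rep(trait$baseline, nrow(ch1)))
  g <- genotype_scores(ch1, ch2, loci, arch$dominance)
  if (trait$centered) {
    as.numeric(trait$baseline + g %*% alpha - sum(alpha) * trait$baseline)
  } else {
    as.numeric(g %*% alpha + trait$baseline)
  }
}
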