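#' Canned simulation scenarios
#'
#' Parameter builders for the package's reference study conditions: the
#' IBD-IBE barrier landscape, two-habitat divergent selection, a monogenic
#' environmental cline, a Wright-Fisher-style drift emulation, a selective
#' sweep in a linked block, and a demographic bottleneck. Each returns a
#' complete parameter list for [build_model()]; companion `analyse_*` helpers
#' compute the statistics each scenario is read with.
#'
#' @name scenarios
NULL

#' IBD-IBE barrier scenario
#'
#' A species (stationary size ~2,450) on a 50 x 50 landscape: a central
#' 5-column high-resistance barrier serves as both the movement/dispersal
#' surface and the carrying-capacity layer (zero K inside the barrier), and a
#' selection layer of two opposed gradients drives a 10-locus trait with
#' selection coefficient `phi`. Barrier crossings of the central column range
#' are tracked. With `barrier = FALSE` the central band is maximally
#' permeable and the total carrying capacity is kept equal.
#'
#' @param barrier include the high-resistance central band.
#' @param phi trait selection coefficient.
#' @param T main timesteps.
#' @param nrows,ncols landscape size.
#' @return parameter list.
#' @export
scenario_ibd_ibe <- function(barrier = TRUE, phi = 0.05, T = 1000,
                             nrows = 50, ncols = 50) {
  bcols <- c(floor(ncols / 2) - 3, floor(ncols / 2) + 3)  # 7 columns
  n_outside <- nrows * (ncols - (bcols[2] - bcols[1] + 1))
  target_N <- 2450
  # localized mating and dispersal clump the population, so the stationary
  # size settles at ~0.68 of the summed carrying capacity; K is scaled so the
  # stationary population matches the scenario's nominal size
  k_calib <- 1 / 0.68
  K_factor <- k_calib * if (barrier) target_N / n_outside else
    target_N / (nrows * ncols)
  move_layer <- list(
    name = "habitat",
    kind = if (barrier) "barrier" else "uniform",
    barrier_cols = as.list(bcols), inside = 0, outside = 1, value = 1,
    roles = list("movement", "dispersal", "carrying_capacity"))
  env_layer <- list(name = "env", kind = "opposed_gradients",
                    barrier_cols = as.list(bcols), inside_value = 0.5,
                    roles = list("selection"))
  list(
    landscape = list(nrows = nrows, ncols = ncols,
                     layers = list(move_layer, env_layer)),
    species = list(
      r = 0.5, b = 0.2, lambda_offspring = 2, mating_radius = 5,
      repro_age = 1, density_window = 5,
      K_layer = "habitat", K_factor = K_factor,
      movement = list(enabled = TRUE, distance_mean = 0.5,
                      distance_shape = 0.5, surface_layer = "habitat",
                      mode = "mixture", kappa = 12, approx_len = 1000),
      dispersal = list(distance_mean = 0.5, distance_shape = 0.5,
                       surface_layer = "habitat", mode = "mixture",
                       kappa = 12, approx_len = 1000),
      genome = list(L = 80, recomb_rate = 0.5, n_recomb_paths = 1000,
                    start_freq = 0.5,
                    traits = list(list(name = "adaptive", n_loci = 10,
                                       phi = phi, gamma = 1,
                                       selection_layer = "env")))),
    model = list(T = T, track_zone = as.list(c(bcols[1] - 1, bcols[2])),
                 burn_in = list(min_length = 100, lag = 50, alpha = 0.05,
                                cadence = 10, max_length = 500)))
}

#' IBD / IBE / MMRR analysis of a finished run
#'
#' Subsamples individuals, computes PCA-based genetic distances plus
#' geographic and environmental distances, and runs the paired partial
#' Mantel tests (IBD: genetic ~ geographic | environmental; IBE:
#' genetic ~ environmental | geographic) and the full MMRR model. Also
#' summarises the mean population size over the second half of the run and
#' the per-timestep barrier-crossing rate.
#'
#' @param model a completed IBD-IBE `gl_model`.
#' @param n_sample individuals used in the distance analyses.
#' @param n_perm Mantel/MMRR permutations.
#' @return tibble with `mantel_ibd`, `mantel_ibe`, `mmrr_r2`, `mean_N`,
#'   `crossing_rate`.
#' @export
analyse_ibd_ibe <- function(model, n_sample = 600, n_perm = 99) {
  pop <- model$pop
  n <- length(pop$x)
  keep <- if (n > n_sample) sort(sample.int(n, n_sample)) else seq_len(n)
  gd <- genetic_distances_pca(pop$ch1[keep, , drop = FALSE],
                              pop$ch2[keep, , drop = FALSE])
  cc <- coords_to_cell(pop$x[keep], pop$y[keep], model$landscape$dims)
  tr <- model$arch$traits[[1]]
  e <- layer_at_time(model$landscape$layers[[tr$layer]], model$t)[cc$cell]
  dm <- distance_matrices(pop$x[keep], pop$y[keep], e)
  ibd <- partial_mantel(gd$dist, dm$geo, dm$env, n_perm = n_perm)
  ibe <- partial_mantel(gd$dist, dm$env, dm$geo, n_perm = n_perm)
  mm <- mmrr(gd$dist, list(geo = dm$geo, env = dm$env), n_perm = n_perm)
  lg <- run_log(model, "main")
  half <- lg[lg$t > max(lg$t) / 2, ]
  tibble::tibble(
    mantel_ibd = ibd$r, mantel_ibd_p = ibd$p,
    mantel_ibe = ibe$r, mantel_ibe_p = ibe$p,
    mmrr_r2 = mm$r_squared, mmrr_p = mm$p_model,
    mean_N = mean(half$N),
    crossing_rate = sum(lg$crossings) / nrow(lg))
}

#' Two-habitat divergent-selection scenario
#'
#' A landscape evenly divided into two habitat blocks with environmental
#' values 0 and 1 serving as the selection layer of a 10-locus trait; used to
#' study migration-selection equilibrium and phenotype-habitat matching.
#'
#' @param phi selection coefficient.
#' @param T main timesteps.
#' @param nrows,ncols landscape size.
#' @export
scenario_divergent_selection <- function(phi = 0.05, T = 500,
                                         nrows = 26, ncols = 26) {
  list(
    landscape = list(
      nrows = nrows, ncols = ncols,
      layers = list(
        list(name = "habitat", kind = "uniform", value = 1,
             roles = list("carrying_capacity")),
        list(name = "env", kind = "barrier",
             barrier_cols = as.list(c(ncols %/% 2 + 1, ncols)),
             inside = 1, outside = 0, roles = list("selection")))),
    species = list(
      r = 0.5, b = 0.2, lambda_offspring = 2, mating_radius = 3,
      repro_age = 1, density_window = 5, K_layer = "habitat", K_factor = 1,
      movement = list(enabled = TRUE, distance_mean = 0.6,
                      distance_shape = 0.5, surface_layer = NULL),
      dispersal = list(distance_mean = 0.6, distance_shape = 0.5,
                       surface_layer = NULL),
      genome = list(L = 60, recomb_rate = 0.5, n_recomb_paths = 500,
                    start_freq = 0.5,
                    traits = list(list(name = "adaptive", n_loci = 10,
                                       phi = phi, gamma = 1,
                                       selection_layer = "env")))),
    model = list(T = T,
                 burn_in = list(min_length = 100, lag = 50, alpha = 0.05,
                                cadence = 10, max_length = 400)))
}

#' Monogenic environmental-cline scenario
#'
#' A symmetric linear gradient is the selection layer of a monogenic trait;
#' local adaptation produces a cline in the allele frequency of the trait
#' locus.
#'
#' @param phi selection coefficient.
#' @param T main timesteps.
#' @param nrows,ncols landscape size.
#' @export
scenario_cline <- function(phi = 0.05, T = 500, nrows = 26, ncols = 26) {
  list(
    landscape = list(
      nrows = nrows, ncols = ncols,
      layers = list(
        list(name = "habitat", kind = "uniform", value = 1,
             roles = list("carrying_capacity")),
        list(name = "env", kind = "gradient", direction = "x",
             roles = list("selection")))),
    species = list(
      r = 0.5, b = 0.2, lambda_offspring = 2, mating_radius = 3,
      repro_age = 1, density_window = 5, K_layer = "habitat", K_factor = 1,
      movement = list(enabled = TRUE, distance_mean = 1,
                      distance_shape = 0.5, surface_layer = NULL),
      dispersal = list(distance_mean = 1, distance_shape = 0.5,
                       surface_layer = NULL),
      genome = list(L = 60, recomb_rate = 0.5, n_recomb_paths = 500,
                    start_freq = 0.5,
                    traits = list(list(name = "adaptive", n_loci = 1,
                                       phi = phi, gamma = 1,
                                       selection_layer = "env")))),
    model = list(T = T,
                 burn_in = list(min_length = 100, lag = 50, alpha = 0.05,
                                cadence = 10, max_length = 400)))
}

#' Phenotype-environment association of a finished run
#'
#' Logistic regression (quasibinomial logit) of individual phenotype on the
#' selection-layer value at the individual's location; returns the
#' McFadden-style pseudo R^2.
#'
#' @param model a completed `gl_model` with at least one trait.
#' @return tibble with `pseudo_r2`, `p`, `n`.
#' @export
analyse_phenotype_env <- function(model) {
  pop <- model$pop
  tr <- model$arch$traits[[1]]
  cc <- coords_to_cell(pop$x, pop$y, model$landscape$dims)
  e <- layer_at_time(model$landscape$layers[[tr$layer]], model$t)[cc$cell]
  fit <- logistic_pseudo_r2(pop$z[, 1], e)
  tibble::tibble(pseudo_r2 = fit$pseudo_r2, p = fit$p, n = length(e))
}

#' Wright-Fisher-style drift emulation scenario
#'
#' Selection off, movement off, mate search spanning the landscape, global
#' density regulation, and many unlinked neutral loci starting at frequency
#' 0.5: allele-frequency trajectories drift to fixation and the mean fixation
#' time grows with population size.
#'
#' @param N target population size.
#' @param L neutral locus count.
#' @export
scenario_wright_fisher <- function(N = 100, L = 250) {
  side <- 10
  list(
    landscape = list(nrows = side, ncols = side,
                     layers = list(list(name = "habitat", kind = "uniform",
                                        value = 1,
                                        roles = list("carrying_capacity")))),
    species = list(
      r = 0.5, b = 0.5, lambda_offspring = 2, mating_radius = 2 * side,
      repro_age = 1, density_window = 4 * side,
      # high turnover plus newborn ineligibility hold the stationary size at
      # ~0.43 of sum(K); scale K so the realized size matches the nominal N
      K_layer = "habitat", K_factor = N / side^2 / 0.43,
      movement = list(enabled = FALSE),
      dispersal = list(distance_mean = 3, distance_shape = 1,
                       surface_layer = NULL),
      genome = list(L = L, recomb_rate = 0.5, n_recomb_paths = 200,
                    start_freq = 0.5, traits = list())),
    model = list(T = 10, selection = FALSE,
                 burn_in = list(min_length = 60, lag = 30, alpha = 0.05,
                                cadence = 10, max_length = 200)))
}

#' Mean fixation time across loci from a tracked run
#'
#' @param model a model run with `track_allele_freq = TRUE`.
#' @return tibble with `n_fixed`, `n_loci`, `mean_fix_time` (non-fixed loci
#'   censored at the last timestep).
#' @export
fixation_times <- function(model) {
  fr <- model$allele_freq
  T_run <- nrow(fr)
  fix_t <- apply(fr, 2, function(f) {
    i <- which(f == 0 | f == 1)
    if (length(i) == 0) NA_integer_ else min(i)
  })
  tibble::tibble(n_fixed = sum(!is.na(fix_t)), n_loci = length(fix_t),
                 mean_fix_time = mean(ifelse(is.na(fix_t), T_run, fix_t)))
}

#' Selective-sweep scenario
#'
#' A 101-locus block with inter-locus recombination `rho` and a monogenic
#' trait at the central locus, absent at the start; a homogeneous selection
#' layer at value 1 makes the 1 allele beneficial everywhere. Introduce
#' copies with [introduce_mutation()] after burn-in and watch mean fitness
#' rise from `1 - phi` toward 1 while diversity erodes around the locus.
#'
#' @param phi selection coefficient.
#' @param rho inter-locus recombination rate.
#' @param T main timesteps.
#' @export
scenario_sweep <- function(phi = 0.3, rho = 0.01, T = 250) {
  side <- 22
  list(
    landscape = list(
      nrows = side, ncols = side,
      layers = list(
        list(name = "habitat", kind = "uniform", value = 1,
             roles = list("carrying_capacity")),
        list(name = "env", kind = "uniform", value = 1,
             roles = list("selection")))),
    species = list(
      # the selection load before the sweep is ~phi, so the per-capita birth
      # rate must exceed it for the population to persist
      r = 0.5, b = 0.5, lambda_offspring = 2, mating_radius = 8,
      repro_age = 1, density_window = 7, K_layer = "habitat", K_factor = 1,
      movement = list(enabled = TRUE, distance_mean = 1,
                      distance_shape = 0.5, surface_layer = NULL),
      dispersal = list(distance_mean = 1, distance_shape = 0.5,
                       surface_layer = NULL),
      genome = list(L = 101, recomb_rate = rho, n_recomb_paths = 1000,
                    start_freq = c(rep(0.5, 50), 0, rep(0.5, 50)),
                    traits = list(list(name = "swept", loci = list(51),
                                       phi = phi, gamma = 1,
                                       selection_layer = "env")))),
    model = list(T = T,
                 burn_in = list(min_length = 80, lag = 40, alpha = 0.05,
                                cadence = 10, max_length = 300)))
}

#' Introduce a beneficial mutation into a running model
#'
#' Sets the 1 allele on one chromatid of `n_copies` randomly chosen
#' individuals at `locus` and refreshes phenotypes.
#'
#' @param model a `gl_model` in the main phase.
#' @param locus locus position.
#' @param n_copies number of carrier chromatids to create.
#' @export
introduce_mutation <- function(model, locus, n_copies = 10) {
  n <- nrow(model$pop$ch1)
  rows <- with_stream(model$streams, "mutation",
                      sample.int(n, min(n_copies, n)))
  model$pop$ch1[rows, locus] <- 1L
  if (length(model$arch$traits) > 0) {
    z <- vapply(model$arch$traits, function(tr) {
      compute_phenotype(model$pop$ch1, model$pop$ch2, tr, model$arch)
    }, numeric(n))
    if (n == 1) z <- matrix(z, 1)
    model$pop$z <- z
  }
  model
}

#' Linear stepping-stone scenario
#'
#' Six habitable islands in a row separated by uninhabitable gaps; neutral
#' loci accumulate genetic structure so that pairwise FST increases with
#' inter-island distance.
#'
#' @param n_islands islands in the chain.
#' @param T main timesteps.
#' @export
scenario_stepping_stone <- function(n_islands = 6, T = 150) {
  island_width <- 8; gap <- 2
  nc <- n_islands * island_width + (n_islands - 1) * gap
  list(
    landscape = list(
      nrows = 12, ncols = nc,
      layers = list(list(name = "islands", kind = "islands",
                         n_islands = n_islands,
                         island_width = island_width, gap = gap,
                         roles = list("carrying_capacity")))),
    species = list(
      r = 0.5, b = 0.3, lambda_offspring = 2, mating_radius = 3,
      repro_age = 1, density_window = 5, K_layer = "islands", K_factor = 2,
      movement = list(enabled = TRUE, distance_mean = 0.7,
                      distance_shape = 0.5, surface_layer = NULL),
      dispersal = list(distance_mean = 0.7, distance_shape = 0.5,
                       surface_layer = NULL),
      genome = list(L = 60, recomb_rate = 0.5, n_recomb_paths = 200,
                    start_freq = 0.5, traits = list())),
    model = list(T = T, selection = FALSE,
                 burn_in = list(min_length = 60, lag = 30, alpha = 0.05,
                                cadence = 10, max_length = 200)))
}

#' Assign individuals of a stepping-stone run to island demes
#'
#' @param model a completed stepping-stone `gl_model`.
#' @param n_islands islands in the chain.
#' @return list of `list(ch1=, ch2=)` genome sets, one per island (ordered
#'   along the chain).
#' @export
island_demes <- function(model, n_islands = 6) {
  island_width <- 8; gap <- 2
  starts <- seq(1, by = island_width + gap, length.out = n_islands)
  isl <- findInterval(model$pop$x, starts - 1)
  isl[isl > n_islands] <- n_islands
  lapply(seq_len(n_islands), function(i) {
    idx <- which(isl == i)
    list(ch1 = model$pop$ch1[idx, , drop = FALSE],
         ch2 = model$pop$ch2[idx, , drop = FALSE])
  })
}

#' Demographic-bottleneck scenario
#'
#' Neutral loci on a uniform landscape; the carrying capacity is multiplied
#' by 0.3 at `t_start` and restored at `t_end` (a 70% reduction for
#' `t_end - t_start` timesteps), elevating the rate of allele-frequency
#' change during the bottleneck.
#'
#' @param t_start,t_end bottleneck timesteps.
#' @param T main timesteps.
#' @export
scenario_bottleneck <- function(t_start = 100, t_end = 150, T = 300) {
  side <- 18
  list(
    landscape = list(nrows = side, ncols = side,
                     layers = list(list(name = "habitat", kind = "uniform",
                                        value = 1,
                                        roles = list("carrying_capacity")))),
    species = list(
      r = 0.5, b = 0.3, lambda_offspring = 2, mating_radius = 6,
      repro_age = 1, density_window = 7, K_layer = "habitat", K_factor = 1,
      movement = list(enabled = TRUE, distance_mean = 1,
                      distance_shape = 0.5, surface_layer = NULL),
      dispersal = list(distance_mean = 1, distance_shape = 0.5,
                       surface_layer = NULL),
      genome = list(L = 100, recomb_rate = 0.5, n_recomb_paths = 500,
                    start_freq = 0.5, traits = list()),
      demographic_changes = list(
        list(kind = "custom", timesteps = as.list(c(t_start, t_end)),
             factors = as.list(c(0.3, 1 / 0.3))))),
    model = list(T = T, selection = FALSE,
                 burn_in = list(min_length = 80, lag = 40, alpha = 0.05,
                                cadence = 10, max_length = 300)))
}

#' Rate of allele-frequency change by epoch
#'
#' Mean absolute per-step allele-frequency change (averaged over loci) within
#' a window of timesteps.
#'
#' @param model a model run with `track_allele_freq = TRUE`.
#' @param from,to timestep window (inclusive).
#' @export
freq_change_rate <- function(model, from, to) {
  fr <- model$allele_freq[from:to, , drop = FALSE]
  mean(abs(diff(fr)))
}
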