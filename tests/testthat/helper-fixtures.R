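# shared fixtures: all generated in code, nothing stored on disk

# tiny architecture: L loci, uniform recombination, optional single trait
tiny_arch <- function(L = 10, rate = 0.5, trait_loci = NULL, phi = 0.05,
                      start_freq = 0.5, ...) {
  traits <- if (is.null(trait_loci)) list() else
    list(gl_trait(trait_loci, phi = phi, layer = "env", name = "t1"))
  gl_genarch(L, recomb_rates = rate, traits = traits,
             start_freq = start_freq, ...)
}

# minimal fast-running model parameters on a uniform landscape
tiny_params <- function(L = 12, T = 5, nrows = 12, ncols = 12, K = 2,
                        selection = FALSE, n_trait_loci = 0) {
  traits <- if (n_trait_loci > 0) {
    list(list(name = "t1", n_loci = n_trait_loci, phi = 0.05,
              selection_layer = "env"))
  } else list()
  list(
    landscape = list(
      nrows = nrows, ncols = ncols,
      layers = list(
        list(name = "habitat", kind = "uniform", value = 1,
             roles = list("carrying_capacity")),
        list(name = "env", kind = "gradient", direction = "x",
             roles = list("selection")))),
    species = list(
      r = 0.5, b = 0.3, lambda_offspring = 2, mating_radius = 4,
      repro_age = 1, density_window = 5, K_layer = "habitat", K_factor = K,
      movement = list(enabled = TRUE, distance_mean = 0.5,
                      distance_shape = 0.5, surface_layer = NULL),
      dispersal = list(distance_mean = 0.5, distance_shape = 0.5,
                       surface_layer = NULL),
      genome = list(L = L, recomb_rate = 0.5, n_recomb_paths = 50,
                    start_freq = 0.5, traits = traits)),
    model = list(T = T, selection = selection,
                 burn_in = list(min_length = 60, lag = 30, alpha = 0.05,
                                cadence = 5, max_length = 200)))
}

quiet_build <- function(params, seed) {
  suppressWarnings(build_model(params, seed))
}
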