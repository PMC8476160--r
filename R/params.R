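#' Annotated parameters file
#'
#' Models are parameterised by a YAML document with `landscape`, `species`
#' (including genome, traits, movement, mating and mortality settings) and
#' `model` sections. Every optional subsystem has an off switch, omitted keys
#' take documented defaults, and unknown keys are rejected with their
#' location. [make_params_file()] emits an informatively annotated template
#' that parses straight back into a runnable model.
#'
#' @name params
NULL

default_layer_params <- function() {
  list(name = "layer_1", kind = "uniform", value = 1.0, direction = "x",
       reverse = FALSE, barrier_cols = NULL, inside = 0.0, outside = 1.0,
       inside_value = 0.5, smooth = 3, n_islands = 6, island_width = 8,
       gap = 2, file = NULL, roles = list(), change = NULL)
}

default_trait_params <- function() {
  list(name = "trait_1", n_loci = 10, loci = NULL, effect_size = NULL,
       phi = 0.05, gamma = 1.0, selection_layer = NULL, mu = 0.0,
       centered = TRUE)
}

default_change_params <- function() {
  list(mode = "interpolated", timesteps = list(), terminal = NULL,
       series = NULL)
}

default_dem_change_params <- function() {
  list(kind = "custom", timesteps = list(), factor = 1.0, factors = NULL,
       band = c(0.5, 2))
}

#' Default parameter document
#'
#' @param n_layers,n_traits how many layer/trait blocks to include.
#' @return nested list of defaults for every parameter.
#' @export
default_params <- function(n_layers = 1, n_traits = 0) {
  layers <- lapply(seq_len(n_layers), function(i) {
    l <- default_layer_params(); l$name <- paste0("layer_", i); l
  })
  traits <- lapply(seq_len(n_traits), function(i) {
    tr <- default_trait_params(); tr$name <- paste0("trait_", i); tr
  })
  list(
    landscape = list(nrows = 20, ncols = 20, layers = layers),
    species = list(
      r = 0.5, b = 0.2, lambda_offspring = 2.0, fixed_offspring = FALSE,
      mating_radius = 5.0, pair_weighting = "uniform", repro_age = 1,
      max_age = NULL, sex_ratio = 0.5, dioecious = FALSE,
      density_window = 5, K_layer = "layer_1", K_factor = 1.0,
      p_min = 0.001, p_max = 0.999,
      movement = list(enabled = TRUE, distance_mean = 0.5,
                      distance_shape = 0.5, surface_layer = NULL,
                      mode = "mixture", kappa = 12.0, approx_len = 1000),
      dispersal = list(distance_mean = 0.5, distance_shape = 0.5,
                       surface_layer = NULL, mode = "mixture", kappa = 12.0,
                       approx_len = 1000),
      genome = list(L = 100, recomb_rate = 0.5, n_recomb_paths = 1000,
                    use_paths = TRUE, dominance = 0, mu_neutral = 0.0,
                    mu_deleterious = 0.0, prop_deleterious = 0.0,
                    start_freq = 0.5, traits = traits),
      demographic_changes = list()
    ),
    model = list(T = 100, selection = TRUE, record_pedigree = FALSE,
                 track_zone = NULL, memory_warn_elements = 2e8,
                 burn_in = list(min_length = 100, lag = 50, alpha = 0.05,
                                cadence = 10, max_length = 2000))
  )
}

# keys whose children are free-form (lists of blocks validated separately)
.block_list_keys <- c("layers", "traits", "demographic_changes")

validate_against <- function(given, defaults, path = "") {
  if (!is.list(given)) return(invisible(TRUE))
  for (key in names(given)) {
    here <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      stop("unknown parameter key: '", here, "'", call. = FALSE)
    }
    if (key %in% .block_list_keys) {
      blk_default <- switch(key,
                            layers = default_layer_params(),
                            traits = default_trait_params(),
                            demographic_changes = default_dem_change_params())
      for (i in seq_along(given[[key]])) {
        validate_against(given[[key]][[i]], blk_default,
                         paste0(here, "[", i, "]"))
      }
    } else if (key == "change") {
      if (!is.null(given[[key]])) {
        validate_against(given[[key]], default_change_params(), here)
      }
    } else if (is.list(given[[key]]) && is.list(defaults[[key]]) &&
               !is.null(names(defaults[[key]]))) {
      validate_against(given[[key]], defaults[[key]], here)
    }
  }
  invisible(TRUE)
}

merge_defaults <- function(given, defaults) {
  if (is.null(given)) return(defaults)
  if (!is.list(given) || !is.list(defaults) || is.null(names(defaults))) {
    return(given)
  }
  out <- defaults
  for (key in names(given)) {
    if (key %in% .block_list_keys) {
      blk_default <- switch(key,
                            layers = default_layer_params(),
                            traits = default_trait_params(),
                            demographic_changes = default_dem_change_params())
      out[[key]] <- lapply(given[[key]], merge_defaults, defaults = blk_default)
    } else if (key == "change") {
      out[[key]] <- if (is.null(given[[key]])) NULL else
        merge_defaults(given[[key]], default_change_params())
    } else if (is.list(given[[key]]) && is.list(defaults[[key]]) &&
               !is.null(names(defaults[[key]]))) {
      out[[key]] <- merge_defaults(given[[key]], defaults[[key]])
    } else {
      out[[key]] <- given[[key]]
    }
  }
  out
}

#' Validate a parameters document
#'
#' Rejects unknown keys (naming their location) and fills defaults for every
#' omitted optional value.
#'
#' @param params nested list (e.g. from [read_params()]).
#' @return the completed parameter list.
#' @export
validate_params <- function(params) {
  validate_against(params, default_params())
  full <- merge_defaults(params, default_params(n_layers = 0))
  if (length(full$landscape$layers) < 1) {
    stop("a landscape needs at least one layer")
  }
  for (tr in full$species$genome$traits) {
    if (!is.null(tr$phi) && is.numeric(tr$phi) && (tr$phi < 0 || tr$phi > 1)) {
      stop("trait '", tr$name, "': phi must lie in [0, 1]")
    }
    if (tr$gamma <= 0) stop("trait '", tr$name, "': gamma must be > 0")
  }
  full
}

#' Read a parameters file
#'
#' @param path YAML parameters file.
#' @return validated, default-completed parameter list.
#' @export
read_params <- function(path) {
  params <- yaml::read_yaml(path)
  validate_params(params)
}

#' Write an annotated parameters template
#'
#' Emits a commented YAML template with `n_layers` layer blocks and
#' `n_traits` trait blocks; the emitted file parses back into a buildable
#' model unchanged.
#'
#' @param path output path.
#' @param n_layers,n_traits block counts.
#' @export
make_params_file <- function(path, n_layers = 1, n_traits = 0) {
  p <- default_params(n_layers, n_traits)
  header <- c(
    "# landgen parameters file",
    "# Every parameter is optional: omitted keys take the defaults shown",
    "# here. Unknown keys are rejected. Subsystems (movement surfaces,",
    "# selection, change events, pedigree recording) all have off switches.",
    "")
  ann <- c(
    "# landscape: stack of equally dimensioned raster layers.",
    "#   layer kinds: uniform (value), gradient (direction, reverse),",
    "#   barrier (barrier_cols, inside, outside), opposed_gradients",
    "#   (barrier_cols, inside_value), random (smooth), file (file = path).",
    "#   roles: movement, dispersal, carrying_capacity, selection.",
    "#   change: {mode: interpolated, timesteps: [...], terminal: <layer",
    "#   spec>} or {mode: custom, timesteps: [...], series: [<layer spec>]}.",
    "# species: r = logistic growth rate per timestep; b = per-pair mating",
    "#   probability; lambda_offspring = mean offspring per mating event;",
    "#   mating_radius in cell widths; pair_weighting uniform |",
    "#   inverse_distance | nearest; density_window = side (cells) of the",
    "#   density-estimation window; K_layer x K_factor gives per-cell",
    "#   carrying capacity; p_min/p_max clamp the density mortality.",
    "#   movement/dispersal: Wald distance (mean, shape); surface_layer",
    "#   names a resistance layer (null = isotropic); kappa = von Mises",
    "#   concentration; approx_len = stored directions per cell.",
    "#   genome: L diallelic loci; recomb_rate scalar or per-gap list in",
    "#   [0, 0.5]; n_recomb_paths sets the recombination-path deck (1/R is",
    "#   the finest representable rate difference); use_paths: false uses",
    "#   on-the-fly recombination (homogeneous maps only); mutation rates",
    "#   are per locus per gamete; traits list loci counts or explicit",
    "#   positions, selection coefficient phi, curvature gamma and the",
    "#   selection layer tracked.",
    "# model: T main timesteps; burn_in block controls the stationarity",
    "#   battery (lag/alpha/cadence); track_zone = [x0, x1] tracks barrier",
    "#   crossings of that column range.",
    "")
  body <- yaml::as.yaml(p, indent.mapping.sequence = TRUE)
  writeLines(c(header, ann, body), path)
  invisible(path)
}
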