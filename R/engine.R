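#' Model assembly and the main timestep loop
#'
#' A model couples one species to a landscape. A run starts with a pre-genomic
#' burn-in (movement + mating + density-dependent mortality, no genomes, no
#' selection) that ends when the stationarity battery passes; genomes are then
#' randomly assigned from the genomic architecture -- the main phase starts
#' with no pedigree and no spatial genetic structure -- and each main timestep
#' applies, in order: movement (optional), mating (requisite), mortality
#' (density dependence plus optional selection), and change events, which take
#' effect at the ends of their scheduled timesteps. A single master seed fully
#' determines a run.
#'
#' @name engine
NULL

build_layer_from_spec <- function(spec, dims) {
  vals <- switch(spec$kind,
    uniform = gl_raster(matrix(spec$value, dims[1], dims[2])),
    gradient = make_gradient_raster(dims, spec$direction,
                                    isTRUE(spec$reverse)),
    barrier = make_barrier_raster(dims,
                                  seq(spec$barrier_cols[[1]],
                                      spec$barrier_cols[[2]]),
                                  spec$inside, spec$outside),
    opposed_gradients = make_opposed_gradients_raster(
      dims, seq(spec$barrier_cols[[1]], spec$barrier_cols[[2]]),
      spec$inside_value),
    islands = make_islands_raster(dims, spec$n_islands, spec$island_width,
                                  spec$gap, spec$value),
    random = make_random_raster(dims, spec$smooth),
    file = read_raster_tiff(spec$file)$raster,
    stop("unknown layer kind: ", spec$kind))
  change <- NULL
  if (!is.null(spec$change)) {
    ch <- spec$change
    if (identical(ch$mode, "interpolated")) {
      term <- build_layer_from_spec(merge_defaults(ch$terminal,
                                                   default_layer_params()),
                                    dims)$raster
      change <- env_change_event("interpolated",
                                 unlist(ch$timesteps), terminal = term)
    } else {
      series <- lapply(ch$series, function(s) {
        build_layer_from_spec(merge_defaults(s, default_layer_params()),
                              dims)$raster
      })
      change <- env_change_event("custom", unlist(ch$timesteps),
                                 series = series)
    }
  }
  gl_layer(vals, name = spec$name, roles = unlist(spec$roles), change = change)
}

#' Demographic change-event factor schedule
#'
#' Expands an event into per-timestep multiplicative factors on the carrying
#' capacity raster: exponential events repeat a fixed factor, cyclical events
#' alternate factor and 1/factor, random events draw log-uniform factors from
#' a band, and custom events list explicit factors.
#'
#' @param event list with `kind`, `timesteps`, and `factor`/`factors`/`band`.
#' @return tibble with `timestep` and `factor`.
#' @export
dem_change_schedule <- function(event) {
  ts <- as.integer(unlist(event$timesteps))
  if (length(ts) == 0) return(tibble::tibble(timestep = integer(),
                                             factor = numeric()))
  if (any(diff(ts) <= 0)) stop("change timesteps must be strictly increasing")
  f <- switch(event$kind,
    exponential = rep(event$factor, length(ts)),
    cyclical = rep_len(c(event$factor, 1 / event$factor), length(ts)),
    random = exp(stats::runif(length(ts), log(event$band[[1]]),
                              log(event$band[[2]]))),
    custom = as.numeric(unlist(event$factors)),
    stop("unknown demographic change kind: ", event$kind))
  if (length(f) != length(ts)) stop("need one factor per timestep")
  if (any(f <= 0)) stop("factors must be > 0")
  tibble::tibble(timestep = ts, factor = f)
}

#' Carrying-capacity raster after demographic change events at time t
#'
#' Multiplies K by the cumulative product of all event factors scheduled at
#' timesteps <= t.
#'
#' @param K the baseline carrying-capacity raster.
#' @param schedule tibble from [dem_change_schedule()] (possibly several
#'   events row-bound).
#' @param t timestep.
#' @export
apply_dem_change <- function(K, schedule, t) {
  if (nrow(schedule) == 0) return(K)
  f <- prod(schedule$factor[schedule$timestep <= t])
  K * f
}

#' Build a model from parameters and a master seed
#'
#' Precomputes everything random that is fixed for the run: the landscape's
#' random layers, trait locus assignments, the recombination-path deck, the
#' movement and dispersal surfaces (including one surface per scheduled step
#' of any change event on their source layers), demographic change factors,
#' and the founding population. The same parameters and seed always produce
#' bitwise-identical precomputed structures.
#'
#' @param params parameter list (see [read_params()] / [default_params()]).
#' @param seed master seed.
#' @return a `gl_model`.
#' @export
build_model <- function(params, seed) {
  params <- validate_params(params)
  streams <- rng_streams(seed)
  dims <- c(params$landscape$nrows, params$landscape$ncols)

  layers <- with_stream(streams, "landscape", {
    lapply(params$landscape$layers, build_layer_from_spec, dims = dims)
  })
  landscape <- gl_landscape(layers)

  sp <- params$species
  gp <- sp$genome
  L <- gp$L
  arch <- with_stream(streams, "genome", {
    taken <- integer(0)
    traits <- vector("list", length(gp$traits))
    for (ti in seq_along(gp$traits)) {
      tp <- gp$traits[[ti]]
      if (is.null(tp$selection_layer) ||
          !tp$selection_layer %in% names(landscape$layers)) {
        stop("trait '", tp$name, "' must name an existing selection_layer")
      }
      loci <- if (!is.null(tp$loci)) as.integer(unlist(tp$loci)) else {
        pool <- setdiff(seq_len(L), taken)
        sort(sample(pool, tp$n_loci))
      }
      taken <- c(taken, loci)
      es <- if (is.null(tp$effect_size)) NULL else
        rep(tp$effect_size, length(loci))
      traits[[ti]] <- gl_trait(loci, effect_sizes = es, phi = tp$phi,
                               gamma = tp$gamma, layer = tp$selection_layer,
                               mu = tp$mu, centered = isTRUE(tp$centered),
                               name = tp$name)
    }
    rr <- unlist(gp$recomb_rate)
    gl_genarch(L, recomb_rates = rr, dominance = gp$dominance,
               mu_neutral = gp$mu_neutral,
               mu_deleterious = gp$mu_deleterious, traits = traits,
               start_freq = unlist(gp$start_freq),
               prop_deleterious = gp$prop_deleterious)
  })

  paths <- NULL
  if (isTRUE(gp$use_paths)) {
    paths <- with_stream(streams, "genome",
                         generate_recomb_paths(arch, gp$n_recomb_paths))
  } else if (length(unique(arch$recomb_rates)) > 1) {
    stop("on-the-fly recombination requires a homogeneous recombination map")
  }

  build_surface_series <- function(mv) {
    if (is.null(mv$surface_layer)) return(NULL)
    lyr <- landscape$layers[[mv$surface_layer]]
    if (is.null(lyr)) stop("unknown surface layer: ", mv$surface_layer)
    mk <- function(r) build_movement_surface(r, kappa = mv$kappa,
                                             M = mv$approx_len,
                                             mode = mv$mode)
    out <- list(timesteps = 0L, surfaces = list(mk(lyr$raster)))
    if (!is.null(lyr$schedule)) {
      for (s in lyr$schedule) {
        out$timesteps <- c(out$timesteps, s$timestep)
        out$surfaces <- c(out$surfaces, list(mk(s$raster)))
      }
    }
    out
  }
  move_surf <- with_stream(streams, "movement",
                           build_surface_series(sp$movement))
  disp_surf <- with_stream(streams, "movement",
                           build_surface_series(sp$dispersal))

  n_surf_elem <- function(s) if (is.null(s)) 0 else
    sum(vapply(s$surfaces, function(x) length(x$cols), numeric(1)))
  precomp <- (if (is.null(paths)) 0 else length(paths$paths)) +
    n_surf_elem(move_surf) + n_surf_elem(disp_surf)
  if (precomp > params$model$memory_warn_elements) {
    warning(sprintf(paste0("precomputed structures hold %.3g elements ",
                           "(paths + movement surfaces); consider fewer ",
                           "paths, a shorter approximation column, or fewer ",
                           "change steps"), precomp))
  }

  dem_sched <- with_stream(streams, "landscape", {
    if (length(sp$demographic_changes) == 0) {
      tibble::tibble(timestep = integer(), factor = numeric())
    } else {
      dplyr::arrange(dplyr::bind_rows(lapply(sp$demographic_changes,
                                             dem_change_schedule)),
                     .data$timestep)
    }
  })

  species <- gl_species_params(
    r = sp$r, b = sp$b, lambda_offspring = sp$lambda_offspring,
    fixed_offspring = isTRUE(sp$fixed_offspring),
    mating_radius = sp$mating_radius, pair_weighting = sp$pair_weighting,
    repro_age = sp$repro_age, max_age = sp$max_age, sex_ratio = sp$sex_ratio,
    dioecious = isTRUE(sp$dioecious), density_window = sp$density_window,
    K_layer = sp$K_layer, K_factor = sp$K_factor,
    p_min = sp$p_min, p_max = sp$p_max)

  K0 <- layer_at_time(landscape$layers[[species$K_layer]], 0) *
    species$K_factor
  n0 <- max(2L, round(sum(K0)))
  pop <- with_stream(streams, "burnin", {
    list(id = seq_len(n0),
         x = stats::runif(n0, 0, dims[2]),
         y = stats::runif(n0, 0, dims[1]),
         sex = stats::rbinom(n0, 1L, species$sex_ratio),
         age = rep(as.integer(species$repro_age), n0),
         ch1 = NULL, ch2 = NULL, z = NULL)
  })

  pedigree <- new.env(parent = emptyenv())
  pedigree$individuals <- list()
  pedigree$parentage <- list()
  pedigree$gametes <- list()

  zone <- if (is.null(params$model$track_zone)) NULL else
    as.numeric(unlist(params$model$track_zone))
  side <- if (is.null(zone)) NULL else zone_side(pop$x, zone)

  structure(list(
    params = params, species = species, arch = arch, paths = paths,
    use_paths = isTRUE(gp$use_paths),
    landscape = landscape, move_surf = move_surf, disp_surf = disp_surf,
    dem_sched = dem_sched, streams = streams, seed = seed,
    pop = pop, t = 0L, phase = "burnin", next_id = n0 + 1L,
    pedigree = pedigree, record_pedigree = isTRUE(params$model$record_pedigree),
    zone = zone, side = side, crossings = integer(0),
    logs = list(), burnin_state = NULL, status = "built"),
    class = "gl_model")
}

#' @export
print.gl_model <- function(x, ...) {
  cat(sprintf("<gl_model t=%d phase=%s N=%d status=%s>\n",
              x$t, x$phase, length(x$pop$x), x$status))
  invisible(x)
}

zone_side <- function(x, zone) {
  ifelse(x < zone[1], -1L, ifelse(x > zone[2], 1L, 0L))
}

current_surface <- function(series, t) {
  if (is.null(series)) return(NULL)
  series$surfaces[[findInterval(t, series$timesteps)]]
}

current_K <- function(model) {
  K <- layer_at_time(model$landscape$layers[[model$species$K_layer]],
                     model$t) * model$species$K_factor
  apply_dem_change(K, model$dem_sched, model$t)
}

# omega and |e - z| matrices (individuals x traits) at the current timestep
trait_fitness_matrix <- function(model) {
  traits <- model$arch$traits
  n <- length(model$pop$x)
  if (length(traits) == 0 || is.null(model$pop$z)) {
    return(list(omega = NULL, mismatch = NULL))
  }
  cc <- coords_to_cell(model$pop$x, model$pop$y, model$landscape$dims)
  omega <- matrix(1, n, length(traits))
  mism <- matrix(0, n, length(traits))
  for (p in seq_along(traits)) {
    tr <- traits[[p]]
    e_raster <- layer_at_time(model$landscape$layers[[tr$layer]], model$t)
    e <- e_raster[cc$cell]
    phi <- if (is.character(tr$phi)) {
      layer_at_time(model$landscape$layers[[tr$phi]], model$t)[cc$cell]
    } else tr$phi
    z <- model$pop$z[, p]
    mism[, p] <- abs(e - z)
    omega[, p] <- fitness_trait(z, e, phi, tr$gamma)
  }
  list(omega = omega, mismatch = mism)
}

subset_pop <- function(pop, keep) {
  out <- list(id = pop$id[keep], x = pop$x[keep], y = pop$y[keep],
              sex = pop$sex[keep], age = pop$age[keep],
              ch1 = if (is.null(pop$ch1)) NULL else
                pop$ch1[keep, , drop = FALSE],
              ch2 = if (is.null(pop$ch2)) NULL else
                pop$ch2[keep, , drop = FALSE],
              z = if (is.null(pop$z)) NULL else pop$z[keep, , drop = FALSE])
  out
}

#' Advance a model one timestep
#'
#' Applies, in order: movement (if enabled), mating (mate search, Bernoulli
#' mating decisions, gamete formation with recombination and mutation,
#' offspring dispersal from the parental midpoint), mortality (logistic
#' density dependence times selection on all traits), and change events
#' (which take effect for subsequent timesteps). Newborns do not move in
#' their birth timestep.
#'
#' @param model a `gl_model`.
#' @return the advanced model.
#' @export
step_model <- function(model) {
  sp <- model$species
  pop <- model$pop
  dims <- model$landscape$dims
  burnin <- identical(model$phase, "burnin")
  crossings_step <- 0L

  # --- movement ---------------------------------------------------------
  if (isTRUE(model$params$species$movement$enabled) && length(pop$x) > 0) {
    mv <- model$params$species$movement
    surf <- current_surface(model$move_surf, model$t)
    new_xy <- with_stream(model$streams, "movement",
      move_positions(pop$x, pop$y, surf,
                     list(mean = mv$distance_mean, shape = mv$distance_shape),
                     dims))
    pop$x <- new_xy$x; pop$y <- new_xy$y
    if (!is.null(model$zone)) {
      s_new <- zone_side(pop$x, model$zone)
      prev <- model$side
      crossed <- !is.na(prev) & prev != 0L & s_new == -prev
      crossings_step <- crossings_step + sum(crossed)
      model$side <- ifelse(s_new != 0L, s_new, prev)
    }
  }

  # --- mating -----------------------------------------------------------
  births <- 0L
  eligible <- pop$age >= sp$repro_age
  pairs <- with_stream(model$streams, "mating", {
    p <- find_mating_pairs(pop$x, pop$y, eligible, pop$sex,
                           radius = sp$mating_radius,
                           weighting = sp$pair_weighting,
                           dioecious = sp$dioecious)
    p <- decide_matings(p, sp$b)
    p
  })
  if (nrow(pairs) > 0) {
    noff <- with_stream(model$streams, "mating",
                        draw_n_offspring(nrow(pairs), sp$lambda_offspring,
                                         sp$fixed_offspring))
    G <- sum(noff)
    if (G > 0) {
      pa <- rep(pairs[, 1], noff); pb <- rep(pairs[, 2], noff)
      mutrec <- NULL
      gam_a <- gam_b <- NULL
      patha_idx <- pathb_idx <- NULL
      if (!burnin) {
        if (model$use_paths) {
          idx <- with_stream(model$streams, "genome",
                             draw_path_indices(model$paths, 2L * G))
          patha_idx <- idx[seq_len(G)]
          pathb_idx <- idx[G + seq_len(G)]
          gam_a <- make_gametes(pop$ch1, pop$ch2, pa,
                                model$paths$paths[patha_idx, , drop = FALSE])
          gam_b <- make_gametes(pop$ch1, pop$ch2, pb,
                                model$paths$paths[pathb_idx, , drop = FALSE])
        } else {
          gam_a <- with_stream(model$streams, "genome",
            recombine_on_the_fly(pop$ch1, pop$ch2, pa,
                                 model$arch$recomb_rates[1]))
          gam_b <- with_stream(model$streams, "genome",
            recombine_on_the_fly(pop$ch1, pop$ch2, pb,
                                 model$arch$recomb_rates[1]))
        }
        mut <- with_stream(model$streams, "mutation",
                           apply_mutations(rbind(gam_a, gam_b), model$arch))
        model$arch <- mut$arch
        gam_a <- mut$gametes[seq_len(G), , drop = FALSE]
        gam_b <- mut$gametes[G + seq_len(G), , drop = FALSE]
        mutrec <- mut$records
      }
      dv <- model$params$species$dispersal
      dsurf <- current_surface(model$disp_surf, model$t)
      off_xy <- with_stream(model$streams, "mating",
        disperse_positions(pop$x[pa], pop$y[pa], pop$x[pb], pop$y[pb],
                           dsurf,
                           list(mean = dv$distance_mean,
                                shape = dv$distance_shape), dims))
      off_sex <- with_stream(model$streams, "mating",
                             stats::rbinom(G, 1L, sp$sex_ratio))
      ids <- model$next_id:(model$next_id + G - 1L)
      model$next_id <- model$next_id + G

      # the spatial pedigree exists only for the genomic (main) phase: the
      # post-burn-in population are its founders
      if (model$record_pedigree && !burnin) {
        ped <- model$pedigree
        ped$individuals[[length(ped$individuals) + 1L]] <- tibble::tibble(
          id = ids, birth_t = model$t + 1L, death_t = NA_integer_,
          x = off_xy$x, y = off_xy$y, sex = off_sex)
        ped$parentage[[length(ped$parentage) + 1L]] <- tibble::tibble(
          child = rep(ids, 2L), parent = c(pop$id[pa], pop$id[pb]))
        if (!burnin) {
          switch_pos <- function(pm) {
            apply(pm, 1, function(p) which(diff(p) != 0L))
          }
          pma <- if (model$use_paths)
            model$paths$paths[patha_idx, , drop = FALSE] else
              reconstruct_path(gam_a, pop$ch1[pa, , drop = FALSE],
                               pop$ch2[pa, , drop = FALSE])
          pmb <- if (model$use_paths)
            model$paths$paths[pathb_idx, , drop = FALSE] else
              reconstruct_path(gam_b, pop$ch1[pb, , drop = FALSE],
                               pop$ch2[pb, , drop = FALSE])
          ped$gametes[[length(ped$gametes) + 1L]] <- tibble::tibble(
            child = rep(ids, 2L),
            parent = c(pop$id[pa], pop$id[pb]),
            chromatid = rep(c(1L, 2L), each = G),
            start = c(pma[, 1], pmb[, 1]),
            switches = c(lapply(seq_len(G), function(i) {
              which(diff(pma[i, ]) != 0L)
            }), lapply(seq_len(G), function(i) {
              which(diff(pmb[i, ]) != 0L)
            })))
        }
      }

      z_off <- NULL
      if (!burnin && length(model$arch$traits) > 0) {
        z_off <- vapply(model$arch$traits, function(tr) {
          compute_phenotype(gam_a, gam_b, tr, model$arch)
        }, numeric(G))
        if (G == 1) z_off <- matrix(z_off, 1)
      }
      if (!is.null(model$zone)) {
        mid_side <- zone_side((pop$x[pa] + pop$x[pb]) / 2, model$zone)
        off_side <- zone_side(off_xy$x, model$zone)
        crossings_step <- crossings_step +
          sum(mid_side != 0L & off_side == -mid_side)
        model$side <- c(model$side, ifelse(off_side != 0L, off_side,
                                           mid_side))
      }
      pop <- list(
        id = c(pop$id, ids), x = c(pop$x, off_xy$x), y = c(pop$y, off_xy$y),
        sex = c(pop$sex, off_sex), age = c(pop$age, rep(0L, G)),
        ch1 = if (burnin) NULL else rbind(pop$ch1, gam_a),
        ch2 = if (burnin) NULL else rbind(pop$ch2, gam_b),
        z = if (burnin || is.null(pop$z)) NULL else rbind(pop$z, z_off))
      births <- G
    }
  }

  # --- mortality --------------------------------------------------------
  n <- length(pop$x)
  deaths <- 0L
  mean_fit <- NA_real_; mean_mism <- NA_real_
  if (n > 0) {
    dens <- estimate_density(pop$x, pop$y, dims, sp$density_window)
    K <- current_K(model)
    cc <- coords_to_cell(pop$x, pop$y, dims)
    beta <- sp$b * sp$lambda_offspring / 2
    p_dxy <- p_death_density(dens[cc$cell], K[cc$cell], sp$r, beta,
                             sp$p_min, sp$p_max)
    model$pop <- pop
    tf <- if (!burnin && isTRUE(model$params$model$selection)) {
      trait_fitness_matrix(model)
    } else list(omega = NULL, mismatch = NULL)
    del <- if (!burnin && length(model$arch$delet_s) > 0) {
      deleterious_factors(pop$ch1, pop$ch2, model$arch)
    } else NULL
    p_tot <- p_death_total(p_dxy, tf$omega, del)
    survive <- with_stream(model$streams, "mortality",
                           apply_mortality(p_tot, pop$age, sp$max_age))
    deaths <- sum(!survive)
    if (model$record_pedigree && !burnin && deaths > 0) {
      ped <- model$pedigree
      ped$individuals[[length(ped$individuals) + 1L]] <- tibble::tibble(
        id = pop$id[!survive], birth_t = NA_integer_,
        death_t = model$t + 1L,
        x = NA_real_, y = NA_real_, sex = NA_integer_)
    }
    if (!is.null(tf$omega)) {
      w <- apply(tf$omega, 1, prod)
      if (!is.null(del)) w <- w * del
      mean_fit <- mean(w[survive])
      mean_mism <- mean(rowMeans(tf$mismatch)[survive])
    } else if (!burnin) {
      mean_fit <- 1
    }
    pop <- subset_pop(pop, survive)
    if (!is.null(model$zone)) model$side <- model$side[survive]
  }

  # --- bookkeeping ------------------------------------------------------
  pop$age <- pop$age + 1L
  model$pop <- pop
  model$t <- model$t + 1L
  model$crossings <- c(model$crossings, crossings_step)
  model$logs[[length(model$logs) + 1L]] <- tibble::tibble(
    phase = model$phase, t = model$t, N = length(pop$x),
    births = births, deaths = deaths, mean_fitness = mean_fit,
    mean_mismatch = mean_mism, crossings = crossings_step)
  model
}

# recover the chromatid-selection path implied by a gamete (used only for
# pedigree recording under on-the-fly recombination; ambiguous at
# homozygous loci, resolved toward chromatid 1)
reconstruct_path <- function(gam, ch1rows, ch2rows) {
  p <- matrix(0L, nrow(gam), ncol(gam))
  p[gam == ch2rows & gam != ch1rows] <- 1L
  p
}

#' Run a model: burn-in, genome assignment, main phase
#'
#' Burn-in steps continue until [burnin_complete()] passes (tested every
#' `cadence` steps past `min_length`) or `max_length` is hit (with a
#' warning). Each individual then receives a randomly assigned genome and the
#' main phase runs `T` timesteps, logging population size, births, deaths,
#' mean fitness, and mean phenotype-environment mismatch. Extinction ends the
#' run early with status `"extinct"`.
#'
#' @param model a `gl_model` from [build_model()].
#' @param T main timesteps (default from the params file).
#' @param track_allele_freq record the per-locus pooled allele frequency each
#'   main timestep (matrix in `model$allele_freq`).
#' @return the completed model; per-timestep logs via [run_log()].
#' @export
run_model <- function(model, T = NULL, track_allele_freq = FALSE) {
  if (is.null(T)) T <- model$params$model$T
  bp <- model$params$model$burn_in

  if (identical(model$phase, "burnin")) {
    state <- list(popsize = numeric(0), spatial_mean = numeric(0),
                  spatial_sd = numeric(0), min_length = bp$min_length,
                  lag = bp$lag, alpha = bp$alpha)
    counts_prev <- cell_counts(model$pop$x, model$pop$y,
                               model$landscape$dims)
    converged <- FALSE
    for (i in seq_len(bp$max_length)) {
      model <- step_model(model)
      if (length(model$pop$x) == 0) {
        model$status <- "extinct"
        model <- finalize_logs(model)
        return(model)
      }
      counts_t <- cell_counts(model$pop$x, model$pop$y,
                              model$landscape$dims)
      ss <- spatial_diff_stats(counts_t, counts_prev)
      counts_prev <- counts_t
      state$popsize <- c(state$popsize, length(model$pop$x))
      state$spatial_mean <- c(state$spatial_mean, ss[1])
      state$spatial_sd <- c(state$spatial_sd, ss[2])
      if (i >= bp$min_length && i %% bp$cadence == 0) {
        done <- with_stream(model$streams, "burnin", burnin_complete(state))
        if (done) { converged <- TRUE; break }
      }
    }
    if (!converged) {
      warning("burn-in reached max_length without passing the ",
              "stationarity battery; proceeding")
    }
    model$burnin_state <- state
    model$burnin_steps <- length(state$popsize)

    # genomes are assigned only now: the main phase starts with no pedigree
    n <- length(model$pop$x)
    g <- with_stream(model$streams, "genome",
                     init_genomes(model$arch, n))
    model$pop$ch1 <- g$ch1; model$pop$ch2 <- g$ch2
    if (length(model$arch$traits) > 0) {
      z <- vapply(model$arch$traits, function(tr) {
        compute_phenotype(g$ch1, g$ch2, tr, model$arch)
      }, numeric(n))
      if (n == 1) z <- matrix(z, 1)
      model$pop$z <- z
    }
    if (model$record_pedigree) {
      ped <- model$pedigree
      ped$individuals[[length(ped$individuals) + 1L]] <- tibble::tibble(
        id = model$pop$id, birth_t = 0L, death_t = NA_integer_,
        x = model$pop$x, y = model$pop$y, sex = model$pop$sex)
    }
    model$phase <- "main"
    model$t <- 0L
    model$crossings <- integer(0)
    if (!is.null(model$zone)) model$side <- zone_side(model$pop$x, model$zone)
  }

  freq <- if (track_allele_freq) vector("list", T) else NULL
  for (i in seq_len(T)) {
    model <- step_model(model)
    if (track_allele_freq) {
      freq[[i]] <- colMeans((model$pop$ch1 + model$pop$ch2) / 2)
    }
    if (length(model$pop$x) == 0) {
      model$status <- "extinct"
      break
    }
  }
  if (track_allele_freq) {
    model$allele_freq <- do.call(rbind, freq[!vapply(freq, is.null,
                                                     logical(1))])
  }
  if (!identical(model$status, "extinct")) model$status <- "completed"
  finalize_logs(model)
}

finalize_logs <- function(model) {
  model$log <- if (length(model$logs)) dplyr::bind_rows(model$logs) else
    tibble::tibble(phase = character(), t = integer(), N = integer(),
                   births = integer(), deaths = integer(),
                   mean_fitness = numeric(), mean_mismatch = numeric(),
                   crossings = integer())
  model
}

#' Per-timestep run log
#'
#' @param model a run `gl_model`.
#' @param phase `"main"` (default), `"burnin"`, or `"all"`.
#' @return tibble with timestep, N, births, deaths, mean fitness, mean
#'   phenotype-environment mismatch, and barrier crossings.
#' @export
run_log <- function(model, phase = c("main", "burnin", "all")) {
  phase <- match.arg(phase)
  model <- finalize_logs(model)
  lg <- model$log
  if (phase != "all") lg <- dplyr::filter(lg, .data$phase == .env$phase)
  lg
}

#' Individual table with locations, environmental values, and phenotypes
#'
#' @param model a `gl_model`.
#' @return tibble: one row per live individual with id, x, y, sex, age, the
#'   value of every landscape layer at its location, and its phenotypes.
#' @export
individuals_table <- function(model) {
  pop <- model$pop
  out <- tibble::tibble(id = pop$id, x = pop$x, y = pop$y, sex = pop$sex,
                        age = pop$age, timestep = model$t)
  cc <- coords_to_cell(pop$x, pop$y, model$landscape$dims)
  for (l in model$landscape$layers) {
    out[[paste0("env_", l$name)]] <- layer_at_time(l, model$t)[cc$cell]
  }
  if (!is.null(pop$z)) {
    for (p in seq_along(model$arch$traits)) {
      out[[paste0("z_", model$arch$traits[[p]]$name)]] <- pop$z[, p]
    }
  }
  out
}

#' Pedigree tables recorded during a run
#'
#' @param model a `gl_model` run with `record_pedigree = TRUE`.
#' @return list of tibbles: `individuals` (birth/death records), `parentage`
#'   (child, parent pairs), `gametes` (per-gamete recombination start
#'   chromatid and switch positions).
#' @export
pedigree_tables <- function(model) {
  ped <- model$pedigree
  ind <- if (length(ped$individuals)) dplyr::bind_rows(ped$individuals) else
    tibble::tibble(id = integer(), birth_t = integer(), death_t = integer(),
                   x = numeric(), y = numeric(), sex = integer())
  births <- dplyr::filter(ind, !is.na(.data$birth_t))
  deaths <- dplyr::filter(ind, !is.na(.data$death_t))
  individuals <- dplyr::left_join(
    births, dplyr::select(deaths, "id", "death_t"), by = "id",
    suffix = c("", ".d"))
  if ("death_t.d" %in% names(individuals)) {
    individuals$death_t <- individuals$death_t.d
    individuals$death_t.d <- NULL
  }
  list(individuals = individuals,
       parentage = if (length(ped$parentage))
         dplyr::bind_rows(ped$parentage) else
           tibble::tibble(child = integer(), parent = integer()),
       gametes = if (length(ped$gametes)) dplyr::bind_rows(ped$gametes) else
         tibble::tibble(child = integer(), parent = integer(),
                        chromatid = integer(), start = integer(),
                        switches = list()))
}
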