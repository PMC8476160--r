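#' Landscape rasters, layers, and environmental change events
#'
#' A landscape is an ordered stack of equally dimensioned raster layers. Each
#' layer can serve one or more roles: a movement- or dispersal-resistance
#' surface, the carrying-capacity field of the logistic mortality model, or
#' the selection layer an adaptive trait tracks. Environmental layers are
#' dimensionless and live in [0, 1].
#'
#' Continuous coordinates follow the cell convention: cell (row i, col j),
#' 1-based, spans x in [j-1, j) and y in [i-1, i); an individual's cell is the
#' floor of its coordinates plus one. x runs along columns, y along rows.
#'
#' @name landscape
NULL

#' Create a raster
#'
#' @param values numeric matrix (nrows x ncols); all values must be finite.
#' @return a `gl_raster`: the matrix with a class attribute.
#' @export
gl_raster <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite raster cells at (row, col): ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  }
  structure(values, class = c("gl_raster", "matrix", "array"))
}

#' Min-max rescale a raster to [0, 1]
#'
#' Environmental layers must lie in [0, 1] to act as selection surfaces.
#' A constant raster maps to all 0.5 (a deliberately homogeneous landscape
#' rather than an error).
#'
#' @param raster a `gl_raster` or numeric matrix.
#' @return a `gl_raster` with values in [0, 1].
#' @export
rescale_unit <- function(raster) {
  r <- gl_raster(raster)
  rng <- range(r)
  if (diff(rng) == 0) {
    r[] <- 0.5
  } else {
    r[] <- (r - rng[1]) / diff(rng)
  }
  r
}

#' Environmental change event
#'
#' Either a terminal raster reached by cell-wise linear interpolation over the
#' scheduled timesteps (`mode = "interpolated"`), or an explicit series of
#' rasters labeled by timestep (`mode = "custom"`). Changes apply at the ends
#' of the scheduled timesteps.
#'
#' @param mode `"interpolated"` or `"custom"`.
#' @param timesteps strictly increasing integer timesteps.
#' @param terminal terminal raster (interpolated mode).
#' @param series list of rasters, one per timestep (custom mode).
#' @export
env_change_event <- function(mode = c("interpolated", "custom"),
                             timesteps, terminal = NULL, series = NULL) {
  mode <- match.arg(mode)
  timesteps <- as.integer(timesteps)
  if (length(timesteps) < 1 || any(diff(timesteps) <= 0)) {
    stop("change timesteps must be strictly increasing")
  }
  if (mode == "interpolated") {
    if (is.null(terminal)) stop("interpolated mode needs a terminal raster")
    terminal <- gl_raster(terminal)
  } else {
    if (is.null(series) || length(series) != length(timesteps)) {
      stop("custom mode needs one raster per timestep")
    }
    series <- lapply(series, gl_raster)
  }
  structure(list(mode = mode, timesteps = timesteps,
                 terminal = terminal, series = series),
            class = "gl_env_change")
}

#' Cell-wise linear interpolation series between two rasters
#'
#' The i-th of K scheduled rasters is `start + (i/K) * (terminal - start)`;
#' the last equals the terminal raster exactly. Increments are equal fractions
#' of the total change per scheduled step, regardless of gaps between the
#' scheduled timesteps.
#'
#' @param start,terminal dimension-matched rasters.
#' @param change_timesteps strictly increasing timesteps (length K >= 1).
#' @return list of `list(timestep=, raster=)`, one per scheduled step.
#' @export
build_interpolation_series <- function(start, terminal, change_timesteps) {
  start <- gl_raster(start); terminal <- gl_raster(terminal)
  if (!all(dim(start) == dim(terminal))) stop("raster dimension mismatch")
  ts <- as.integer(change_timesteps)
  if (length(ts) < 1 || any(diff(ts) <= 0)) stop("timesteps must be strictly increasing")
  K <- length(ts)
  lapply(seq_len(K), function(i) {
    list(timestep = ts[i],
         raster = gl_raster(start + (i / K) * (terminal - start)))
  })
}

#' Create a layer
#'
#' @param raster a `gl_raster` or matrix.
#' @param name layer name.
#' @param roles subset of `c("movement", "dispersal", "carrying_capacity",
#'   "selection")`; a layer may hold several roles simultaneously.
#' @param change optional `gl_env_change`.
#' @export
gl_layer <- function(raster, name = "layer",
                     roles = character(), change = NULL) {
  raster <- gl_raster(raster)
  allowed <- c("movement", "dispersal", "carrying_capacity", "selection")
  if (!all(roles %in% allowed)) {
    stop("unknown roles: ", paste(setdiff(roles, allowed), collapse = ", "))
  }
  env_roles <- intersect(roles, c("movement", "dispersal", "selection"))
  if (length(env_roles) && (min(raster) < 0 || max(raster) > 1)) {
    stop("environmental-role layers must lie in [0, 1]; use rescale_unit()")
  }
  schedule <- NULL
  if (!is.null(change)) {
    stopifnot(inherits(change, "gl_env_change"))
    if (change$mode == "interpolated") {
      schedule <- build_interpolation_series(raster, change$terminal,
                                             change$timesteps)
    } else {
      ok <- vapply(change$series, function(r) all(dim(r) == dim(raster)),
                   logical(1))
      if (!all(ok)) stop("change-series raster dimension mismatch")
      schedule <- Map(function(t, r) list(timestep = t, raster = r),
                      change$timesteps, change$series)
    }
  }
  structure(list(name = name, raster = raster, roles = roles,
                 change = change, schedule = schedule),
            class = "gl_layer")
}

#' Raster of a layer in force at time t
#'
#' Piecewise constant and right-continuous: returns the most recent scheduled
#' raster with timestep <= t, else the original raster.
#'
#' @param layer a `gl_layer`.
#' @param t timestep (>= 0).
#' @export
layer_at_time <- function(layer, t) {
  stopifnot(inherits(layer, "gl_layer"), t >= 0)
  if (is.null(layer$schedule)) return(layer$raster)
  ts <- vapply(layer$schedule, `[[`, integer(1), "timestep")
  i <- findInterval(t, ts)
  if (i == 0) layer$raster else layer$schedule[[i]]$raster
}

#' Create a landscape (a stack of layers)
#'
#' @param layers list of `gl_layer`s sharing dimensions.
#' @param georef optional list with `transform` (affine, c(x0, dx, y0, dy))
#'   and `crs` (text tag).
#' @export
gl_landscape <- function(layers, georef = NULL) {
  if (inherits(layers, "gl_layer")) layers <- list(layers)
  if (length(layers) < 1) stop("a landscape needs at least one layer")
  stopifnot(all(vapply(layers, inherits, logical(1), "gl_layer")))
  dims <- dim(layers[[1]]$raster)
  ok <- vapply(layers, function(l) all(dim(l$raster) == dims), logical(1))
  if (!all(ok)) stop("all layers must share dimensions")
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  structure(list(dims = dims, layers = layers, georef = georef),
            class = "gl_landscape")
}

#' @export
print.gl_landscape <- function(x, ...) {
  cat(sprintf("<gl_landscape %d x %d, %d layer(s)>\n",
              x$dims[1], x$dims[2], length(x$layers)))
  for (l in x$layers) {
    cat(sprintf("  %-12s roles: %-40s change: %s\n", l$name,
                paste(l$roles, collapse = ","),
                if (is.null(l$schedule)) "none"
                else paste(length(l$schedule), "steps")))
  }
  invisible(x)
}

# ---- cell arithmetic ---------------------------------------------------

#' Cell indices for continuous coordinates
#'
#' @param x,y coordinates in cell units.
#' @param dims c(nrows, ncols).
#' @return list with `row`, `col` (1-based) and `cell` (column-major index).
#' @keywords internal
coords_to_cell <- function(x, y, dims) {
  col <- pmin(floor(x) + 1L, dims[2]); col <- pmax(col, 1L)
  row <- pmin(floor(y) + 1L, dims[1]); row <- pmax(row, 1L)
  list(row = as.integer(row), col = as.integer(col),
       cell = as.integer((col - 1L) * dims[1] + row))
}

# ---- programmatic landscape generators --------------------------------

#' Linear gradient layer
#'
#' @param dims c(nrows, ncols).
#' @param direction `"x"` (increases with column) or `"y"`.
#' @param reverse flip the gradient.
#' @export
make_gradient_raster <- function(dims, direction = c("x", "y"),
                                 reverse = FALSE) {
  direction <- match.arg(direction)
  nr <- dims[1]; nc <- dims[2]
  if (direction == "x") {
    v <- if (nc == 1) 0.5 else (seq_len(nc) - 1) / (nc - 1)
    m <- matrix(v, nr, nc, byrow = TRUE)
  } else {
    v <- if (nr == 1) 0.5 else (seq_len(nr) - 1) / (nr - 1)
    m <- matrix(v, nr, nc)
  }
  if (reverse) m <- 1 - m
  gl_raster(m)
}

#' Vertical barrier layer
#'
#' Value `outside` everywhere except a central band of columns at `inside`.
#'
#' @param dims c(nrows, ncols).
#' @param barrier_cols integer columns forming the barrier.
#' @param inside,outside cell values inside/outside the band.
#' @export
make_barrier_raster <- function(dims, barrier_cols,
                                inside = 0, outside = 1) {
  m <- matrix(outside, dims[1], dims[2])
  m[, barrier_cols] <- inside
  gl_raster(m)
}

#' Smoothed random field layer
#'
#' Uniform noise smoothed by repeated 3x3 mean filtering, then rescaled to
#' [0, 1]; a light-weight stand-in for a neutral landscape model.
#'
#' @param dims c(nrows, ncols).
#' @param smooth number of smoothing passes.
#' @export
make_random_raster <- function(dims, smooth = 3) {
  m <- matrix(stats::runif(prod(dims)), dims[1], dims[2])
  for (i in seq_len(smooth)) m <- mean_filter3(m)
  rescale_unit(m)
}

# 3x3 mean filter with edge replication
mean_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + p[di + seq_len(nr), dj + seq_len(nc)]
  }
  out / 9
}

#' Island chain layer
#'
#' A row of equally sized habitable column blocks (value `inside`) separated
#' by uninhabitable gaps (value 0): the classic linear stepping-stone
#' arrangement.
#'
#' @param dims c(nrows, ncols).
#' @param n_islands number of islands.
#' @param island_width,gap column widths of islands and gaps.
#' @param inside island cell value.
#' @export
make_islands_raster <- function(dims, n_islands = 6, island_width = 8,
                                gap = 2, inside = 1) {
  need <- n_islands * island_width + (n_islands - 1) * gap
  if (need > dims[2]) stop("landscape too narrow for the island chain")
  m <- matrix(0, dims[1], dims[2])
  starts <- seq(1, by = island_width + gap, length.out = n_islands)
  for (s in starts) m[, s:(s + island_width - 1)] <- inside
  attr(m, "island_starts") <- starts
  gl_raster(m)
}

#' Two opposed horizontal gradients split by a vertical band
#'
#' Left half runs 0 to 1 toward the band, right half 1 to 0 away from it, so
#' the landscape contains location pairs spanning the full range of
#' geographic-by-environmental distance combinations. Cells inside the band
#' take `inside_value`.
#'
#' @param dims c(nrows, ncols).
#' @param barrier_cols columns of the central band.
#' @param inside_value value within the band.
#' @export
make_opposed_gradients_raster <- function(dims, barrier_cols,
                                          inside_value = 0.5) {
  nr <- dims[1]; nc <- dims[2]
  left <- seq_len(min(barrier_cols) - 1)
  right <- seq(max(barrier_cols) + 1, nc)
  m <- matrix(inside_value, nr, nc)
  m[, left] <- matrix((left - 1) / (length(left) - 1), nr, length(left),
                      byrow = TRUE)
  m[, right] <- matrix(rev((seq_along(right) - 1) / (length(right) - 1)),
                       nr, length(right), byrow = TRUE)
  gl_raster(m)
}
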