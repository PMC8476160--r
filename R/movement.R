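#' Anisotropic movement and dispersal
#'
#' Individuals move along vectors composed of a Wald (inverse-Gaussian)
#' distance and a direction drawn either uniformly on the circle or from a
#' movement surface: an array of per-cell unimodal or mixture von Mises
#' distributions derived from a resistance layer. Each cell's distribution is
#' represented by an "approximation column" of M pre-sampled directions; a
#' runtime draw samples one stored value, so movement costs O(1) random draws
#' per step.
#'
#' @name movement
NULL

# fixed neighbour ordering (tie-break and mixture component order):
# N, NE, E, SE, S, SW, W, NW; (dr, dc) offsets in row/col space.
NEIGHBOR_OFFSETS <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                          dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
# center-to-center directions; x runs along columns, y along rows,
# so dx = dc and dy = dr (diagonals at odd multiples of pi/4)
NEIGHBOR_ANGLES <- atan2(NEIGHBOR_OFFSETS[, "dr"],
                         NEIGHBOR_OFFSETS[, "dc"]) %% (2 * pi)

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mode (radians); scalar or length-n.
#' @param kappa concentration (>= 0).
#' @return angles in [0, 2*pi).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return((stats::runif(n, 0, 2 * pi) + mu) %% (2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(acc)
    if (k > 0) {
      th <- sign(stats::runif(k) - 0.5) * acos(pmin(pmax(f[acc], -1), 1))
      out[(got + 1L):(got + k)] <- th
      got <- got + k
    }
  }
  (out + mu) %% (2 * pi)
}

#' Draw from a Wald (inverse-Gaussian) distribution
#'
#' Mean/shape parameterisation: `E[X] = mean`, `Var[X] = mean^3 / shape`.
#' Michael-Schucany-Haas transformation method.
#'
#' @param n number of draws.
#' @param mean,shape strictly positive parameters.
#' @export
rwald <- function(n, mean, shape) {
  if (mean <= 0 || shape <= 0) stop("mean and shape must be > 0")
  nu <- stats::rnorm(n)^2
  x <- mean + mean^2 * nu / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * nu + mean^2 * nu^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

# per-cell neighbour values and directions; edge cells get NA for missing
# neighbours (weight 0 in mixtures, excluded from the unimodal argmax)
neighbor_values <- function(values) {
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr * nc, 8L)
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  for (k in 1:8) {
    r2 <- rows + NEIGHBOR_OFFSETS[k, "dr"]
    c2 <- cols + NEIGHBOR_OFFSETS[k, "dc"]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    out[ok, k] <- values[cbind(r2[ok], c2[ok])]
  }
  out
}

#' Build a movement surface from a resistance layer
#'
#' Unimodal mode assigns each cell one von Mises distribution with mode
#' pointing at the highest-valued 8-neighbour (ties broken by the fixed
#' N, NE, E, SE, S, SW, W, NW ordering). Mixture mode draws each stored
#' direction by first picking neighbour k with probability proportional to
#' its cell value, then sampling von Mises around the direction to k's
#' center. Cells whose neighbours are all zero (or missing) fall back to
#' uniform directions.
#'
#' @param layer a `gl_layer` or raster with values in [0, 1].
#' @param kappa von Mises concentration (>= 0).
#' @param M approximation-column length (>= 1).
#' @param mode `"mixture"` (default) or `"unimodal"`.
#' @return a `gl_move_surface`.
#' @export
build_movement_surface <- function(layer, kappa = 12, M = 1000,
                                   mode = c("mixture", "unimodal")) {
  mode <- match.arg(mode)
  values <- if (inherits(layer, "gl_layer")) layer$raster else gl_raster(layer)
  if (min(values) < 0 || max(values) > 1) {
    stop("movement layers must lie in [0, 1]")
  }
  if (M < 1) stop("M must be >= 1")
  nbr <- neighbor_values(unclass(values))
  ncells <- nrow(nbr)
  cols <- matrix(0, M, ncells)
  uniform_fallback <- FALSE
  if (mode == "unimodal") {
    best <- apply(nbr, 1, function(v) {
      if (all(is.na(v))) return(NA_integer_)
      which.max(replace(v, is.na(v), -Inf))  # first max = fixed-order tie-break
    })
    base <- rvonmises(M * ncells, 0, kappa)
    mu <- NEIGHBOR_ANGLES[best]
    cols[] <- (base + rep(mu, each = M)) %% (2 * pi)
  } else {
    w <- replace(nbr, is.na(nbr), 0)
    tot <- rowSums(w)
    zero <- tot <= 0
    if (any(zero)) uniform_fallback <- TRUE
    comp <- matrix(1L, M, ncells)
    for (ci in which(!zero)) {
      comp[, ci] <- sample.int(8L, M, replace = TRUE, prob = w[ci, ])
    }
    base <- rvonmises(M * ncells, 0, kappa)
    mu <- NEIGHBOR_ANGLES[comp]
    cols[] <- (base + mu) %% (2 * pi)
    if (any(zero)) {
      cols[, zero] <- stats::runif(M * sum(zero), 0, 2 * pi)
    }
  }
  if (uniform_fallback) {
    warning("cells with all-zero neighbourhoods fall back to uniform directions")
  }
  structure(list(cols = cols, M = as.integer(M), kappa = kappa, mode = mode,
                 dims = dim(values),
                 layer_name = if (inherits(layer, "gl_layer")) layer$name
                 else "raster"),
            class = "gl_move_surface")
}

#' Draw movement directions from a surface
#'
#' Uniformly samples one stored direction from each queried cell's
#' approximation column; O(1) per draw.
#'
#' @param surface a `gl_move_surface`.
#' @param cells column-major cell indices (one per draw).
#' @export
draw_directions <- function(surface, cells) {
  n <- length(cells)
  if (any(cells < 1 | cells > ncol(surface$cols))) {
    stop("cell index out of bounds")
  }
  idx <- (cells - 1L) * surface$M + sample.int(surface$M, n, replace = TRUE)
  surface$cols[idx]
}

#' Displace positions along drawn vectors, keeping them inside the landscape
#'
#' Candidate positions falling outside the landscape have their full vector
#' (direction and distance) redrawn up to `max_attempts` times; any still
#' outside are truncated along the vector at the boundary minus 1e-6 cell
#' widths. Redrawing (rather than reflecting) preserves the surface-driven
#' anisotropy of the direction distribution.
#'
#' @param x,y current positions.
#' @param surface a `gl_move_surface` or NULL for isotropic directions.
#' @param wald list(mean=, shape=) step-length parameters.
#' @param dims c(nrows, ncols).
#' @param max_attempts redraw rounds before truncation.
#' @return list with updated `x`, `y`.
#' @export
move_positions <- function(x, y, surface, wald, dims, max_attempts = 50) {
  n <- length(x)
  if (n == 0) return(list(x = x, y = y))
  eps <- 1e-6
  xmax <- dims[2] - eps; ymax <- dims[1] - eps
  draw_vec <- function(xs, ys) {
    m <- length(xs)
    th <- if (is.null(surface)) stats::runif(m, 0, 2 * pi) else
      draw_directions(surface, coords_to_cell(xs, ys, dims)$cell)
    d <- if (wald$mean == 0) numeric(m) else rwald(m, wald$mean, wald$shape)
    list(th = th, d = d)
  }
  v <- draw_vec(x, y)
  nx <- x + v$d * cos(v$th)
  ny <- y + v$d * sin(v$th)
  out <- which(nx < eps | nx > xmax | ny < eps | ny > ymax)
  attempt <- 0L
  while (length(out) > 0 && attempt < max_attempts) {
    v2 <- draw_vec(x[out], y[out])
    nx[out] <- x[out] + v2$d * cos(v2$th)
    ny[out] <- y[out] + v2$d * sin(v2$th)
    v$th[out] <- v2$th; v$d[out] <- v2$d
    out <- out[nx[out] < eps | nx[out] > xmax | ny[out] < eps | ny[out] > ymax]
    attempt <- attempt + 1L
  }
  if (length(out) > 0) {
    # truncate the step where the vector first leaves the landscape
    dx <- nx[out] - x[out]; dy <- ny[out] - y[out]
    tx <- rep(1, length(out)); ty <- rep(1, length(out))
    tx[dx > 0] <- (xmax - x[out][dx > 0]) / dx[dx > 0]
    tx[dx < 0] <- (eps - x[out][dx < 0]) / dx[dx < 0]
    ty[dy > 0] <- (ymax - y[out][dy > 0]) / dy[dy > 0]
    ty[dy < 0] <- (eps - y[out][dy < 0]) / dy[dy < 0]
    tt <- pmin(pmax(pmin(tx, ty), 0), 1)
    nx[out] <- x[out] + tt * dx
    ny[out] <- y[out] + tt * dy
    nx[out] <- pmin(pmax(nx[out], eps), xmax)
    ny[out] <- pmin(pmax(ny[out], eps), ymax)
  }
  list(x = nx, y = ny)
}

#' Offspring dispersal from the parental midpoint
#'
#' The dispersal vector is drawn exactly like a movement vector (isotropic or
#' surface-driven), originating at the parents' midpoint.
#'
#' @param xa,ya,xb,yb parent positions.
#' @param surface a `gl_move_surface` or NULL.
#' @param wald list(mean=, shape=) dispersal-distance parameters.
#' @param dims c(nrows, ncols).
#' @return list with offspring `x`, `y`.
#' @export
disperse_positions <- function(xa, ya, xb, yb, surface, wald, dims) {
  move_positions((xa + xb) / 2, (ya + yb) / 2, surface, wald, dims)
}
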