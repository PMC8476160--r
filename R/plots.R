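#' ggplot2 visual diagnostics
#'
#' Raster maps with individuals coloured by phenotype or genetic PC scores,
#' movement-surface rose diagrams, simulated movement tracks, and autoplot
#' methods for run logs.
#'
#' @name plots
NULL

raster_df <- function(raster) {
  r <- unclass(raster)
  tibble::tibble(
    x = rep(seq_len(ncol(r)) - 0.5, each = nrow(r)),
    y = rep(seq_len(nrow(r)) - 0.5, ncol(r)),
    value = as.vector(r))
}

#' Map a raster layer
#'
#' @param layer a `gl_layer` or raster.
#' @param t timestep (for layers with change events).
#' @export
plot_layer <- function(layer, t = 0) {
  r <- if (inherits(layer, "gl_layer")) layer_at_time(layer, t) else
    gl_raster(layer)
  ggplot2::ggplot(raster_df(r), ggplot2::aes(.data$x, .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cells)", y = "y (cells)", fill = "value") +
    ggplot2::theme_minimal()
}

#' Map individuals coloured by phenotype over a layer
#'
#' @param model a `gl_model`.
#' @param trait trait name (default: first trait).
#' @param layer layer name (default: the trait's selection layer).
#' @export
plot_phenotype <- function(model, trait = NULL, layer = NULL) {
  traits <- model$arch$traits
  if (length(traits) == 0) stop("model has no traits")
  tr <- if (is.null(trait)) traits[[1]] else traits[[trait]]
  lname <- if (is.null(layer)) tr$layer else layer
  p_idx <- match(tr$name, names(traits))
  plot_layer(model$landscape$layers[[lname]], model$t) +
    ggplot2::geom_point(
      data = tibble::tibble(x = model$pop$x, y = model$pop$y,
                            z = model$pop$z[, p_idx]),
      ggplot2::aes(.data$x, .data$y, colour = .data$z),
      inherit.aes = FALSE, size = 0.8) +
    ggplot2::scale_colour_viridis_c(option = "plasma", name = "phenotype")
}

#' Rose diagrams of a movement surface
#'
#' Circular histograms of the stored approximation-column directions for a
#' subsample of cells; longer wedges mark more probable movement directions.
#'
#' @param surface a `gl_move_surface`.
#' @param cells cell indices to show (default: up to 25 evenly spaced).
#' @param bins angular bins.
#' @export
plot_movement_surface <- function(surface, cells = NULL, bins = 16) {
  ncells <- ncol(surface$cols)
  if (is.null(cells)) {
    cells <- unique(round(seq(1, ncells, length.out = min(25, ncells))))
  }
  df <- dplyr::bind_rows(lapply(cells, function(ci) {
    tibble::tibble(cell = ci, angle = surface$cols[, ci])
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$angle)) +
    ggplot2::geom_histogram(breaks = seq(0, 2 * pi, length.out = bins + 1),
                            fill = "steelblue") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Simulate and plot a single movement track
#'
#' @param layer resistance layer.
#' @param surface a `gl_move_surface` built from it.
#' @param wald list(mean=, shape=).
#' @param n_steps track length.
#' @param start c(x, y) start position (default: landscape center).
#' @return ggplot; the track itself in attribute `"track"`.
#' @export
plot_movement_track <- function(layer, surface, wald = list(mean = 0.5,
                                                            shape = 0.5),
                                n_steps = 5000, start = NULL) {
  dims <- dim(if (inherits(layer, "gl_layer")) layer$raster else layer)
  if (is.null(start)) start <- c(dims[2] / 2, dims[1] / 2)
  xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
  xs[1] <- start[1]; ys[1] <- start[2]
  for (i in seq_len(n_steps)) {
    nxt <- move_positions(xs[i], ys[i], surface, wald, dims)
    xs[i + 1] <- nxt$x; ys[i + 1] <- nxt$y
  }
  track <- tibble::tibble(step = 0:n_steps, x = xs, y = ys)
  p <- plot_layer(layer) +
    ggplot2::geom_path(data = track, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, linewidth = 0.2,
                       colour = "red")
  attr(p, "track") <- track
  p
}

#' Autoplot a model run log
#'
#' Population size, births/deaths, and (when selection is on) mean fitness
#' and mean phenotype-environment mismatch over main-phase timesteps.
#'
#' @param object a `gl_model`.
#' @param ... unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.gl_model <- function(object, ...) {
  lg <- run_log(object, "main")
  long <- tidyr::pivot_longer(
    dplyr::select(lg, "t", "N", "mean_fitness", "mean_mismatch"),
    -"t", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "timestep", y = NULL) +
    ggplot2::theme_minimal()
}
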