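#' Suitability and category grids
#'
#' A `suitability_grid` is a single georeferenced layer of continuous model
#' scores (percentile index in \[0, 50\] for the envelope model, Gower
#' similarity <= 100 for the similarity model) tagged with the model that
#' produced it. A `category_grid` carries integer suitability codes
#' 0..5 = unsuitable, low, medium, high, very_high, excellent.
#'
#' @name suitability_grid
NULL

suitability_levels <- c("unsuitable", "low", "medium", "high", "very_high",
                        "excellent")

new_suitability_grid <- function(scores, georef, model) {
  structure(
    list(scores = scores, origin_lon = georef$origin_lon,
         origin_lat = georef$origin_lat, cell_size = georef$cell_size,
         model = model),
    class = "suitability_grid"
  )
}

new_category_grid <- function(codes, georef, model) {
  structure(
    list(codes = codes, origin_lon = georef$origin_lon,
         origin_lat = georef$origin_lat, cell_size = georef$cell_size,
         model = model, legend = setNames(0:5, suitability_levels)),
    class = "category_grid"
  )
}

#' @export
dim.suitability_grid <- function(x) dim(x$scores)

#' @export
dim.category_grid <- function(x) dim(x$codes)

#' @export
print.suitability_grid <- function(x, ...) {
  v <- x$scores[!is.na(x$scores)]
  cat(sprintf("<suitability_grid> model %s, %d x %d cells, scores %.2f..%.2f\n",
              x$model, nrow(x$scores), ncol(x$scores),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
print.category_grid <- function(x, ...) {
  tab <- table(factor(x$codes, levels = 0:5, labels = suitability_levels))
  cat(sprintf("<category_grid> model %s, %d x %d cells\n", x$model,
              nrow(x$codes), ncol(x$codes)))
  print(tab)
  invisible(x)
}

grid_as_tibble <- function(values, x) {
  d <- dim(values)
  row <- rep(seq_len(d[1]), times = d[2])
  col <- rep(seq_len(d[2]), each = d[1])
  v <- as.vector(values)
  keep <- !is.na(v)
  tibble(
    row = row[keep], col = col[keep],
    lon = x$origin_lon + (col[keep] - 0.5) * x$cell_size,
    lat = x$origin_lat - (row[keep] - 0.5) * x$cell_size,
    value = v[keep]
  )
}

#' @rdname suitability_grid
#' @param x,object A `suitability_grid` or `category_grid`.
#' @param ... Unused.
#' @export
as_tibble.suitability_grid <- function(x, ...) {
  dplyr::rename(grid_as_tibble(x$scores, x), score = "value")
}

#' @rdname suitability_grid
#' @export
as_tibble.category_grid <- function(x, ...) {
  df <- grid_as_tibble(x$codes, x)
  dplyr::mutate(df,
                class = factor(suitability_levels[.data$value + 1],
                               levels = suitability_levels),
                value = NULL)
}

#' @rdname suitability_grid
#' @export
autoplot.suitability_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$lon, .data$lat, fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = sprintf("%s suitability", object$model))
}

#' @rdname suitability_grid
#' @export
autoplot.category_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$lon, .data$lat, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = 1,
                               drop = FALSE) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = sprintf("%s suitability classes", object$model))
}

#' Write a grid with its legend
#'
#' Category grids are written as integer ESRI ASCII rasters with a sidecar
#' JSON legend (`<path>.legend.json`); suitability grids as floating-point
#' ASCII rasters.
#'
#' @param grid A `suitability_grid` or `category_grid`.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  values <- if (inherits(grid, "category_grid")) grid$codes else grid$scores
  write_ascii_grid(values, path, grid$origin_lon, grid$origin_lat,
                   grid$cell_size)
  if (inherits(grid, "category_grid")) {
    jsonlite::write_json(as.list(grid$legend),
                         paste0(path, ".legend.json"), auto_unbox = TRUE)
  }
  invisible(path)
}
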