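#' Multi-layer bioclimatic raster stack
#'
#' A `climate_stack` holds one georeferenced layer per bioclimatic variable on
#' a shared regular longitude/latitude grid (WGS84 decimal degrees). Layers
#' are stored as numeric matrices with row 1 at the northern edge; `NA` cells
#' are nodata and the nodata mask must agree across layers.
#'
#' @param layers Named list of numeric matrices, all with identical dimensions
#'   and identical `NA` patterns. Names are the variable names (e.g. `bio12`).
#' @param origin_lon,origin_lat Longitude/latitude in decimal degrees of the
#'   north-west corner of the grid (the outer corner of cell `[1, 1]`).
#' @param cell_size Cell edge length in decimal degrees (> 0).
#'
#' @return An object of class `climate_stack`.
#' @seealso [make_climate_stack()] to simulate one, [read_ascii_stack()] /
#'   [write_ascii_stack()] for ESRI ASCII grid I/O.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4)
#' st <- climate_stack(list(bio12 = m), origin_lon = 100, origin_lat = 40,
#'                     cell_size = 0.5)
#' dim(st)
climate_stack <- function(layers, origin_lon, origin_lat, cell_size) {
  if (!is.list(layers) || length(layers) == 0L) {
    abort("`layers` must be a non-empty named list of matrices.")
  }
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    abort("`layers` must have unique, non-empty names.")
  }
  dims <- vapply(layers, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1])) {
    abort("All layers must share the same dimensions.")
  }
  stopifnot_scalar_number(origin_lon, "origin_lon")
  stopifnot_scalar_number(origin_lat, "origin_lat")
  stopifnot_scalar_number(cell_size, "cell_size")
  if (cell_size <= 0) abort("`cell_size` must be > 0.")
  mask <- is.na(layers[[1]])
  for (v in nm[-1]) {
    if (!identical(is.na(layers[[v]]), mask)) {
      abort(sprintf("Layer '%s' has a nodata mask differing from layer '%s'.",
                    v, nm[1]))
    }
  }
  structure(
    list(layers = layers, origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size),
    class = "climate_stack"
  )
}

#' @export
dim.climate_stack <- function(x) dim(x$layers[[1]])

#' Variable names of a climate stack
#' @param stack A [climate_stack()].
#' @return Character vector of layer names.
#' @export
stack_vars <- function(stack) names(stack$layers)

n_cells <- function(stack) prod(dim(stack))

nodata_mask <- function(stack) is.na(stack$layers[[1]])

#' @export
print.climate_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<climate_stack> %d x %d cells, %d layer(s): %s\n", d[1], d[2],
    length(x$layers), paste(stack_vars(x), collapse = ", ")))
  cat(sprintf("  NW corner (%.4f, %.4f), cell size %g deg, %d nodata cell(s)\n",
              x$origin_lon, x$origin_lat, x$cell_size, sum(nodata_mask(x))))
  invisible(x)
}

# --- georeference arithmetic -------------------------------------------------

# Cell centre coordinates for (row, col) indices (row 1 = north edge).
cell_center_lon <- function(stack, col) stack$origin_lon + (col - 0.5) * stack$cell_size
cell_center_lat <- function(stack, row) stack$origin_lat - (row - 0.5) * stack$cell_size

# Map points to grid indices; points on a shared cell edge belong to the
# cell to the south/east (floor rule). Returns a list(row, col, inside).
locate_cells <- function(stack, lon, lat) {
  d <- dim(stack)
  col <- floor((lon - stack$origin_lon) / stack$cell_size) + 1L
  row <- floor((stack$origin_lat - lat) / stack$cell_size) + 1L
  # points exactly on the south/east outer edge belong to the last cell
  col[lon == stack$origin_lon + d[2] * stack$cell_size] <- d[2]
  row[lat == stack$origin_lat - d[1] * stack$cell_size] <- d[1]
  inside <- row >= 1L & row <= d[1] & col >= 1L & col <= d[2]
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

same_georef <- function(a, b, tol = 1e-9) {
  identical(dim(a), dim(b)) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

georef_string <- function(x) {
  sprintf("[%d x %d, NW (%.6f, %.6f), cell %.8f deg]",
          dim(x)[1], dim(x)[2], x$origin_lon, x$origin_lat, x$cell_size)
}

#' Tidy a climate stack into a long tibble
#'
#' One row per non-nodata cell and variable, with cell-centre coordinates.
#'
#' @param x A [climate_stack()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `lon`, `lat`, `variable`,
#'   `value`.
#' @export
as_tibble.climate_stack <- function(x, ...) {
  d <- dim(x)
  row <- rep(seq_len(d[1]), times = d[2])
  col <- rep(seq_len(d[2]), each = d[1])
  keep <- !as.vector(nodata_mask(x))
  base <- tibble(
    row = row[keep], col = col[keep],
    lon = cell_center_lon(x, col[keep]),
    lat = cell_center_lat(x, row[keep])
  )
  vals <- purrr::map(x$layers, ~ as.vector(.x)[keep])
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(base, as_tibble(vals)),
    cols = -c("row", "col", "lon", "lat"),
    names_to = "variable", values_to = "value"
  )
  long
}

#' @rdname as_tibble.climate_stack
#' @param object A [climate_stack()].
#' @export
autoplot.climate_stack <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}
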