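#' Geodesic area of a lon/lat grid cell
#'
#' Spherical-band area `R^2 * dlambda * (sin(lat_top) - sin(lat_bottom))`
#' with the authalic Earth radius R = 6371.0072 km: exact on the sphere for
#' a cell bounded by meridians and parallels.
#'
#' @param lat_center Latitude of the cell centre, degrees; the cell must not
#'   cross a pole.
#' @param cell_size Cell edge in degrees.
#' @return Cell area in km^2 (vectorised over `lat_center`).
#' @export
#' @examples
#' cell_area_km2(0, 2.5 / 60)  # ~21.47 km^2 at the equator
cell_area_km2 <- function(lat_center, cell_size) {
  if (any(abs(lat_center) > 90)) abort("`lat_center` must be within [-90, 90].")
  top <- lat_center + cell_size / 2
  bot <- lat_center - cell_size / 2
  if (any(top > 90 + 1e-12) || any(bot < -90 - 1e-12)) {
    abort("Cell crosses a pole.")
  }
  R <- 6371.0072
  rad <- pi / 180
  R^2 * (cell_size * rad) * (sin(pmin(top, 90) * rad) - sin(pmax(bot, -90) * rad))
}

# Per-row cell areas of a grid-like object (row 1 = north).
row_areas <- function(x, n_rows) {
  lat <- x$origin_lat - (seq_len(n_rows) - 0.5) * x$cell_size
  cell_area_km2(lat, x$cell_size)
}

#' Per-class areas of a category grid
#'
#' Sums the geodesic cell areas of every suitability class, reported in
#' 10^4 km^2; classes absent from the grid report 0.
#'
#' @param cat A [category_grid] (see [classify_bioclim()]).
#' @param digits Decimal places for the reported areas (default `NULL`:
#'   unrounded).
#' @return A tibble with columns `class`, `code`, `area_1e4_km2`.
#' @export
class_areas <- function(cat, digits = NULL) {
  areas <- row_areas(cat, nrow(cat$codes))
  per_class <- vapply(0:5, function(code) {
    hit <- !is.na(cat$codes) & cat$codes == code
    sum(rowSums(hit) * areas)
  }, numeric(1))
  out <- tibble(
    class = factor(suitability_levels, levels = suitability_levels),
    code = 0:5,
    area_1e4_km2 = per_class / 1e4
  )
  if (!is.null(digits)) {
    out$area_1e4_km2 <- round_half_away(out$area_1e4_km2, digits)
  }
  out
}

#' Percent change between scenario areas
#'
#' `100 * (future - current) / current`, rounded half away from zero to one
#' decimal (the rounding used in published scenario tables). A class absent
#' now but present in the future has no defined percent change and reports
#' `NA` (a "new class").
#'
#' @param current_area,future_area Areas in any common unit (vectorised).
#' @param digits Decimal places (default 1; `NULL` for unrounded).
#' @return Numeric percent change(s); `NA` where `current_area` is 0.
#' @export
#' @examples
#' percent_change(16.5, 15.5)  # -6.1
#' percent_change(27.5, 32.3)  # 17.5
percent_change <- function(current_area, future_area, digits = 1) {
  if (any(current_area < 0) || any(future_area < 0)) {
    abort("Areas must be >= 0.")
  }
  pc <- ifelse(current_area == 0, NA_real_,
               100 * (future_area - current_area) / current_area)
  if (!is.null(digits)) pc <- round_half_away(pc, digits)
  pc
}

#' Scenario change table
#'
#' Combines [class_areas()] of a current and a future category grid with
#' [percent_change()] into one table shaped like a published
#' current/future/change summary.
#'
#' @param current,future [category_grid]s on the same georeference.
#' @param digits Decimal places for areas and percent change (default 1).
#' @return A tibble with `class`, `current_area`, `future_area`,
#'   `change_percent` (areas in 10^4 km^2).
#' @export
change_table <- function(current, future, digits = 1) {
  if (!same_georef(current, future)) {
    abort(sprintf("Georeference mismatch: current %s vs future %s.",
                  georef_string(current), georef_string(future)))
  }
  cur <- class_areas(current, digits = digits)
  fut <- class_areas(future, digits = digits)
  tibble(
    class = cur$class,
    current_area = cur$area_1e4_km2,
    future_area = fut$area_1e4_km2,
    change_percent = percent_change(cur$area_1e4_km2, fut$area_1e4_km2,
                                    digits = digits)
  )
}

transition_levels <- c("other", "retained", "lost", "new")

#' Retained / lost / new habitat for a focal class
#'
#' Compares two category grids cell by cell for one focal suitability class:
#' `retained` cells are focal in both scenarios, `lost` only in the current
#' one, `new` only in the future one, `other` in neither.
#'
#' @param current,future [category_grid]s with identical georeference and
#'   nodata mask.
#' @param focal Focal class, name or code (default `"excellent"`).
#' @return A `transition_grid` (codes 0..3 = other/retained/lost/new) with a
#'   `summary` tibble of per-category cell counts and areas (10^4 km^2).
#'   `as_tibble()` and `autoplot()` methods apply.
#' @export
transition_map <- function(current, future, focal = "excellent") {
  if (!same_georef(current, future)) {
    abort(sprintf("Georeference mismatch: current %s vs future %s.",
                  georef_string(current), georef_string(future)))
  }
  if (!identical(is.na(current$codes), is.na(future$codes))) {
    abort("Nodata masks of the two grids differ.")
  }
  code <- if (is.character(focal)) match(focal, suitability_levels) - 1L else
    as.integer(focal)
  if (is.na(code) || code < 0 || code > 5) {
    abort(sprintf("Unknown focal class '%s'.", focal))
  }
  in_cur <- current$codes == code
  in_fut <- future$codes == code
  codes <- matrix(NA_integer_, nrow(current$codes), ncol(current$codes))
  ok <- !is.na(current$codes)
  codes[ok] <- ifelse(in_cur[ok] & in_fut[ok], 1L,
               ifelse(in_cur[ok] & !in_fut[ok], 2L,
               ifelse(!in_cur[ok] & in_fut[ok], 3L, 0L)))
  areas <- row_areas(current, nrow(codes))
  summary <- tibble(
    category = factor(transition_levels, levels = transition_levels),
    cells = vapply(0:3, function(k) sum(codes == k, na.rm = TRUE), numeric(1)),
    area_1e4_km2 = vapply(0:3, function(k) {
      hit <- !is.na(codes) & codes == k
      sum(rowSums(hit) * areas) / 1e4
    }, numeric(1))
  )
  structure(
    list(codes = codes, origin_lon = current$origin_lon,
         origin_lat = current$origin_lat, cell_size = current$cell_size,
         focal = suitability_levels[code + 1], summary = summary),
    class = "transition_grid"
  )
}

#' @export
print.transition_grid <- function(x, ...) {
  cat(sprintf("<transition_grid> focal class '%s'\n", x$focal))
  print(x$summary)
  invisible(x)
}

#' @rdname transition_map
#' @param x,object A `transition_grid`.
#' @param ... Unused.
#' @export
as_tibble.transition_grid <- function(x, ...) {
  df <- grid_as_tibble(x$codes, x)
  dplyr::mutate(df,
                category = factor(transition_levels[.data$value + 1],
                                  levels = transition_levels),
                value = NULL)
}

#' @rdname transition_map
#' @export
autoplot.transition_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$lon, .data$lat, fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(other = "grey90",
                                          retained = "#1a9850",
                                          lost = "#d73027",
                                          new = "#4575b4"), drop = FALSE) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = sprintf("'%s' habitat transitions", object$focal))
}

#' Patch statistics of a focal class
#'
#' Connected components of the focal class under 4- (rook, default) or
#' 8-connectivity, quantifying habitat fragmentation by patch count and
#' size.
#'
#' @param cat A [category_grid].
#' @param focal Focal class name or code (default `"excellent"`).
#' @param connectivity 4 or 8.
#' @return A tibble with `n_patches`, `mean_patch_cells`, `max_patch_cells`
#'   (all 0 when the class is absent).
#' @export
patch_stats <- function(cat, focal = "excellent", connectivity = 4) {
  code <- if (is.character(focal)) match(focal, suitability_levels) - 1L else
    as.integer(focal)
  if (is.na(code) || code < 0 || code > 5) {
    abort(sprintf("Unknown focal class '%s'.", focal))
  }
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  m <- !is.na(cat$codes) & cat$codes == code
  nr <- nrow(m)
  nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  n_patch <- 0L
  sizes <- integer(0)
  offs <- if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(c(-1L, 0L, 1L), 3), rep(c(-1L, 0L, 1L), each = 3))[-5, ]
  }
  todo <- which(m & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    n_patch <- n_patch + 1L
    queue <- start
    lab[start] <- n_patch
    size <- 0L
    while (length(queue) > 0) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      r0 <- ((cell - 1L) %% nr) + 1L
      c0 <- ((cell - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offs))) {
        r1 <- r0 + offs[k, 1]
        c1 <- c0 + offs[k, 2]
        if (r1 >= 1L && r1 <= nr && c1 >= 1L && c1 <= nc &&
            m[r1, c1] && lab[r1, c1] == 0L) {
          lab[r1, c1] <- n_patch
          queue <- c(queue, (c1 - 1L) * nr + r1)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  tibble(
    n_patches = n_patch,
    mean_patch_cells = if (n_patch > 0) mean(sizes) else 0,
    max_patch_cells = if (n_patch > 0) max(sizes) else 0
  )
}
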