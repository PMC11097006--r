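#' Specify a synthetic bioclimatic raster stack
#'
#' Describes a stack of spatially smooth, cross-correlated climate layers on a
#' regular lon/lat grid. Each layer is generated as
#' `mean + sd * field`, where `field` is a standard normal random field:
#' i.i.d. cell noise is first mixed across variables by a square-root factor
#' of `correlation`, then smoothed with a uniform moving average of radius
#' `smoothness` (edge-truncated) and rescaled back to unit sample variance so
#' the marginal mean/sd calibration survives smoothing.
#'
#' @param variables A data frame with columns `name`, `mean`, `sd` (native
#'   units of each bioclimatic variable).
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param origin_lon,origin_lat North-west corner, decimal degrees.
#' @param cell_size Cell size in decimal degrees.
#' @param correlation Symmetric positive-semidefinite matrix with unit
#'   diagonal giving the cross-variable correlation of the generating fields.
#'   Defaults to the identity.
#' @param smoothness Integer radius (in cells) of the spatial moving-average
#'   smoother; 0 disables smoothing.
#' @param seed Integer seed making the stack reproducible.
#'
#' @return A `synthetic_climate_spec` list.
#' @seealso [make_climate_stack()], [default_climate_spec()]
#' @export
synthetic_climate_spec <- function(variables, n_rows, n_cols,
                                   origin_lon = 98.5, origin_lat = 40.4,
                                   cell_size = 0.125,
                                   correlation = NULL, smoothness = 0L,
                                   seed = 1L) {
  variables <- as_tibble(variables)
  if (!all(c("name", "mean", "sd") %in% names(variables))) {
    abort("`variables` needs columns name, mean, sd.")
  }
  if (anyDuplicated(variables$name)) abort("Variable names must be unique.")
  if (any(variables$sd < 0)) abort("Variable `sd` must be >= 0.")
  if (n_rows < 1 || n_cols < 1) abort("`n_rows` and `n_cols` must be >= 1.")
  if (cell_size <= 0) abort("`cell_size` must be > 0.")
  v <- nrow(variables)
  if (is.null(correlation)) correlation <- diag(v)
  correlation <- as.matrix(correlation)
  if (!identical(dim(correlation), c(v, v))) {
    abort("`correlation` must be square with one row per variable.")
  }
  if (max(abs(correlation - t(correlation))) > 1e-8) {
    abort("`correlation` matrix must be symmetric.")
  }
  if (max(abs(diag(correlation) - 1)) > 1e-8) {
    abort("`correlation` matrix must have unit diagonal.")
  }
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    abort("`correlation` matrix is not positive semidefinite.")
  }
  structure(
    list(variables = variables, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), origin_lon = origin_lon,
         origin_lat = origin_lat, cell_size = cell_size,
         correlation = correlation, smoothness = as.integer(smoothness),
         seed = as.integer(seed)),
    class = "synthetic_climate_spec"
  )
}

#' Default synthetic scenario: six selected bioclimatic variables
#'
#' The default stack emulates the variable set retained after collinearity
#' pruning in east-central China analyses: bio6 (min temperature of the
#' coldest month, degC), bio8 (mean temperature of the wettest quarter, degC),
#' bio10 (mean temperature of the warmest quarter, degC), bio11 (mean
#' temperature of the coldest quarter, degC), bio12 (annual precipitation,
#' mm) and bio13 (precipitation of the wettest month, mm), with means and
#' spreads matching published occurrence-site summaries for the first five
#' and a realistic monsoon-climate value for bio13. Cross-correlations come
#' from a three-factor model (winter temperature, summer temperature,
#' precipitation), which is positive semidefinite by construction.
#'
#' @param n_rows,n_cols Grid dimensions, default 120 x 120.
#' @param seed Seed, default 20240516.
#' @param smoothness Smoothing radius in cells, default 2.
#' @return A [synthetic_climate_spec()].
#' @export
default_climate_spec <- function(n_rows = 120L, n_cols = 120L,
                                 seed = 20240516L, smoothness = 2L) {
  vars <- tibble(
    name = c("bio6", "bio8", "bio10", "bio11", "bio12", "bio13"),
    mean = c(-1.7, 23.6, 25.3, 3.6, 1113.2, 190),
    sd   = c(4.0, 2.5, 1.9, 3.3, 369.4, 70)
  )
  # factor loadings: winter temperature, summer temperature, precipitation
  L <- rbind(
    bio6  = c(0.90, 0.10, 0.15),
    bio8  = c(0.30, 0.80, 0.10),
    bio10 = c(0.20, 0.85, 0.00),
    bio11 = c(0.92, 0.15, 0.10),
    bio12 = c(0.45, 0.20, 0.75),
    bio13 = c(0.40, 0.25, 0.80)
  )
  C <- L %*% t(L)
  diag(C) <- 1
  synthetic_climate_spec(vars, n_rows = n_rows, n_cols = n_cols,
                         correlation = C, smoothness = smoothness,
                         seed = seed)
}

# Symmetric square root of a PSD matrix (negative round-off clipped to 0).
psd_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C)) %*% t(e$vectors)
}

# Uniform moving-average smoothing over a (2r+1)^2 window, edge-truncated.
# The rectangular window makes the filter separable even at the edges.
box_smooth <- function(m, r) {
  if (r <= 0) return(m)
  band <- function(n) {
    w <- outer(seq_len(n), seq_len(n), function(i, j) as.numeric(abs(i - j) <= r))
    w / rowSums(w)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate a synthetic climate stack
#'
#' @param spec A [synthetic_climate_spec()].
#' @return A [climate_stack()] with one layer per specified variable,
#'   bit-identical across calls with the same spec (including seed).
#' @export
#' @examples
#' st <- make_climate_stack(default_climate_spec(n_rows = 40, n_cols = 40))
#' st
make_climate_stack <- function(spec) {
  if (!inherits(spec, "synthetic_climate_spec")) {
    abort("`spec` must be a synthetic_climate_spec.")
  }
  v <- nrow(spec$variables)
  ncell <- spec$n_rows * spec$n_cols
  Z <- with_seed(spec$seed, matrix(rnorm(ncell * v), ncell, v))
  X <- Z %*% psd_sqrt(spec$correlation)
  layers <- vector("list", v)
  for (k in seq_len(v)) {
    f <- matrix(X[, k], spec$n_rows, spec$n_cols)
    if (spec$smoothness > 0) {
      f <- box_smooth(f, spec$smoothness)
      s <- sd(as.vector(f))
      if (s > 0) f <- f / s  # restore unit variance lost to smoothing
    }
    layers[[k]] <- spec$variables$mean[k] + spec$variables$sd[k] * f
  }
  names(layers) <- spec$variables$name
  climate_stack(layers, spec$origin_lon, spec$origin_lat, spec$cell_size)
}

#' Shift a stack into a future scenario
#'
#' Applies a per-variable additive change to every cell, standing in for a
#' downscaled future-climate projection (e.g. a doubled-CO2 scenario).
#' Georeference and nodata cells are preserved.
#'
#' @param current A [climate_stack()].
#' @param deltas Named numeric vector of additive shifts; names must be
#'   existing variables. Variables not named are left unchanged.
#' @return A [climate_stack()].
#' @export
make_future_stack <- function(current, deltas) {
  unknown <- setdiff(names(deltas), stack_vars(current))
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown variable(s) in `deltas`: %s. Valid names: %s.",
      paste(unknown, collapse = ", "),
      paste(stack_vars(current), collapse = ", ")))
  }
  layers <- current$layers
  for (v in names(deltas)) layers[[v]] <- layers[[v]] + deltas[[v]]
  climate_stack(layers, current$origin_lon, current$origin_lat,
                current$cell_size)
}

#' Default future-scenario shifts
#'
#' A warming-plus-wetting shift typical of doubled-CO2 projections for
#' east-central China: +2.5 degC on winter temperatures, +2 degC on summer
#' temperatures, +5% of the mean on precipitation totals.
#'
#' @return Named numeric vector of per-variable deltas for the
#'   [default_climate_spec()] variable set.
#' @export
default_future_deltas <- function() {
  c(bio6 = 2.5, bio8 = 2.0, bio10 = 2.0, bio11 = 2.5,
    bio12 = 0.05 * 1113.2, bio13 = 0.05 * 190)
}

#' Specify the true presence envelope of a virtual species
#'
#' Ground truth for envelope-recovery tests: cells whose values fall inside
#' the per-variable box receive `inside_weight`, others `outside_weight`.
#'
#' @param lower,upper Named numeric vectors of per-variable bounds (native
#'   units); names must match and `lower <= upper` per variable.
#' @param inside_weight Sampling weight inside the box (> 0).
#' @param outside_weight Weight outside (>= 0, default 0).
#' @return A `true_envelope_spec` list.
#' @export
true_envelope_spec <- function(lower, upper, inside_weight = 1,
                               outside_weight = 0) {
  if (!identical(sort(names(lower)), sort(names(upper)))) {
    abort("`lower` and `upper` must have matching variable names.")
  }
  upper <- upper[names(lower)]
  if (any(lower > upper)) abort("Each `lower` bound must be <= its `upper`.")
  if (inside_weight <= 0) abort("`inside_weight` must be > 0.")
  if (outside_weight < 0) abort("`outside_weight` must be >= 0.")
  structure(list(lower = lower, upper = upper, inside_weight = inside_weight,
                 outside_weight = outside_weight),
            class = "true_envelope_spec")
}

#' Default true envelope for the synthetic scenario
#'
#' One standard deviation around each variable's specified mean, i.e. the
#' climatic core of the simulated species' range.
#'
#' @param spec A [synthetic_climate_spec()], default [default_climate_spec()].
#' @param half_width Box half-width in units of each variable's sd.
#' @return A [true_envelope_spec()].
#' @export
default_envelope <- function(spec = default_climate_spec(), half_width = 1) {
  lo <- setNames(spec$variables$mean - half_width * spec$variables$sd,
                 spec$variables$name)
  hi <- setNames(spec$variables$mean + half_width * spec$variables$sd,
                 spec$variables$name)
  true_envelope_spec(lo, hi)
}

#' Sample virtual occurrence records from a stack
#'
#' Draws `n` distinct cells without replacement with probability proportional
#' to the envelope weight, and places one record at each sampled cell's
#' centre. Each record carries its cell's environmental values so tests can
#' verify extraction round-trips exactly.
#'
#' @param stack A [climate_stack()].
#' @param env A [true_envelope_spec()]; its variable names must exist in the
#'   stack.
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @return An occurrence table (see [read_occurrences()]) with extra columns
#'   holding the generating cell values of every stack variable.
#' @export
sample_occurrences <- function(stack, env, n, seed = 1L) {
  if (n < 1) abort("`n` must be >= 1.")
  missing_vars <- setdiff(names(env$lower), stack_vars(stack))
  if (length(missing_vars) > 0) {
    abort(sprintf("Envelope variable(s) not in stack: %s.",
                  paste(missing_vars, collapse = ", ")))
  }
  inside <- !nodata_mask(stack)
  for (v in names(env$lower)) {
    lay <- stack$layers[[v]]
    inside <- inside & !is.na(lay) & lay >= env$lower[[v]] & lay <= env$upper[[v]]
  }
  w <- ifelse(inside, env$inside_weight, env$outside_weight)
  w[as.vector(nodata_mask(stack))] <- 0
  if (all(w == 0)) abort("no habitable cells")
  eligible <- sum(w > 0)
  if (n > eligible) {
    abort(sprintf(
      "Cannot draw %d occurrences without replacement: only %d cells have positive weight.",
      n, eligible))
  }
  idx <- with_seed(seed, sample.int(length(w), n, replace = FALSE, prob = w))
  d <- dim(stack)
  row <- ((idx - 1L) %% d[1]) + 1L
  col <- ((idx - 1L) %/% d[1]) + 1L
  vals <- purrr::map(stack$layers, ~ .x[cbind(row, col)])
  occ <- dplyr::bind_cols(
    tibble(
      id = sprintf("syn_%04d", seq_len(n)),
      lon = cell_center_lon(stack, col),
      lat = cell_center_lat(stack, row),
      elevation = NA_real_,
      label = NA_character_
    ),
    as_tibble(vals)
  )
  new_occurrence_tbl(occ, provenance = list(raw = n, rejected = 0L,
                                            thinned = 0L))
}
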