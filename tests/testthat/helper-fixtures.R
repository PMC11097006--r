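# Small in-code fixtures shared across the suite.

# A stack built directly from matrices (row 1 = north), default georef
# 1-degree cells with NW corner (100 E, 40 N).
tiny_stack <- function(..., origin_lon = 100, origin_lat = 40, cell_size = 1) {
  climate_stack(list(...), origin_lon = origin_lon, origin_lat = origin_lat,
                cell_size = cell_size)
}

# Constant single-layer stack.
const_stack <- function(value = 7, nr = 4, nc = 5, name = "bio1", ...) {
  args <- list(matrix(value, nr, nc))
  names(args) <- name
  do.call(tiny_stack, c(args, list(...)))
}

occ_table <- function(lon, lat, elevation = NA_real_, label = NA_character_,
                      id = NULL) {
  df <- tibble::tibble(lon = lon, lat = lat, elevation = elevation,
                       label = label)
  if (!is.null(id)) df$id <- id
  read_occurrences(df)
}

# A quick two-variable spec for generator tests.
pair_spec <- function(rho, n = 100, smoothness = 0, seed = 42) {
  synthetic_climate_spec(
    data.frame(name = c("a", "b"), mean = c(0, 10), sd = c(1, 2)),
    n_rows = n, n_cols = n,
    correlation = matrix(c(1, rho, rho, 1), 2, 2),
    smoothness = smoothness, seed = seed
  )
}

# A one-row suitability grid from a score vector, for classifier tests.
new_grid_for_tests <- function(vals, model) {
  nichebox:::new_suitability_grid(
    matrix(vals, nrow = 1),
    list(origin_lon = 0, origin_lat = 1, cell_size = 1),
    model
  )
}

# Construct a numeric vector of length n with exactly this sample mean and
# sample sd (n - 1 denominator), used to rebuild printed summary rows.
vector_with_moments <- function(n, mean, sd, seed = 1) {
  z <- withr::with_seed(seed, rnorm(n))
  z <- as.vector(scale(z))  # exact mean 0, sample sd 1
  mean + sd * z
}
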