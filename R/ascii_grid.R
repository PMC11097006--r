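# ESRI ASCII grid reader/writer. No raster package is a dependency of this
# package, so the lowest-common-denominator interchange format is implemented
# directly: a 6-line header (ncols/nrows/xllcorner/yllcorner/cellsize/
# NODATA_value) followed by nrows whitespace-separated rows, north first.

#' Read and write ESRI ASCII grids
#'
#' `write_ascii_grid()`/`read_ascii_grid()` handle a single layer;
#' `write_ascii_stack()` writes one `.asc` file per variable into a directory
#' and `read_ascii_stack()` reassembles them into a [climate_stack()].
#'
#' @param path File path of a single `.asc` grid.
#' @param grid A numeric matrix (row 1 = north) to write.
#' @param origin_lon,origin_lat North-west corner in decimal degrees.
#' @param cell_size Cell size in decimal degrees.
#' @param nodata Value written for `NA` cells (default -9999).
#' @return `read_ascii_grid()` returns a list with `grid`, `origin_lon`,
#'   `origin_lat`, `cell_size`; `read_ascii_stack()` returns a
#'   [climate_stack()]; the writers return their path(s) invisibly.
#' @export
write_ascii_grid <- function(grid, path, origin_lon, origin_lat, cell_size,
                             nodata = -9999) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  header <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", origin_lon),
    sprintf("yllcorner %.10g", origin_lat - nr * cell_size),
    sprintf("cellsize %.10g", cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  g <- grid
  g[is.na(g)] <- nodata
  body <- apply(g, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]])) {
      abort(sprintf("ASCII grid '%s' is missing header field '%s'.", path, key))
    }
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    abort(sprintf("ASCII grid '%s': expected %d values, found %d.",
                  path, nr * nc, length(vals)))
  }
  g <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) g[g == hdr$nodata_value] <- NA_real_
  list(
    grid = g,
    origin_lon = hdr$xllcorner,
    origin_lat = hdr$yllcorner + nr * hdr$cellsize,
    cell_size = hdr$cellsize
  )
}

#' @rdname write_ascii_grid
#' @param stack A [climate_stack()].
#' @param dir Directory receiving/holding one `<variable>.asc` per layer.
#' @param variables For `read_ascii_stack()`: variable names to read; defaults
#'   to every `.asc` file found in `dir`.
#' @export
write_ascii_stack <- function(stack, dir, nodata = -9999) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(stack_vars(stack), function(v) {
    write_ascii_grid(stack$layers[[v]], file.path(dir, paste0(v, ".asc")),
                     stack$origin_lon, stack$origin_lat, stack$cell_size,
                     nodata = nodata)
  }, character(1))
  invisible(paths)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_stack <- function(dir, variables = NULL) {
  if (is.null(variables)) {
    files <- list.files(dir, pattern = "\\.asc$")
    variables <- sub("\\.asc$", "", files)
  }
  if (length(variables) == 0L) {
    abort(sprintf("No .asc grids found in '%s'.", dir))
  }
  reads <- lapply(variables, function(v) {
    read_ascii_grid(file.path(dir, paste0(v, ".asc")))
  })
  first <- reads[[1]]
  layers <- setNames(lapply(reads, `[[`, "grid"), variables)
  climate_stack(layers, first$origin_lon, first$origin_lat, first$cell_size)
}
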