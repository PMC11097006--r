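#' Occurrence tables
#'
#' An `occurrence_tbl` is a tibble of presence records with columns `id`,
#' `lon`, `lat` (WGS84 decimal degrees), `elevation` (metres, may be `NA`)
#' and `label` (free admin text, may be `NA`), plus a provenance attribute
#' counting raw, rejected and thinned records.
#'
#' @name occurrence_tbl
NULL

new_occurrence_tbl <- function(df, provenance = list(raw = nrow(df),
                                                     rejected = 0L,
                                                     thinned = 0L)) {
  df <- as_tibble(df)
  structure(df, provenance = provenance,
            class = c("occurrence_tbl", class(df)))
}

#' Provenance counts of an occurrence table
#' @param occ An occurrence table.
#' @return Named list with `raw`, `rejected`, `thinned` counts.
#' @export
provenance <- function(occ) attr(occ, "provenance")

#' Read presence records from a delimited text file
#'
#' Rows with unparsable or out-of-range coordinates (|lon| > 180, |lat| > 90,
#' non-finite elevation) are dropped and counted in the provenance rather
#' than raising an error; missing required columns or duplicated ids do
#' raise.
#'
#' @param source Path to a delimited text file with a header, or a data
#'   frame. Comma and tab delimiters are auto-detected for files.
#' @param lon_col,lat_col,elevation_col,label_col,id_col Column names to use.
#'   `elevation`, `label` and `id` are optional; ids are auto-generated when
#'   absent.
#' @return An [occurrence_tbl].
#' @export
#' @examples
#' df <- data.frame(lon = c(110, 115), lat = c(30, 35))
#' read_occurrences(df)
read_occurrences <- function(source, lon_col = "lon", lat_col = "lat",
                             elevation_col = "elevation", label_col = "label",
                             id_col = "id") {
  if (is.character(source) && length(source) == 1L) {
    df <- readr::read_delim(source, delim = NULL, show_col_types = FALSE,
                            progress = FALSE)
  } else {
    df <- as_tibble(source)
  }
  missing_cols <- setdiff(c(lon_col, lat_col), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  n_raw <- nrow(df)
  out <- tibble(
    id = if (id_col %in% names(df)) as.character(df[[id_col]]) else
      sprintf("occ_%04d", seq_len(n_raw)),
    lon = suppressWarnings(as.numeric(df[[lon_col]])),
    lat = suppressWarnings(as.numeric(df[[lat_col]])),
    elevation = if (elevation_col %in% names(df))
      suppressWarnings(as.numeric(df[[elevation_col]])) else NA_real_,
    label = if (label_col %in% names(df)) as.character(df[[label_col]]) else
      NA_character_
  )
  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicated occurrence id(s): %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  ok <- is.finite(out$lon) & is.finite(out$lat) &
    out$lon >= -180 & out$lon <= 180 & out$lat >= -90 & out$lat <= 90 &
    (is.na(out$elevation) | is.finite(out$elevation))
  new_occurrence_tbl(out[ok, , drop = FALSE],
                     provenance = list(raw = n_raw,
                                       rejected = as.integer(sum(!ok)),
                                       thinned = 0L))
}

#' Write an occurrence table to delimited text
#' @param occ An [occurrence_tbl].
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path, delim = ",") {
  readr::write_delim(as_tibble(occ), path, delim = delim, na = "")
  invisible(path)
}

#' Thin presence records to one per grid cell
#'
#' Spatial thinning against the modelling grid: within each raster cell only
#' the first record (input order) is kept, reducing spatial autocorrelation
#' and duplicate sites the way county-level deduplication does in published
#' compilations. Idempotent.
#'
#' @param occ An [occurrence_tbl].
#' @param grid A [climate_stack()] supplying the georeference.
#' @return A thinned [occurrence_tbl]; provenance `thinned` is incremented by
#'   the number of removed records.
#' @export
thin_to_cells <- function(occ, grid) {
  loc <- locate_cells(grid, occ$lon, occ$lat)
  if (any(!loc$inside)) {
    bad <- which(!loc$inside)[1]
    abort(sprintf(
      "Occurrence '%s' at (%.4f, %.4f) falls outside the grid extent %s.",
      occ$id[bad], occ$lon[bad], occ$lat[bad], georef_string(grid)))
  }
  cell <- paste(loc$row, loc$col)
  keep <- !duplicated(cell)
  prov <- provenance(occ)
  prov$thinned <- prov$thinned + as.integer(sum(!keep))
  new_occurrence_tbl(occ[keep, , drop = FALSE], provenance = prov)
}

#' Altitudinal class composition of the records
#'
#' Percentages of records in the four altitude classes low (< 800 m),
#' mid (800-1600 m), mid-high (1600-2400 m) and high (> 2400 m). Class
#' boundaries are half-open, lower-inclusive, so 800 m counts as mid.
#' Records without elevation are excluded from the denominator.
#'
#' @param occ An [occurrence_tbl] with at least one elevation value.
#' @param digits Decimal places for the percentages (default 1).
#' @return A tibble with columns `class`, `n`, `percent`.
#' @export
altitude_class_summary <- function(occ, digits = 1) {
  elev <- occ$elevation[!is.na(occ$elevation)]
  if (length(elev) == 0) abort("no elevation data")
  breaks <- c(-Inf, 800, 1600, 2400, Inf)
  labels <- c("low", "mid", "mid_high", "high")
  cls <- cut(elev, breaks = breaks, labels = labels, right = FALSE)
  counts <- as.integer(table(cls))
  tibble(
    class = factor(labels, levels = labels),
    n = counts,
    percent = round_half_away(100 * counts / length(elev), digits)
  )
}

#' Random train/test split of presence records
#'
#' Splits the records into a training and a validation subset at the given
#' fraction (default the conventional 70/30). The train size is
#' `n * train_fraction` rounded half away from zero; the split is a plain
#' random partition, reproducible per seed.
#'
#' @param occ An [occurrence_tbl] with at least 2 records.
#' @param train_fraction Proportion assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both [occurrence_tbl]s.
#' @export
split_train_test <- function(occ, train_fraction = 0.7, seed = 1L) {
  n <- nrow(occ)
  if (n < 2) abort("too few records to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  n_train <- as.integer(round_half_away(n * train_fraction))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample.int(n, n_train))
  prov <- provenance(occ)
  list(
    train = new_occurrence_tbl(occ[sort(idx), , drop = FALSE], prov),
    test = new_occurrence_tbl(occ[setdiff(seq_len(n), idx), , drop = FALSE],
                              prov)
  )
}

#' Geographic extent of the records
#'
#' @param occ A non-empty [occurrence_tbl].
#' @param digits Optional rounding of the bounds (default `NULL`: exact).
#' @return A tibble with one row: `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @export
extent_summary <- function(occ, digits = NULL) {
  if (nrow(occ) == 0) abort("Cannot summarise the extent of an empty table.")
  out <- tibble(
    lon_min = min(occ$lon), lon_max = max(occ$lon),
    lat_min = min(occ$lat), lat_max = max(occ$lat)
  )
  if (!is.null(digits)) out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(), ~ round_half_away(.x, digits)))
  out
}

#' @export
print.occurrence_tbl <- function(x, ...) {
  p <- provenance(x)
  cat(sprintf("<occurrence_tbl> %d record(s) (raw %d, rejected %d, thinned %d)\n",
              nrow(x), p$raw, p$rejected, p$thinned))
  NextMethod()
}
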