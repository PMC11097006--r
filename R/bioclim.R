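#' Fit a climatic percentile envelope (BIOCLIM)
#'
#' Stores, per variable, the sorted training values and the observed
#' min/max. Prediction scores a site by how central its values are within
#' the training distribution (see [bioclim_score()]); any value outside a
#' variable's observed range puts the site outside the envelope.
#'
#' @param train Environmental matrix from [extract_at_points()] (an optional
#'   `id` column is ignored).
#' @param min_rows Minimum number of training rows (default 5).
#' @return A `bioclim_envelope` with per-variable sorted values, `min`/`max`,
#'   and `n_train`. Constant training variables trigger a warning (they make
#'   the envelope a zero-width slab on that axis) but stay valid.
#' @export
#' @examples
#' env <- data.frame(bio12 = 1:100)
#' fit <- fit_bioclim(env)
#' bioclim_score(fit, c(bio12 = 50))
fit_bioclim <- function(train, min_rows = 5) {
  m <- env_values(as_tibble(train))
  if (nrow(m) < min_rows) {
    abort(sprintf("Need at least %d training rows, got %d.", min_rows, nrow(m)))
  }
  constant <- colnames(m)[apply(m, 2L, function(x) max(x) == min(x))]
  if (length(constant) > 0) {
    warn(sprintf("Constant training variable(s): %s.",
                 paste(constant, collapse = ", ")))
  }
  sorted <- lapply(seq_len(ncol(m)), function(j) sort(m[, j]))
  names(sorted) <- colnames(m)
  structure(
    list(sorted = sorted,
         min = vapply(sorted, min, numeric(1)),
         max = vapply(sorted, max, numeric(1)),
         variables = colnames(m),
         n_train = nrow(m)),
    class = "bioclim_envelope"
  )
}

#' @export
print.bioclim_envelope <- function(x, ...) {
  cat(sprintf("<bioclim_envelope> %d variable(s), %d training point(s)\n",
              length(x$variables), x$n_train))
  print(tibble(variable = x$variables, min = x$min, max = x$max))
  invisible(x)
}

#' @rdname fit_bioclim
#' @param x A `bioclim_envelope`.
#' @param ... Unused.
#' @export
tidy.bioclim_envelope <- function(x, ...) {
  tibble(variable = x$variables, min = unname(x$min), max = unname(x$max),
         n_train = x$n_train)
}

# Two-tailed percentile position of values `x` within sorted training values
# `sv`: p = (#less + 0.5 * #equal) / n, tail score min(p, 1 - p), and exactly
# 0 strictly outside [min, max]. Vectorised over x.
percentile_tail <- function(x, sv) {
  n <- length(sv)
  lt <- findInterval(x, sv, left.open = TRUE)   # count of sv <  x
  le <- findInterval(x, sv)                     # count of sv <= x
  p <- (lt + 0.5 * (le - lt)) / n
  s <- pmin(p, 1 - p)
  s[x < sv[1] | x > sv[n]] <- 0
  s
}

#' Score a site against a fitted envelope
#'
#' The suitability index is `100 * min` over variables of the two-tailed
#' percentile tail score: for variable v with value x, `p` is the mid-rank
#' fraction of training values below x and the tail score is `min(p, 1 - p)`.
#' The index is maximal (50) at the joint training median and exactly 0 when
#' any variable falls outside its observed training range.
#'
#' @param envelope A [fit_bioclim()] result.
#' @param x Named numeric vector covering every envelope variable.
#' @return A single score in \[0, 50\].
#' @export
bioclim_score <- function(envelope, x) {
  miss <- setdiff(envelope$variables, names(x))
  if (length(miss) > 0) {
    abort(sprintf("Missing variable(s) in `x`: %s.",
                  paste(miss, collapse = ", ")))
  }
  tails <- vapply(envelope$variables, function(v) {
    sv <- envelope$sorted[[v]]
    n <- length(sv)
    lt <- sum(sv < x[[v]])
    eq <- sum(sv == x[[v]])
    if (x[[v]] < sv[1] || x[[v]] > sv[n]) return(0)
    p <- (lt + 0.5 * eq) / n
    min(p, 1 - p)
  }, numeric(1))
  100 * min(tails)
}

#' Score every grid cell of a stack
#'
#' @param envelope A [fit_bioclim()] result.
#' @param stack A [climate_stack()] containing every envelope variable.
#' @return A [suitability_grid] tagged `"bioclim"`; nodata propagates.
#' @export
bioclim_predict_grid <- function(envelope, stack) {
  miss <- setdiff(envelope$variables, stack_vars(stack))
  if (length(miss) > 0) {
    abort(sprintf("Stack is missing layer(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  tails <- NULL
  for (v in envelope$variables) {
    s <- percentile_tail(as.vector(stack$layers[[v]]), envelope$sorted[[v]])
    tails <- if (is.null(tails)) s else pmin(tails, s)
  }
  scores <- matrix(100 * tails, nrow(stack$layers[[1]]), ncol(stack$layers[[1]]))
  scores[nodata_mask(stack)] <- NA_real_
  new_suitability_grid(scores, stack, "bioclim")
}

#' Classify suitability scores into the six bands
#'
#' For the envelope model the percentile-index bands are: unsuitable (score
#' 0), low (0-2.5\], medium (2.5-5\], high (5-10\], very high (10-20\] and
#' excellent (> 20); band edges are upper-inclusive. For the similarity
#' model the confidence thresholds are: unsuitable below 90, then
#' lower-inclusive bands \[90, 92), \[92, 94), \[94, 96), \[96, 98) and
#' \[98, 100\].
#'
#' @param scores A [suitability_grid] carrying the matching model tag.
#' @return A [category_grid] with codes 0..5.
#' @export
classify_bioclim <- function(scores) {
  if (!inherits(scores, "suitability_grid") || scores$model != "bioclim") {
    abort("wrong model tag: `scores` must be a bioclim-tagged suitability_grid")
  }
  s <- scores$scores
  codes <- matrix(NA_integer_, nrow(s), ncol(s))
  ok <- !is.na(s)
  v <- s[ok]
  codes[ok] <- ifelse(v <= 0, 0L,
               ifelse(v <= 2.5, 1L,
               ifelse(v <= 5, 2L,
               ifelse(v <= 10, 3L,
               ifelse(v <= 20, 4L, 5L)))))
  new_category_grid(codes, scores, "bioclim")
}
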