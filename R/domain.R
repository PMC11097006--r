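#' Fit a Gower-similarity reference (DOMAIN)
#'
#' Stores the training points and the per-variable range (max - min over the
#' training points only). Prediction scores a site by its range-standardised
#' Gower similarity to the most similar training point: distance is the mean
#' over variables of `|x_v - t_v| / range_v` and the similarity is
#' `100 * (1 - min distance)`; 100 means identical to some training point,
#' values are unbounded below and not floored.
#'
#' @param train Environmental matrix (an optional `id` column is ignored)
#'   with at least 1 row.
#' @return A `domain_reference`.
#' @export
#' @examples
#' env <- data.frame(bio12 = c(0, 10))
#' ref <- fit_domain(env)
#' domain_similarity(ref, c(bio12 = 5))
fit_domain <- function(train) {
  m <- env_values(as_tibble(train))
  if (nrow(m) < 1) abort("Need at least 1 training row.")
  structure(
    list(points = m,
         range = apply(m, 2L, function(x) max(x) - min(x)),
         variables = colnames(m)),
    class = "domain_reference"
  )
}

#' @export
print.domain_reference <- function(x, ...) {
  cat(sprintf("<domain_reference> %d training point(s), %d variable(s)\n",
              nrow(x$points), length(x$variables)))
  print(tibble(variable = x$variables, range = unname(x$range)))
  invisible(x)
}

# Gower distance contributions for one variable, vectorised over x.
# A zero training range makes the variable a match/mismatch indicator:
# contribution 0 when x equals the constant, else 1 (the |d|/r -> 0/1 limit).
gower_contrib <- function(x, t_v, r_v) {
  if (r_v == 0) as.numeric(x != t_v) else abs(x - t_v) / r_v
}

#' Gower similarity of a site to the reference
#'
#' @param ref A [fit_domain()] result.
#' @param x Named numeric vector covering every reference variable.
#' @return Similarity (<= 100, may be negative; 100 iff `x` coincides with a
#'   training point on every variable).
#' @export
domain_similarity <- function(ref, x) {
  miss <- setdiff(ref$variables, names(x))
  if (length(miss) > 0) {
    abort(sprintf("Missing variable(s) in `x`: %s.",
                  paste(miss, collapse = ", ")))
  }
  d <- apply(ref$points, 1L, function(t) {
    mean(vapply(ref$variables,
                function(v) gower_contrib(x[[v]], t[[v]], ref$range[[v]]),
                numeric(1)))
  })
  100 * (1 - min(d))
}

#' Score every grid cell of a stack by Gower similarity
#'
#' Exact nearest-training-point search (full scan).
#'
#' @param ref A [fit_domain()] result.
#' @param stack A [climate_stack()] containing every reference variable.
#' @return A [suitability_grid] tagged `"domain"`; nodata propagates.
#' @export
domain_predict_grid <- function(ref, stack) {
  miss <- setdiff(ref$variables, stack_vars(stack))
  if (length(miss) > 0) {
    abort(sprintf("Stack is missing layer(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  nv <- length(ref$variables)
  vals <- lapply(ref$variables, function(v) as.vector(stack$layers[[v]]))
  names(vals) <- ref$variables
  best <- rep(Inf, length(vals[[1]]))
  for (i in seq_len(nrow(ref$points))) {
    acc <- 0
    for (v in ref$variables) {
      acc <- acc + gower_contrib(vals[[v]], ref$points[i, v], ref$range[[v]])
    }
    best <- pmin(best, acc / nv)
  }
  scores <- matrix(100 * (1 - best), nrow(stack$layers[[1]]),
                   ncol(stack$layers[[1]]))
  scores[nodata_mask(stack)] <- NA_real_
  new_suitability_grid(scores, stack, "domain")
}

#' @rdname classify_bioclim
#' @export
classify_domain <- function(scores) {
  if (!inherits(scores, "suitability_grid") || scores$model != "domain") {
    abort("wrong model tag: `scores` must be a domain-tagged suitability_grid")
  }
  s <- scores$scores
  codes <- matrix(NA_integer_, nrow(s), ncol(s))
  ok <- !is.na(s)
  v <- s[ok]
  codes[ok] <- ifelse(v < 90, 0L,
               ifelse(v < 92, 1L,
               ifelse(v < 94, 2L,
               ifelse(v < 96, 3L,
               ifelse(v < 98, 4L, 5L)))))
  new_category_grid(codes, scores, "domain")
}
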