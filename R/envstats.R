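#' Extract environmental values at occurrence points
#'
#' Looks up the value of every stack layer in the cell containing each
#' record. Records falling in nodata cells (in any layer) are dropped; the
#' number dropped is recorded in the `"dropped_nodata"` attribute.
#'
#' @param stack A [climate_stack()].
#' @param occ An [occurrence_tbl]; all points must lie inside the stack
#'   extent.
#' @return A tibble (the environmental matrix) with column `id` plus one
#'   numeric column per stack variable.
#' @export
extract_at_points <- function(stack, occ) {
  loc <- locate_cells(stack, occ$lon, occ$lat)
  if (any(!loc$inside)) {
    bad <- which(!loc$inside)[1]
    abort(sprintf(
      "Occurrence '%s' at (%.4f, %.4f) falls outside the stack extent %s.",
      occ$id[bad], occ$lon[bad], occ$lat[bad], georef_string(stack)))
  }
  idx <- cbind(loc$row, loc$col)
  vals <- purrr::map(stack$layers, ~ .x[idx])
  env <- dplyr::bind_cols(tibble(id = occ$id), as_tibble(vals))
  complete <- stats::complete.cases(env)
  out <- env[complete, , drop = FALSE]
  attr(out, "dropped_nodata") <- as.integer(sum(!complete))
  out
}

env_values <- function(env) {
  as.matrix(env[, setdiff(names(env), "id"), drop = FALSE])
}

#' Descriptive statistics of the environmental matrix
#'
#' Per-variable minimum, maximum, mean, sample standard deviation (n - 1),
#' coefficient of variation `cv = 100 * sd / |mean|`, and the normal 95%
#' confidence interval of the mean `mean -/+ 1.96 * sd / sqrt(n)`. With a
#' zero mean and positive spread the cv is undefined and reported as `NA`.
#'
#' @param env Environmental matrix from [extract_at_points()] (or any data
#'   frame of numeric columns, an optional `id` column is ignored). Needs at
#'   least 2 rows.
#' @param digits Decimal places for the reported columns (default 1,
#'   `NULL` for unrounded values).
#' @return A tibble with columns `variable`, `n`, `min`, `max`, `mean`, `sd`,
#'   `cv`, `ci95_low`, `ci95_high`.
#' @export
#' @examples
#' env <- data.frame(bio12 = c(800, 1000, 1200, 1400))
#' descriptive_stats(env)
descriptive_stats <- function(env, digits = 1) {
  m <- env_values(as_tibble(env))
  if (nrow(m) < 2) abort("Need at least 2 rows for descriptive statistics.")
  n <- nrow(m)
  stats_one <- function(x) {
    mu <- mean(x)
    s <- sd(x)
    half <- 1.96 * s / sqrt(n)
    cv <- if (mu == 0 && s > 0) NA_real_ else if (s == 0) 0 else 100 * s / abs(mu)
    c(min = min(x), max = max(x), mean = mu, sd = s, cv = cv,
      ci95_low = mu - half, ci95_high = mu + half)
  }
  res <- t(apply(m, 2L, stats_one))
  out <- dplyr::bind_cols(tibble(variable = colnames(m), n = n),
                          as_tibble(res))
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      c("min", "max", "mean", "sd", "cv", "ci95_low", "ci95_high"),
      ~ round_half_away(.x, digits)))
  }
  out
}

# VIF of one variable against the remaining columns, via ordinary least
# squares. R^2 within 1e-12 of 1 (perfect collinearity) maps to the 1e12
# sentinel so the greedy removal loop stays total.
vif_one <- function(m, j) {
  if (ncol(m) == 1L) return(1)
  y <- m[, j]
  X <- m[, -j, drop = FALSE]
  fit <- lm(y ~ X)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  if (r2 >= 1 - 1e-12) 1e12 else 1 / (1 - r2)
}

#' Stepwise variance-inflation-factor variable pruning
#'
#' Iteratively computes the VIF of every remaining variable (`1 / (1 - R^2)`
#' from regressing it on the others) and removes the variable with the
#' largest VIF while any VIF is at or above the threshold; variables tied at
#' the maximum are resolved by dropping the one later in column order.
#' Perfectly collinear variables get a `1e12` sentinel VIF and are removed
#' like any other.
#'
#' @param env Environmental matrix with at least 3 variables and more rows
#'   than variables.
#' @param threshold Removal threshold; the conventional cutoff of 5 keeps
#'   only variables with VIF < 5.
#' @return A `vif_report` with elements `kept` (character), `dropped`
#'   (tibble of variable + VIF at removal) and `rounds` (tibble of round,
#'   variable, vif, dropped flag). `tidy()` returns the rounds table.
#' @export
vif_stepwise <- function(env, threshold = 5) {
  m <- env_values(as_tibble(env))
  if (ncol(m) < 3) abort("Need at least 3 variables for stepwise VIF.")
  if (nrow(m) <= ncol(m)) abort("Need more rows than variables for VIF.")
  rounds <- list()
  dropped <- list()
  r <- 0L
  repeat {
    r <- r + 1L
    vifs <- vapply(seq_len(ncol(m)), function(j) vif_one(m, j), numeric(1))
    worst <- max(vifs)
    # ties at the maximum: drop the later column
    j_drop <- max(which(vifs == worst))
    drop_now <- worst >= threshold && ncol(m) > 1
    rounds[[r]] <- tibble(
      round = r, variable = colnames(m), vif = vifs,
      dropped = drop_now & seq_len(ncol(m)) == j_drop
    )
    if (!drop_now) break
    dropped[[length(dropped) + 1L]] <- tibble(
      variable = colnames(m)[j_drop], vif = worst)
    m <- m[, -j_drop, drop = FALSE]
  }
  structure(
    list(kept = colnames(m),
         dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
           tibble(variable = character(), vif = numeric()),
         rounds = dplyr::bind_rows(rounds),
         threshold = threshold),
    class = "vif_report"
  )
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("<vif_report> threshold %g: kept %d variable(s), dropped %d\n",
              x$threshold, length(x$kept), nrow(x$dropped)))
  cat("  kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped) > 0) {
    cat("  dropped (in order):",
        paste(sprintf("%s (VIF %.2f)", x$dropped$variable, x$dropped$vif),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname vif_stepwise
#' @param x A `vif_report`.
#' @param ... Unused.
#' @export
tidy.vif_report <- function(x, ...) x$rounds

#' @rdname vif_stepwise
#' @export
glance.vif_report <- function(x, ...) {
  tibble(n_kept = length(x$kept), n_dropped = nrow(x$dropped),
         threshold = x$threshold, max_vif_kept = {
           last <- dplyr::filter(x$rounds, .data$round == max(.data$round))
           max(last$vif)
         })
}

#' Principal component analysis of the environmental matrix
#'
#' Eigen-decomposition of the correlation matrix (covariance when
#' `standardize = FALSE`; correlation is the default because bioclimatic
#' variables mix degC, mm and dimensionless seasonality). Components are
#' ordered by descending eigenvalue; each loading column is sign-fixed so
#' its largest-magnitude entry is positive.
#'
#' @param env Environmental matrix with >= 2 variables and >= 3 rows.
#' @param standardize Use the correlation matrix (default) instead of the
#'   covariance matrix.
#' @return An `env_pca` with `eigenvalues`, `proportion` (percent of variance
#'   per component) and `loadings` (variable x component matrix, unit-length
#'   columns). `tidy()` gives long-format loadings; `glance()` the variance
#'   table.
#' @export
pca_env <- function(env, standardize = TRUE) {
  m <- env_values(as_tibble(env))
  if (ncol(m) < 2) abort("Need at least 2 variables for PCA.")
  if (nrow(m) < 3) abort("Need at least 3 rows for PCA.")
  if (standardize) {
    sds <- apply(m, 2L, sd)
    zero <- colnames(m)[sds == 0]
    if (length(zero) > 0) {
      abort(sprintf("Zero-variance column(s) cannot be standardized: %s.",
                    paste(zero, collapse = ", ")))
    }
    S <- cor(m)
  } else {
    S <- var(m)
  }
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors
  # sign convention: largest-magnitude loading positive in every column
  for (k in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
  }
  dimnames(L) <- list(colnames(m), paste0("PC", seq_len(ncol(L))))
  structure(
    list(eigenvalues = ev, proportion = 100 * ev / sum(ev), loadings = L,
         standardize = standardize, n = nrow(m)),
    class = "env_pca"
  )
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("<env_pca> %d components (%s matrix)\n", length(x$eigenvalues),
              if (x$standardize) "correlation" else "covariance"))
  print(tibble(component = paste0("PC", seq_along(x$eigenvalues)),
               eigenvalue = round(x$eigenvalues, 3),
               percent_variance = round(x$proportion, 2)), n = 5)
  invisible(x)
}

#' @rdname pca_env
#' @param x An `env_pca`.
#' @param ... Unused.
#' @export
tidy.env_pca <- function(x, ...) {
  as_tibble(x$loadings, rownames = "variable") %>%
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @rdname pca_env
#' @export
glance.env_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         percent_variance = x$proportion,
         cumulative_percent = cumsum(x$proportion))
}
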