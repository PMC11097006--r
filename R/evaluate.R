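#' Sample background (pseudo-absence) cells
#'
#' Draws `n` distinct non-nodata cells uniformly at random, excluding every
#' cell that contains a presence record, and extracts their environmental
#' values. Presence-only models need such a background sample for ROC/AUC
#' validation.
#'
#' @param stack A [climate_stack()].
#' @param exclude An [occurrence_tbl] of presence records to exclude.
#' @param n Number of background cells.
#' @param seed Integer seed.
#' @return A tibble like [extract_at_points()] output (`id` column
#'   `bg_<row>_<col>`), plus `lon`/`lat` attributes-free coordinate columns.
#' @export
sample_background <- function(stack, exclude, n, seed = 1L) {
  d <- dim(stack)
  eligible <- !nodata_mask(stack)
  if (nrow(exclude) > 0) {
    loc <- locate_cells(stack, exclude$lon, exclude$lat)
    inb <- loc$inside
    eligible[cbind(loc$row[inb], loc$col[inb])] <- FALSE
  }
  idx_pool <- which(as.vector(eligible))
  if (n > length(idx_pool)) {
    abort(sprintf(
      "Requested %d background cells but only %d are eligible (non-nodata, non-presence).",
      n, length(idx_pool)))
  }
  idx <- if (n == length(idx_pool)) idx_pool else
    with_seed(seed, sample(idx_pool, n))
  row <- ((idx - 1L) %% d[1]) + 1L
  col <- ((idx - 1L) %/% d[1]) + 1L
  vals <- purrr::map(stack$layers, ~ .x[cbind(row, col)])
  dplyr::bind_cols(
    tibble(id = sprintf("bg_%d_%d", row, col),
           lon = cell_center_lon(stack, col),
           lat = cell_center_lat(stack, row)),
    as_tibble(vals)
  )
}

#' Rank-based AUC of presence versus background scores
#'
#' The Mann-Whitney statistic with mid-rank tie handling: the probability
#' that a random presence site outscores a random background site, ties
#' counted half. 0.5 means the model is uninformative.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(3, 5), c(1, 4))  # 3 favourable of 4 pairs -> 0.75
auc <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0) abort("`presence_scores` is empty.")
  if (length(background_scores) == 0) abort("`background_scores` is empty.")
  np <- length(presence_scores)
  nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' AUC performance band
#'
#' The conventional five bands: fail \[0.5, 0.6), bad \[0.6, 0.7), fair
#' \[0.7, 0.8), good \[0.8, 0.9), excellent \[0.9, 1\]; edges are
#' lower-inclusive. Values below 0.5 (worse than random) also report "fail".
#'
#' @param mean_auc AUC value in \[0, 1\].
#' @return One of `"fail"`, `"bad"`, `"fair"`, `"good"`, `"excellent"`.
#' @export
auc_band <- function(mean_auc) {
  if (mean_auc < 0 || mean_auc > 1) abort("`mean_auc` must be in [0, 1].")
  if (mean_auc < 0.6) "fail"
  else if (mean_auc < 0.7) "bad"
  else if (mean_auc < 0.8) "fair"
  else if (mean_auc < 0.9) "good"
  else "excellent"
}

#' Replicated split-sample evaluation with grid averaging
#'
#' For each of `k` replicates: a fresh 70/30 (configurable) presence split
#' with seed `seed + replicate`, a model fit on the training subset, a
#' whole-grid prediction, and an AUC of the test-presence scores against a
#' fresh uniform background sample. The k prediction grids are averaged
#' cellwise into the final suitability surface, mirroring the practice of
#' averaging multiple prediction layers from repeated random splits.
#'
#' @param occ Thinned [occurrence_tbl] of presences.
#' @param stack A [climate_stack()].
#' @param model `"bioclim"` or `"domain"`.
#' @param k Number of replicates (>= 2, default 10).
#' @param background_n Background sample size per replicate; default 10x the
#'   number of test presences, capped at the number of eligible cells.
#' @param train_fraction Training proportion (default 0.7).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A list with `report` (an `eval_report`: per-replicate AUCs, mean,
#'   sd, band, sizes) and `grid` (the averaged [suitability_grid]).
#' @export
replicate_evaluation <- function(occ, stack, model = c("bioclim", "domain"),
                                 k = 10, background_n = NULL,
                                 train_fraction = 0.7, seed = 1L) {
  model <- match.arg(model)
  if (k < 2) abort("`k` must be >= 2.")
  aucs <- numeric(k)
  sum_scores <- NULL
  bg_used <- NA_integer_
  for (r in seq_len(k)) {
    parts <- split_train_test(occ, train_fraction, seed = seed + r)
    train_env <- extract_at_points(stack, parts$train)
    fit <- if (model == "bioclim") fit_bioclim(train_env) else
      fit_domain(train_env)
    grid <- if (model == "bioclim") bioclim_predict_grid(fit, stack) else
      domain_predict_grid(fit, stack)
    test_loc <- locate_cells(stack, parts$test$lon, parts$test$lat)
    test_scores <- grid$scores[cbind(test_loc$row, test_loc$col)]
    n_bg <- if (is.null(background_n)) 10L * nrow(parts$test) else background_n
    eligible <- sum(!nodata_mask(stack)) - nrow(occ)
    n_bg <- min(n_bg, eligible)
    bg <- sample_background(stack, occ, n_bg, seed = seed + 1000L + r)
    bg_loc <- locate_cells(stack, bg$lon, bg$lat)
    bg_scores <- grid$scores[cbind(bg_loc$row, bg_loc$col)]
    aucs[r] <- auc(test_scores[!is.na(test_scores)],
                   bg_scores[!is.na(bg_scores)])
    sum_scores <- if (is.null(sum_scores)) grid$scores else
      sum_scores + grid$scores
    bg_used <- n_bg
  }
  mean_auc <- mean(aucs)
  report <- structure(
    list(model = model, auc = aucs, mean_auc = mean_auc,
         sd_auc = sd(aucs), band = auc_band(min(max(mean_auc, 0), 1)),
         n_replicates = k, background_n = bg_used, seed = seed,
         train_fraction = train_fraction),
    class = "eval_report"
  )
  list(report = report,
       grid = new_suitability_grid(sum_scores / k, stack, model))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s: AUC %.3f +/- %.4f over %d replicate(s) -> %s\n",
    x$model, x$mean_auc, x$sd_auc, x$n_replicates, x$band))
  cat(sprintf("  background n = %d per replicate, train fraction %.2f, seed %d\n",
              x$background_n, x$train_fraction, x$seed))
  invisible(x)
}

#' @rdname replicate_evaluation
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(model = x$model, replicate = seq_len(x$n_replicates), auc = x$auc)
}

#' @rdname replicate_evaluation
#' @export
glance.eval_report <- function(x, ...) {
  tibble(model = x$model, mean_auc = x$mean_auc, sd_auc = x$sd_auc,
         band = x$band, n_replicates = x$n_replicates,
         background_n = x$background_n, seed = x$seed)
}
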