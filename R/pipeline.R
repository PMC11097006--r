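#' Subset the layers of a climate stack
#'
#' @param stack A [climate_stack()].
#' @param variables Character vector of layer names to keep.
#' @return A [climate_stack()] with only those layers.
#' @export
select_layers <- function(stack, variables) {
  miss <- setdiff(variables, stack_vars(stack))
  if (length(miss) > 0) {
    abort(sprintf("Stack is missing layer(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  climate_stack(stack$layers[variables], stack$origin_lon, stack$origin_lat,
                stack$cell_size)
}

#' Write a complete synthetic scenario to disk
#'
#' Generates a current stack, a shifted future stack, an occurrence sample
#' from the true envelope, and a ground-truth JSON (envelope bounds) that
#' downstream recovery tests can check against. Everything is plain text:
#' ESRI ASCII grids and delimited occurrences.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [synthetic_climate_spec()] (default [default_climate_spec()]).
#' @param envelope A [true_envelope_spec()] (default [default_envelope()]).
#' @param n_occurrences Number of presence records (default 604, a typical
#'   compiled national occurrence set after county-level cleaning).
#' @param deltas Future-scenario shifts (default [default_future_deltas()]).
#' @param seed Seed for the occurrence sample.
#' @return Invisibly, a list with the in-memory `current`, `future` stacks
#'   and `occurrences` table.
#' @export
simulate_scenario <- function(out_dir, spec = default_climate_spec(),
                              envelope = default_envelope(spec),
                              n_occurrences = 604, deltas = default_future_deltas(),
                              seed = spec$seed) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  current <- make_climate_stack(spec)
  deltas <- deltas[intersect(names(deltas), stack_vars(current))]
  future <- make_future_stack(current, deltas)
  occ <- sample_occurrences(current, envelope, n_occurrences, seed = seed)
  write_ascii_stack(current, file.path(out_dir, "current"))
  write_ascii_stack(future, file.path(out_dir, "future"))
  write_occurrences(occ, file.path(out_dir, "occurrences.csv"))
  jsonlite::write_json(
    list(lower = as.list(envelope$lower), upper = as.list(envelope$upper),
         inside_weight = envelope$inside_weight,
         outside_weight = envelope$outside_weight,
         n_occurrences = n_occurrences, seed = seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(current = current, future = future, occurrences = occ))
}

#' Pipeline configuration
#'
#' @param occurrences An [occurrence_tbl] or a path to a delimited file.
#' @param current A [climate_stack()] or a directory of `.asc` grids.
#' @param future Optional future-scenario stack or directory; when absent the
#'   scenario comparison stage is skipped.
#' @param out_dir Output directory.
#' @param models Subset of `c("bioclim", "domain")`.
#' @param vif_threshold VIF pruning threshold (default 5).
#' @param train_fraction Training proportion (default 0.7).
#' @param replicates Number of evaluation replicates k (default 10, >= 2).
#' @param background_n Background sample size per replicate (`NULL`: 10x the
#'   test presences).
#' @param focal_class Focal class for the transition map (default
#'   `"excellent"`).
#' @param seed Base seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(occurrences, current, future = NULL,
                            out_dir = tempfile("nichebox_run_"),
                            models = c("bioclim", "domain"),
                            vif_threshold = 5, train_fraction = 0.7,
                            replicates = 10, background_n = NULL,
                            focal_class = "excellent", seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  if (replicates < 2) abort("`replicates` must be >= 2.")
  structure(
    list(occurrences = occurrences, current = current, future = future,
         out_dir = out_dir, models = models, vif_threshold = vif_threshold,
         train_fraction = train_fraction, replicates = replicates,
         background_n = background_n, focal_class = focal_class,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Averaged projection of replicate fits onto another stack
#'
#' Repeats the replicated 70/30 fitting of [replicate_evaluation()] (same
#' seeding rule, so replicate grids match across the two functions) but
#' predicts onto `predict_stack` — typically a future-scenario stack —
#' returning the cellwise mean of the k prediction grids. Training values are
#' always extracted from `fit_stack`, the climate the presences were observed
#' under.
#'
#' @inheritParams replicate_evaluation
#' @param fit_stack Stack used for training-value extraction.
#' @param predict_stack Stack to score.
#' @return The averaged [suitability_grid].
#' @export
replicate_project <- function(occ, fit_stack, predict_stack,
                              model = c("bioclim", "domain"), k = 10,
                              train_fraction = 0.7, seed = 1L) {
  model <- match.arg(model)
  sum_scores <- NULL
  for (r in seq_len(k)) {
    parts <- split_train_test(occ, train_fraction, seed = seed + r)
    train_env <- extract_at_points(fit_stack, parts$train)
    fit <- if (model == "bioclim") fit_bioclim(train_env) else
      fit_domain(train_env)
    grid <- if (model == "bioclim") bioclim_predict_grid(fit, predict_stack)
      else domain_predict_grid(fit, predict_stack)
    sum_scores <- if (is.null(sum_scores)) grid$scores else
      sum_scores + grid$scores
  }
  new_suitability_grid(sum_scores / k, predict_stack, model)
}

load_stack_input <- function(x) {
  if (inherits(x, "climate_stack")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_ascii_stack(x))
  abort("Stack inputs must be climate_stack objects or .asc directories.")
}

#' Run the full modelling pipeline
#'
#' Orchestrates the stages prepare (read + thin), select (descriptive stats,
#' stepwise VIF, PCA), fit/predict/average per model (replicated splits),
#' classify, evaluate (replicated AUC) and, when a future stack is supplied,
#' compare (change table, transition map, patch statistics). All tables and
#' grids are written under `config$out_dir` and a manifest records the seed,
#' package version, input hashes and per-stage timings.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results plus the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.")
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(
    package = "nichebox",
    version = as.character(packageVersion("nichebox")),
    seed = config$seed,
    models = config$models,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(), stages = list(), notes = character()
  )
  timings <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  for (nm in c("occurrences", "current", "future")) {
    x <- config[[nm]]
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      files <- if (dir.exists(x)) list.files(x, full.names = TRUE) else x
      manifest$inputs[[nm]] <- list(
        path = x, md5 = unname(tools::md5sum(files)))
    }
  }

  # prepare
  occ <- stage("prepare", {
    o <- if (inherits(config$occurrences, "occurrence_tbl")) config$occurrences
      else read_occurrences(config$occurrences)
    current <- load_stack_input(config$current)
    thin_to_cells(o, current)
  })
  current <- load_stack_input(config$current)
  future <- if (!is.null(config$future)) load_stack_input(config$future) else NULL

  # select
  sel <- stage("select", {
    env <- extract_at_points(current, occ)
    stats_tbl <- descriptive_stats(env)
    vif <- vif_stepwise(env, threshold = config$vif_threshold)
    pca <- if (length(vif$kept) >= 2) pca_env(env[, c("id", vif$kept)])
    list(env = env, stats = stats_tbl, vif = vif, pca = pca)
  })
  readr::write_csv(sel$stats, file.path(out, "descriptive_stats.csv"))
  readr::write_csv(tidy(sel$vif), file.path(out, "vif_rounds.csv"))
  jsonlite::write_json(
    list(kept = sel$vif$kept, dropped = sel$vif$dropped,
         threshold = config$vif_threshold),
    file.path(out, "vif_report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(sel$pca)) {
    readr::write_csv(tidy(sel$pca), file.path(out, "pca_loadings.csv"))
    readr::write_csv(glance(sel$pca), file.path(out, "pca_variance.csv"))
  }

  model_stack <- select_layers(current, sel$vif$kept)
  future_stack <- if (!is.null(future)) select_layers(future, sel$vif$kept)

  results <- list()
  for (model in config$models) {
    ev <- stage(paste0("evaluate_", model), {
      replicate_evaluation(occ, model_stack, model = model,
                           k = config$replicates,
                           background_n = config$background_n,
                           train_fraction = config$train_fraction,
                           seed = config$seed)
    })
    write_grid(ev$grid, file.path(out, sprintf("%s_current_suitability.asc",
                                               model)))
    jsonlite::write_json(as.list(glance(ev$report)),
                         file.path(out, sprintf("%s_eval.json", model)),
                         auto_unbox = TRUE, digits = NA)
    cat_cur <- if (model == "bioclim") classify_bioclim(ev$grid) else
      classify_domain(ev$grid)
    write_grid(cat_cur, file.path(out, sprintf("%s_current_classes.asc",
                                               model)))
    res <- list(eval = ev$report, current_grid = ev$grid,
                current_classes = cat_cur)
    if (!is.null(future)) {
      fut_grid <- stage(paste0("project_", model), {
        replicate_project(occ, model_stack, future_stack, model,
                          config$replicates, config$train_fraction,
                          config$seed)
      })
      cat_fut <- if (model == "bioclim") classify_bioclim(fut_grid) else
        classify_domain(fut_grid)
      write_grid(fut_grid, file.path(out, sprintf("%s_future_suitability.asc",
                                                  model)))
      write_grid(cat_fut, file.path(out, sprintf("%s_future_classes.asc",
                                                 model)))
      cmp <- stage(paste0("compare_", model), {
        list(
          change = change_table(cat_cur, cat_fut),
          transitions = transition_map(cat_cur, cat_fut,
                                       focal = config$focal_class),
          patches_current = patch_stats(cat_cur, focal = config$focal_class),
          patches_future = patch_stats(cat_fut, focal = config$focal_class)
        )
      })
      readr::write_csv(cmp$change, file.path(out, sprintf("%s_change.csv",
                                                          model)))
      jsonlite::write_json(
        list(focal = config$focal_class,
             transitions = cmp$transitions$summary,
             patches_current = cmp$patches_current,
             patches_future = cmp$patches_future),
        file.path(out, sprintf("%s_change.json", model)),
        auto_unbox = TRUE, digits = NA)
      res <- c(res, list(future_grid = fut_grid, future_classes = cat_fut),
               cmp)
    }
    results[[model]] <- res
  }
  if (is.null(future)) {
    manifest$notes <- c(manifest$notes, "no scenario comparison")
  }

  manifest$provenance <- provenance(occ)
  manifest$stages <- timings
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(occurrences = occ, select = sel, models = results,
                 manifest = manifest, out_dir = out))
}
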