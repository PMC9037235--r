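# Run configuration and the end-to-end pipeline:
# simulate (or ingest) -> segment -> postprocess -> metrics.

#' Build a run configuration
#'
#' Nested configuration covering every stage. All randomness in a run
#' flows from the single `seed`: scene `i` of a run uses a seed derived
#' deterministically from it.
#'
#' @param scene a [scene_config()] used as the template for simulated
#'   scenes (its own `seed` is overridden per image).
#' @param features a [feature_config()].
#' @param postprocess a [postprocess_config()].
#' @param n_train_images,n_count_images number of simulated images used
#'   for training and counting.
#' @param n_trees,max_depth,pixel_cap forest hyperparameters, see
#'   [pit_classifier()].
#' @param min_cells minimum counted cells per sample for the
#'   `sufficient_count` flag.
#' @param rule splenic-function rule, see [classify_splenic_function()].
#' @param pit_size_average pit-size averaging mode, see
#'   [pit_morphometrics()].
#' @param loa_bound_overall,loa_bound_low Bland-Altman acceptance
#'   bounds, see [check_loa_acceptance()].
#' @param seed global integer seed.
#' @param verbosity 0 silent, 1 stage summaries, 2 per-image detail.
#' @return A `run_config` object.
#' @export
run_config <- function(scene = scene_config(), features = feature_config(),
                       postprocess = postprocess_config(),
                       n_train_images = 2, n_count_images = 2,
                       n_trees = 80, max_depth = 24, pixel_cap = 10000,
                       min_cells = 500, rule = "el_hoss_2018",
                       pit_size_average = "per_pit",
                       loa_bound_overall = 5, loa_bound_low = 1.5,
                       seed = 1L, verbosity = 1) {
  structure(list(scene = scene, features = features, postprocess = postprocess,
                 n_train_images = as.integer(n_train_images),
                 n_count_images = as.integer(n_count_images),
                 n_trees = n_trees, max_depth = max_depth, pixel_cap = pixel_cap,
                 min_cells = min_cells, rule = rule,
                 pit_size_average = pit_size_average,
                 loa_bound_overall = loa_bound_overall,
                 loa_bound_low = loa_bound_low,
                 seed = as.integer(seed), verbosity = verbosity),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Strict single-dialect JSON: unknown keys at any level are rejected.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown run_config key(s): ", paste(bad, collapse = ", "))
  args <- raw
  if (!is.null(raw$scene)) {
    check_keys(raw$scene, names(formals(scene_config)), "scene")
    args$scene <- do.call(scene_config, as_config_args(raw$scene))
  }
  if (!is.null(raw$features)) {
    check_keys(raw$features, c("scales_px", names(feature_config()$kinds)), "features")
    args$features <- do.call(feature_config, raw$features)
  }
  if (!is.null(raw$postprocess)) {
    pk <- setdiff(names(formals(postprocess_config)), character(0))
    check_keys(raw$postprocess, pk, "postprocess")
    args$postprocess <- do.call(postprocess_config, raw$postprocess)
  }
  do.call(run_config, args)
}

check_keys <- function(x, known, where) {
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

as_config_args <- function(x) {
  if (!is.null(x$artefact_rates)) x$artefact_rates <- as.list(x$artefact_rates)
  x
}

#' Write a run configuration as JSON
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$scene <- unclass(out$scene)
  out$features <- list(scales_px = config$features$scales_px)
  for (k in names(config$features$kinds))
    out$features[[k]] <- unname(config$features$kinds[k])
  out$postprocess <- unclass(config$postprocess)
  out$postprocess$edge_policy <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pipe_log <- function(verbosity, level, ...) {
  if (verbosity >= level) message(sprintf(...))
}

#' Run the full automated PIT-count pipeline
#'
#' Simulates training and counting scenes from the run configuration (or
#' ingests user images with truth labels for training), trains the pixel
#' classifier, segments the counting images, applies the macro-style
#' post-processing, and summarises each image as a sample. With an
#' `output_dir`, writes per-image object tables, a `sample_results.csv`,
#' and the resolved configuration beside the outputs; reruns at a fixed
#' seed are byte-identical.
#'
#' @param config a [run_config()].
#' @param output_dir optional output directory.
#' @param train_images,train_labels optional user-supplied training data
#'   (lists of [dic_image()] and label matrices) replacing simulated
#'   training scenes.
#' @param count_images optional user-supplied images to count,
#'   replacing simulated counting scenes.
#' @return List with the fitted `classifier`, per-image `tables`,
#'   `samples` (one `sample_result` per image), `pooled` (a
#'   `sample_result` over all counted images), and when counting
#'   simulated scenes, `truth` (per-image truth statistics).
#' @export
run_pipeline <- function(config, output_dir = NULL,
                         train_images = NULL, train_labels = NULL,
                         count_images = NULL) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbosity
  pipe_log(v, 1, "pipeline: seed %d", config$seed)

  scene_at <- function(i) {
    sc <- config$scene
    sc$seed <- derive_seed(config$seed, i)
    sample_scene(sc)
  }

  if (is.null(train_images)) {
    pipe_log(v, 1, "simulating %d training scene(s)", config$n_train_images)
    train_scenes <- lapply(seq_len(config$n_train_images), scene_at)
    train_images <- lapply(train_scenes, render_dic)
    train_labels <- lapply(train_scenes, `[[`, "truth_label_map")
  }
  classifier <- pit_classifier(train_images, train_labels,
                               features = config$features,
                               n_trees = config$n_trees,
                               max_depth = config$max_depth,
                               pixel_cap = config$pixel_cap,
                               seed = config$seed)
  pipe_log(v, 1, "classifier trained on %d image(s)", length(train_images))

  truth <- NULL
  if (is.null(count_images)) {
    pipe_log(v, 1, "simulating %d counting scene(s)", config$n_count_images)
    count_scenes <- lapply(seq_len(config$n_count_images) + config$n_train_images,
                           scene_at)
    count_images <- lapply(count_scenes, render_dic)
    truth <- lapply(count_scenes, scene_truth_stats)
  }

  tables <- vector("list", length(count_images))
  samples <- vector("list", length(count_images))
  for (i in seq_along(count_images)) {
    labels <- predict(classifier, count_images[[i]])
    tab <- analyze_labels(labels, count_images[[i]]$pixel_size_um,
                          config$postprocess)
    tables[[i]] <- tab
    samples[[i]] <- summarize_sample(tab, min_cells = config$min_cells,
                                     rule = config$rule,
                                     pit_size_average = config$pit_size_average)
    excl <- samples[[i]]$exclusions
    pipe_log(v, 2,
             "image %d: %d instance(s); excluded size=%d edge=%d solidity=%d; pitted %d/%d",
             i, nrow(tab), excl["excluded_size"], excl["excluded_edge"],
             excl["excluded_solidity"], samples[[i]]$n_pitted,
             samples[[i]]$n_cells_counted)
  }
  names(tables) <- names(samples) <- sprintf("image_%02d", seq_along(count_images))

  pooled_tab <- do.call(rbind, lapply(tables, as.data.frame))
  class(pooled_tab) <- c("object_table", "data.frame")
  pooled <- summarize_sample(pooled_tab, min_cells = config$min_cells,
                             rule = config$rule,
                             pit_size_average = config$pit_size_average)
  pipe_log(v, 1, "pooled: %d cells counted, %%PIT %s", pooled$n_cells_counted,
           if (is.na(pooled$percent_pit)) "undefined"
           else sprintf("%.2f", pooled$percent_pit))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(tables))
      write_object_table(tables[[i]],
                         file.path(output_dir, sprintf("objects_image_%02d.csv", i)))
    write_sample_results(samples, file.path(output_dir, "sample_results.csv"))
    write_run_config(config, file.path(output_dir, "run_config.json"))
  }

  invisible(list(classifier = classifier, tables = tables, samples = samples,
                 pooled = pooled, truth = truth))
}
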