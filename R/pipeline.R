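#' Default pipeline configuration
#'
#' Nested list mirroring the stage structure: `scenegen`, `labeling`,
#' `network`, `training`, `evaluation`, `enhancement`. Can be serialized
#' to / read from YAML.
#'
#' @param seed Master seed recorded in every artifact.
#' @param n_scenes Number of scenes to generate.
#' @param epochs Training epochs.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L, n_scenes = 200L, epochs = 10L) {
  list(version = 1L, seed = as.integer(seed),
       scenegen = list(n_scenes = as.integer(n_scenes), image_side = 256L,
                       depth_range = c(1, 7), physical_size_range = c(40, 120),
                       background_depth = 8, noise_sd = 2,
                       n_objects_range = c(0L, 5L)),
       labeling = list(alpha = 0.5, beta = 0.75),
       network = list(dropout_zero_prob = 0.5),
       training = list(epochs = as.integer(epochs), learning_rate = 5e-4,
                       batch_size = 64L, input_side = 32L,
                       fractions = c(0.8, 0.1, 0.1)),
       evaluation = list(grid_step = 0.01),
       enhancement = list(grid_dims = 32L, n_examples = 3L))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing keys fall back to
#'   [default_run_config()] values.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  .stop_if(!file.exists(path), "no such config file: ", path)
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  merge <- function(b, u) {
    for (nm in names(u)) {
      b[[nm]] <- if (is.list(b[[nm]]) && is.list(u[[nm]])) {
        merge(b[[nm]], u[[nm]])
      } else u[[nm]]
    }
    b
  }
  merge(base, user)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' generate -> label -> train -> calibrate -> evaluate -> enhance, writing
#' all artifacts (config copy, checkpoint, training log, evaluation
#' report, example comparison panels) under `out_dir`. Every artifact
#' records the seed and the configuration hash. Deterministic under the
#' config seed.
#'
#' @param config Nested list from [default_run_config()] /
#'   [read_run_config()].
#' @param out_dir Output directory.
#' @param verbose Log stage progress.
#' @return Invisibly, a list with the trained `model`, `report`,
#'   calibrated `threshold`, training `log` and `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         verbose = TRUE) {
  .stop_if(missing(out_dir) || is.null(out_dir), "out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  config$hash <- hash
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       digits = NA, auto_unbox = TRUE)
  say <- function(...) if (verbose) message("[retina-focus] ", ...)
  sg <- config$scenegen
  spec <- scene_spec(image_side = sg$image_side, n_objects = 0L,
                     depth_range = sg$depth_range,
                     physical_size_range = sg$physical_size_range,
                     background_depth = sg$background_depth,
                     noise_sd = sg$noise_sd)
  say("generating ", sg$n_scenes, " scenes")
  data <- generate_training_data(spec, sg$n_scenes, seed = config$seed,
                                 input_side = config$training$input_side,
                                 n_objects_range = sg$n_objects_range)
  split <- split_dataset(sg$n_scenes, config$training$fractions,
                         seed = config$seed + 1L)
  model <- build_model(network_config(
    image_side = sg$image_side,
    dropout_zero_prob = config$network$dropout_zero_prob),
    seed = config$seed + 2L)
  tcfg <- train_config(epochs = config$training$epochs,
                       learning_rate = config$training$learning_rate,
                       batch_size = config$training$batch_size,
                       input_side = config$training$input_side,
                       seed = config$seed + 3L)
  say("training for ", tcfg$epochs, " epochs")
  fit <- train_model(model, data, split, tcfg, verbose = verbose)
  save_checkpoint(fit$model, file.path(out_dir, "checkpoint.json"))
  utils::write.csv(fit$log, file.path(out_dir, "train_log.csv"),
                   row.names = FALSE)
  thr <- calibrate_model_threshold(fit$model, data, split$validation,
                                   grid_step = config$evaluation$grid_step)
  say("calibrated threshold: ", thr)
  preds <- predict_scenes(fit$model, data, split$test)
  report <- evaluation_report(t(preds),
                              t(data$targets[, split$test, drop = FALSE]),
                              threshold = thr)
  write_eval_report(report, file.path(out_dir, "eval_report.json"))
  en <- config$enhancement
  set.seed(config$seed + 4L)
  for (i in seq_len(en$n_examples)) {
    sp <- spec
    sp$n_objects <- sample(1:5, 1)
    s <- generate_scene(sp)
    panels <- enhance_scene(s, grid_dims = en$grid_dims)
    write_comparison(panels, file.path(out_dir,
                                       sprintf("comparison_%02d.png", i)))
  }
  say("done; artifacts in ", out_dir)
  invisible(list(model = fit$model, report = report, threshold = thr,
                 log = fit$log, out_dir = out_dir, hash = hash))
}
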