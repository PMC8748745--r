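#' @title Pipeline orchestration
#'
#' @description End-to-end commands over one configuration with one
#' user-facing hyperparameter (`min_area`). Changing `min_area` only affects
#' the clustering stage and never requires retraining: the second stage
#' takes no parameters from the first. Each command is also exposed through
#' the `cellseg3d` command-line script (subcommands `simulate`, `train`,
#' `segment`, `evaluate`).
#'
#' @name cli_pipeline
NULL

#' Default pipeline configuration
#'
#' Every field has a default; the configuration round-trips losslessly
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#' Defaults: `min_area` 30 faces, loss `alpha` 0.1, training cuboids
#' 56^3..64^3 with batch size 7, absorption ratio 0.5.
#'
#' @param ... Named overrides, nested lists merged over the defaults (e.g.
#'   `phantom = list(n_cells = 40)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  base <- list(
    seed = 1L,
    min_area = 30,
    alpha = 0.1,
    h_sep = 3L,
    paths = list(intensity = NULL, labels = NULL, checkpoint = NULL,
                 masks = NULL, output_dir = ".", pred = NULL, gt = NULL),
    tile = list(extent = c(64L, 64L, 64L), overlap = c(8L, 8L, 8L)),
    phantom = list(extent = c(64L, 64L, 64L), n_cells = 30L,
                   membrane_thickness = 2, noise_sd = 0.05, hole_rate = 0,
                   hole_radius = 2, background_margin = 2L),
    network = list(n_levels = 3L, base_channels = 16L),
    train = list(cuboid_min = c(56L, 56L, 56L), cuboid_max = c(64L, 64L, 64L),
                 batch_size = 7L, learning_rate = 1e-3, steps = 200L,
                 w_min = 0.5, pairs = list()))
  ov <- list(...)
  merge <- function(a, b) {
    for (nm in names(b)) {
      bv <- b[[nm]]
      if (is.list(a[[nm]]) && is.list(bv) && !is.null(names(bv)))
        a[[nm]] <- merge(a[[nm]], bv)
      else a[nm] <- list(bv)  # list() form keeps NULL fields in place
    }
    a
  }
  structure(merge(base, ov), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.out_path <- function(config, name) {
  dir.create(config$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$paths$output_dir, name)
}

#' Simulate a phantom dataset
#'
#' Writes five files to the output directory: the intensity volume
#' (`phantom_intensity.tif`), instance labels (`phantom_labels.tif`),
#' semantic masks (`phantom_masks.h5`, one dataset per class), loss weights
#' (`phantom_weights.h5`) and the phantom specification
#' (`phantom_spec.json`). Deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the named vector of written paths.
#' @export
cmd_simulate <- function(config = pipeline_config()) {
  ph <- config$phantom
  spec <- phantom_spec(extent = ph$extent, n_cells = ph$n_cells,
                       membrane_thickness = ph$membrane_thickness,
                       noise_sd = ph$noise_sd, hole_rate = ph$hole_rate,
                       hole_radius = ph$hole_radius,
                       background_margin = ph$background_margin,
                       seed = config$seed)
  gen <- generate_phantom(spec)
  masks <- semantic_masks_from_labels(gen$labels, ph$membrane_thickness)
  weights <- lapply(masks, reverse_distance_weights,
                    w_min = config$train$w_min)
  paths <- c(intensity = .out_path(config, "phantom_intensity.tif"),
             labels = .out_path(config, "phantom_labels.tif"),
             masks = .out_path(config, "phantom_masks.h5"),
             weights = .out_path(config, "phantom_weights.h5"),
             spec = .out_path(config, "phantom_spec.json"))
  write_intensity_volume(pmin(pmax(gen$intensity, 0), 1), paths["intensity"])
  write_label_volume(gen$labels, paths["labels"])
  first <- TRUE
  for (cls in names(masks)) {
    cpp_h5_write(paths[["masks"]], cls, as.numeric(aperm(masks[[cls]], 3:1)),
                 dim(masks[[cls]]), TRUE, first)
    cpp_h5_write(paths[["weights"]], cls,
                 as.numeric(aperm(weights[[cls]], 3:1)),
                 dim(weights[[cls]]), FALSE, first)
    first <- FALSE
  }
  jsonlite::write_json(unclass(spec), paths["spec"], auto_unbox = TRUE)
  invisible(paths)
}

.load_training_pairs <- function(config) {
  pairs <- config$train$pairs
  if (length(pairs) == 0L)
    stop("no training pairs configured (train$pairs)", call. = FALSE)
  lapply(pairs, function(p) {
    if (!file.exists(p$intensity) || !file.exists(p$labels))
      stop("missing training volume: ", p$intensity, " / ", p$labels,
           call. = FALSE)
    list(intensity = read_intensity_volume(p$intensity, p$dataset_key),
         labels = read_label_volume(p$labels))
  })
}

#' Train the semantic network
#'
#' Trains (or, with `init_from`, fine-tunes) the segmentation network on the
#' configured training pairs and writes a checkpoint plus a JSON training
#' log to the output directory.
#'
#' @param config A [pipeline_config()].
#' @param init_from Optional checkpoint path to warm-start from
#'   (transfer-learning mode).
#' @return Invisibly, the checkpoint path.
#' @export
cmd_train <- function(config = pipeline_config(), init_from = NULL) {
  dataset <- .load_training_pairs(config)
  tc <- config$train
  cfg <- train_config(cuboid_min = tc$cuboid_min, cuboid_max = tc$cuboid_max,
                      batch_size = tc$batch_size,
                      learning_rate = tc$learning_rate, steps = tc$steps,
                      seed = config$seed, alpha = config$alpha,
                      w_min = tc$w_min)
  net_cfg <- network_config(n_levels = config$network$n_levels,
                            base_channels = config$network$base_channels)
  init <- if (!is.null(init_from)) load_network(init_from) else NULL
  mt <- config$phantom$membrane_thickness
  fit <- train_semantic_model(dataset, cfg, net_cfg, init = init,
                              membrane_thickness = mt)
  ckpt <- config$paths$checkpoint
  if (is.null(ckpt)) ckpt <- .out_path(config, "checkpoint.rds")
  save_network(fit$net, ckpt)
  jsonlite::write_json(as.data.frame(fit$log),
                       .out_path(config, "training_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ckpt)
}

#' Segment a volume into cell instances
#'
#' Either runs the full two-stage pipeline (network prediction, argmax,
#' touching-area clustering) on the configured intensity volume, or — with
#' `masks_in` — skips the network and clusters the given semantic masks
#' directly. Writes the instance label volume and a JSON summary.
#'
#' @param config A [pipeline_config()].
#' @param masks_in Optional HDF5 path with `background` / `membrane` /
#'   `foreground` datasets to bypass the network.
#' @return Invisibly, the `instance_segmentation` result.
#' @export
cmd_segment <- function(config = pipeline_config(), masks_in = NULL) {
  if (!is.null(masks_in)) {
    masks <- lapply(setNames(.canonical_classes, .canonical_classes),
                    function(cls) {
                      r <- cpp_h5_read(masks_in, cls)
                      aperm(array(as.integer(round(r$data)), rev(r$dims)), 3:1)
                    })
  } else {
    if (is.null(config$paths$intensity))
      stop("no intensity volume configured", call. = FALSE)
    image <- read_intensity_volume(config$paths$intensity,
                                   config$paths$dataset_key)
    net <- load_network(config$paths$checkpoint)
    probs <- predict_semantic_volume(image, net,
                                     tile_extent = config$tile$extent,
                                     overlap = config$tile$overlap)
    masks <- semantic_argmax(probs)
  }
  seg <- segment_instances(masks, min_area = config$min_area,
                           h_sep = config$h_sep)
  out <- .out_path(config, "instances.tif")
  write_label_volume(seg$labels, out)
  vols <- as.integer(table(seg$labels[seg$labels > 0]))
  jsonlite::write_json(
    list(n_instances = seg$n_instances, instance_volumes = vols,
         min_area = config$min_area,
         provenance = as.list(seg$provenance)),
    .out_path(config, "segment_summary.json"), auto_unbox = TRUE)
  invisible(seg)
}

#' Evaluate a predicted segmentation
#'
#' Reads predicted and ground-truth label volumes from the configured paths
#' and writes the evaluation report as JSON and CSV.
#'
#' @param config A [pipeline_config()] with `paths$pred` and `paths$gt`.
#' @return Invisibly, the `evaluation_report`.
#' @export
cmd_evaluate <- function(config = pipeline_config()) {
  if (is.null(config$paths$pred) || !file.exists(config$paths$pred))
    stop("missing prediction labels: ", config$paths$pred, call. = FALSE)
  if (is.null(config$paths$gt) || !file.exists(config$paths$gt))
    stop("missing ground-truth labels: ", config$paths$gt, call. = FALSE)
  pred <- read_label_volume(config$paths$pred)
  gt <- read_label_volume(config$paths$gt)
  rep <- evaluate_segmentation(pred, gt)
  scalar <- rep[setdiff(names(rep), "matches")]
  jsonlite::write_json(scalar, .out_path(config, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(rep$matches, .out_path(config, "evaluation_cells.csv"),
                   row.names = FALSE)
  invisible(rep)
}
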