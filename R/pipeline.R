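## Pipeline orchestration: the training workflow (scenes -> automatic ground
## truth -> augmented dataset -> trained model) and the segmentation workflow
## (model -> tiled probability maps -> instances -> evaluation), driven by a
## single YAML config with per-module sections. Every command writes a
## manifest recording the seed and a hash of the config so runs are
## reproducible and the held-out evaluation site can be cross-checked
## against the training inputs.

#' Default pipeline configuration
#'
#' A nested list with one section per module (`scene`, `illumination`,
#' `groundtruth`, `augment`, `network`, `training`, `tiling`,
#' `segmentation`) plus global fields `mode`, `rng_seed`, `n_sites`,
#' `heldout_site` and `output_dir`. Any field can be overridden in the YAML
#' file read by [read_pipeline_config()].
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    mode = "timelapse",
    rng_seed = 1L,
    n_sites = 9L,
    heldout_site = 9L,
    output_dir = "brightseg_run",
    scene = list(width = 256L, height = 256L, n_cells = 15L,
                 cell_radius_range = c(12, 18),
                 nucleus_radius_range = c(4, 7),
                 min_center_distance = 40,
                 z_offsets = c(0.5, 1.5, 2.5),
                 illumination_amplitude = 0.15,
                 noise_sd = 0.01, bf_contrast = 1),
    illumination = list(knot_spacing = NULL, n_iterations = 3L,
                        exclusion_k = 2.0, spline_order = 3L),
    groundtruth = list(dilation_disk_diameter = 5L, min_nucleus_area = 25,
                       threshold_method = "otsu", split_touching = TRUE),
    augment = list(patch_size = 64L, patches_per_image = 40L,
                   flip_lr_prob = 0.5, flip_ud_prob = 0.5,
                   foreground_factor = 3),
    network = list(n_levels = 2L, base_features = 4L,
                   n_residual_blocks = 1L, input_size = 64L),
    training = list(initial_lr = 0.001, total_iterations = 2000L,
                    lr_drop_every = 5000L, lr_drop_factor = 0.1,
                    batch_size = 1L),
    tiling = list(tile_size = 240L, gaussian_sigma = 60),
    segmentation = list(prob_threshold = 0.5, seed_smoothing_sigma = 3,
                        seed_min_distance = 10, min_cell_area = 25,
                        dilation_size = 9L))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML fields override the defaults of [default_pipeline_config()];
#' omitted fields keep their default values.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param seed optional seed override.
#' @return nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL, seed = NULL) {
  cfg <- default_pipeline_config()
  hash <- "defaults"
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
    hash <- unname(tools::md5sum(path))
  }
  if (!is.null(seed)) cfg$rng_seed <- as.integer(seed)
  cfg$config_hash <- hash
  cfg
}

scene_spec_from_config <- function(cfg, site) {
  do.call(scene_spec, c(cfg$scene,
                        list(rng_seed = derive_seed(cfg$rng_seed, site),
                             mode = cfg$mode)))
}

write_manifest <- function(dir, name, manifest) {
  jsonlite::write_json(manifest, file.path(dir, name), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
}

#' Simulate the imaging sites of a run
#'
#' Generates `n_sites` synthetic scenes (per-site seeds derived from the
#' global seed) and writes each as a TIFF directory plus a run manifest.
#'
#' @param config pipeline configuration list.
#' @return invisibly, the manifest (paths, seeds, config hash).
#' @export
cmd_simulate <- function(config = default_pipeline_config()) {
  out <- file.path(config$output_dir, "scenes")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sites <- seq_len(config$n_sites)
  dirs <- character(0)
  for (s in sites) {
    spec <- scene_spec_from_config(config, s)
    scene <- generate_scene(spec)
    d <- file.path(out, sprintf("site%02d", s))
    write_scene(scene, d)
    dirs <- c(dirs, d)
  }
  manifest <- list(command = "simulate", rng_seed = config$rng_seed,
                   config_hash = config$config_hash, mode = config$mode,
                   sites = dirs)
  write_manifest(out, "manifest.json", manifest)
  invisible(manifest)
}

#' Generate ground truth, build the dataset and train the model
#'
#' Runs automatic ground-truth generation and augmentation on every site
#' except the held-out one, then trains the network. The manifest records
#' the training sites and the excluded evaluation site.
#'
#' @param config pipeline configuration list.
#' @param verbose print training progress.
#' @return invisibly, a list with the trained `model`, `loss_trace` and
#'   `manifest`.
#' @export
cmd_train <- function(config = default_pipeline_config(), verbose = FALSE) {
  scene_dir <- file.path(config$output_dir, "scenes")
  sites <- list.dirs(scene_dir, recursive = FALSE)
  if (length(sites) == 0) stopf("no scenes found under %s; run cmd_simulate",
                                scene_dir)
  heldout <- sprintf("site%02d", config$heldout_site)
  train_sites <- sites[basename(sites) != heldout]
  gcfg <- do.call(groundtruth_config, config$groundtruth)
  icfg <- do.call(illumination_config, config$illumination)
  pairs <- list()
  gt_dir <- file.path(config$output_dir, "groundtruth")
  dir.create(gt_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in train_sites) {
    scene <- read_scene(d)
    pair <- build_training_pairs(scene, gcfg, icfg)
    write_label_tiff(pair$labels,
                     file.path(gt_dir, paste0(basename(d), "_labels.tif")))
    pairs[[length(pairs) + 1L]] <- pair
  }
  acfg <- do.call(augment_config,
                  c(config$augment,
                    list(rng_seed = derive_seed(config$rng_seed, 101L))))
  dataset <- build_dataset(pairs, acfg)
  ds_path <- file.path(config$output_dir, "training_set.rds")
  write_dataset(dataset, ds_path)
  in_channels <- dim(pairs[[1]]$data)[3]
  arch <- do.call(architecture_spec,
                  c(config$network, list(in_channels = in_channels)))
  model <- build_network(arch, init_seed = derive_seed(config$rng_seed, 202L))
  tcfg <- do.call(training_config,
                  c(config$training,
                    list(rng_seed = derive_seed(config$rng_seed, 303L),
                         checkpoint_every = 500,
                         checkpoint_dir = file.path(config$output_dir,
                                                    "checkpoints"))))
  fit <- train_network(model, dataset, tcfg, verbose = verbose)
  model_path <- file.path(config$output_dir, "model.rds")
  save_model(fit$model, model_path)
  manifest <- list(command = "train", rng_seed = config$rng_seed,
                   config_hash = config$config_hash,
                   training_sites = basename(train_sites),
                   heldout_site = heldout,
                   n_samples = length(dataset),
                   dataset = ds_path, model = model_path)
  write_manifest(config$output_dir, "train_manifest.json", manifest)
  invisible(list(model = fit$model, loss_trace = fit$loss_trace,
                 manifest = manifest))
}

## Load the data channels of a scene directory the way training did:
## illumination-corrected bright-field stack (timelapse) or non-nuclear
## channels (multichannel5).
load_site_data <- function(dir, config) {
  scene <- read_scene(dir)
  icfg <- do.call(illumination_config, config$illumination)
  if (config$mode == "timelapse") {
    bf_cfg <- icfg; bf_cfg$exclusion_side <- "both"
    planes <- correct_zstack(scene$brightfield, bf_cfg)
  } else {
    fcfg <- icfg; fcfg$exclusion_side <- "upper"
    planes <- lapply(scene$channels5[2:5], function(ch)
      correct_illumination(ch, estimate_background(ch, fcfg)))
  }
  norm <- normalize_data(array(unlist(planes),
                               c(dim(planes[[1]]), length(planes))))
  list(scene = scene, data = norm)
}

#' Segment a directory of sites with the trained model
#'
#' Tiled two-pass inference followed by watershed instance extraction and
#' label-safe dilation; one mask TIFF per site, same base name.
#'
#' @param config pipeline configuration list.
#' @param sites site directory names to segment (default: all simulated
#'   sites).
#' @return invisibly, the manifest.
#' @export
cmd_segment <- function(config = default_pipeline_config(), sites = NULL) {
  model_path <- file.path(config$output_dir, "model.rds")
  if (!file.exists(model_path)) stopf("no model at %s; run cmd_train",
                                      model_path)
  model <- load_model(model_path)
  scene_dir <- file.path(config$output_dir, "scenes")
  if (is.null(sites))
    sites <- basename(list.dirs(scene_dir, recursive = FALSE))
  tcfg <- do.call(tiling_config, config$tiling)
  scfg <- do.call(segmentation_config, config$segmentation)
  out <- file.path(config$output_dir, "masks")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  masks <- character(0)
  for (s in sites) {
    site <- load_site_data(file.path(scene_dir, s), config)
    prob <- predict_tiled(model, site$data, tcfg)
    inst <- probability_to_instances(prob, scfg)
    inst <- dilate_labels(inst, scfg$dilation_size)
    p <- file.path(out, paste0(s, "_mask.tif"))
    write_label_tiff(inst, p)
    write_image_tiff(prob, file.path(out, paste0(s, "_prob.tif")))
    masks <- c(masks, p)
  }
  manifest <- list(command = "segment", rng_seed = config$rng_seed,
                   config_hash = config$config_hash, sites = sites,
                   masks = masks)
  write_manifest(out, "manifest.json", manifest)
  invisible(manifest)
}

#' Evaluate predicted masks against automatically generated ground truth
#'
#' For each requested site, regenerates the automatic ground truth from the
#' fluorescence channels (never taken from the training outputs), computes
#' per-cell F-scores and the cumulative curve, and summarizes across sites.
#' Errors if a requested site was part of the training manifest — the
#' evaluation ground truth must be disjoint from the training inputs.
#'
#' @param config pipeline configuration list.
#' @param sites site names to evaluate (default: the held-out site).
#' @param check_disjoint verify sites are absent from the training manifest.
#' @return invisibly, list with `per_cell` (data.frame), `curves`,
#'   `summary`.
#' @export
cmd_evaluate <- function(config = default_pipeline_config(), sites = NULL,
                         check_disjoint = TRUE) {
  if (is.null(sites)) sites <- sprintf("site%02d", config$heldout_site)
  tm_path <- file.path(config$output_dir, "train_manifest.json")
  if (check_disjoint && file.exists(tm_path)) {
    tm <- jsonlite::read_json(tm_path, simplifyVector = TRUE)
    bad <- intersect(sites, tm$training_sites)
    if (length(bad))
      stopf("evaluation sites used in training: %s",
            paste(bad, collapse = ", "))
  }
  gcfg <- do.call(groundtruth_config, config$groundtruth)
  icfg <- do.call(illumination_config, config$illumination)
  out <- file.path(config$output_dir, "evaluation")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  per_cell <- list(); curves <- list()
  for (s in sites) {
    scene <- read_scene(file.path(config$output_dir, "scenes", s))
    gt <- build_training_pairs(scene, gcfg, icfg)$labels
    mask <- read_label_tiff(file.path(config$output_dir, "masks",
                                      paste0(s, "_mask.tif")))
    pc <- per_cell_fscore(gt, mask)
    pc$site <- s
    per_cell[[s]] <- pc
    curves[[s]] <- cumulative_curve(pc$fscore)
    utils::write.csv(pc, file.path(out, paste0(s, "_per_cell.csv")),
                     row.names = FALSE)
    utils::write.csv(curves[[s]], file.path(out, paste0(s, "_curve.csv")),
                     row.names = FALSE)
  }
  summary <- summarize_sites(curves)
  utils::write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)
  res <- list(per_cell = do.call(rbind, per_cell), curves = curves,
              summary = summary)
  write_manifest(out, "manifest.json",
                 list(command = "evaluate", rng_seed = config$rng_seed,
                      config_hash = config$config_hash, sites = sites))
  invisible(res)
}
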