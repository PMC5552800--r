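## Shared fixtures and independent oracles. Expensive fixtures are memoized
## per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

## Small timelapse scene with well-separated cells plus its automatic
## ground-truth training pair.
fixture_scene <- function() memo("scene", {
  spec <- scene_spec(width = 160, height = 160, n_cells = 6,
                     cell_radius_range = c(10, 14),
                     nucleus_radius_range = c(3, 5),
                     min_center_distance = 34, rng_seed = 5)
  generate_scene(spec)
})

fixture_pair <- function() memo("pair", {
  suppressWarnings(build_training_pairs(fixture_scene()))
})

## The desk-scale "tiny" network used throughout the tests.
tiny_arch <- function(in_channels = 3, input_size = 96)
  architecture_spec(n_levels = 2, base_features = 4, n_residual_blocks = 1,
                    input_size = input_size, in_channels = in_channels)

## Training sample fixture for the memorization checks: one 96x96 patch cut
## by the augment module from a small scene's automatic ground truth.
fixture_overfit_sample <- function() memo("overfit", {
  spec <- scene_spec(width = 128, height = 128, n_cells = 4,
                     cell_radius_range = c(10, 14),
                     nucleus_radius_range = c(3, 5),
                     min_center_distance = 30, rng_seed = 5)
  sc <- generate_scene(spec)
  pair <- suppressWarnings(build_training_pairs(sc))
  suppressWarnings(build_dataset(
    list(pair), augment_config(patch_size = 96, patches_per_image = 1,
                               rng_seed = 2)))
})

## Independent brute-force per-cell F-score oracle: explicit double loop
## over label pairs and pixel-index sets, with the same tie rule (largest
## overlap, then larger prediction, then lower id).
brute_force_fscore <- function(reference, predicted) {
  gt_ids <- sort(unique(reference[reference > 0]))
  out <- data.frame(gt_id = gt_ids, pred_id = 0L, fscore = 0)
  pred_ids <- sort(unique(predicted[predicted > 0]))
  for (i in seq_along(gt_ids)) {
    a <- which(reference == gt_ids[i])
    best <- c(inter = 0, parea = 0, id = 0)
    for (p in pred_ids) {
      b <- which(predicted == p)
      inter <- length(intersect(a, b))
      if (inter == 0) next
      better <- inter > best["inter"] ||
        (inter == best["inter"] && length(b) > best["parea"])
      if (better) best <- c(inter = inter, parea = length(b), id = p)
    }
    if (best["id"] > 0) {
      out$pred_id[i] <- best["id"]
      out$fscore[i] <- 2 * best["inter"] / (length(a) + best["parea"])
    }
  }
  out
}

## Random instance label image built from non-overlapping-ish rectangles.
random_label_image <- function(H, W, n_objects) {
  lab <- matrix(0L, H, W)
  for (k in seq_len(n_objects)) {
    h <- sample(3:10, 1); w <- sample(3:10, 1)
    r <- sample.int(H - h, 1); c <- sample.int(W - w, 1)
    lab[r:(r + h), c:(c + w)] <- k
  }
  relabel_consecutive(lab)
}

## Probability field of Gaussian bumps (max-combined).
bump_field <- function(H, W, centers, sigma, height = 0.95) {
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(H) - centers[i, 1])^2,
                (seq_len(W) - centers[i, 2])^2, `+`)
    out <- pmax(out, height * exp(-d2 / (2 * sigma^2)))
  }
  out
}

## Elementwise (1x1 receptive field) probability model and its whole-image
## application; output depends only on the first channel's pixel value.
pixelwise_model <- function() function(tile) 1 / (1 + exp(1 - 2 * tile[, , 1]))

## Tile-framing-dependent model: returns the tile mean everywhere, so
## stitched maps are piecewise constant with steps at tile edges.
tile_mean_model <- function() function(tile) {
  matrix(mean(tile), dim(tile)[1], dim(tile)[2])
}
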