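## Patch augmentation and training-set assembly.
##
## Each (data, label) image pair is randomly flipped, mirror-extended to nine
## times its area, randomly cropped into fixed-size patches, normalized per
## channel, and given a per-pixel weight image that balances the foreground
## and background classes in the loss (with an extra foreground emphasis
## factor).

#' Augmentation configuration
#'
#' @param patch_size square patch side in pixels (the network input size).
#' @param patches_per_image random crops drawn per source pair; the default
#'   750 yields 6000 samples from 8 source sites.
#' @param flip_lr_prob,flip_ud_prob probabilities of left-right / up-down
#'   flips (one draw per source pair).
#' @param rng_seed integer seed making dataset builds bit-reproducible.
#' @param foreground_factor extra weight multiplier on the foreground class
#'   after balancing.
#' @return an `augment_config` list.
#' @export
augment_config <- function(patch_size = 480, patches_per_image = 750,
                           flip_lr_prob = 0.5, flip_ud_prob = 0.5,
                           rng_seed = 1L, foreground_factor = 3) {
  if (patch_size < 1) stopf("patch_size must be >= 1")
  if (any(c(flip_lr_prob, flip_ud_prob) < 0) ||
      any(c(flip_lr_prob, flip_ud_prob) > 1))
    stopf("flip probabilities must be in [0, 1]")
  if (foreground_factor <= 0) stopf("foreground_factor must be > 0")
  structure(list(patch_size = as.integer(patch_size),
                 patches_per_image = as.integer(patches_per_image),
                 flip_lr_prob = flip_lr_prob, flip_ud_prob = flip_ud_prob,
                 rng_seed = as.integer(rng_seed),
                 foreground_factor = foreground_factor),
            class = "augment_config")
}

#' Mirror-extend an image to nine times its area
#'
#' Produces a 3H x 3W image whose central block is the input and whose eight
#' surrounding blocks are mirror reflections (symmetric padding: the border
#' pixel is included in the reflection).
#'
#' @param image matrix or H x W x C array.
#' @return extended matrix/array of size 3H x 3W.
#' @export
mirror_extend <- function(image) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  ri <- c(rev(seq_len(H)), seq_len(H), rev(seq_len(H)))
  ci <- c(rev(seq_len(W)), seq_len(W), rev(seq_len(W)))
  if (length(d) == 2) image[ri, ci, drop = FALSE]
  else image[ri, ci, , drop = FALSE]
}

#' Randomly flip a data/label pair, keeping them spatially consistent
#'
#' The same flip decisions (drawn from the current RNG stream) are applied
#' to both images.
#'
#' @param data matrix or H x W x C array.
#' @param label matrix with the same spatial size.
#' @param flip_lr_prob,flip_ud_prob flip probabilities.
#' @return list with flipped `data`, `label`, and the logical decisions
#'   `flipped_lr`, `flipped_ud`.
#' @export
random_flip <- function(data, label, flip_lr_prob = 0.5, flip_ud_prob = 0.5) {
  assert_same_dim(data, label, "data and label")
  lr <- runif(1) < flip_lr_prob
  ud <- runif(1) < flip_ud_prob
  flip2 <- function(x) {
    d <- dim(x)
    ri <- if (ud) rev(seq_len(d[1])) else seq_len(d[1])
    ci <- if (lr) rev(seq_len(d[2])) else seq_len(d[2])
    if (length(d) == 2) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
  }
  list(data = flip2(data), label = flip2(label),
       flipped_lr = lr, flipped_ud = ud)
}

#' Crop the same random window from a data/label pair
#'
#' The offset is drawn uniformly over all valid positions.
#'
#' @param data matrix or H x W x C array (typically mirror-extended).
#' @param label matrix with the same spatial size.
#' @param patch_size square window side, pixels.
#' @return list with `data`, `label` patches and the 1-based `offset`
#'   `(row, col)` of the window's top-left corner.
#' @export
random_crop <- function(data, label, patch_size) {
  assert_same_dim(data, label, "data and label")
  d <- dim(data)
  if (patch_size > d[1] || patch_size > d[2])
    stopf("patch_size %d exceeds image size %dx%d", patch_size, d[1], d[2])
  r0 <- sample.int(d[1] - patch_size + 1L, 1L)
  c0 <- sample.int(d[2] - patch_size + 1L, 1L)
  ri <- r0:(r0 + patch_size - 1L)
  ci <- c0:(c0 + patch_size - 1L)
  dd <- if (length(d) == 2) data[ri, ci, drop = FALSE]
        else data[ri, ci, , drop = FALSE]
  list(data = dd, label = label[ri, ci, drop = FALSE],
       offset = c(row = r0, col = c0))
}

#' Normalize data channels to [0, 1] and subtract the median
#'
#' Per channel: `x' = (x - min) / (max - min)`, then `x'' = x' - median(x')`,
#' so the output median is 0 and all values lie in `[-1, 1]`. A constant
#' channel becomes all zeros with a warning.
#'
#' @param data matrix or H x W x C array.
#' @return normalized data of the same shape.
#' @export
normalize_data <- function(data) {
  x <- as_channels(data)
  for (c in seq_len(dim(x)[3])) {
    ch <- x[, , c]
    rng <- range(ch)
    if (diff(rng) == 0) {
      warnf("constant channel %d normalized to all zeros", c)
      x[, , c] <- 0
    } else {
      ch <- (ch - rng[1]) / diff(rng)
      x[, , c] <- ch - stats::median(ch)
    }
  }
  if (is.matrix(data)) {
    out <- x[, , 1]
    dim(out) <- dim(data)
    out
  } else x
}

#' Build the class-balancing weight image for a binary label patch
#'
#' Background weight is 1 and foreground weight is
#' `foreground_factor * N_bg / N_fg`, so the total foreground weight equals
#' `foreground_factor` times the total background weight. Foreground
#' weights are quantized to multiples of 2^-20 (a relative perturbation
#' below 1e-6) with the remainder placed on a single pixel, which makes the
#' balance identity hold *exactly* in floating-point arithmetic, in any
#' summation order, whenever `foreground_factor` is itself exactly
#' representable. A single-class patch gets all weights 1 with a warning.
#'
#' @param label binary (or instance) label matrix; any id > 0 is foreground.
#' @param foreground_factor extra foreground emphasis (default 3).
#' @return positive weight matrix of the same size.
#' @export
make_weight_image <- function(label, foreground_factor = 3) {
  if (!is.matrix(label)) stopf("label must be a matrix")
  fg <- label > 0
  n_fg <- sum(fg); n_bg <- length(label) - n_fg
  w <- matrix(1, nrow(label), ncol(label))
  if (n_fg == 0 || n_bg == 0) {
    warnf("single-class patch: uniform weights")
    return(w)
  }
  target <- foreground_factor * n_bg
  ## dyadic quantization: weights that are multiples of 2^-20 sum exactly
  ## (no rounding in any order), so the class balance is an identity rather
  ## than an approximation
  scale <- 2^20
  q <- floor(target * scale / n_fg) / scale
  if (q * n_fg > target) q <- q - 1 / scale
  remainder <- target - q * n_fg
  idx <- which(fg)
  w[idx] <- q
  w[idx[1]] <- q + remainder
  w
}

#' Build an augmented, weighted training set from (data, label) pairs
#'
#' For each pair: random flip, mirror extension, `patches_per_image` random
#' crops, per-channel normalization of the data patch, binarization of the
#' label patch, and weight-image computation. Fully deterministic given
#' `cfg$rng_seed`.
#'
#' @param pairs list of lists with elements `data` (H x W x C array or
#'   matrix) and `labels` (label matrix), e.g. [build_training_pairs()]
#'   outputs.
#' @param cfg an [augment_config()].
#' @return object of class `training_set`: list of samples (`data`, `label`,
#'   `weight`) with the config and seed attached as attributes.
#' @export
build_dataset <- function(pairs, cfg = augment_config()) {
  if (length(pairs) == 0) stopf("need at least one (data, label) pair")
  samples <- with_seed(cfg$rng_seed, {
    out <- vector("list", length(pairs) * cfg$patches_per_image)
    i <- 0L
    for (pair in pairs) {
      d <- as_channels(pair$data)
      lab <- pair$labels
      if (cfg$patch_size > 3 * min(dim(lab)))
        stopf("patch_size must be at most 3x the smallest image dimension")
      fl <- random_flip(d, lab, cfg$flip_lr_prob, cfg$flip_ud_prob)
      dext <- mirror_extend(fl$data)
      lext <- mirror_extend(fl$label)
      for (k in seq_len(cfg$patches_per_image)) {
        cr <- random_crop(dext, lext, cfg$patch_size)
        label <- (cr$label > 0) * 1L
        storage.mode(label) <- "integer"
        i <- i + 1L
        out[[i]] <- list(
          data = suppressWarnings(normalize_data(cr$data)),
          label = label,
          weight = suppressWarnings(
            make_weight_image(label, cfg$foreground_factor)))
      }
    }
    out
  })
  structure(samples, class = "training_set", config = cfg,
            rng_seed = cfg$rng_seed)
}

#' Serialize a training set
#'
#' Writes the samples plus their config and seed as a single RDS container,
#' or as the plain-TIFF fallback layout (one directory per sample holding
#' `data.tif`, `label.tif`, `weight.tif`).
#'
#' @param dataset a `training_set` from [build_dataset()].
#' @param path output `.rds` file (format `"rds"`) or directory
#'   (format `"tiff"`).
#' @param format `"rds"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("rds", "tiff")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(dataset, path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(dataset)) {
      d <- file.path(path, sprintf("sample%05d", i))
      dir.create(d, showWarnings = FALSE)
      s <- dataset[[i]]
      planes <- lapply(seq_len(dim(s$data)[3]), function(c) s$data[, , c])
      write_image_tiff(planes, file.path(d, "data.tif"))
      write_label_tiff(s$label, file.path(d, "label.tif"))
      write_image_tiff(s$weight, file.path(d, "weight.tif"))
    }
    cfg <- attr(dataset, "config"); class(cfg) <- NULL
    yaml::write_yaml(cfg, file.path(path, "config.yaml"))
  }
  invisible(path)
}

#' Read a training set written by [write_dataset()] (RDS format)
#'
#' @param path `.rds` file path.
#' @return a `training_set`.
#' @export
read_dataset <- function(path) readRDS(path)
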