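## Automatic ground-truth generation from fluorescence channels.
##
## Nuclei are segmented from the nuclear channel by global (Otsu)
## thresholding with watershed declumping; cells are then grown from the
## nuclei as seeds over the contrast-enhanced (grayscale-dilated) cytoplasm
## channel, restricted to a thresholded foreground mask, following the
## primary/secondary-object convention of CellProfiler-style pipelines.

#' Ground-truth generation configuration
#'
#' @param dilation_disk_diameter diameter (odd, pixels) of the disc used for
#'   grayscale dilation of the cytoplasm channel before seeded growth.
#' @param min_nucleus_area nuclei smaller than this (pixels^2) are removed.
#' @param threshold_method global threshold rule; currently `"otsu"`.
#' @param split_touching declump touching nuclei with a distance-transform
#'   watershed.
#' @return a `groundtruth_config` list.
#' @export
groundtruth_config <- function(dilation_disk_diameter = 5,
                               min_nucleus_area = 25,
                               threshold_method = "otsu",
                               split_touching = TRUE) {
  if (dilation_disk_diameter < 1 || dilation_disk_diameter %% 2 != 1)
    stopf("dilation_disk_diameter must be odd and >= 1")
  if (min_nucleus_area < 0) stopf("min_nucleus_area must be >= 0")
  threshold_method <- match.arg(threshold_method, "otsu")
  structure(list(dilation_disk_diameter = as.integer(dilation_disk_diameter),
                 min_nucleus_area = as.numeric(min_nucleus_area),
                 threshold_method = threshold_method,
                 split_touching = isTRUE(split_touching)),
            class = "groundtruth_config")
}

#' Average-project a z-stack into a single channel image
#'
#' @param zstack non-empty list of equally sized intensity matrices.
#' @return pixelwise arithmetic mean matrix.
#' @export
average_project <- function(zstack) {
  if (!is.list(zstack) || length(zstack) == 0)
    stopf("zstack must be a non-empty list of matrices")
  for (p in zstack) assert_same_dim(zstack[[1]], p, "z-planes")
  Reduce(`+`, zstack) / length(zstack)
}

#' Segment nuclei by global thresholding plus watershed declumping
#'
#' Foreground is every pixel at or above the global Otsu threshold; touching
#' nuclei are split by a watershed on the distance transform (shape-based
#' declumping); components below `min_nucleus_area` are dropped and ids are
#' relabeled consecutively. Every output object is spatially connected.
#'
#' @param nuclei_image illumination-corrected, projected nuclear channel.
#' @param cfg a [groundtruth_config()].
#' @return label matrix; empty (all zero, with a warning) when no pixel
#'   clears the threshold.
#' @export
segment_nuclei <- function(nuclei_image, cfg = groundtruth_config()) {
  assert_matrix(nuclei_image)
  empty <- matrix(0L, nrow(nuclei_image), ncol(nuclei_image))
  if (diff(range(nuclei_image)) < .Machine$double.eps) {
    warnf("contrast-free nuclei image; empty nuclei mask")
    return(empty)
  }
  ## the threshold must clear the background noise floor: on an object-free
  ## image Otsu merely splits the noise distribution, so require the
  ## threshold to sit distinctly above the bulk of the intensities
  thr <- otsu_threshold(nuclei_image)
  guard <- stats::median(nuclei_image) + 3 * stats::mad(nuclei_image)
  if (thr <= guard) {
    warnf("global threshold does not clear the noise floor; empty nuclei mask")
    return(empty)
  }
  fg <- nuclei_image >= thr
  mask <- as_ebimage(fg * 1)
  if (cfg$split_touching) {
    dm <- EBImage::distmap(mask)
    ## ext controls the neighborhood for regional-maximum seeds: of the order
    ## of the smallest believable nucleus radius
    ext <- max(1L, as.integer(floor(sqrt(cfg$min_nucleus_area / pi))))
    lab <- EBImage::watershed(dm, tolerance = 1, ext = ext)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  labels <- from_ebimage(lab)
  storage.mode(labels) <- "integer"
  labels <- filter_small_objects(labels, cfg$min_nucleus_area)
  labels <- relabel_consecutive(labels)
  if (max(labels) == 0L)
    warnf("no nuclei survive thresholding and size filtering; empty mask")
  labels
}

#' Grow cell regions from nuclear seeds over the cytoplasm channel
#'
#' The cytoplasm image is contrast-enhanced by grayscale dilation with a
#' disc-shaped structuring element, thresholded globally to obtain the cell
#' foreground, and partitioned among the nuclei by seeded region growing
#' (the propagation algorithm CellProfiler uses for secondary objects).
#' Every output cell keeps the id of its seed nucleus; cells without a seed
#' do not exist.
#'
#' @param cytoplasm_image illumination-corrected, projected cytoplasm channel.
#' @param nuclei seed label matrix (e.g. [segment_nuclei()] output).
#' @param cfg a [groundtruth_config()].
#' @return cell label matrix with `ids == ids(nuclei)`.
#' @export
segment_cells <- function(cytoplasm_image, nuclei,
                          cfg = groundtruth_config()) {
  assert_matrix(cytoplasm_image)
  nuclei <- validate_label_image(nuclei)
  assert_same_dim(cytoplasm_image, nuclei, "cytoplasm image and nuclei")
  if (all(nuclei == 0)) {
    warnf("no nuclear seeds; empty cell mask")
    return(matrix(0L, nrow(cytoplasm_image), ncol(cytoplasm_image)))
  }
  brush <- EBImage::makeBrush(cfg$dilation_disk_diameter, shape = "disc")
  dil <- from_ebimage(EBImage::dilate(as_ebimage(cytoplasm_image), brush))
  thr <- otsu_threshold(dil)
  ## the grayscale dilation inflates the thresholded support by the brush
  ## radius; erode the mask back so cell outlines track the true intensity
  ## support rather than its dilation
  fg <- from_ebimage(EBImage::erode(as_ebimage((dil >= thr) * 1), brush)) > 0
  fg <- fg | nuclei > 0   # seeds always belong to the foreground
  cells <- EBImage::propagate(as_ebimage(dil), seeds = as_ebimage(nuclei),
                              mask = as_ebimage(fg * 1), lambda = 1e-4)
  out <- from_ebimage(cells)
  storage.mode(out) <- "integer"
  out
}

#' Build (data, label) training pairs from a scene's channels
#'
#' Orchestrates the automatic training-set generation for one imaging site:
#' per-plane illumination correction, average projection of the fluorescence
#' stacks, nuclei segmentation and (in timelapse mode) seeded cell growth.
#'
#' In timelapse mode the data is the corrected 3-plane bright-field stack and
#' the label is the cell mask; in multichannel5 mode the data is the four
#' corrected non-nuclear channels and the label is the nuclei mask (there is
#' no cytoplasm stage).
#'
#' @param scene a `synthetic_scene` (or any list with the same channel
#'   fields).
#' @param cfg a [groundtruth_config()].
#' @param illum_cfg base [illumination_config()]; the bright-field planes are
#'   corrected with two-sided exclusion, fluorescence with one-sided.
#' @return list with `data` (H x W x C array, C = 3 or 4), `labels` (cell or
#'   nuclei label matrix), and `nuclei` (nuclei label matrix).
#' @export
build_training_pairs <- function(scene, cfg = groundtruth_config(),
                                 illum_cfg = illumination_config()) {
  fluor_cfg <- illum_cfg; fluor_cfg$exclusion_side <- "upper"
  bf_cfg <- illum_cfg; bf_cfg$exclusion_side <- "both"
  if (scene$spec$mode == "timelapse") {
    bf <- correct_zstack(scene$brightfield, bf_cfg)
    nuc <- average_project(correct_zstack(scene$nuclei_channel, fluor_cfg))
    cyto <- average_project(correct_zstack(scene$cytoplasm_channel, fluor_cfg))
    nuclei <- segment_nuclei(nuc, cfg)
    cells <- segment_cells(cyto, nuclei, cfg)
    data <- array(unlist(bf), dim = c(nrow(nuclei), ncol(nuclei), length(bf)))
    list(data = data, labels = cells, nuclei = nuclei)
  } else {
    chans <- lapply(scene$channels5, function(ch)
      correct_illumination(ch, estimate_background(ch, fluor_cfg)))
    nuclei <- segment_nuclei(chans[[1]], cfg)
    data <- array(unlist(chans[2:5]),
                  dim = c(nrow(nuclei), ncol(nuclei), 4L))
    list(data = data, labels = nuclei, nuclei = nuclei)
  }
}
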