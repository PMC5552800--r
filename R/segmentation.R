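## From blended probability maps to instance label images.
##
## The probability map is thresholded, seeds are planted at well-separated
## local maxima of a smoothed copy, the foreground is partitioned among the
## seeds by watershed-style region growing, and the resulting instances are
## expanded by a label-safe dilation to compensate for the network's
## systematic under-estimation of cell extent.

#' Instance extraction configuration
#'
#' @param prob_threshold foreground threshold on the probability map, in
#'   `(0, 1)`.
#' @param seed_smoothing_sigma Gaussian sigma (pixels) applied before seed
#'   detection.
#' @param seed_min_distance minimum separation (pixels) between seed maxima.
#' @param min_cell_area instances smaller than this (pixels^2) are dropped.
#' @param dilation_size odd side of the square dilation element (9 for
#'   bright-field time-lapse, 3 for the five-channel mode).
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(prob_threshold = 0.5,
                                seed_smoothing_sigma = 3,
                                seed_min_distance = 10,
                                min_cell_area = 25,
                                dilation_size = 9) {
  if (prob_threshold <= 0 || prob_threshold >= 1)
    stopf("prob_threshold must be in (0, 1)")
  if (dilation_size < 1 || dilation_size %% 2 != 1)
    stopf("dilation_size must be odd and >= 1")
  structure(list(prob_threshold = prob_threshold,
                 seed_smoothing_sigma = seed_smoothing_sigma,
                 seed_min_distance = as.integer(seed_min_distance),
                 min_cell_area = as.numeric(min_cell_area),
                 dilation_size = as.integer(dilation_size)),
            class = "segmentation_config")
}

## Local maxima of `x` within `mask`, separated by at least min_distance:
## pixels equal to the grayscale dilation of x over a disc of that radius.
## Plateau maxima are merged into one seed per connected component.
find_seeds <- function(x, mask, min_distance) {
  r <- max(1L, as.integer(min_distance))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  localmax <- from_ebimage(EBImage::dilate(as_ebimage(x), brush))
  seeds <- (x >= localmax) & mask
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(seeds * 1)))
  storage.mode(lab) <- "integer"
  lab
}

#' Convert a probability map to instance labels
#'
#' Foreground is `prob >= prob_threshold`; seeds are the regional maxima of
#' the Gaussian-smoothed map with minimum separation `seed_min_distance`;
#' the foreground is then partitioned among the seeds by seeded
#' watershed-style growing on the probability landscape. Components below
#' `min_cell_area` are removed and ids are relabeled consecutively.
#'
#' @param prob probability matrix in `[0, 1]`.
#' @param cfg a [segmentation_config()].
#' @return instance label matrix (empty when nothing clears the threshold).
#' @export
probability_to_instances <- function(prob, cfg = segmentation_config()) {
  assert_matrix(prob)
  if (min(prob) < 0 || max(prob) > 1)
    stopf("probability map must lie in [0, 1]")
  fg <- prob >= cfg$prob_threshold
  if (!any(fg))
    return(matrix(0L, nrow(prob), ncol(prob)))
  sm <- gblur0(prob, cfg$seed_smoothing_sigma)
  seeds <- find_seeds(sm, fg, cfg$seed_min_distance)
  if (!any(seeds > 0))
    return(matrix(0L, nrow(prob), ncol(prob)))
  lab <- EBImage::propagate(as_ebimage(sm), seeds = as_ebimage(seeds),
                            mask = as_ebimage(fg * 1), lambda = 1e-4)
  labels <- from_ebimage(lab)
  storage.mode(labels) <- "integer"
  labels <- filter_small_objects(labels, cfg$min_cell_area)
  relabel_consecutive(labels)
}

#' Label-safe dilation of an instance mask
#'
#' Each label expands into the background under a square structuring element
#' of the given size (Chebyshev radius `(size - 1) / 2`), implemented as
#' iterative nearest-label growth: expansion never overwrites another label,
#' and a background pixel reachable from several labels in the same step
#' goes to the lowest id. The label count is preserved.
#'
#' @param labels instance label matrix.
#' @param dilation_size odd square element side.
#' @return dilated label matrix.
#' @export
dilate_labels <- function(labels, dilation_size = 9) {
  labels <- validate_label_image(labels)
  if (dilation_size < 1 || dilation_size %% 2 != 1)
    stopf("dilation_size must be odd and >= 1")
  r <- (dilation_size - 1L) %/% 2L
  if (r == 0L || all(labels == 0)) return(labels)
  H <- nrow(labels); W <- ncol(labels)
  out <- labels
  for (step in seq_len(r)) {
    cur <- out
    cand <- matrix(Inf, H, W)
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        src_r <- seq_len(H) - dr; src_c <- seq_len(W) - dc
        keep_r <- src_r >= 1 & src_r <= H
        keep_c <- src_c >= 1 & src_c <= W
        shifted <- matrix(Inf, H, W)
        sh <- cur[src_r[keep_r], src_c[keep_c], drop = FALSE]
        sh[sh == 0L] <- Inf
        shifted[keep_r, keep_c] <- sh
        cand <- pmin(cand, shifted)
      }
    }
    grow <- out == 0L & is.finite(cand)
    if (!any(grow)) break
    out[grow] <- as.integer(cand[grow])
  }
  out
}
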