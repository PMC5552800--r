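## Instance label images and TIFF serialization.
##
## A label image is a non-negative integer matrix: 0 is background, k > 0 is
## object k. Label images are the currency between ground-truth generation,
## instance segmentation and evaluation.

#' Validate a label image
#'
#' Checks that `labels` is a non-negative integer-valued matrix with ids small
#' enough for 16-bit serialization.
#'
#' @param labels matrix of non-negative integers; 0 = background.
#' @return the validated label matrix (integer storage), invisibly.
#' @export
validate_label_image <- function(labels) {
  if (!is.matrix(labels)) stopf("label image must be a matrix")
  if (any(!is.finite(labels))) stopf("label image contains non-finite values")
  if (any(labels < 0)) stopf("label image contains negative ids")
  if (any(labels != round(labels))) stopf("label ids must be integers")
  if (max(labels) > 65535) stopf("label ids exceed 65535 (16-bit limit)")
  storage.mode(labels) <- "integer"
  invisible(labels)
}

#' Relabel objects with consecutive ids 1..n
#'
#' Ids are renumbered in order of their first appearance in column-major scan
#' order; background stays 0.
#'
#' @param labels label image matrix.
#' @return relabeled integer matrix.
#' @export
relabel_consecutive <- function(labels) {
  ids <- unique(labels[labels > 0])
  if (length(ids) == 0) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- labels
  pos <- labels > 0
  out[pos] <- map[labels[pos]]
  storage.mode(out) <- "integer"
  out
}

## Drop objects smaller than min_area pixels (0 disables).
filter_small_objects <- function(labels, min_area) {
  if (min_area <= 0) return(labels)
  ids <- labels[labels > 0]
  if (length(ids) == 0) return(labels)
  areas <- tabulate(ids, nbins = max(ids))
  kill <- which(areas > 0 & areas < min_area)
  if (length(kill)) labels[labels %in% kill] <- 0L
  labels
}

#' Write a label image as 16-bit single-page TIFF
#'
#' @param labels label image matrix (max id 65535).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  labels <- validate_label_image(labels)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a 16-bit label TIFF written by [write_label_tiff()]
#'
#' @param path file path.
#' @return integer label matrix.
#' @export
read_label_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  out <- round(x * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write an intensity image (or z-stack) as floating-point TIFF
#'
#' Multi-plane stacks (lists of matrices) become multi-page TIFFs, one page
#' per plane.
#'
#' @param x matrix, or list of matrices of equal size.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  pages <- if (is.list(x)) x else list(x)
  ## 32-bit pages are stored as floats, where values outside [0,1] are
  ## legitimate; the writer's range warning does not apply to that format
  suppressWarnings(
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                    compression = "none"))
  invisible(path)
}

#' Read an intensity TIFF as matrix or list of plane matrices
#'
#' @param path file path.
#' @param as_stack return a list of planes even for single-page files.
#' @return matrix (single page, `as_stack = FALSE`) or list of matrices.
#' @export
read_image_tiff <- function(path, as_stack = FALSE) {
  x <- tiff::readTIFF(path, all = TRUE)
  x <- lapply(x, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  if (!as_stack && length(x) == 1L) x[[1]] else x
}
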