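## Seam-free tiled inference.
##
## Full images are processed as two grids of non-overlapping tiles, the
## second shifted by half a tile so its tile centers sit on the first grid's
## edges. Each pass's stitched probability map is blended with
## Gaussian-weighted averaging that down-weights every pixel near its own
## tile's edges, removing the edge artifacts a single tiling produces.

#' Tiling configuration
#'
#' @param tile_size square tile side, pixels.
#' @param shift second-pass offset; fixed at `tile_size / 2` (tiles shifted
#'   left and up by half a tile).
#' @param gaussian_sigma sigma of the blending weight, pixels.
#' @return a `tiling_config` list.
#' @export
tiling_config <- function(tile_size = 240, shift = tile_size / 2,
                          gaussian_sigma = tile_size / 4) {
  if (shift != tile_size / 2)
    stopf("shift must equal tile_size / 2 (half-tile second pass)")
  if (gaussian_sigma <= 0) stopf("gaussian_sigma must be > 0")
  if (tile_size < 2 || tile_size %% 2 != 0)
    stopf("tile_size must be an even positive number")
  structure(list(tile_size = as.integer(tile_size), shift = as.integer(shift),
                 gaussian_sigma = gaussian_sigma),
            class = "tiling_config")
}

#' Gaussian blending weight tile
#'
#' Separable Gaussian centered on the tile, normalized to maximum 1 and
#' floored at `1e-6` so every pixel keeps positive weight.
#'
#' @param tile_size square tile side.
#' @param sigma Gaussian sigma in pixels.
#' @return `tile_size` x `tile_size` weight matrix.
#' @export
gaussian_weight <- function(tile_size, sigma) {
  if (sigma <= 0) stopf("sigma must be > 0")
  ctr <- (tile_size + 1) / 2
  g <- exp(-((seq_len(tile_size) - ctr)^2) / (2 * sigma^2))
  w <- outer(g, g)
  pmax(w / max(w), 1e-6)
}

#' Tile grids of the two inference passes
#'
#' The image is conceptually mirror-padded by one tile on the top/left and
#' enough on the bottom/right that both grids consist of full tiles and
#' every original pixel is covered by exactly one tile per pass. Offsets are
#' relative to the padded canvas; `origin` locates original pixel (1, 1).
#'
#' @param image_size `(height, width)` of the original image.
#' @param cfg a [tiling_config()].
#' @return list with `pass1`, `pass2` (data.frames of tile `row`/`col`
#'   starts), `canvas` (padded size) and `origin`.
#' @export
tile_passes <- function(image_size, cfg = tiling_config()) {
  H <- image_size[1]; W <- image_size[2]
  ts <- cfg$tile_size; sh <- cfg$shift
  canvas <- c(ts + ceiling(H / ts) * ts + ts,
              ts + ceiling(W / ts) * ts + ts)
  grid1 <- list(row = as.integer(seq(1L, canvas[1] - ts + 1L, by = ts)),
                col = as.integer(seq(1L, canvas[2] - ts + 1L, by = ts)))
  grid2 <- list(row = as.integer(seq(1L + sh, canvas[1] - ts + 1L, by = ts)),
                col = as.integer(seq(1L + sh, canvas[2] - ts + 1L, by = ts)))
  expand_grid <- function(g)
    data.frame(row = rep(g$row, times = length(g$col)),
               col = rep(g$col, each = length(g$row)))
  list(pass1 = expand_grid(grid1), pass2 = expand_grid(grid2),
       canvas = as.integer(canvas), origin = c(ts + 1L, ts + 1L))
}

## Mirror-pad a channel array onto the tiling canvas.
pad_to_canvas <- function(data, passes) {
  x <- as_channels(data)
  d <- dim(x)
  ri <- reflect_index(seq_len(passes$canvas[1]) - passes$origin[1] + 1L, d[1])
  ci <- reflect_index(seq_len(passes$canvas[2]) - passes$origin[2] + 1L, d[2])
  x[ri, ci, , drop = FALSE]
}

## Stitch one pass: run the model tile by tile over its non-overlapping
## grid, filling a canvas-sized probability map.
stitch_pass <- function(forward, padded, tiles, ts, canvas) {
  out <- matrix(NA_real_, canvas[1], canvas[2])
  for (k in seq_len(nrow(tiles))) {
    r <- tiles$row[k]; c <- tiles$col[k]
    tile <- padded[r:(r + ts - 1L), c:(c + ts - 1L), , drop = FALSE]
    out[r:(r + ts - 1L), c:(c + ts - 1L)] <- forward(tile)
  }
  out
}

#' Tiled, Gaussian-blended prediction of a full image
#'
#' Both passes cover every pixel exactly once, so the blend reduces to a
#' per-pixel weighted average of the two stitched maps,
#' `P1 + (P2 - P1) * w2 / (w1 + w2)`, with the Gaussian tile weights `w`.
#' Pixels where both passes agree are returned bit-exactly, so a model whose
#' output is independent of the tile framing (e.g. a pixelwise model) gives
#' exactly its whole-image output.
#'
#' @param model a `brightseg_model`, or a function `f(tile_array) ->
#'   probability matrix` (useful for testing and for wrapping other
#'   predictors).
#' @param data H x W x C array (or matrix for single-channel models).
#' @param cfg a [tiling_config()]; the tile size must be divisible by
#'   `2^n_levels` when a network model is used.
#' @param two_pass set `FALSE` to return the first-pass stitching alone
#'   (exhibits the tile-edge artifacts the second pass removes).
#' @return probability matrix in `[0, 1]`, same size as the input image.
#' @export
predict_tiled <- function(model, data, cfg = tiling_config(),
                          two_pass = TRUE) {
  forward <- if (is.function(model)) model
             else function(tile) nn_predict(model, tile)
  x <- as_channels(data)
  d <- dim(x)
  passes <- tile_passes(d[1:2], cfg)
  padded <- pad_to_canvas(x, passes)
  ts <- cfg$tile_size
  p1 <- stitch_pass(forward, padded, passes$pass1, ts, passes$canvas)
  rows <- passes$origin[1]:(passes$origin[1] + d[1] - 1L)
  cols <- passes$origin[2]:(passes$origin[2] + d[2] - 1L)
  if (!two_pass) return(p1[rows, cols])
  p2 <- stitch_pass(forward, padded, passes$pass2, ts, passes$canvas)
  wt <- gaussian_weight(ts, cfg$gaussian_sigma)
  w1 <- matrix(0, passes$canvas[1], passes$canvas[2])
  w2 <- matrix(0, passes$canvas[1], passes$canvas[2])
  for (k in seq_len(nrow(passes$pass1))) {
    r <- passes$pass1$row[k]; c <- passes$pass1$col[k]
    w1[r:(r + ts - 1L), c:(c + ts - 1L)] <- wt
  }
  for (k in seq_len(nrow(passes$pass2))) {
    r <- passes$pass2$row[k]; c <- passes$pass2$col[k]
    w2[r:(r + ts - 1L), c:(c + ts - 1L)] <- wt
  }
  ## pass-2 tiles may not reach the outermost padding frame; those pixels
  ## keep the pass-1 value (they are outside the original image anyway)
  blend <- p1
  both <- !is.na(p2) & w2 > 0
  blend[both] <- p1[both] +
    (p2[both] - p1[both]) * (w2[both] / (w1[both] + w2[both]))
  blend[rows, cols]
}
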