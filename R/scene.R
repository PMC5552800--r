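## Synthetic microscopy scenes with known instance ground truth.
##
## Emulates the two acquisition modes of the self-training workflow:
##   * "timelapse"     - 3-plane bright-field z-stacks of unstained cells plus
##                       end-point nuclear and cytoplasmic fluorescence stacks;
##   * "multichannel5" - five single-plane fluorescence channels, channel 1
##                       nuclear, the rest other intracellular structures.
## Cells are random ellipses with an interior nucleus; channels are modulated
## by a smooth multiplicative illumination field and corrupted by Gaussian
## noise. The true instance mask is retained as the oracle for every
## downstream stage.

#' Scene specification
#'
#' @param width,height image size in pixels.
#' @param n_cells number of cells to attempt to place.
#' @param cell_radius_range `(min, max)` cell semi-major axis, pixels.
#' @param nucleus_radius_range `(min, max)` nucleus semi-major axis, pixels;
#'   the maximum must be below the minimum cell radius.
#' @param min_center_distance minimum distance between cell centers, pixels.
#' @param z_offsets Gaussian blur sigma (pixels) of each of the 3 focal
#'   planes (timelapse mode).
#' @param illumination_amplitude relative amplitude of the smooth
#'   multiplicative illumination field, in `[0, 1)`.
#' @param noise_sd standard deviation of additive Gaussian noise, intensity
#'   units (images are rendered on a 0..~1 scale).
#' @param bf_contrast scales the bright-field deviations from background
#'   (interior 0.98x, rim 0.85x, halo 1.1x at `bf_contrast = 1`).
#' @param rng_seed integer seed; scenes are bit-reproducible given the spec.
#' @param mode `"timelapse"` or `"multichannel5"`.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 512, height = 512, n_cells = 20,
                       cell_radius_range = c(12, 18),
                       nucleus_radius_range = c(4, 7),
                       min_center_distance = 30,
                       z_offsets = c(0.5, 1.5, 2.5),
                       illumination_amplitude = 0.15,
                       noise_sd = 0.01,
                       bf_contrast = 1,
                       rng_seed = 1L,
                       mode = c("timelapse", "multichannel5")) {
  mode <- match.arg(mode)
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_cells = as.integer(n_cells),
               cell_radius_range = as.numeric(cell_radius_range),
               nucleus_radius_range = as.numeric(nucleus_radius_range),
               min_center_distance = as.numeric(min_center_distance),
               z_offsets = as.numeric(z_offsets),
               illumination_amplitude = as.numeric(illumination_amplitude),
               noise_sd = as.numeric(noise_sd),
               bf_contrast = as.numeric(bf_contrast),
               rng_seed = as.integer(rng_seed), mode = mode)
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (length(cell_radius_range) != 2 || diff(cell_radius_range) < 0)
      stopf("cell_radius_range must be (min, max)")
    if (length(nucleus_radius_range) != 2 || diff(nucleus_radius_range) < 0)
      stopf("nucleus_radius_range must be (min, max)")
    if (nucleus_radius_range[2] >= cell_radius_range[1])
      stopf("nucleus radii must be smaller than the minimum cell radius")
    if (width < 4 * cell_radius_range[2] || height < 4 * cell_radius_range[2])
      stopf("scene must be at least 4 cell radii wide and high")
    if (mode == "timelapse" && length(z_offsets) != 3)
      stopf("timelapse mode requires 3 z-plane blur offsets")
    if (illumination_amplitude < 0 || illumination_amplitude >= 1)
      stopf("illumination_amplitude must be in [0, 1)")
    if (noise_sd < 0) stopf("noise_sd must be >= 0")
    if (n_cells < 0) stopf("n_cells must be >= 0")
  })
  invisible(spec)
}

## Rejection-sampled cell placement. Returns a data.frame of cell geometry;
## may contain fewer than n_cells rows (with a warning).
place_cells <- function(spec) {
  n <- spec$n_cells
  geom <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                     b = numeric(0), theta = numeric(0),
                     na_ = numeric(0), nb = numeric(0), ntheta = numeric(0),
                     ndx = numeric(0), ndy = numeric(0),
                     fluor_nuc = numeric(0), fluor_cyto = numeric(0))
  if (n == 0) return(geom)
  margin <- spec$cell_radius_range[2] + 1
  max_attempts <- 200L * n
  attempts <- 0L
  while (nrow(geom) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cx <- runif(1, margin, spec$width - margin)
    cy <- runif(1, margin, spec$height - margin)
    if (nrow(geom) > 0 &&
        min(sqrt((geom$cx - cx)^2 + (geom$cy - cy)^2)) < spec$min_center_distance)
      next
    a <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
    ecc <- runif(1, 0, 0.7)
    b <- a * sqrt(1 - ecc^2)
    theta <- runif(1, 0, pi)
    na_ <- runif(1, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
    necc <- runif(1, 0, 0.7)
    nb <- na_ * sqrt(1 - necc^2)
    ntheta <- runif(1, 0, pi)
    jmax <- max(0, b - na_ - 1)
    jr <- runif(1, 0, jmax)
    jang <- runif(1, 0, 2 * pi)
    geom <- rbind(geom, data.frame(
      cx = cx, cy = cy, a = a, b = b, theta = theta,
      na_ = na_, nb = nb, ntheta = ntheta,
      ndx = jr * cos(jang), ndy = jr * sin(jang),
      fluor_nuc = runif(1, 0.85, 1.0), fluor_cyto = runif(1, 0.55, 0.75)))
  }
  if (nrow(geom) < n)
    warnf("placed only %d of %d cells after %d attempts", nrow(geom), n,
          attempts)
  geom
}

## Normalized squared elliptical distance of pixel offsets (dx, dy) for an
## ellipse with semi-axes (a, b) rotated by theta; <= 1 means inside.
ellipse_d2 <- function(dx, dy, a, b, theta) {
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2
}

## Rasterize cell/nucleus ellipses into instance masks. Contested pixels go
## to the cell with the smallest normalized elliptical distance.
rasterize_cells <- function(geom, spec, cx = geom$cx, cy = geom$cy) {
  H <- spec$height; W <- spec$width
  truth <- matrix(0L, H, W)
  nuclei <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  if (nrow(geom) == 0) return(list(truth = truth, nuclei = nuclei))
  for (k in seq_len(nrow(geom))) {
    g <- geom[k, ]
    r <- g$a + 2
    rows <- max(1, floor(cy[k] - r)):min(H, ceiling(cy[k] + r))
    cols <- max(1, floor(cx[k] - r)):min(W, ceiling(cx[k] + r))
    dx <- outer(rep(1, length(rows)), cols - cx[k])
    dy <- outer(rows - cy[k], rep(1, length(cols)))
    d2 <- ellipse_d2(dx, dy, g$a, g$b, g$theta)
    sub_t <- truth[rows, cols]; sub_d <- bestd[rows, cols]
    take <- d2 <= 1 & d2 < sub_d
    sub_t[take] <- k
    sub_d[take] <- d2[take]
    truth[rows, cols] <- sub_t
    bestd[rows, cols] <- sub_d
  }
  for (k in seq_len(nrow(geom))) {
    g <- geom[k, ]
    ncx <- cx[k] + g$ndx; ncy <- cy[k] + g$ndy
    r <- g$na_ + 2
    rows <- max(1, floor(ncy - r)):min(H, ceiling(ncy + r))
    cols <- max(1, floor(ncx - r)):min(W, ceiling(ncx + r))
    dx <- outer(rep(1, length(rows)), cols - ncx)
    dy <- outer(rows - ncy, rep(1, length(cols)))
    d2 <- ellipse_d2(dx, dy, g$na_, g$nb, g$ntheta)
    sub_n <- nuclei[rows, cols]
    take <- d2 <= 1 & truth[rows, cols] == k
    sub_n[take] <- k
    nuclei[rows, cols] <- sub_n
  }
  list(truth = truth, nuclei = nuclei)
}

## Smooth multiplicative illumination field: random quadratic polynomial
## surface, modulation scaled to the requested amplitude, unit mean.
make_illumination_field <- function(H, W, amplitude) {
  if (amplitude == 0) return(matrix(1, H, W))
  x <- matrix(rep(seq(-1, 1, length.out = W), each = H), H, W)
  y <- matrix(rep(seq(-1, 1, length.out = H), W), H, W)
  cf <- runif(5, -1, 1)
  g <- cf[1] * x + cf[2] * y + cf[3] * x * y + cf[4] * x^2 + cf[5] * y^2
  g <- g - mean(g)
  m <- max(abs(g))
  if (m == 0) return(matrix(1, H, W))
  f <- 1 + amplitude * g / m
  f / mean(f)
}

## Render noiseless fluorescence intensity images from the instance masks.
render_fluorescence <- function(truth, nuclei, geom, background = 0.08) {
  nuc <- matrix(background, nrow(truth), ncol(truth))
  cyto <- matrix(background, nrow(truth), ncol(truth))
  for (k in seq_len(nrow(geom))) {
    cyto[truth == k] <- geom$fluor_cyto[k]
    nuc[nuclei == k] <- geom$fluor_nuc[k]
  }
  list(nuclei = nuc, cytoplasm = cyto)
}

## Render the noiseless bright-field appearance: interior slightly dark, a
## ~2 px dark rim just inside the boundary, a ~1.5 px bright halo outside.
render_brightfield <- function(geom, spec, cx = geom$cx, cy = geom$cy,
                               background = 0.5) {
  H <- spec$height; W <- spec$width
  f <- matrix(1, H, W)
  for (k in seq_len(nrow(geom))) {
    g <- geom[k, ]
    halo_scale <- 1 + 1.5 / g$b
    r <- g$a * halo_scale + 2
    rows <- max(1, floor(cy[k] - r)):min(H, ceiling(cy[k] + r))
    cols <- max(1, floor(cx[k] - r)):min(W, ceiling(cx[k] + r))
    dx <- outer(rep(1, length(rows)), cols - cx[k])
    dy <- outer(rows - cy[k], rep(1, length(cols)))
    rn <- sqrt(ellipse_d2(dx, dy, g$a, g$b, g$theta))
    rim_in <- max(0, 1 - 2 / g$b)
    sub <- f[rows, cols]
    sub[rn < rim_in] <- 0.98
    sub[rn >= rim_in & rn <= 1] <- 0.85
    halo <- rn > 1 & rn <= halo_scale & sub == 1
    sub[halo] <- 1.1
    f[rows, cols] <- sub
  }
  background * (1 + spec$bf_contrast * (f - 1))
}

## Blur per z-plane, apply the illumination field, add noise.
render_zstack <- function(clean, z_offsets, field, noise_sd) {
  lapply(z_offsets, function(s) {
    plane <- gblur0(clean, s) * field
    if (noise_sd > 0)
      plane <- plane + matrix(rnorm(length(plane), 0, noise_sd),
                              nrow(plane), ncol(plane))
    pmax(plane, 0)
  })
}

#' Generate a synthetic microscopy scene
#'
#' Places elliptical cells (each with one interior nucleus) by rejection
#' sampling, rasterizes the true instance mask, and renders the imaging
#' channels of the requested mode. Everything is deterministic given
#' `spec$rng_seed`.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `synthetic_scene` with elements `truth` and
#'   `nuclei_truth` (instance label matrices with matching ids), the imaging
#'   channels of the mode (`brightfield`, `nuclei_channel`,
#'   `cytoplasm_channel` as 3-plane lists for timelapse; `channels5` as a
#'   5-image list with channel 1 nuclear for multichannel5), per-cell
#'   geometry, and the spec with `n_placed` recorded.
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$rng_seed, {
    geom <- place_cells(spec)
    masks <- rasterize_cells(geom, spec)
    build_scene_channels(spec, geom, masks)
  })
}

## Renders channels for already-placed geometry; consumes RNG for the
## illumination fields and noise, so call order must stay fixed.
build_scene_channels <- function(spec, geom, masks) {
  H <- spec$height; W <- spec$width
  fl <- render_fluorescence(masks$truth, masks$nuclei, geom)
  spec$n_placed <- nrow(geom)
  scene <- list(truth = masks$truth, nuclei_truth = masks$nuclei,
                geometry = geom, spec = spec)
  if (spec$mode == "timelapse") {
    bf <- render_brightfield(geom, spec)
    field_bf <- make_illumination_field(H, W, spec$illumination_amplitude)
    field_nuc <- make_illumination_field(H, W, spec$illumination_amplitude)
    field_cyto <- make_illumination_field(H, W, spec$illumination_amplitude)
    scene$brightfield <- render_zstack(bf, spec$z_offsets, field_bf,
                                       spec$noise_sd)
    scene$nuclei_channel <- render_zstack(fl$nuclei, spec$z_offsets,
                                          field_nuc, spec$noise_sd)
    scene$cytoplasm_channel <- render_zstack(fl$cytoplasm, spec$z_offsets,
                                             field_cyto, spec$noise_sd)
  } else {
    chans <- vector("list", 5)
    base <- list(fl$nuclei, fl$cytoplasm)
    for (i in 1:5) {
      clean <- if (i == 1) fl$nuclei else {
        ## non-nuclear structures: cytoplasm-like with per-channel gain
        0.08 + (fl$cytoplasm - 0.08) * runif(1, 0.6, 1.1)
      }
      field <- make_illumination_field(H, W, spec$illumination_amplitude)
      chans[[i]] <- render_zstack(clean, 0.8, field, spec$noise_sd)[[1]]
    }
    scene$channels5 <- chans
  }
  class(scene) <- "synthetic_scene"
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %dx%d, %d cells placed, mode=%s, seed=%d\n",
              x$spec$width, x$spec$height, x$spec$n_placed, x$spec$mode,
              x$spec$rng_seed))
  invisible(x)
}

#' Generate a bright-field time series with end-point staining
#'
#' Cells drift by cumulative Gaussian offsets between frames; only the final
#' frame carries fluorescence channels, mirroring an end-point staining
#' protocol where the stains are added after the last time point.
#'
#' @param spec a [scene_spec()] in timelapse mode.
#' @param n_timepoints number of frames (>= 1).
#' @param drift_sd per-frame center displacement SD in pixels.
#' @return list with `frames` (per frame: `brightfield` z-stack, `truth`
#'   mask, `centers`) and `scene`, the full [generate_scene()]-style scene of
#'   the final frame.
#' @export
generate_time_series <- function(spec, n_timepoints, drift_sd = 1) {
  validate_scene_spec(spec)
  if (spec$mode != "timelapse") stopf("time series require timelapse mode")
  if (n_timepoints < 1) stopf("n_timepoints must be >= 1")
  with_seed(spec$rng_seed, {
    geom <- place_cells(spec)
    n <- nrow(geom)
    frames <- vector("list", n_timepoints)
    cx <- geom$cx; cy <- geom$cy
    for (t in seq_len(n_timepoints)) {
      if (t > 1 && n > 0) {
        cx <- cx + rnorm(n, 0, drift_sd)
        cy <- cy + rnorm(n, 0, drift_sd)
        margin <- spec$cell_radius_range[2] + 1
        cx <- pmin(pmax(cx, margin), spec$width - margin)
        cy <- pmin(pmax(cy, margin), spec$height - margin)
      }
      masks <- rasterize_cells(geom, spec, cx, cy)
      bf <- render_brightfield(geom, spec, cx, cy)
      field <- make_illumination_field(spec$height, spec$width,
                                       spec$illumination_amplitude)
      frames[[t]] <- list(
        brightfield = render_zstack(bf, spec$z_offsets, field, spec$noise_sd),
        truth = masks$truth,
        centers = cbind(cx = cx, cy = cy))
    }
    geom_final <- geom
    geom_final$cx <- cx; geom_final$cy <- cy
    masks <- rasterize_cells(geom_final, spec)
    scene <- build_scene_channels(spec, geom_final, masks)
    list(frames = frames, scene = scene)
  })
}

#' Write a scene to disk as TIFFs plus a plain-text metadata sidecar
#'
#' Channels become multi-page 32-bit TIFFs (one page per z-plane), truth
#' masks 16-bit label TIFFs, and `metadata.yaml` records the spec and seed.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_label_tiff(scene$truth, file.path(dir, "truth.tif"))
  write_label_tiff(scene$nuclei_truth, file.path(dir, "nuclei_truth.tif"))
  if (scene$spec$mode == "timelapse") {
    write_image_tiff(scene$brightfield, file.path(dir, "brightfield.tif"))
    write_image_tiff(scene$nuclei_channel, file.path(dir, "nuclei.tif"))
    write_image_tiff(scene$cytoplasm_channel, file.path(dir, "cytoplasm.tif"))
  } else {
    for (i in seq_along(scene$channels5))
      write_image_tiff(scene$channels5[[i]],
                       file.path(dir, sprintf("channel%d.tif", i)))
  }
  meta <- scene$spec
  class(meta) <- NULL
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir scene directory.
#' @return a `synthetic_scene` (geometry is not round-tripped).
#' @export
read_scene <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  scene <- list(truth = read_label_tiff(file.path(dir, "truth.tif")),
                nuclei_truth = read_label_tiff(file.path(dir, "nuclei_truth.tif")),
                spec = meta)
  if (meta$mode == "timelapse") {
    scene$brightfield <- read_image_tiff(file.path(dir, "brightfield.tif"), TRUE)
    scene$nuclei_channel <- read_image_tiff(file.path(dir, "nuclei.tif"), TRUE)
    scene$cytoplasm_channel <- read_image_tiff(file.path(dir, "cytoplasm.tif"), TRUE)
  } else {
    scene$channels5 <- lapply(1:5, function(i)
      read_image_tiff(file.path(dir, sprintf("channel%d.tif", i))))
  }
  class(scene) <- "synthetic_scene"
  scene
}
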