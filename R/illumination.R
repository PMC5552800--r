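## Illumination correction by iterative spline surface fitting.
##
## A tensor-product B-spline surface is fitted to robust local (block
## median) background samples; pixels/blocks whose residual marks them as
## foreground are iteratively clipped to the current surface and the fit
## repeated, so the final surface tracks the smooth background rather than
## the objects. Correction divides by the unit-mean surface, preserving the
## global intensity scale.

#' Illumination correction configuration
#'
#' @param knot_spacing spacing between spline knots in pixels (>= 8); the
#'   default `NULL` uses `image width / 8` at fit time.
#' @param n_iterations number of fit/clip rounds (>= 1).
#' @param exclusion_k residual-SD multiplier beyond which samples count as
#'   foreground and are clipped to the current surface before the refit.
#' @param spline_order polynomial degree of the spline pieces (3 = cubic).
#' @param exclusion_side `"upper"` clips only bright residuals (suits
#'   fluorescence, where foreground is strictly bright); `"both"` clips
#'   both tails (suits bright-field, where cells deviate both ways).
#' @return an `illumination_config` list.
#' @export
illumination_config <- function(knot_spacing = NULL, n_iterations = 3,
                                exclusion_k = 2.0, spline_order = 3,
                                exclusion_side = c("upper", "both")) {
  exclusion_side <- match.arg(exclusion_side)
  if (!is.null(knot_spacing) && knot_spacing < 8)
    stopf("knot_spacing must be >= 8 pixels")
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  if (exclusion_k <= 0) stopf("exclusion_k must be > 0")
  structure(list(knot_spacing = knot_spacing, n_iterations = n_iterations,
                 exclusion_k = exclusion_k, spline_order = spline_order,
                 exclusion_side = exclusion_side),
            class = "illumination_config")
}

## B-spline basis over 1..n with knots every `spacing` pixels.
spline_basis <- function(n, spacing, degree) {
  knots <- if (n > 2 * spacing) seq(spacing, n - spacing, by = spacing) else NULL
  splines::bs(seq_len(n), knots = knots, degree = degree, intercept = TRUE,
              Boundary.knots = c(1, n))
}

#' Estimate the smooth background (illumination) surface of an image
#'
#' Iterative scheme on a regular pixel lattice of at most `max_fit_pixels`
#' samples. The starting surface is the (flat) global median, which no
#' foreground object can bias as long as objects cover a minority of
#' pixels. Each iteration clips pixels whose residual against the current
#' surface exceeds `exclusion_k * residual SD` (one- or two-sided per the
#' config) to that surface, then refits the tensor-product spline to the
#' clipped values. Clipping rather than deleting keeps the fit supported
#' everywhere, so the surface cannot oscillate inside object regions.
#'
#' @param image numeric intensity matrix with finite values.
#' @param cfg an [illumination_config()].
#' @param max_fit_pixels cap on the number of lattice samples entering the
#'   least-squares problems.
#' @return object of class `background_surface`: list with `surface` (strictly
#'   positive matrix, same size) and `n_used` (samples unclipped in the final
#'   iteration).
#' @export
estimate_background <- function(image, cfg = illumination_config(),
                                max_fit_pixels = 40000) {
  assert_matrix(image)
  H <- nrow(image); W <- ncol(image)
  if (H < 16 || W < 16)
    stopf("image too small for background estimation (need >= 16 px per axis)")
  spacing <- cfg$knot_spacing
  if (is.null(spacing)) spacing <- max(8, floor(W / 8))
  By <- spline_basis(H, spacing, cfg$spline_order)   # H x ky
  Bx <- spline_basis(W, spacing, cfg$spline_order)   # W x kx
  ky <- ncol(By); kx <- ncol(Bx)

  stride <- max(1L, as.integer(floor(sqrt((H * W) / max_fit_pixels))))
  ri <- seq(1L, H, by = stride)
  ci <- seq(1L, W, by = stride)
  nr <- length(ri); nc <- length(ci)
  Bys <- By[ri, , drop = FALSE]
  Bxs <- Bx[ci, , drop = FALSE]
  X <- matrix(0, nr * nc, kx * ky)
  for (a in seq_len(kx))
    X[, ((a - 1) * ky + 1):(a * ky)] <-
      Bys[rep(seq_len(nr), nc), , drop = FALSE] * rep(Bxs[, a], each = nr)

  ## ridge-stabilized (weighted) least squares; the penalty is vanishingly
  ## small and only guards against rank deficiency of the tensor basis
  ## fits are centered (mean removed and added back) so a constant image is
  ## reproduced exactly whatever the ridge does to the basis coefficients
  lambda <- 1e-8 * mean(colSums(X^2))
  solve_coef <- function(zv, w = NULL) {
    mz <- if (is.null(w)) mean(zv) else stats::weighted.mean(zv, w)
    zc <- zv - mz
    if (is.null(w)) {
      XtX <- crossprod(X); rhs <- crossprod(X, zc)
    } else {
      Xw <- X * sqrt(w)
      XtX <- crossprod(Xw); rhs <- crossprod(X, w * zc)
    }
    diag(XtX) <- diag(XtX) + lambda
    list(coef = as.vector(solve(XtX, rhs)), mz = mz)
  }

  z <- as.vector(image[ri, ci])
  ## initial fit on winsorized values: clamping at median +/- 5 MAD removes
  ## high-contrast foreground before the first fit while leaving smooth
  ## illumination gradients (a few MAD wide) untouched
  med <- stats::median(z)
  m <- stats::mad(z)
  z_init <- if (m > 0) pmin(z, med + 5 * m) else z
  if (cfg$exclusion_side == "both" && m > 0)
    z_init <- pmax(z_init, med - 5 * m)
  fit <- solve_coef(z_init)
  fitted <- as.vector(X %*% fit$coef) + fit$mz
  inlier <- rep(TRUE, length(z))
  for (it in seq_len(cfg$n_iterations - 1L)) {
    ## residuals are always taken against the original pixels, so values
    ## flagged under an early (coarse) surface can re-enter once the fit
    ## improves; the residual scale comes from the current inlier set
    resid <- z - fitted
    ## robust (MAD) residual scale: blurred foreground shades continuously
    ## into the background and would keep an SD-based threshold loose
    s <- stats::mad(resid[inlier])
    if (!is.finite(s) || s == 0) s <- stats::sd(resid[inlier])
    if (is.finite(s) && s > 0) {
      outlier <- if (cfg$exclusion_side == "both")
        abs(resid) > cfg$exclusion_k * s
      else
        resid > cfg$exclusion_k * s
      inlier <- !outlier
    }
    ## outliers are pinned to the current surface with near-zero weight:
    ## they stop influencing the refit but still keep fully-excluded
    ## regions supported, so the spline cannot oscillate there
    z_work <- z
    z_work[!inlier] <- fitted[!inlier]
    w <- ifelse(inlier, 1, 0.01)
    fit <- solve_coef(z_work, w)
    fitted <- as.vector(X %*% fit$coef) + fit$mz
  }
  n_used <- sum(inlier)
  C <- matrix(fit$coef, ky, kx)
  surface <- By %*% C %*% t(Bx) + fit$mz
  ## illumination is a multiplicative modulation of amplitude < 1: a surface
  ## value far below the typical level is boundary overshoot of the spline,
  ## not signal, so clamp there instead of amplifying the correction
  floor_val <- max(1e-8, 0.2 * abs(stats::median(surface)))
  surface <- pmax(surface, floor_val)
  structure(list(surface = surface, n_used = n_used),
            class = "background_surface")
}

#' Divide out an illumination surface
#'
#' `corrected = image / (surface / mean(surface))`: division by the unit-mean
#' surface, so an image equal to its own surface becomes the constant
#' `mean(surface)` and the global intensity scale is preserved.
#'
#' @param image intensity matrix.
#' @param surface a `background_surface` or a strictly positive matrix of the
#'   same size.
#' @return corrected intensity matrix.
#' @export
correct_illumination <- function(image, surface) {
  if (inherits(surface, "background_surface")) surface <- surface$surface
  assert_matrix(image); assert_matrix(surface)
  assert_same_dim(image, surface, "image and surface")
  if (any(surface <= 0)) stopf("illumination surface must be strictly positive")
  image / (surface / mean(surface))
}

#' Estimate and correct illumination on every plane of a z-stack
#'
#' @param zstack list of intensity matrices (equal sizes).
#' @param cfg an [illumination_config()].
#' @return list of corrected planes.
#' @export
correct_zstack <- function(zstack, cfg = illumination_config()) {
  if (!is.list(zstack) || length(zstack) == 0)
    stopf("zstack must be a non-empty list of matrices")
  lapply(zstack, function(plane)
    correct_illumination(plane, estimate_background(plane, cfg)))
}
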