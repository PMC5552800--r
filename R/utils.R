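#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Shared validation and small numeric helpers.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("'%s' must be a numeric matrix", name)
  if (!all(is.finite(x)))
    stopf("'%s' contains non-finite values", name)
  invisible(x)
}

assert_same_dim <- function(a, b, what = "inputs") {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  if (!identical(as.integer(da), as.integer(db)))
    stopf("%s must share dimensions (got %dx%d vs %dx%d)",
          what, da[1], da[2], db[1], db[2])
  invisible(TRUE)
}

## Coerce 2-D matrix or H x W x C array to a 3-D array.
as_channels <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stopf("expected a matrix or H x W x C array")
  x
}

## Symmetric (mirror, border pixel included) reflection of out-of-range
## indices into 1..n; period 2n, works for arbitrarily large excursions.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  p <- (idx - 1L) %% (2L * n)
  p <- ifelse(p < 0L, p + 2L * n, p)
  as.integer(ifelse(p < n, p + 1L, 2L * n - p))
}

## Evaluate a function with a locally-seeded RNG without disturbing the
## caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a bounded child seed from a parent seed and a stream index,
## keeping results in 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103L + 7919L * as.double(stream)) %% 2147483629)
}

as_ebimage <- function(x) EBImage::Image(t(x))
from_ebimage <- function(img) t(EBImage::imageData(img))

## Gaussian blur that tolerates sigma == 0 (identity) and keeps plain
## matrices as the working currency.
gblur0 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  from_ebimage(EBImage::gblur(as_ebimage(x), sigma = sigma))
}

## Otsu threshold on an arbitrary-range matrix. The histogram range is
## taken between robust quantiles so a handful of extreme pixels cannot
## compress the histogram of everything else into a few bins.
otsu_threshold <- function(x) {
  rng <- stats::quantile(x, c(0.001, 0.999), names = FALSE)
  if (diff(rng) == 0) rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(as_ebimage(pmin(pmax(x, rng[1]), rng[2])),
                range = rng, levels = 256L)
}
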