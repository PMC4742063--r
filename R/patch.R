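#' Descriptor configuration
#'
#' Bundles the tunable parameters of the CCP descriptor.  The defaults follow
#' the reference design: 9x9 patches (81 DCT coefficients), a single 8-bit
#' histogram, an offset grid from -1 to 1 in steps of 0.02, and 2000 training
#' patches sampled per image.
#'
#' @param n Patch width in pixels; odd, >= 3 (default 9).
#' @param b Bits (comparisons) per histogram (default 8).
#' @param groups Number of concatenated histograms (default 1).
#' @param delta_lo,delta_hi,delta_step Offset grid for the comparison
#'   threshold delta (defaults -1, 1, 0.02; 101 grid values).
#' @param p Training patches sampled per image (default 2000).
#' @param window,sigma2 Orientation-field estimation parameters, see
#'   [estimate_orientation_field()].
#' @param stride Center stride when describing an image; 1 (the default) uses
#'   every eligible foreground pixel.
#' @param cost Linear SVM regularization constant C (default 1).
#' @return A list of class `ccp_config`.
#' @seealso [ccp_variant()] for the named histogram layouts.
#' @export
ccp_config <- function(n = 9, b = 8, groups = 1,
                       delta_lo = -1, delta_hi = 1, delta_step = 0.02,
                       p = 2000, window = 33, sigma2 = 10,
                       stride = 1, cost = 1) {
  stopifnot(n %% 2 == 1, n >= 3, b >= 1, groups >= 1,
            delta_step > 0, delta_hi > delta_lo,
            p >= 1, stride >= 1)
  cfg <- list(n = as.integer(n), b = as.integer(b),
              groups = as.integer(groups),
              delta_lo = delta_lo, delta_hi = delta_hi,
              delta_step = delta_step,
              p = as.integer(p), window = as.integer(window),
              sigma2 = sigma2, stride = as.integer(stride), cost = cost)
  class(cfg) <- "ccp_config"
  cfg
}

#' Parse a histogram-concatenation variant string
#'
#' Variant strings of the form `"GxB"` denote G concatenated histograms of B
#' bits each, e.g. `"1x8"` (one 256-bin histogram), `"4x6"` (four 64-bin
#' histograms, 256 features), `"2x8"` (512 features) and `"8x6"` (512
#' features).  Arbitrary `"GxB"` combinations are accepted.
#'
#' @param variant Character like `"4x6"`.
#' @param ... Further arguments passed to [ccp_config()].
#' @return A `ccp_config` with `groups` and `b` set; its `feature_length`
#'   is `groups * 2^b`.
#' @export
ccp_variant <- function(variant, ...) {
  m <- regmatches(variant, regexec("^([0-9]+)x([0-9]+)$", variant))[[1L]]
  if (length(m) != 3L)
    stop("variant must look like 'GxB', e.g. '1x8' or '4x6'; got '",
         variant, "'")
  ccp_config(groups = as.integer(m[2L]), b = as.integer(m[3L]), ...)
}

#' @rdname ccp_variant
#' @param cfg A `ccp_config`.
#' @export
feature_length <- function(cfg) cfg$groups * 2L^cfg$b

# Minimal distance from a patch center to every image border so that the
# rotated n x n footprint (any angle) stays inside the image, with one extra
# pixel for the bilinear neighborhood.
patch_margin <- function(n) as.integer(ceiling(n * sqrt(2) / 2) + 1)

#' Orthonormal DCT-II basis matrix
#'
#' Returns the n x n orthonormal type-II DCT matrix `C`, so that the 2-D
#' transform of a patch `P` is `C %*% P %*% t(C)`.
#'
#' @param n Patch width.
#' @return n x n numeric matrix.
#' @export
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' Two-dimensional DCT of a square patch
#'
#' Computes the orthonormal 2-D type-II DCT and returns the coefficients as a
#' vector in the package's fixed index numbering: coefficient (u, v) with
#' u, v in 0..n-1 maps to index `i = u*n + v + 1` (row-major, 1-based), so
#' index 1 is the DC coefficient.  Orthonormality implies Parseval's
#' identity, `sum(d^2) == sum(patch^2)`.
#'
#' @param patch n x n numeric matrix.
#' @return Numeric vector of length `n^2` of DCT coefficients.
#' @export
dct2 <- function(patch) {
  n <- nrow(patch)
  stopifnot(ncol(patch) == n, all(is.finite(patch)))
  C <- dct_matrix(n)
  d <- C %*% unclass(patch) %*% t(C)
  as.vector(t(d))   # row-major: i = u*n + v + 1
}

#' Extract a rotation-invariant patch
#'
#' Samples an n x n patch centered at `center`, rotated so that the patch
#' x-axis is aligned with the local ridge orientation `theta`; after
#' extraction the dominant texture orientation of the patch is horizontal.
#' Sampling uses bilinear interpolation of the source image (inverse
#' mapping).  For `theta = 0` the patch equals the plain axis-aligned crop.
#'
#' @param img Numeric intensity matrix.
#' @param center Integer c(row, col) of the patch center.
#' @param theta Local orientation in degrees (see
#'   [estimate_orientation_field()] for the angle convention).
#' @param n Patch width (odd).
#' @return n x n numeric matrix; an error is signaled if the rotated
#'   footprint does not lie fully inside the image (patches are rejected,
#'   never padded).
#' @export
extract_patch <- function(img, center, theta, n = 9) {
  r <- center[1L]; c <- center[2L]
  rad <- (n - 1) / 2 * sqrt(2) + 1   # rotated footprint + bilinear neighbors
  if (r - rad < 1 || c - rad < 1 || r + rad > nrow(img) || c + rad > ncol(img))
    stop("patch footprint at (", r, ",", c, ") exits the image")
  P <- extract_patch_coeffs(img, matrix(c(r, c), 1L), theta, n,
                            raw_patches = TRUE)
  matrix(P[1L, ], n, n, byrow = TRUE)
}

# Batch patch extraction + DCT via compiled code.  centers is a k x 2 matrix
# of (row, col); theta is a scalar or length-k vector of degrees.  Returns a
# k x n^2 matrix of DCT coefficient vectors (or raw patch samples, row-major,
# if raw_patches = TRUE).
extract_patch_coeffs <- function(img, centers, theta, n = 9,
                                 raw_patches = FALSE) {
  centers <- matrix(as.numeric(centers), ncol = 2L)
  theta <- rep_len(as.numeric(theta), nrow(centers))
  D <- if (raw_patches) diag(n) else dct_matrix(n)
  ccp_patch_coeffs(unclass(img), centers, theta * pi / 180, as.integer(n), D,
                   as.logical(raw_patches))
}

#' Sample training patch centers from a foreground mask
#'
#' Draws `p` pixel coordinates independently and uniformly at random (with
#' replacement) from the eligible foreground, i.e. foreground pixels whose
#' rotated patch footprint lies fully inside the image.
#'
#' @param mask Logical foreground matrix.
#' @param p Number of centers to draw.
#' @param n Patch width (determines the border margin).
#' @return Integer p x 2 matrix of (row, col) coordinates.
#' @export
sample_patch_centers <- function(mask, p, n = 9) {
  el <- eligible_centers(mask, n)
  if (nrow(el) == 0L)
    stop("no eligible foreground pixels (mask empty or too close to border)")
  el[sample.int(nrow(el), p, replace = TRUE), , drop = FALSE]
}

# All foreground pixels at distance >= patch_margin(n) from every border,
# optionally on a stride-subsampled grid.
eligible_centers <- function(mask, n = 9, stride = 1L) {
  m <- patch_margin(n)
  ok <- matrix(FALSE, nrow(mask), ncol(mask))
  rows <- seq(m, nrow(mask) - m + 1L, by = stride)
  cols <- seq(m, ncol(mask) - m + 1L, by = stride)
  rows <- rows[rows >= 1]; cols <- cols[cols >= 1]
  if (length(rows) && length(cols)) ok[rows, cols] <- TRUE
  which(mask & ok, arr.ind = TRUE)
}
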