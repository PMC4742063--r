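# Separable 2-D convolution with reflective boundary handling.  The kernel is
# given as its two 1-D factors (odd lengths).  Implemented as two banded
# matrix products, which is fast enough for the image sizes handled here.
conv_sep <- function(x, ky, kx = ky) {
  band <- function(n, k) {
    r <- (length(k) - 1L) %/% 2L
    np <- n + 2L * r
    M <- matrix(0, n, np)
    idx <- cbind(rep(seq_len(n), each = length(k)),
                 rep(seq_len(n), each = length(k)) + seq_along(k) - 1L)
    M[idx] <- rep(rev(k), n)   # convolution: kernel reversed
    M
  }
  pad_idx <- function(n, r) {
    # reflective (mirror without repeating the edge pixel); falls back to
    # edge replication for images narrower than the kernel radius
    i <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    pmin(pmax(i, 1L), n)
  }
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  xp <- x[pad_idx(nrow(x), ry), pad_idx(ncol(x), rx), drop = FALSE]
  band(nrow(x), ky) %*% xp %*% t(band(ncol(x), kx))
}

sobel_gradients <- function(img) {
  img <- unclass(img)
  list(gx = conv_sep(img, ky = c(1, 2, 1), kx = c(-1, 0, 1)),
       gy = conv_sep(img, ky = c(-1, 0, 1), kx = c(1, 2, 1)))
}

#' Estimate a fingerprint orientation field by averaging squared gradients
#'
#' Computes the per-pixel dominant ridge orientation of an oriented texture.
#' Image gradients are approximated by the Sobel operator; their doubled-angle
#' second-moment sums are averaged over a Gaussian-weighted window, and the
#' ridge orientation is the direction perpendicular to the dominant gradient
#' direction.
#'
#' Angles are reported in degrees in \[0, 180), where 0 corresponds to the
#' x-axis and angles increase clockwise (raster convention, y pointing down).
#' The orientation is defined modulo 180 degrees: ridge orientation is an
#' axis, not a direction.
#'
#' @param img Numeric intensity matrix (see [load_gray_image()]).
#' @param window Odd window width in pixels for the local average (default 33).
#' @param sigma2 Variance (px^2) of the Gaussian weight over the window
#'   (default 10); the kernel is centered, truncated at the window edge and
#'   normalized to sum 1.
#' @return A list of class `orientation_field` with elements `theta` (degrees,
#'   \[0,180)) and `coherence` (in \[0,1\]; 0 where the local gradient energy
#'   vanishes, e.g. on constant images).
#' @export
estimate_orientation_field <- function(img, window = 33, sigma2 = 10) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (nrow(img) < window || ncol(img) < window)
    warning("image smaller than the averaging window; ",
            "orientations rely heavily on boundary reflection")
  g <- sobel_gradients(img)
  r <- (window - 1L) %/% 2L
  k <- exp(-(seq(-r, r))^2 / (2 * sigma2))
  k <- k / sum(k)
  gxx <- conv_sep(g$gx * g$gx, k)
  gyy <- conv_sep(g$gy * g$gy, k)
  gxy <- conv_sep(g$gx * g$gy, k)
  # doubled-angle average: dominant gradient direction is
  # atan2(2 Gxy, Gxx - Gyy) / 2; ridges run perpendicular to it
  theta <- (atan2(2 * gxy, gxx - gyy) * 90 / pi + 90) %% 180
  denom <- gxx + gyy
  coh <- sqrt((gxx - gyy)^2 + 4 * gxy^2)
  coh <- ifelse(denom > .Machine$double.eps * max(denom, 1), coh / denom, 0)
  flat <- denom <= .Machine$double.eps * max(denom, 1)
  if (all(flat)) {
    message("constant image: orientation undefined, returning theta = 0")
    theta[] <- 0
  } else {
    theta[flat] <- 0
  }
  structure(list(theta = theta, coherence = coh), class = "orientation_field")
}

#' Variance-based foreground segmentation
#'
#' A simple fallback segmentation for when no externally computed mask is
#' available: the image is tiled into blocks, the intensity standard
#' deviation of each block is computed, blocks are thresholded by Otsu's
#' criterion on the block standard deviations, and the largest connected
#' component of above-threshold blocks is kept as foreground.
#'
#' This is a deliberately simple stand-in intended for textured foregrounds on
#' comparatively flat backgrounds, such as the synthetic ridge images produced
#' by [synth_image()].  For real sensor data an externally computed mask
#' should be preferred (see [read_mask()]).
#'
#' @param img Numeric intensity matrix.
#' @param block Block width in pixels (default 16).
#' @return Logical matrix of the image shape, `TRUE` on the foreground.
#' @export
segment_foreground <- function(img, block = 16) {
  img <- unclass(img)
  if (length(img) == 0L) stop("empty image")
  nbr <- ceiling(nrow(img) / block)
  nbc <- ceiling(ncol(img) / block)
  bsd <- matrix(0, nbr, nbc)
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    rows <- ((i - 1L) * block + 1L):min(i * block, nrow(img))
    cols <- ((j - 1L) * block + 1L):min(j * block, ncol(img))
    v <- img[rows, cols]
    bsd[i, j] <- if (length(v) > 1L) sd(v) else 0
  }
  if (diff(range(bsd)) < .Machine$double.eps) {
    warning("no intensity-variance contrast between blocks; empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  thr <- EBImage::otsu(bsd, range = range(bsd))
  fg <- bsd > thr
  # Otsu always splits; on a homogeneously textured image the two "classes"
  # are nearly identical and everything is foreground
  if (any(fg) && any(!fg) &&
      mean(bsd[!fg]) > 0.5 * mean(bsd[fg]))
    fg[] <- TRUE
  if (any(fg)) {
    lab <- EBImage::bwlabel(fg)
    keep <- which.max(tabulate(lab[lab > 0L]))
    fg <- lab == keep
  }
  # upscale block grid to pixel resolution
  fg[cbind(rep(pmin((seq_len(nrow(img)) - 1L) %/% block + 1L, nbr),
               times = ncol(img)),
           rep(pmin((seq_len(ncol(img)) - 1L) %/% block + 1L, nbc),
               each = nrow(img)))] |>
    matrix(nrow(img), ncol(img))
}
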