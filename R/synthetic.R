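#' Configuration of the synthetic ridge-valley generator
#'
#' The generator emulates the aspects of fingerprint images the CCP
#' descriptor reacts to: an oriented ridge-valley texture with a locally
#' dominant orientation and a ridge wavelength in the typical 4--12 px
#' range, a compact foreground on a flat background, and two classes whose
#' local spectra differ in a controlled way.  Class contrast is planted in
#' the ridge profile's harmonic content and in the additive noise level,
#' mimicking the material-texture differences between live skin and spoof
#' replicas: the live profile is a pure sinusoid, the spoof profile adds
#' 2nd and 3rd harmonics and extra noise.
#'
#' @param size Image width and height in pixels (default 128).
#' @param lambda Ridge wavelength in px (default 8).
#' @param orientation `"varying"` (default) draws, per image, a random base
#'   direction plus a smooth quadratic phase distortion (orientation varies
#'   by roughly +-15 degrees across the image, no singular points);
#'   `"constant"` uses a single random orientation per image.
#' @param contrast Class-contrast multiplier: spoof harmonic weights are
#'   `contrast * c(0.5, 0.3)` and spoof noise is `noise + 4 * contrast`.
#'   `contrast = 0` makes the two classes identically distributed (the null
#'   control); 1 is the default planted separation.
#' @param noise Additive Gaussian noise standard deviation for the live
#'   class, in intensity levels (default 8).
#' @param amplitude Ridge amplitude in intensity levels (default 80).
#' @param fg_radius Foreground disk radius as a fraction of `size`
#'   (default 0.40).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(size = 128, lambda = 8,
                         orientation = c("varying", "constant"),
                         contrast = 1, noise = 8, amplitude = 80,
                         fg_radius = 0.40) {
  stopifnot(lambda >= 3, noise >= 0, size >= 48, contrast >= 0)
  structure(list(size = as.integer(size), lambda = lambda,
                 orientation = match.arg(orientation),
                 contrast = contrast, noise = noise,
                 amplitude = amplitude, fg_radius = fg_radius),
            class = "synth_config")
}

#' Generate one synthetic ridge image with ground truth
#'
#' Evaluates a class-specific ridge profile on a smooth phase field whose
#' gradient is perpendicular to the ground-truth ridge orientation, adds
#' i.i.d. Gaussian noise, quantizes to 8 bits and attaches the analytic
#' orientation field and a disk foreground mask.
#'
#' @param cfg A [synth_config()].
#' @param class_label 1 = live, 0 = spoof.
#' @param seed Integer seed; the same seed reproduces the image bit for bit.
#' @return List with `img` (matrix, 0--255 integers), `mask` (logical
#'   matrix), `theta` (ground-truth orientation field, degrees in \[0,180)),
#'   and `label`.
#' @export
synth_image <- function(cfg = synth_config(), class_label = 1L, seed = 1L) {
  set.seed(as.integer(seed))
  s <- cfg$size
  x <- matrix(rep(seq_len(s), each = s), s, s)    # column index
  y <- matrix(rep(seq_len(s), times = s), s, s)   # row index (down)
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  psi <- runif(1, 0, pi)          # wave direction (across the ridges)
  if (cfg$orientation == "varying") {
    beta <- runif(2, -0.25, 0.25)
  } else beta <- c(0, 0)
  xr <- (x - cx) / s; yr <- (y - cy) / s
  k <- 2 * pi / cfg$lambda
  phase <- k * ((x * cos(psi) + y * sin(psi)) +
                  s * (beta[1] * (xr^2 - yr^2) / 2 + beta[2] * xr * yr))
  gx <- cos(psi) + beta[1] * xr + beta[2] * yr
  gy <- sin(psi) - beta[1] * yr + beta[2] * xr
  theta <- (atan2(gy, gx) * 180 / pi + 90) %% 180

  if (class_label == 1L) {
    g <- sin(phase)
    sigma <- cfg$noise
  } else {
    h <- cfg$contrast * c(0.5, 0.3)
    g <- (sin(phase) + h[1] * sin(2 * phase) + h[2] * sin(3 * phase)) /
      sqrt(1 + sum(h^2))
    sigma <- cfg$noise + 4 * cfg$contrast
  }
  img <- 127.5 + cfg$amplitude * g + rnorm(length(g), sd = sigma)
  img <- matrix(pmin(pmax(round(img), 0), 255), s, s)
  mask <- (x - cx)^2 + (y - cy)^2 <= (cfg$fg_radius * s)^2
  # flatten the background so variance-based segmentation can find the disk
  img[!mask] <- 230
  list(img = img, mask = mask, theta = theta, label = as.integer(class_label))
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes PNG images, binary PNG masks, plain-text orientation fields and a
#' manifest CSV (columns `path`, `label`, `mask`, `orientation`) for a
#' balanced or unbalanced two-class set.  Fully reproducible: the same seed
#' yields byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param n_live,n_spoof Number of live / spoof images.
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @param prefix File-name prefix (default `"img"`), useful to keep several
#'   sets in one directory.
#' @return The manifest data frame (also written to
#'   `file.path(dir, paste0(prefix, "_manifest.csv"))`).
#' @export
synth_dataset <- function(dir, n_live = 100, n_spoof = 100,
                          cfg = synth_config(), seed = 1L, prefix = "img") {
  stopifnot(n_live >= 1, n_spoof >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  set.seed(as.integer(seed))
  n <- n_live + n_spoof
  seeds <- sample.int(.Machine$integer.max, n)
  labels <- rep(c(1L, 0L), c(n_live, n_spoof))
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    cls <- if (labels[k] == 1L) "live" else "spoof"
    stem <- sprintf("%s_%s_%04d", prefix, cls, k)
    sim <- synth_image(cfg, labels[k], seeds[k])
    p_img <- file.path(dir, paste0(stem, ".png"))
    p_mask <- file.path(dir, paste0(stem, "_mask.png"))
    p_of <- file.path(dir, paste0(stem, "_of.txt"))
    write_gray_image(sim$img, p_img)
    write_mask(sim$mask, p_mask)
    write_orientation_field(sim$theta, p_of)
    rows[[k]] <- data.frame(path = p_img, label = labels[k],
                            mask = p_mask, orientation = p_of)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, paste0(prefix, "_manifest.csv")),
            row.names = FALSE)
  manifest
}

#' Synthetic patch coefficients with a planted discriminative pair
#'
#' Generates two classes of absolute-DCT-coefficient vectors that are
#' identically distributed on every index except a planted pair `(i, j)`:
#' in the live class coefficient `i` is shifted up and `j` down by
#' `separation` pooled standard deviations, and vice versa in the spoof
#' class.  Used to verify that the exhaustive comparison search recovers a
#' known signal.
#'
#' @param n_per_class Patches per class.
#' @param m Number of coefficient indices (e.g. `n^2`).
#' @param planted Integer pair `c(i, j)` carrying the signal.
#' @param separation Mean shift in standard-deviation units (default 1.5).
#' @param seed Integer seed.
#' @return List with `coeffs` (2*n_per_class x m matrix of signed
#'   coefficients) and `labels` (1 = live, 0 = spoof).
#' @export
synth_patch_coeffs <- function(n_per_class = 500, m = 81,
                               planted = c(2L, 5L), separation = 1.5,
                               seed = 1L) {
  stopifnot(length(planted) == 2L, planted[1] != planted[2],
            all(planted >= 1), all(planted <= m))
  set.seed(as.integer(seed))
  n <- 2L * n_per_class
  base <- matrix(abs(rnorm(n * m, mean = 4, sd = 1)), n, m)
  labels <- rep(c(1L, 0L), each = n_per_class)
  i <- planted[1]; j <- planted[2]
  shift <- separation * ifelse(labels == 1L, 1, -1)
  base[, i] <- abs(4 + shift + rnorm(n))
  base[, j] <- abs(4 - shift + rnorm(n))
  signs <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
  list(coeffs = base * signs, labels = labels)
}
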