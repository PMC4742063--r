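#' Binary pattern bin number of one patch
#'
#' Applies `b` learned comparisons to the normalized DCT coefficients of a
#' patch; bit `x` (x = 0, ..., b-1) of the bin number is 1 when
#' `(c_i_x + delta_x) > c_j_x`, and the bin number is
#' `y = sum(2^x * bit_x)`, in 0 .. 2^b - 1.
#'
#' @param coeffs Raw DCT coefficient vector (length `n^2`) or matrix
#'   (patches x `n^2`).
#' @param rules Data frame with columns `i, j, delta` (the `b` comparisons
#'   of one histogram group, in rank order: row 1 is bit 0).
#' @param stats `ccp_stats` used for normalization.
#' @return Integer bin number(s) in `0 .. 2^b - 1`.
#' @export
compute_pattern <- function(coeffs, rules, stats) {
  cn <- normalize_coefficients(rbind(coeffs), stats)
  y <- integer(nrow(cn))
  for (x in seq_len(nrow(rules))) {
    bit <- (cn[, rules$i[x]] + rules$delta[x]) > cn[, rules$j[x]]
    y <- y + as.integer(bit) * 2L^(x - 1L)
  }
  y
}

# Histograms of pattern bin numbers for a matrix of patch coefficients.
# Rules are assigned to groups in rank-block order (rules 1..b -> group 1,
# b+1..2b -> group 2, ...); each group's 2^b-bin histogram is normalized by
# the patch count and the groups are concatenated.  Only the coefficient
# columns referenced by the rules are normalized.
pattern_histograms <- function(coeffs, ruleset) {
  cfg <- ruleset$config
  b <- cfg$b
  rules <- ruleset$rules
  used <- sort(unique(c(rules$i, rules$j)))
  st <- ruleset$stats
  cu <- normalize_coefficients(coeffs[, used, drop = FALSE],
                               list(mean = st$mean[used], sd = st$sd[used]))
  col_of <- match(seq_along(st$mean), used)
  out <- numeric(0)
  for (g in seq_len(cfg$groups)) {
    y <- integer(nrow(cu))
    for (x in seq_len(b)) {
      r <- (g - 1L) * b + x
      bit <- (cu[, col_of[rules$i[r]]] + rules$delta[r]) >
        cu[, col_of[rules$j[r]]]
      y <- y + as.integer(bit) * 2L^(x - 1L)
    }
    out <- c(out, tabulate(y + 1L, nbins = 2L^b) / length(y))
  }
  out
}

#' Compute the CCP descriptor of an image
#'
#' Extracts the rotation-invariant patch at every eligible foreground pixel
#' (foreground pixels far enough from the border that the rotated patch
#' footprint stays inside the image), computes DCT coefficients and pattern
#' bin numbers, and summarizes them into `groups` histograms of `2^b` bins
#' each.  Every histogram holds relative frequencies (it sums to 1), which
#' makes the descriptor invariant to the size of the foreground area.
#'
#' @param img Numeric intensity matrix.
#' @param ruleset A `ccp_rules` object (or a fitted [ccp_fit()] model).
#' @param mask Logical foreground mask; defaults to [segment_foreground()].
#' @param of Orientation field (matrix of degrees or an `orientation_field`);
#'   defaults to [estimate_orientation_field()].
#' @param stride Center stride; 1 (default) uses every eligible pixel.
#' @return Numeric feature vector of length `groups * 2^b` with attribute
#'   `n_patches`.
#' @export
describe_image <- function(img, ruleset, mask = NULL, of = NULL,
                           stride = NULL) {
  if (inherits(ruleset, "ccp_model")) ruleset <- ruleset$ruleset
  cfg <- ruleset$config
  if (is.null(stride)) stride <- cfg$stride
  if (is.null(mask)) mask <- segment_foreground(img)
  if (is.null(of)) of <- estimate_orientation_field(img, cfg$window, cfg$sigma2)
  theta <- if (inherits(of, "orientation_field")) of$theta else of
  centers <- eligible_centers(mask, cfg$n, stride)
  if (nrow(centers) == 0L)
    stop("no eligible foreground patches in image")
  coeffs <- extract_patch_coeffs(img, centers, theta[centers], cfg$n)
  feat <- pattern_histograms(coeffs, ruleset)
  attr(feat, "n_patches") <- nrow(centers)
  feat
}

# Descriptors for a whole manifest; returns a matrix (images x features).
describe_manifest <- function(manifest, ruleset, progress = FALSE) {
  feats <- matrix(NA_real_, nrow(manifest), feature_length(ruleset$config))
  for (k in seq_len(nrow(manifest))) {
    inp <- load_manifest_row(manifest, k, ruleset$config)
    feats[k, ] <- describe_image(inp$img, ruleset, inp$mask, inp$of)
    if (progress && k %% 25L == 0L)
      message("described ", k, "/", nrow(manifest), " images")
  }
  feats
}

# Load one manifest row: image plus optional mask / orientation files.
load_manifest_row <- function(manifest, k, cfg) {
  img <- load_gray_image(manifest$path[k])
  mask <- if (!is.null(manifest$mask) && nzchar(manifest$mask[k]))
    read_mask(manifest$mask[k], dim(img)) else segment_foreground(img)
  of <- if (!is.null(manifest$orientation) &&
            nzchar(manifest$orientation[k]))
    read_orientation_field(manifest$orientation[k], dim(img))
  else estimate_orientation_field(img, cfg$window, cfg$sigma2)
  list(img = img, mask = mask, of = of)
}

#' Write or read a feature table
#'
#' Feature tables are CSV files with one row per image: `path`, `label`, and
#' the `groups * 2^b` descriptor columns `f1, f2, ...` in group-major order
#' (histogram 1 bins 0..2^b-1, then histogram 2, ...).
#'
#' @param features Numeric matrix (images x features).
#' @param manifest Data frame with at least `path` and `label`.
#' @param path Output CSV path.
#' @return The file path (write) or a list with `manifest` and `features`
#'   (read), invisibly for the writer.
#' @export
write_feature_table <- function(features, manifest, path) {
  df <- data.frame(path = manifest$path, label = manifest$label,
                   features, check.names = FALSE)
  names(df) <- c("path", "label", paste0("f", seq_len(ncol(features))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  list(manifest = df[, c("path", "label")],
       features = as.matrix(df[, -(1:2), drop = FALSE]))
}
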