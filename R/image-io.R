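#' Read a grayscale image
#'
#' Reads a raster image (PNG or TIFF) and returns it as a numeric matrix of
#' intensities on the 0--255 scale, rows indexed top to bottom.  Multi-channel
#' images are converted to a single channel by averaging the channels; images
#' with higher bit depth are rescaled to 0--255 by max-range division.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A numeric matrix (class `gray_image`) with values in \[0, 255\].
#' @export
load_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG and TIFF are supported)")
  )
  if (is.list(px)) px <- px[[1L]]
  if (length(dim(px)) == 3L) {
    # channel average; drop a pure alpha channel first (RGBA / GA)
    nc <- dim(px)[3L]
    if (nc %in% c(2L, 4L)) px <- px[, , -nc, drop = FALSE]
    px <- apply(px, c(1L, 2L), mean)
  }
  if (length(px) == 0L) stop("zero-size image: ", path)
  img <- px * 255
  class(img) <- c("gray_image", class(img))
  img
}

#' Write a grayscale image as PNG
#'
#' @param img Numeric matrix with intensities in \[0, 255\].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(pmin(pmax(unclass(img) / 255, 0), 1), path)
  invisible(path)
}

#' Read a binary foreground mask
#'
#' Masks are binary PNG images: 0 encodes background, 255 foreground.  The
#' mask must have the same shape as the image it belongs to.
#'
#' @param path Path to a PNG mask.
#' @param dim_ref Optional c(rows, cols) to validate the mask shape against.
#' @return A logical matrix, `TRUE` on the foreground.
#' @export
read_mask <- function(path, dim_ref = NULL) {
  m <- load_gray_image(path) > 127
  if (!is.null(dim_ref) && !all(dim(m) == dim_ref[1:2]))
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match image shape ", paste(dim_ref[1:2], collapse = "x"))
  if (!any(m)) warning("mask has no foreground pixels: ", path)
  m
}

#' @rdname read_mask
#' @param mask Logical matrix to write.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read or write an orientation field as a plain-text grid
#'
#' Orientation fields are stored as whitespace-separated grids of angles in
#' degrees, one image row per line, row-major, with values in \[0, 180):
#' 0 is the x-axis and angles increase clockwise (the y-axis points down, as
#' usual for raster images).  Values outside the range are wrapped modulo 180
#' with a warning.
#'
#' @param path Path of the text file.
#' @param dim_ref Optional c(rows, cols) to validate the grid shape against.
#' @return A numeric matrix of angles in degrees, in \[0, 180).
#' @export
read_orientation_field <- function(path, dim_ref = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop("ragged orientation grid in ", path)
  theta <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
  if (anyNA(theta)) stop("non-numeric entries in orientation grid ", path)
  if (!is.null(dim_ref) && !all(dim(theta) == dim_ref[1:2]))
    stop("orientation grid shape ", paste(dim(theta), collapse = "x"),
         " does not match image shape ", paste(dim_ref[1:2], collapse = "x"))
  if (any(theta < 0 | theta >= 180)) {
    warning("orientation values outside [0,180) wrapped modulo 180 in ", path)
    theta <- theta %% 180
  }
  theta
}

#' @rdname read_orientation_field
#' @param theta Numeric matrix of angles in degrees.
#' @param digits Number of decimal digits written (default 2).
#' @export
write_orientation_field <- function(theta, path, digits = 2) {
  theta <- round(theta %% 180, digits) %% 180   # 179.9996 rounds to 180 -> 0
  txt <- apply(theta, 1L, paste, collapse = " ")
  writeLines(txt, path)
  invisible(path)
}
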