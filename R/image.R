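#' Microscope image container
#'
#' Wraps a pixel array together with an image identifier. Pixels are stored
#' on the 8-bit scale (values in \[0, 255\], doubles), row-major: a grayscale
#' image is an `height x width` matrix, an RGB image an `height x width x 3`
#' array. This 8-bit convention is the package-wide intensity scale;
#' descriptors normalise internally where they need \[0, 1\].
#'
#' @param pixels Numeric matrix (grayscale) or 3-d array with 3 channels (RGB).
#' @param image_id Character scalar identifying the image.
#' @param source_path Optional path the image was read from.
#' @return An object of class `stoma_image`.
#' @export
stoma_image <- function(pixels, image_id = "image", source_path = NULL) {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3L &&
                              dim(pixels)[3] == 3L)))
    stop("pixels must be an H x W matrix or an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop("pixel intensities must be finite and within [0, 255]", call. = FALSE)
  structure(
    list(pixels = pixels, image_id = as.character(image_id),
         source_path = source_path),
    class = "stoma_image"
  )
}

#' @export
print.stoma_image <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf("<stoma_image '%s': %d x %d px, %d channel%s, 8-bit>\n",
              x$image_id, d[1], d[2], ch, if (ch > 1) "s" else ""))
  invisible(x)
}

#' @export
dim.stoma_image <- function(x) dim(x$pixels)

img_height <- function(image) dim(image$pixels)[1]
img_width  <- function(image) dim(image$pixels)[2]

#' Load a PNG or TIFF microscope image
#'
#' Reads an 8-bit grayscale or RGB image. RGB is preserved as three channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A [stoma_image].
#' @export
load_image <- function(path, image_id = NULL) {
  if (!file.exists(path))
    stop(sprintf("image file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext),
         call. = FALSE)
  )
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE] else px <- px[, , 1]
  }
  if (is.null(image_id))
    image_id <- tools::file_path_sans_ext(basename(path))
  stoma_image(round(px * 255), image_id = image_id, source_path = path)
}

#' Write a microscope image as PNG or TIFF
#'
#' @param image A [stoma_image].
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "stoma_image"))
  px <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(px, path),
    tif  = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext),
         call. = FALSE)
  )
  invisible(path)
}

# BT.601 luminance weights; the single grayscale convention of the package.
.lum_weights <- c(0.299, 0.587, 0.114)

#' Convert an image to grayscale
#'
#' RGB input is reduced with BT.601 luminance weights (0.299, 0.587, 0.114);
#' grayscale input is returned unchanged, so conversion is idempotent.
#'
#' @param image A [stoma_image] with 1 or 3 channels.
#' @return A single-channel [stoma_image].
#' @export
to_grayscale <- function(image) {
  stopifnot(inherits(image, "stoma_image"))
  d <- dim(image$pixels)
  if (length(d) == 2L) return(image)
  if (length(d) == 3L && d[3] == 3L) {
    g <- image$pixels[, , 1] * .lum_weights[1] +
         image$pixels[, , 2] * .lum_weights[2] +
         image$pixels[, , 3] * .lum_weights[3]
    out <- image
    out$pixels <- g
    return(out)
  }
  stop(sprintf("cannot convert image with %d channels to grayscale", d[3]),
       call. = FALSE)
}

#' Bounding box (0-based, half-open)
#'
#' Boxes cover rows `[row0, row0 + height)` and columns `[col0, col0 + width)`
#' of the parent image, 0-based and row-major. This is the single coordinate
#' convention used throughout the package.
#'
#' @param row0,col0 Top-left corner (0-based).
#' @param height,width Extent in pixels, both strictly positive.
#' @return An object of class `bbox`.
#' @export
bbox <- function(row0, col0, height, width) {
  row0 <- as.integer(row0); col0 <- as.integer(col0)
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(row0) || is.na(col0) || row0 < 0L || col0 < 0L)
    stop("bbox origin must be non-negative", call. = FALSE)
  if (is.na(height) || is.na(width) || height <= 0L || width <= 0L)
    stop("bbox height and width must be positive", call. = FALSE)
  structure(list(row0 = row0, col0 = col0, height = height, width = width),
            class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox rows [%d,%d) cols [%d,%d)>\n",
              x$row0, x$row0 + x$height, x$col0, x$col0 + x$width))
  invisible(x)
}

bbox_inside <- function(box, image_shape) {
  box$row0 >= 0L && box$col0 >= 0L &&
    box$row0 + box$height <= image_shape[1] &&
    box$col0 + box$width <= image_shape[2]
}

# Vectorised intersection area of one box against a data.frame of boxes
# (columns row0, col0, height, width). Returns a numeric vector.
bbox_intersection_area <- function(box, boxes) {
  if (nrow(boxes) == 0L) return(numeric(0))
  r0 <- pmax(box$row0, boxes$row0)
  c0 <- pmax(box$col0, boxes$col0)
  r1 <- pmin(box$row0 + box$height, boxes$row0 + boxes$height)
  c1 <- pmin(box$col0 + box$width, boxes$col0 + boxes$width)
  pmax(0, r1 - r0) * pmax(0, c1 - c0)
}

bbox_center <- function(boxes) {
  # integer center pixel of each box in a data.frame, 0-based
  data.frame(row = boxes$row0 + boxes$height %/% 2L,
             col = boxes$col0 + boxes$width %/% 2L)
}

#' Crop a window from an image
#'
#' Output pixel `(r, c)` equals input pixel `(row0 + r, col0 + c)`. A box that
#' exceeds the image bounds is an error; there is no silent clipping.
#'
#' @param image A [stoma_image].
#' @param box A [bbox] fully inside the image.
#' @return A [stoma_image] of the box's dimensions.
#' @export
crop_window <- function(image, box) {
  stopifnot(inherits(image, "stoma_image"), inherits(box, "bbox"))
  d <- dim(image$pixels)
  if (!bbox_inside(box, d))
    stop(sprintf(
      "crop box rows [%d,%d) cols [%d,%d) exceeds image bounds %d x %d",
      box$row0, box$row0 + box$height, box$col0, box$col0 + box$width,
      d[1], d[2]), call. = FALSE)
  rows <- (box$row0 + 1L):(box$row0 + box$height)
  cols <- (box$col0 + 1L):(box$col0 + box$width)
  px <- if (length(d) == 3L) image$pixels[rows, cols, , drop = FALSE]
        else image$pixels[rows, cols, drop = FALSE]
  stoma_image(px, image_id = image$image_id)
}

#' Labeled region
#'
#' A fixed-size window in a parent image carrying a class label.
#'
#' @param box A [bbox] of the configured window shape.
#' @param label `"stoma"` or `"non_stoma"`.
#' @param image_id Identifier of the parent image.
#' @param window_shape Expected `(height, width)`; the box must match.
#' @return An object of class `labeled_region`.
#' @export
labeled_region <- function(box, label, image_id,
                           window_shape = c(151L, 258L)) {
  label <- match.arg(label, c("stoma", "non_stoma"))
  if (box$height != window_shape[1] || box$width != window_shape[2])
    stop(sprintf("region box is %d x %d but the window shape is %d x %d",
                 box$height, box$width, window_shape[1], window_shape[2]),
         call. = FALSE)
  structure(list(box = box, label = label, image_id = as.character(image_id)),
            class = "labeled_region")
}
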