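#' 8-bit RGB image container
#'
#' An `rgb_image` is an `H x W x 3` integer array with values in
#' `[0, 255]` plus an `id` attribute. All perturbation operators consume
#' and produce this representation so that pixel arithmetic is exact.
#'
#' @param pixels Numeric or integer `H x W x 3` array with values in
#'   `[0, 255]` (integers), or in `[0, 1]` if `scale01 = TRUE`.
#' @param id Image identifier string.
#' @param scale01 If `TRUE`, `pixels` are on `[0, 1]` and are scaled by
#'   255 and rounded half away from zero.
#' @return An `rgb_image`.
#' @export
rgb_image <- function(pixels, id = "img", scale01 = FALSE) {
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) stop("zero-sized image", call. = FALSE)
  if (scale01) pixels <- round_half_away(pixels * 255)
  px <- as.integer(round_half_away(pixels))
  if (anyNA(px) || min(px) < 0L || max(px) > 255L) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  dim(px) <- d
  structure(px, id = as.character(id), class = "rgb_image")
}

#' Round half away from zero
#'
#' The rounding convention used by every 8-bit stage of the perturbation
#' pipeline (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat("rgb_image '", attr(x, "id"), "': ", d[1], "x", d[2],
      " px, value range [", min(x), ", ", max(x), "]\n", sep = "")
  invisible(x)
}

image_id <- function(img) attr(img, "id") %||% "img"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an image file into an `rgb_image`
#'
#' PNG files are decoded with the `png` package. JPEG files are decoded
#' through `EBImage` when that package is installed. Grayscale input is
#' replicated to three channels; an alpha channel is dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @param id Identifier; defaults to the file name without extension.
#' @return An `rgb_image`.
#' @export
read_image <- function(path, id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    }
    a <- EBImage::imageData(EBImage::readImage(path))
    a <- aperm(a, c(2, 1, 3))   # EBImage stores x,y; convert to row,col
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  rgb_image(a, id = id %||% tools::file_path_sans_ext(basename(path)),
            scale01 = TRUE)
}

#' Write an `rgb_image` to a PNG file
#'
#' @param img An `rgb_image`.
#' @param path Output path.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Constant-color image (test and documentation helper)
#'
#' @param value Length-1 or length-3 pixel value(s) in `[0, 255]`.
#' @param side Image side in pixels.
#' @param id Identifier.
#' @return An `rgb_image` of size `side x side`.
#' @export
constant_image <- function(value, side = 8L, id = "const") {
  if (length(value) == 1L) value <- rep(value, 3L)
  px <- array(rep(as.numeric(value), each = side * side),
              dim = c(side, side, 3L))
  rgb_image(px, id = id)
}

# trusted constructor for kernel outputs (already integer, in range, dimmed)
new_rgb_image <- function(px, id = "img") {
  structure(px, id = as.character(id), class = "rgb_image")
}
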