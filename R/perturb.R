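#' Photometric factor sample
#'
#' One point in the five-dimensional photometric parameter space. The
#' nominal sample `(1, 1, 1, 1, 0)` leaves an image unchanged (after
#' resizing).
#'
#' @param brightness,contrast,sharpness,saturation Multiplicative
#'   enhancement factors (`>= 0`; 1 is the identity).
#' @param hue Normalized circular hue shift in `[-1, 1]` (0 is the
#'   identity; the operating range of the default bounds is
#'   `[-0.1, 0.1]`).
#' @return A named numeric vector of class `factor_sample`.
#' @export
factor_sample <- function(brightness = 1, contrast = 1, sharpness = 1,
                          saturation = 1, hue = 0) {
  s <- c(brightness = brightness, contrast = contrast, sharpness = sharpness,
         saturation = saturation, hue = hue)
  if (any(s[1:4] < 0)) stop("enhancement factors must be >= 0", call. = FALSE)
  if (abs(s[["hue"]]) > 1) stop("hue shift must lie in [-1, 1]", call. = FALSE)
  structure(s, class = c("factor_sample", "numeric"))
}

#' @rdname factor_sample
#' @export
nominal_sample <- function() factor_sample()

as_factor_sample <- function(x) {
  if (inherits(x, "factor_sample")) return(x)
  x <- unlist(x)
  nms <- names(x)
  if (is.null(nms)) {
    stopifnot(length(x) == 5L)
    nms <- photometric_factors()
    names(x) <- nms
  }
  stopifnot(all(photometric_factors() %in% nms))
  do.call(factor_sample, as.list(x[photometric_factors()]))
}

#' Resize an image with bilinear interpolation
#'
#' Standardizes inputs to the working resolution of the perturbation
#' pipeline (128 x 128 by default, matching common dermoscopy-model input
#' sizes). Pixel centers are aligned (`(i + 0.5) * scale - 0.5` source
#' mapping); an input already at the target size is returned
#' byte-for-byte unchanged.
#'
#' @param img An `rgb_image`.
#' @param side Target side length in pixels.
#' @return A `side x side` `rgb_image`.
#' @export
resize_image <- function(img, side = 128L) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img)
  out <- .cpp_resize_bilinear(as.integer(img), d[1], d[2], as.integer(side))
  dim(out) <- c(side, side, 3L)
  new_rgb_image(out, id = image_id(img))
}

.enhance_kinds <- c(brightness = 1L, contrast = 2L, saturation = 3L,
                    sharpness = 4L)

#' Apply one 8-bit photometric enhancement
#'
#' Each enhancement linearly interpolates (or extrapolates, for factors
#' above 1) between a degenerate image and the original:
#' `out = round_clip((1 - factor) * degenerate + factor * original)`,
#' computed per pixel per channel with rounding half away from zero and
#' clipping to `[0, 255]`. The degenerate image is
#' \describe{
#'   \item{brightness}{all black;}
#'   \item{contrast}{the uniform image at the rounded mean of the integer
#'     luma values, `luma = round((299 R + 587 G + 114 B) / 1000)`;}
#'   \item{saturation}{the per-pixel integer-luma grayscale image
#'     replicated to three channels;}
#'   \item{sharpness}{a smoothed copy using the 3 x 3 kernel
#'     `[[1,1,1],[1,5,1],[1,1,1]] / 13` (rounded to 8 bits), with the
#'     one-pixel border ring copied unchanged from the original.}
#' }
#' `factor = 1` is a byte-exact identity for every kind.
#'
#' @param img An `rgb_image`.
#' @param kind One of `"brightness"`, `"contrast"`, `"saturation"`,
#'   `"sharpness"`.
#' @param factor Non-negative enhancement factor.
#' @return An `rgb_image` of the same size.
#' @export
enhance <- function(img, kind, factor) {
  stopifnot(inherits(img, "rgb_image"))
  if (length(kind) != 1L || !kind %in% names(.enhance_kinds)) {
    stop("unknown enhancement kind: ", paste(kind, collapse = ", "),
         call. = FALSE)
  }
  if (!is.finite(factor) || factor < 0) {
    stop("enhancement factor must be non-negative", call. = FALSE)
  }
  d <- dim(img)
  out <- .cpp_enhance(as.integer(img), d[1], d[2], .enhance_kinds[[kind]],
                      as.numeric(factor))
  new_rgb_image(out, id = image_id(img))
}

#' Shift the hue channel with circular wrap-around
#'
#' Converts to 8-bit HSV (all three channels on `[0, 255]`), applies
#' `H_new = (H_old + round(delta_h * 255)) mod 256` (rounding half away
#' from zero), leaves S and V untouched, and converts back to RGB. The
#' integer shift makes hue shifts compose additively modulo 256 and makes
#' `delta_h` followed by `-delta_h` restore the hue channel exactly.
#'
#' @param img An `rgb_image`.
#' @param delta_h Normalized hue shift in `[-1, 1]`.
#' @return An `rgb_image`.
#' @export
shift_hue <- function(img, delta_h) {
  stopifnot(inherits(img, "rgb_image"))
  if (!is.finite(delta_h) || abs(delta_h) > 1) {
    stop("delta_h must lie in [-1, 1]", call. = FALSE)
  }
  d <- dim(img)
  out <- .cpp_shift_hue(as.integer(img), d[1], d[2], as.numeric(delta_h))
  new_rgb_image(out, id = image_id(img))
}

#' Integer hue shift for a normalized delta
#'
#' The additive term of the hue-update rule on the 8-bit hue channel:
#' `round_half_away(delta_h * 255)`, applied modulo 256.
#'
#' @param delta_h Normalized hue shift.
#' @return Integer shift in hue units.
#' @export
hue_shift_amount <- function(delta_h) {
  as.integer(round_half_away(delta_h * 255))
}

#' Convert between 8-bit RGB and 8-bit HSV
#'
#' Hexcone conversion with all three HSV channels quantized to
#' `[0, 255]`; used internally by [shift_hue()] and exposed for audit.
#'
#' @param img An `rgb_image` (for `rgb_to_hsv8`) or an `H x W x 3`
#'   integer array of HSV values (for `hsv8_to_rgb`).
#' @return An `H x W x 3` integer array (HSV), or an `rgb_image` (RGB).
#' @export
rgb_to_hsv8 <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img)
  .cpp_rgb_to_hsv8(as.integer(img), d[1], d[2])
}

#' @rdname rgb_to_hsv8
#' @export
hsv8_to_rgb <- function(img) {
  d <- dim(img)
  stopifnot(length(d) == 3L, d[3] == 3L)
  rgb_image(.cpp_hsv8_to_rgb(as.integer(img), d[1], d[2]))
}

#' Apply the full photometric perturbation pipeline
#'
#' Applies, in a strict sequential order with internal rounding and
#' clipping at every stage: resize, then the brightness, contrast,
#' sharpness and saturation enhancements, then the circular hue shift.
#' The nominal sample `(1, 1, 1, 1, 0)` reproduces the resized image
#' byte-for-byte; the whole pipeline is deterministic.
#'
#' @param img An `rgb_image`.
#' @param s A `factor_sample` (or named vector / length-5 vector in the
#'   order brightness, contrast, sharpness, saturation, hue).
#' @param side Working resolution (square), default 128.
#' @return A `side x side` `rgb_image`.
#' @export
apply_perturbation <- function(img, s, side = 128L) {
  s <- as_factor_sample(s)
  out <- resize_image(img, side = side)
  out <- enhance(out, "brightness", s[["brightness"]])
  out <- enhance(out, "contrast", s[["contrast"]])
  out <- enhance(out, "sharpness", s[["sharpness"]])
  out <- enhance(out, "saturation", s[["saturation"]])
  shift_hue(out, s[["hue"]])
}
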