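#' Photometric factor bounds
#'
#' A bounds configuration is a data frame with columns `name`, `lo`, `hi`,
#' one row per uncertain factor. The default configuration covers the five
#' photometric factors of the perturbation model with ranges representing
#' clinically plausible acquisition variability: brightness and saturation
#' are multiplicative factors allowed to vary by +/-50%, contrast and
#' sharpness by the more conservative +/-20%, and hue is a normalized
#' circular shift restricted to +/-0.1 (larger shifts distort lesion color
#' beyond anything a camera or lighting change would produce).
#'
#' @param brightness,contrast,sharpness,saturation,hue Length-2 numeric
#'   vectors `c(lo, hi)` overriding the default range of one factor.
#' @return A `factor_bounds` data frame with columns `name`, `lo`, `hi`.
#' @examples
#' default_bounds()
#' default_bounds(hue = c(-0.05, 0.05))
#' @export
default_bounds <- function(brightness = c(0.5, 1.5),
                           contrast   = c(0.8, 1.2),
                           sharpness  = c(0.8, 1.2),
                           saturation = c(0.5, 1.5),
                           hue        = c(-0.1, 0.1)) {
  factor_bounds(
    name = c("brightness", "contrast", "sharpness", "saturation", "hue"),
    lo = c(brightness[1], contrast[1], sharpness[1], saturation[1], hue[1]),
    hi = c(brightness[2], contrast[2], sharpness[2], saturation[2], hue[2])
  )
}

#' Construct a bounds configuration
#'
#' @param name Character vector of factor names.
#' @param lo,hi Numeric vectors of lower/upper bounds (`lo <= hi`).
#' @return A `factor_bounds` data frame.
#' @export
factor_bounds <- function(name, lo, hi) {
  stopifnot(length(name) == length(lo), length(lo) == length(hi))
  if (length(name) < 1L) {
    stop("bounds configuration must contain at least one factor", call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("factor names must be unique", call. = FALSE)
  }
  if (!all(is.finite(lo)) || !all(is.finite(hi))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lo > hi)) {
    bad <- name[lo > hi]
    stop("invalid bounds (lo > hi) for factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(name = as.character(name), lo = as.numeric(lo),
                    hi = as.numeric(hi), stringsAsFactors = FALSE)
  class(out) <- c("factor_bounds", "data.frame")
  out
}

as_factor_bounds <- function(x) {
  if (inherits(x, "factor_bounds")) return(x)
  if (is.data.frame(x) && all(c("name", "lo", "hi") %in% names(x))) {
    return(factor_bounds(x$name, x$lo, x$hi))
  }
  if (is.list(x) && !is.null(names(x))) {
    rng <- lapply(x, function(r) {
      stopifnot(length(r) == 2L)
      as.numeric(r)
    })
    return(factor_bounds(names(x), vapply(rng, `[`, 0, 1L),
                         vapply(rng, `[`, 0, 2L)))
  }
  stop("cannot interpret object as factor bounds", call. = FALSE)
}

photometric_factors <- function() {
  c("brightness", "contrast", "sharpness", "saturation", "hue")
}
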