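# Scalar image statistics used by the analytic probe predictors. Each is
# matched to one photometric factor: under the default perturbation
# bounds, the matched factor should dominate the statistic's variance.
# Scale-dependent statistics (contrast, sharpness) are normalized by a
# mean level so that the wide-range brightness factor (a +/-50%
# multiplicative rescaling that would otherwise scale raw dispersion and
# raw gradient magnitudes alike) does not mask the designed factor.

#' Scalar image statistics for probe predictors
#'
#' @param img An `rgb_image`.
#' @return A scalar statistic:
#' \describe{
#'   \item{`stat_mean_value`}{mean of the HSV value channel / 255
#'     (brightness probe);}
#'   \item{`stat_value_cv`}{coefficient of variation (sd / mean) of the
#'     value channel (contrast probe);}
#'   \item{`stat_mean_saturation`}{mean HSV saturation / 255
#'     (saturation probe);}
#'   \item{`stat_hue_circular_mean`}{circular mean of the hue channel on
#'     `(-0.5, 0.5]` in normalized hue units (hue probe);}
#'   \item{`stat_sharpness`}{mean absolute 4-neighbour Laplacian of the
#'     luma image, normalized by mean luma (sharpness probe).}
#' }
#' @export
stat_mean_value <- function(img) {
  mean(.value_channel(img)) / 255
}

#' @rdname stat_mean_value
#' @export
stat_value_cv <- function(img) {
  v <- .value_channel(img)
  stats::sd(v) / (mean(v) + 1e-8)
}

#' @rdname stat_mean_value
#' @export
stat_mean_saturation <- function(img) {
  v <- .value_channel(img)
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- ifelse(v == 0, 0, (v - mn) / v)
  mean(s)
}

#' @rdname stat_mean_value
#' @export
stat_hue_circular_mean <- function(img) {
  hsv <- rgb_to_hsv8(img)
  theta <- 2 * pi * as.numeric(hsv[, , 1]) / 256
  atan2(mean(sin(theta)), mean(cos(theta))) / (2 * pi)
}

#' @rdname stat_mean_value
#' @export
stat_sharpness <- function(img) {
  L <- (299 * img[, , 1] + 587 * img[, , 2] + 114 * img[, , 3]) / 1000
  h <- nrow(L); w <- ncol(L)
  if (h < 3L || w < 3L) return(0)
  core <- L[2:(h - 1), 2:(w - 1)]
  lap <- 4 * core - L[1:(h - 2), 2:(w - 1)] - L[3:h, 2:(w - 1)] -
    L[2:(h - 1), 1:(w - 2)] - L[2:(h - 1), 3:w]
  mean(abs(lap)) / (mean(L) + 1e-8)
}

.value_channel <- function(img) {
  pmax(img[, , 1], img[, , 2], img[, , 3])
}

probe_statistics <- function() {
  list(brightness = stat_mean_value,
       contrast = stat_value_cv,
       sharpness = stat_sharpness,
       saturation = stat_mean_saturation,
       hue = stat_hue_circular_mean)
}
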