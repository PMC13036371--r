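#' The black-box predictor contract
#'
#' A predictor is any function taking a list of `rgb_image` objects and
#' returning one probability in `[0, 1]` per image (probability of the
#' positive class, e.g. melanoma), deterministic in the input bytes and
#' preserving batch order. `as_predictor()` wraps a raw function and
#' validates the contract on a small deterministic canary batch: output
#' length, range, determinism, and batch-order preservation under
#' reversal.
#'
#' @param fn Function `list of rgb_image -> numeric probabilities`.
#' @param name Human-readable predictor name.
#' @param validate Run the canary-batch check (default `TRUE`).
#' @return A `predictor` object (callable).
#' @export
as_predictor <- function(fn, name = "predictor", validate = TRUE) {
  stopifnot(is.function(fn))
  p <- structure(fn, name = name, class = c("predictor", "function"))
  if (validate) validate_predictor(p)
  p
}

#' @rdname as_predictor
#' @param p A `predictor`.
#' @export
validate_predictor <- function(p) {
  canary <- list(constant_image(c(200, 120, 90), side = 8L, id = "canary1"),
                 constant_image(c(40, 60, 160), side = 8L, id = "canary2"),
                 constant_image(128, side = 8L, id = "canary3"))
  out1 <- p(canary)
  if (!is.numeric(out1) || length(out1) != length(canary)) {
    stop("predictor contract violation: must return one value per image",
         call. = FALSE)
  }
  if (anyNA(out1) || any(out1 < 0) || any(out1 > 1)) {
    stop("predictor contract violation: outputs must lie in [0, 1]",
         call. = FALSE)
  }
  if (!identical(p(canary), out1)) {
    stop("predictor contract violation: outputs must be deterministic",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(p(rev(canary)), rev(out1)))) {
    stop("predictor contract violation: batch order must be preserved",
         call. = FALSE)
  }
  invisible(p)
}

predict_batch <- function(predictor, images) {
  out <- predictor(images)
  if (anyNA(out) || any(out < 0) || any(out > 1)) {
    stop("predictor contract violation: output outside [0, 1]",
         call. = FALSE)
  }
  out
}

#' Analytic probe predictors
#'
#' Builds a synthetic classifier engineered to respond to exactly one
#' photometric factor: a scalar image statistic matched to the factor
#' (see [stat_mean_value()] and friends) mapped through a logistic
#' response `plogis(gain * (statistic - center))`. Under the default
#' perturbation bounds the designed factor should dominate the
#' total-order sensitivity ranking, which makes probes an end-to-end
#' validation instrument for the whole perturb-predict-estimate chain.
#'
#' @param target_factor One of `"brightness"`, `"contrast"`,
#'   `"sharpness"`, `"saturation"`, `"hue"`.
#' @param gain Logistic slope applied to the (dimensionless) statistic.
#' @param center Statistic value mapped to probability 0.5. Use
#'   [calibrate_probe()] to center a probe on a set of images.
#' @return A `predictor`.
#' @examples
#' pr <- make_probe_predictor("brightness", gain = 10, center = 0.5)
#' pr(list(constant_image(200), constant_image(50)))
#' @export
make_probe_predictor <- function(target_factor, gain = 10, center = 0.5) {
  stats_fns <- probe_statistics()
  if (!target_factor %in% names(stats_fns)) {
    stop("unknown factor: ", target_factor, call. = FALSE)
  }
  stat <- stats_fns[[target_factor]]
  as_predictor(
    function(images) {
      vapply(images, function(im) stats::plogis(gain * (stat(im) - center)), 0)
    },
    name = paste0(target_factor, "-probe")
  )
}

#' Center a probe predictor on a set of images
#'
#' Sets the probe's logistic center to the mean nominal statistic of the
#' given images (after resizing), so that the probe operates on the
#' steep part of its response over the perturbation range.
#'
#' @param target_factor Factor name as in [make_probe_predictor()].
#' @param images List of `rgb_image` (or `image_record`) objects.
#' @param gain Logistic slope.
#' @param side Working resolution used for the nominal statistic.
#' @return A calibrated `predictor`.
#' @export
calibrate_probe <- function(target_factor, images, gain = 10, side = 128L) {
  stat <- probe_statistics()[[target_factor]]
  if (is.null(stat)) stop("unknown factor: ", target_factor, call. = FALSE)
  imgs <- lapply(images, as_rgb_image)
  center <- mean(vapply(imgs, function(im) stat(resize_image(im, side)), 0))
  make_probe_predictor(target_factor, gain = gain, center = center)
}

#' Constant-probability predictor (degenerate-path fixture)
#'
#' @param p Constant probability returned for every image.
#' @return A `predictor`.
#' @export
constant_predictor <- function(p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  as_predictor(function(images) rep(p, length(images)),
               name = sprintf("constant(%g)", p))
}

as_rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) return(x)
  if (inherits(x, "image_record")) return(x$image)
  stop("expected an rgb_image or image_record", call. = FALSE)
}
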