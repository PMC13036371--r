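#' Decision-level instability and calibration metrics
#'
#' `flip_rate()` is the fraction of perturbed predictions whose
#' thresholded label differs from the baseline label; the positive rule
#' is `p >= t`, so a baseline exactly at the threshold is positive.
#' `gini_dispersion()` summarizes the dispersion of the binary perturbed
#' predictions as the Gini impurity `2 * p_hat * (1 - p_hat)` (twice the
#' Bernoulli variance), 0 for a perfectly stable decision and 0.5 at
#' maximum instability. `brier()` is the mean squared difference between
#' predicted probabilities and binary outcomes.
#'
#' @param baseline_p Baseline probability (prediction on the unperturbed,
#'   resized image).
#' @param perturbed_p Vector of probabilities under perturbation.
#' @param t Decision threshold in `(0, 1)`.
#' @return A scalar in `[0, 1]` (`flip_rate`, `brier`) or `[0, 0.5]`
#'   (`gini_dispersion`).
#' @examples
#' flip_rate(0.6, c(0.7, 0.4, 0.55, 0.3))  # 0.5
#' gini_dispersion(c(0.9, 0.8, 0.2))       # p_hat = 2/3
#' brier(c(0.8, 0.3), c(1, 0))             # 0.065
#' @export
flip_rate <- function(baseline_p, perturbed_p, t = 0.5) {
  .check_probs(c(baseline_p, perturbed_p))
  .check_threshold(t)
  if (length(perturbed_p) == 0L) {
    stop("perturbed probability vector is empty", call. = FALSE)
  }
  mean((perturbed_p >= t) != (baseline_p >= t))
}

#' @rdname flip_rate
#' @export
gini_dispersion <- function(perturbed_p, t = 0.5) {
  .check_probs(perturbed_p)
  .check_threshold(t)
  if (length(perturbed_p) == 0L) {
    stop("perturbed probability vector is empty", call. = FALSE)
  }
  phat <- mean(perturbed_p >= t)
  2 * phat * (1 - phat)
}

#' @rdname flip_rate
#' @param probabilities Predicted probabilities.
#' @param labels Binary outcomes (0/1), same length.
#' @export
brier <- function(probabilities, labels) {
  .check_probs(probabilities)
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  mean((probabilities - labels)^2)
}

.check_probs <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
}

.check_threshold <- function(t) {
  if (length(t) != 1L || !is.finite(t) || t <= 0 || t >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
}

#' Dataset-level decision metrics report
#'
#' Assembles the flip rate, Gini dispersion and Brier score overall and
#' per diagnostic category from per-image GSA results. The dataset flip
#' rate pools all image-by-perturbation pairs (the evaluation-weighted
#' mean of per-image flip rates); the Gini column reports the mean (and
#' SD) of per-image Gini dispersions; the Brier score uses the baseline
#' (unperturbed) predictions against the labels.
#'
#' @param results List of `per_image_sensitivity`.
#' @param labels Binary label vector aligned to `results` (or named by
#'   image id).
#' @param category_names Names used for the label strata (default
#'   `c("non-melanoma", "melanoma")` for labels 0 and 1).
#' @return Data frame: `category`, `flip_rate`, `gini`, `gini_sd`,
#'   `brier`, `n_images`.
#' @export
decision_report <- function(results, labels,
                            category_names = c("non-melanoma", "melanoma")) {
  if (!is.null(names(labels))) {
    ids <- vapply(results, function(r) r$image_id, "")
    if (all(ids %in% names(labels))) labels <- labels[ids]
  }
  stopifnot(length(labels) == length(results))
  flips <- vapply(results, function(r) r$flip_rate, 0)
  ginis <- vapply(results, function(r) r$gini, 0)
  evals <- vapply(results, function(r) r$n_eval, 0L)
  base <- vapply(results, function(r) r$baseline_p, 0)
  one_row <- function(keep, name) {
    data.frame(
      category = name,
      flip_rate = stats::weighted.mean(flips[keep], evals[keep]),
      gini = mean(ginis[keep]),
      gini_sd = if (sum(keep) > 1L) stats::sd(ginis[keep]) else 0,
      brier = brier(base[keep], labels[keep]),
      n_images = sum(keep)
    )
  }
  parts <- list()
  for (lv in c(1, 0)) {
    keep <- labels == lv
    if (any(keep)) parts[[length(parts) + 1L]] <-
        one_row(keep, category_names[lv + 1L])
  }
  parts[[length(parts) + 1L]] <- one_row(rep(TRUE, length(results)), "overall")
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' One-at-a-time parameter sweep
#'
#' Varies a single photometric factor over a linear grid spanning its
#' bounds (inclusive) while all other factors sit at their nominal
#' values (1.0 for the multiplicative factors, 0.0 for the hue shift),
#' recording the predicted probability at each grid point.
#'
#' @param img An `rgb_image` or `image_record`.
#' @param predictor A `predictor`.
#' @param factor Factor name to sweep.
#' @param n_steps Number of grid points (`>= 2`, default 5).
#' @param bounds Bounds configuration.
#' @param side Working resolution.
#' @return An `oat_sweep`: data frame columns `value`, `probability`,
#'   with attributes `factor`, `image_id`, `nominal`.
#' @export
oat_sweep <- function(img, predictor, factor, n_steps = 5L,
                      bounds = default_bounds(), side = 128L) {
  bounds <- as_factor_bounds(bounds)
  if (!factor %in% bounds$name) {
    stop("unknown factor: ", factor, call. = FALSE)
  }
  if (n_steps < 2L) stop("n_steps must be >= 2", call. = FALSE)
  image <- as_rgb_image(img)
  b <- bounds[bounds$name == factor, ]
  grid <- seq(b$lo, b$hi, length.out = n_steps)
  nominal <- nominal_sample()
  variants <- lapply(grid, function(v) {
    s <- nominal
    s[[factor]] <- v
    apply_perturbation(image, s, side = side)
  })
  probs <- predict_batch(predictor, variants)
  structure(
    data.frame(value = grid, probability = probs),
    factor = factor, image_id = image_id(image),
    nominal = nominal, class = c("oat_sweep", "data.frame")
  )
}

#' @export
plot.oat_sweep <- function(x, ...) {
  graphics::plot(x$value, x$probability, type = "b", pch = 19,
                 xlab = attr(x, "factor"), ylab = "predicted probability",
                 ylim = c(0, 1),
                 main = paste0("OAT sweep: ", attr(x, "factor"), " (",
                               attr(x, "image_id"), ")"), ...)
  invisible(x)
}
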