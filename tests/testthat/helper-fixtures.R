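# shared fixtures, built in code and cached for the duration of a test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_dataset <- function(n = 8L, seed = 11L, side = 128L) {
  cached(sprintf("ds_%d_%d_%d", n, seed, side),
         generate_synthetic_dataset(synthetic_dataset_spec(
           n_images = n, image_side = side, seed = seed)))
}

fixture_images <- function(n = 8L, seed = 11L, side = 128L) {
  lapply(fixture_dataset(n, seed, side)$records, function(r) r$image)
}

# deterministic pseudo-random test image (no RNG state touched)
noise_image <- function(side = 16L, seed = 5L, id = "noise") {
  vals <- (seed + 37 * seq_len(side * side * 3L)^2) %% 256
  rgb_image(array(vals, dim = c(side, side, 3L)), id = id)
}

gradient_image <- function(side = 32L, id = "gradient") {
  g <- matrix(rep(seq(0, 255, length.out = side), each = side), nrow = side)
  rgb_image(array(c(g, g, t(g)), dim = c(side, side, 3L)), id = id)
}

# plain-R oracle for the enhancement semantics, independent of the C++ path
r_enhance_oracle <- function(img, kind, factor) {
  px <- array(as.numeric(img), dim = dim(img))
  rha <- function(x) sign(x) * floor(abs(x) + 0.5)
  luma <- rha((299 * px[, , 1] + 587 * px[, , 2] + 114 * px[, , 3]) / 1000)
  deg <- switch(kind,
    brightness = array(0, dim = dim(px)),
    contrast = array(rha(mean(luma)), dim = dim(px)),
    saturation = array(rep(luma, 3L), dim = dim(px)),
    sharpness = {
      h <- dim(px)[1]; w <- dim(px)[2]
      out <- px
      k <- matrix(c(1, 1, 1, 1, 5, 1, 1, 1, 1), 3) / 13
      for (ch in 1:3) {
        for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
          out[i, j, ch] <- rha(sum(px[(i - 1):(i + 1), (j - 1):(j + 1), ch] * k))
        }
      }
      out
    })
  res <- rha((1 - factor) * deg + factor * px)
  res <- pmin(pmax(res, 0), 255)
  rgb_image(res, id = attr(img, "id"))
}

# fabricate a per_image_sensitivity result (aggregation-level tests)
fake_result <- function(id, S1, ST, degenerate = FALSE, baseline_p = 0.5,
                        flip = 0.1, gini = 0.1, n_eval = 112L) {
  structure(
    list(image_id = id, predictor = "fake",
         S1 = S1, ST = ST,
         S1_clipped = pmin(pmax(S1, 0), 1), ST_clipped = pmin(pmax(ST, 0), 1),
         Vy = 0.01, degenerate = degenerate, baseline_p = baseline_p,
         flip_rate = flip, gini = gini, threshold = 0.5, n_eval = n_eval,
         responses = NULL),
    class = "per_image_sensitivity")
}

fake_factors <- c("brightness", "contrast", "sharpness", "saturation", "hue")

named5 <- function(...) stats::setNames(c(...), fake_factors)
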