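test_that("resizing is the identity at the target size and averages blocks", {
  img <- noise_image(16L)
  expect_identical(unclass(resize_image(img, 16L)), unclass(img))
  # constant color survives interpolation
  cimg <- constant_image(c(13, 200, 77), side = 24L)
  out <- resize_image(cimg, 12L)
  expect_true(all(out[, , 1] == 13 & out[, , 2] == 200 & out[, , 3] == 77))
  # 4x4 -> 2x2 bilinear: each output pixel is the mean of its 2x2 block
  img4 <- noise_image(4L, seed = 9L)
  out2 <- resize_image(img4, 2L)
  for (ch in 1:3) {
    for (i in 1:2) for (j in 1:2) {
      block <- img4[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]
      expect_identical(out2[i, j, ch],
                       as.integer(round_half_away(mean(block))))
    }
  }
})

test_that("factor 1 is a byte-exact identity for every enhancement", {
  img <- noise_image(12L)
  for (kind in c("brightness", "contrast", "saturation", "sharpness")) {
    expect_identical(unclass(enhance(img, kind, 1)), unclass(img),
                     label = kind)
  }
})

test_that("brightness scaling follows exact 8-bit arithmetic with clipping", {
  expect_true(all(enhance(constant_image(100), "brightness", 0.5) == 50))
  expect_true(all(enhance(constant_image(128), "brightness", 1.5) == 192))
  # 1.5 * 200 = 300 clips to 255, not wraps
  expect_true(all(enhance(constant_image(200), "brightness", 1.5) == 255))
})

test_that("smoothing fixes constant images so sharpness leaves them alone", {
  img <- constant_image(91, side = 10L)
  for (f in c(0, 0.5, 1.3)) {
    expect_identical(unclass(enhance(img, "sharpness", f)), unclass(img))
  }
})

test_that("enhancement kernels match an independent plain-R oracle", {
  imgs <- list(noise_image(8L, seed = 2L), gradient_image(8L))
  for (img in imgs) {
    for (kind in c("brightness", "contrast", "saturation", "sharpness")) {
      for (f in c(0, 0.5, 0.8, 1.2, 1.5)) {
        expect_identical(unclass(enhance(img, kind, f)),
                         unclass(r_enhance_oracle(img, kind, f)),
                         label = paste(attr(img, "id"), kind, f))
      }
    }
  }
})

test_that("invalid enhancement requests fail loudly", {
  img <- constant_image(10)
  expect_error(enhance(img, "brightness", -0.1), "non-negative")
  expect_error(enhance(img, "warmth", 1), "unknown enhancement kind")
})

test_that("hue-shift arithmetic wraps on the 8-bit hue circle", {
  expect_identical(hue_shift_amount(0.1), 26L)
  expect_identical((240L + hue_shift_amount(0.1)) %% 256L, 10L)
  expect_identical(hue_shift_amount(-0.1), -26L)
  img <- noise_image(10L)
  expect_identical(unclass(shift_hue(img, 0)), unclass(img))
  # on the H channel itself the integer shift composes additively mod 256
  hsv <- rgb_to_hsv8(img)
  h0 <- hsv[, , 1]
  expect_identical((((h0 + 26L) %% 256L) + 18L) %% 256L,
                   (h0 + 44L) %% 256L)
  # measured through the 8-bit RGB representation the shift is exact up to
  # the one-unit hue quantization of the HSV round trip
  circ <- function(a, b) pmin((a - b) %% 256L, (b - a) %% 256L)
  h1 <- rgb_to_hsv8(shift_hue(img, 0.1))[, , 1]
  gray <- hsv[, , 2] == 0   # hue undefined for achromatic pixels
  expect_lte(max(circ(h1, (h0 + 26L) %% 256L)[!gray]), 1L)
})

test_that("shifting hue forward then back restores hue and RGB up to quantization", {
  img <- resize_image(fixture_images(n = 2L)[[1L]], 64L)
  fwd <- shift_hue(img, 0.1)
  back <- shift_hue(fwd, -0.1)
  circ <- function(a, b) pmin((a - b) %% 256L, (b - a) %% 256L)
  gray <- rgb_to_hsv8(img)[, , 2] == 0
  expect_lte(max(circ(rgb_to_hsv8(back)[, , 1],
                      rgb_to_hsv8(img)[, , 1])[!gray]), 1L)
  # measured HSV round-trip quantization bound on dermoscopy-like pixels
  expect_lte(max(abs(unclass(back) - unclass(img))), 3L)
})

test_that("delta_h outside [-1, 1] is rejected", {
  expect_error(shift_hue(constant_image(10), 1.5), "\\[-1, 1\\]")
})

test_that("the nominal sample reproduces the resized image byte-for-byte", {
  for (img in fixture_images(n = 2L)) {
    expect_identical(unclass(apply_perturbation(img, nominal_sample())),
                     unclass(resize_image(img)))
  }
})

test_that("the perturbation pipeline is deterministic and stays in range", {
  img <- fixture_images(n = 2L)[[2L]]
  samples <- list(
    factor_sample(0.5, 0.8, 1.2, 1.5, -0.1),
    factor_sample(1.5, 1.2, 0.8, 0.5, 0.1),
    factor_sample(1.27, 0.93, 1.07, 0.66, 0.033)
  )
  for (s in samples) {
    a <- apply_perturbation(img, s, side = 64L)
    b <- apply_perturbation(img, s, side = 64L)
    expect_identical(unclass(a), unclass(b))
    expect_true(min(a) >= 0L && max(a) <= 255L)
  }
  expect_true(all(apply_perturbation(constant_image(128, side = 16L),
                                     factor_sample(brightness = 1.5),
                                     side = 16L) == 192L))
})

test_that("stage order matters: swapping brightness and contrast changes pixels", {
  img <- gradient_image(32L)
  bc <- enhance(enhance(img, "brightness", 1.4), "contrast", 0.8)
  cb <- enhance(enhance(img, "contrast", 0.8), "brightness", 1.4)
  expect_false(identical(unclass(bc), unclass(cb)))
})

test_that("pipeline accepts plain named vectors as factor samples", {
  img <- constant_image(100, side = 16L)
  s <- c(brightness = 0.5, contrast = 1, sharpness = 1, saturation = 1,
         hue = 0)
  expect_true(all(apply_perturbation(img, s, side = 16L) == 50L))
})
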