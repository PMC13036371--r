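toy_table <- function(n = 600L, seed = 1L, response = NULL) {
  set.seed(seed)
  tab <- data.frame(
    brightness = runif(n, 0.5, 1.5), contrast = runif(n, 0.8, 1.2),
    sharpness = runif(n, 0.8, 1.2), saturation = runif(n, 0.5, 1.5),
    hue = runif(n, -0.1, 0.1))
  tab$y <- if (is.null(response)) {
    plogis(3 * (tab$brightness - 1))
  } else {
    response(tab)
  }
  tab
}

test_that("the surrogate learns a factor-driven response out of sample", {
  sur <- fit_surrogate(toy_table(), seed = 2L)
  expect_false(sur$skipped)
  expect_gt(sur$r2_holdout, 0.9)
})

test_that("degenerate responses and undersized tables are refused", {
  tab <- toy_table(100L)
  tab$y <- 0.4
  expect_warning(sur <- fit_surrogate(tab, seed = 1L), "degenerate")
  expect_true(sur$skipped)
  expect_error(fit_surrogate(toy_table(30L)), "at least 50")
})

test_that("refitting with the same seed gives identical attributions", {
  tab <- toy_table(300L)
  s1 <- fit_surrogate(tab, seed = 7L)
  s2 <- fit_surrogate(tab, seed = 7L)
  bg <- tab[1:50, ]
  x <- unlist(tab[3, 1:5])
  expect_identical(exact_shapley(s1, x, bg), exact_shapley(s2, x, bg))
  expect_identical(s1$r2_holdout, s2$r2_holdout)
})

test_that("Shapley efficiency holds exactly on the fitted surrogate", {
  tab <- toy_table(300L)
  sur <- fit_surrogate(tab, seed = 3L)
  bg <- tab[1:80, ]
  for (row in c(2L, 11L)) {
    x <- unlist(tab[row, 1:5])
    phi <- exact_shapley(sur, x, bg)
    fx <- photosens:::surrogate_predict(sur, as.data.frame(as.list(x)))
    f0 <- mean(photosens:::surrogate_predict(sur, bg))
    expect_equal(sum(phi), fx - f0, tolerance = 1e-10)
  }
})

test_that("additivity, symmetry and dummy axioms hold on analytic surrogates", {
  factors <- c("a", "b", "c")
  set.seed(4)
  bg <- data.frame(a = runif(50), b = runif(50), c = runif(50))
  # additive: phi_i = f_i(x_i) - mean(f_i(bg_i))
  add <- photosens:::analytic_surrogate(
    function(X) 2 * X$a + 3 * X$b^2 + 0 * X$c, factors)
  x <- c(a = 0.9, b = 0.2, c = 0.7)
  phi <- exact_shapley(add, x, bg)
  expect_equal(phi[["a"]], 2 * 0.9 - mean(2 * bg$a), tolerance = 1e-12)
  expect_equal(phi[["b"]], 3 * 0.2^2 - mean(3 * bg$b^2), tolerance = 1e-12)
  # dummy: an ignored factor gets exactly zero
  expect_equal(phi[["c"]], 0, tolerance = 1e-12)
  # symmetry: duplicated factors with identical positions share credit
  sym <- photosens:::analytic_surrogate(function(X) X$a * X$b, factors)
  bg_sym <- bg
  bg_sym$b <- bg_sym$a
  phi_sym <- exact_shapley(sym, c(a = 0.6, b = 0.6, c = 0.1), bg_sym)
  expect_equal(phi_sym[["a"]], phi_sym[["b"]], tolerance = 1e-12)
})

test_that("exact enumeration agrees with permutation sampling at D = 5", {
  tab <- toy_table(300L, response = function(t) {
    plogis(2 * (t$brightness - 1) + 5 * t$hue + (t$contrast - 1) *
             (t$saturation - 1))
  })
  sur <- fit_surrogate(tab, seed = 5L)
  bg <- tab[1:60, ]
  x <- unlist(tab[7, 1:5])
  exact <- exact_shapley(sur, x, bg)
  approx <- sampling_shapley(sur, x, bg, n_perm = 300L, seed = 6L)
  expect_lt(max(abs(exact - approx)), 0.01)
})

test_that("batched attribution matches one-at-a-time enumeration", {
  tab <- toy_table(200L)
  sur <- fit_surrogate(tab, seed = 8L)
  bg <- tab[1:40, ]
  X <- tab[5:8, 1:5]
  batch <- exact_shapley_batch(sur, X, bg)
  for (k in seq_len(nrow(X))) {
    expect_equal(unname(batch[k, ]),
                 unname(exact_shapley(sur, unlist(X[k, ]), bg)),
                 tolerance = 1e-12)
  }
})

test_that("per-image attribution aggregates mean absolute Shapley values", {
  img <- fixture_images(n = 2L)[[1L]]
  pr <- make_probe_predictor("brightness", gain = 20, center = 0.5)
  r <- run_image_gsa(img, pr, N = 32L, seed = 1L, side = 32L,
                     return_responses = TRUE)
  att <- shapley_attribution(list(r), seed = 1L, n_background = 50L,
                             n_explain = 20L)
  expect_identical(att$overall$factor, default_bounds()$name)
  top <- att$overall$factor[which.max(att$overall$mean_abs_shap)]
  expect_identical(top, "brightness")
  expect_identical(att$n_skipped, 0L)
  # constant-response images are skipped and counted
  rc <- run_image_gsa(img, constant_predictor(0.5), N = 32L, seed = 1L,
                      side = 32L, return_responses = TRUE)
  expect_error(shapley_attribution(list(rc), seed = 1L), "skipped")
  att2 <- shapley_attribution(list(r, rc), seed = 1L, n_background = 50L,
                              n_explain = 10L)
  expect_identical(att2$n_skipped, 1L)
})

test_that("rank concordance compares orderings, not magnitudes", {
  mk_report <- function(st) {
    structure(list(overall = data.frame(factor = names(st),
                                        mean_ST = unname(st))),
              class = "aggregate_report")
  }
  mk_shap <- function(v) {
    structure(list(overall = data.frame(factor = names(v),
                                        mean_abs_shap = unname(v))),
              class = "shapley_attribution")
  }
  st <- c(a = 0.5, b = 0.3, c = 0.1)
  expect_equal(rank_concordance(mk_report(st),
                                mk_shap(c(a = 9, b = 5, c = 2)))$tau, 1)
  rc <- rank_concordance(mk_report(st), mk_shap(c(a = 1, b = 2, c = 3)))
  expect_equal(rc$tau, -1)
  expect_false(rc$top1_agree)
  expect_error(rank_concordance(mk_report(st), mk_shap(c(a = 1, b = 2))),
               "factor sets")
})
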