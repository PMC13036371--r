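test_that("additive responses give S1 = ST = 1/2 per factor", {
  b <- factor_bounds(c("x1", "x2"), c(0, 0), c(1, 1))
  d <- saltelli_sample(b, N = 1024L, seed = 2021L)
  r <- estimate_sobol(d, rowSums(design_matrix(d)))
  expect_false(r$degenerate)
  expect_equal(unname(r$S1), c(0.5, 0.5), tolerance = 0.05)
  expect_lt(max(abs(r$ST - r$S1)), 0.02)
})

test_that("closed-form indices of the analytic registry are recovered", {
  for (case in list(
    list(tf = sobol_test_function("ishigami"), tol_s1 = 0.02, tol_st = 0.03),
    list(tf = sobol_test_function("g_function", a = c(0, 1, 4.5)),
         tol_s1 = 0.03, tol_st = 0.03),
    list(tf = sobol_test_function("additive_linear", coef = c(2, 1)),
         tol_s1 = 0.03, tol_st = 0.03)
  )) {
    tf <- case$tf
    d <- saltelli_sample(tf$bounds, N = 2048L, seed = 2021L)
    r <- estimate_sobol(d, tf$f(design_matrix(d)))
    expect_lt(max(abs(r$S1 - tf$true_S1)), case$tol_s1)
    expect_lt(max(abs(r$ST - tf$true_ST)), case$tol_st)
  }
})

test_that("a constant response sets the degenerate flag instead of dividing", {
  d <- saltelli_sample(default_bounds(), N = 16L, seed = 1L)
  expect_warning(r <- estimate_sobol(d, rep(0.7, nrow(design_matrix(d)))),
                 "variance below tolerance")
  expect_true(r$degenerate)
  expect_identical(unname(r$S1), rep(0, 5))
  expect_identical(unname(r$ST), rep(0, 5))
  expect_true(all(is.finite(r$S1)) && all(is.finite(r$ST)))
})

test_that("response vectors are validated against the design", {
  d <- saltelli_sample(default_bounds(), N = 8L, seed = 1L)
  expect_error(estimate_sobol(d, rep(0.5, 10)), "length")
  y <- rep(0.5, nrow(design_matrix(d)))
  y[3] <- NA
  expect_error(estimate_sobol(d, y), "finite")
})

test_that("raw estimates are reported alongside a [0,1]-clipped view", {
  tf <- sobol_test_function("ishigami")
  d <- saltelli_sample(tf$bounds, N = 256L, seed = 5L)
  r <- estimate_sobol(d, tf$f(design_matrix(d)))
  expect_true(all(r$S1_clipped >= 0 & r$S1_clipped <= 1))
  expect_true(all(r$ST_clipped >= 0 & r$ST_clipped <= 1))
  # x3 is non-additive-inert: its raw S1 may be slightly negative, and the
  # clipped view must not overwrite the raw value
  expect_identical(r$S1_clipped, pmin(pmax(r$S1, 0), 1))
})

test_that("a factor the function ignores has ST near zero", {
  b <- factor_bounds(c("active", "inert"), c(0, 0), c(1, 1))
  d <- saltelli_sample(b, N = 1024L, seed = 9L)
  m <- design_matrix(d)
  r <- estimate_sobol(d, sin(2 * pi * m[, 1]))
  expect_lt(abs(r$ST[["inert"]]), 0.01)
  expect_gt(r$ST[["active"]], 0.9)
})

test_that("brute-force oracle recovers the g-function closed form", {
  tf <- sobol_test_function("g_function", a = c(0, 1))
  r <- brute_force_sobol(tf$f, tf$bounds, n_outer = 1000L, n_inner = 500L,
                         seed = 1L)
  expect_lt(max(abs(r$S1 - tf$true_S1)), 0.03)
  expect_lt(max(abs(r$ST - tf$true_ST)), 0.03)
})

test_that("brute-force oracle flags constants and enforces its budget", {
  b <- factor_bounds("x", 0, 1)
  r <- brute_force_sobol(function(m) rep(1, nrow(m)), b,
                         n_outer = 10L, n_inner = 10L, seed = 1L)
  expect_true(r$degenerate)
  expect_error(brute_force_sobol(function(m) m[, 1], b,
                                 n_outer = 2000L, n_inner = 1000L),
               "budget")
  b5 <- default_bounds()
  expect_error(brute_force_sobol(function(m) m[, 1], b5), "at most 4")
})

test_that("Saltelli estimators and brute-force oracle agree on test functions", {
  for (tf in list(sobol_test_function("ishigami"),
                  sobol_test_function("additive_linear", coef = c(1, 3)))) {
    d <- saltelli_sample(tf$bounds, N = 2048L, seed = 2021L)
    est <- estimate_sobol(d, tf$f(design_matrix(d)))
    bf <- brute_force_sobol(tf$f, tf$bounds, n_outer = 800L, n_inner = 500L,
                            seed = 17L)
    expect_lt(max(abs(est$S1 - bf$S1)), 0.05)
    expect_lt(max(abs(est$ST - bf$ST)), 0.05)
  }
})

test_that("the analytic registry is self-consistent", {
  tf <- sobol_test_function("ishigami")
  # interaction structure: x3 acts only through x1; x2 is purely additive
  expect_equal(tf$true_S1[["x3"]], 0)
  expect_gt(tf$true_ST[["x3"]], 0.2)
  expect_equal(tf$true_S1[["x2"]], tf$true_ST[["x2"]])
  expect_equal(sum(tf$true_S1), 1 - (tf$true_ST[["x3"]] - tf$true_S1[["x3"]]),
               tolerance = 1e-12)
  ta <- sobol_test_function("additive_linear", coef = c(1, 2, 3))
  expect_identical(ta$true_S1, ta$true_ST)
  # a factor with huge a is inert in the g-function
  tg <- sobol_test_function("g_function", a = c(0, 1e6))
  expect_lt(tg$true_S1[["x2"]], 1e-10)
  expect_error(sobol_test_function("nope"))
})
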