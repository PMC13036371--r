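#' Estimate Sobol sensitivity indices from a Saltelli design
#'
#' Computes per-factor first-order indices `S1` (fraction of output
#' variance attributable to a factor alone) and total-order indices `ST`
#' (fraction attributable to the factor including all its interactions)
#' from a response vector aligned to the design's evaluation order.
#'
#' `S1_i` uses the Saltelli-2010 estimator
#' `mean(f(B) * (f(AB_i) - f(A))) / V(Y)` and `ST_i` the Jansen estimator
#' `mean((f(A) - f(AB_i))^2) / (2 * V(Y))`, with the total variance
#' `V(Y)` computed from the pooled `A` and `B` evaluations. Raw estimates
#' may fall slightly outside `[0, 1]` by Monte-Carlo noise; clipped
#' versions are provided alongside, never silently substituted.
#'
#' @param design A `saltelli_design` from [saltelli_sample()].
#' @param y Numeric response vector of length `N * (D + 2)` in the
#'   evaluation order: `f(A)` rows, `f(B)` rows, `f(AB_1)`, ..., `f(AB_D)`.
#' @param var_tol Variance below which the response is declared degenerate
#'   (all indices reported as 0 with a warning, never a division blow-up).
#'   The default suits responses on a probability scale.
#' @return A `sobol_result`: named vectors `S1`, `ST` (raw), `S1_clipped`,
#'   `ST_clipped` (restricted to `[0, 1]`), total variance `Vy`, `n_eval`,
#'   and logical `degenerate`.
#' @examples
#' bounds <- list(x1 = c(0, 1), x2 = c(0, 1))
#' d <- saltelli_sample(bounds, N = 1024, seed = 1)
#' y <- rowSums(design_matrix(d))
#' estimate_sobol(d, y)  # additive: S1 == ST == 0.5 up to MC noise
#' @export
estimate_sobol <- function(design, y, var_tol = 1e-12) {
  stopifnot(inherits(design, "saltelli_design"))
  N <- design$N
  D <- design$D
  if (length(y) != N * (D + 2L)) {
    stop("length(y) must equal N * (D + 2) = ", N * (D + 2L),
         " (got ", length(y), ")", call. = FALSE)
  }
  if (!all(is.finite(y))) {
    stop("response vector contains non-finite values", call. = FALSE)
  }
  fA <- y[seq_len(N)]
  fB <- y[N + seq_len(N)]
  fAB <- lapply(seq_len(D), function(i) y[(i + 1L) * N + seq_len(N)])
  pooled <- c(fA, fB)
  Vy <- mean(pooled^2) - mean(pooled)^2
  nms <- design$bounds$name
  if (!is.finite(Vy) || Vy < var_tol) {
    warning("response variance below tolerance (", format(var_tol),
            "); indices reported as 0", call. = FALSE)
    z <- stats::setNames(numeric(D), nms)
    return(new_sobol_result(z, z, Vy = max(Vy, 0), n_eval = length(y),
                            degenerate = TRUE))
  }
  S1 <- vapply(seq_len(D), function(i) mean(fB * (fAB[[i]] - fA)) / Vy, 0)
  ST <- vapply(seq_len(D), function(i) mean((fA - fAB[[i]])^2) / (2 * Vy), 0)
  new_sobol_result(stats::setNames(S1, nms), stats::setNames(ST, nms),
                   Vy = Vy, n_eval = length(y), degenerate = FALSE)
}

new_sobol_result <- function(S1, ST, Vy, n_eval, degenerate) {
  structure(
    list(S1 = S1, ST = ST,
         S1_clipped = pmin(pmax(S1, 0), 1),
         ST_clipped = pmin(pmax(ST, 0), 1),
         Vy = Vy, n_eval = as.integer(n_eval),
         degenerate = isTRUE(degenerate)),
    class = "sobol_result"
  )
}

#' @export
print.sobol_result <- function(x, digits = 4, ...) {
  cat("Sobol indices (", x$n_eval, " evaluations, V(Y) = ",
      format(x$Vy, digits = digits), if (x$degenerate) ", DEGENERATE" else "",
      ")\n", sep = "")
  print(round(rbind(S1 = x$S1, ST = x$ST), digits))
  invisible(x)
}

#' Brute-force Sobol indices by double-loop Monte Carlo
#'
#' Verification oracle: estimates `S1_i = V(E(Y | X_i)) / V(Y)` and
#' `ST_i = E(V(Y | X_~i)) / V(Y)` by literal conditional-expectation
#' sampling with plain pseudo-random draws — an outer loop over the
#' conditioning variable(s) and an inner loop averaging over the rest.
#' Deliberately independent of the Saltelli design path; intended for
#' tests at desk scale only.
#'
#' @param f Vectorized function taking an `n x D` matrix, returning `n`
#'   responses.
#' @param bounds Bounds configuration (at most 4 factors).
#' @param n_outer,n_inner Outer/inner Monte-Carlo sample counts;
#'   `n_outer * n_inner` must not exceed `1e6`.
#' @param seed Integer seed for the pseudo-random draws.
#' @return A `sobol_result` (no clipping applied beyond the shared view).
#' @export
brute_force_sobol <- function(f, bounds, n_outer = 1000L, n_inner = 500L,
                              seed = 1L) {
  bounds <- as_factor_bounds(bounds)
  D <- nrow(bounds)
  if (D > 4L) {
    stop("brute_force_sobol is a desk-scale oracle; at most 4 factors",
         call. = FALSE)
  }
  if (n_outer * n_inner > 1e6) {
    stop("budget exceeded: n_outer * n_inner must be <= 1e6", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  runif_bounds <- function(n) {
    m <- matrix(stats::runif(n * D), ncol = D)
    for (j in seq_len(D)) {
      m[, j] <- bounds$lo[j] + (bounds$hi[j] - bounds$lo[j]) * m[, j]
    }
    colnames(m) <- bounds$name
    m
  }

  # total variance from one large plain sample
  Vy <- stats::var(f(runif_bounds(n_outer * n_inner)))
  nms <- bounds$name
  if (!is.finite(Vy) || Vy < 1e-12) {
    z <- stats::setNames(numeric(D), nms)
    return(new_sobol_result(z, z, Vy = max(Vy, 0),
                            n_eval = n_outer * n_inner, degenerate = TRUE))
  }

  S1 <- ST <- numeric(D)
  for (i in seq_len(D)) {
    # S1: outer over x_i, inner expectation over the complement
    xi <- runif_bounds(n_outer)[, i]
    cond_mean <- vapply(seq_len(n_outer), function(k) {
      m <- runif_bounds(n_inner)
      m[, i] <- xi[k]
      mean(f(m))
    }, 0)
    # de-bias: Var(means) overestimates V(E(Y|X_i)) by E(V_inner)/n_inner;
    # estimate E(V_inner) over several conditioning points
    inner_var <- mean(vapply(seq_len(min(20L, n_outer)), function(k) {
      m <- runif_bounds(n_inner)
      m[, i] <- xi[k]
      stats::var(f(m))
    }, 0))
    S1[i] <- (stats::var(cond_mean) - inner_var / n_inner) / Vy
    # ST: outer over the complement, inner variance over x_i. The
    # between-point spread of V(Y|X_~i) dominates the Monte-Carlo error,
    # so the budget favors outer points over inner replicates.
    n_outer_st <- 4L * n_outer
    n_inner_st <- max(50L, n_inner %/% 4L)
    outer_pts <- runif_bounds(n_outer_st)
    cond_var <- vapply(seq_len(n_outer_st), function(k) {
      m <- matrix(rep(outer_pts[k, ], each = n_inner_st), ncol = D)
      colnames(m) <- nms
      m[, i] <- bounds$lo[i] + (bounds$hi[i] - bounds$lo[i]) *
        stats::runif(n_inner_st)
      stats::var(f(m))
    }, 0)
    ST[i] <- mean(cond_var) / Vy
  }
  new_sobol_result(stats::setNames(S1, nms), stats::setNames(ST, nms),
                   Vy = Vy, n_eval = 2L * D * n_outer * n_inner,
                   degenerate = FALSE)
}

#' Registry of analytic test functions with closed-form Sobol indices
#'
#' Standard benchmarks of the sensitivity-analysis literature, each
#' returned with its bounds and exact first-order and total-order
#' indices, used to validate the estimators.
#'
#' * `ishigami`: `f(x) = sin(x1) + a*sin(x2)^2 + b*x3^4*sin(x1)` on
#'   `[-pi, pi]^3` (defaults `a = 7`, `b = 0.1`). Nonlinear with a pure
#'   x1:x3 interaction, so `ST3 > S1_3 = 0`.
#' * `g_function`: `prod((|4*x_i - 2| + a_i) / (1 + a_i))` on `[0, 1]^D`;
#'   factor `i` has partial variance `(1/3) / (1 + a_i)^2` and large
#'   `a_i` makes it inert.
#' * `additive_linear`: `sum(c_i * x_i)` on `[0, 1]^D`; additive, so
#'   `S1 == ST` exactly.
#'
#' @param name One of `"ishigami"`, `"g_function"`, `"additive_linear"`.
#' @param ... Parameters forwarded to the entry (`a`, `b` for ishigami;
#'   `a` vector for the g-function; `coef` vector for additive_linear).
#' @return A list with `f` (vectorized over matrix rows), `bounds`,
#'   `true_S1`, `true_ST`, `variance`.
#' @export
sobol_test_function <- function(name = c("ishigami", "g_function",
                                         "additive_linear"), ...) {
  name <- match.arg(name)
  switch(name,
    ishigami = .tf_ishigami(...),
    g_function = .tf_g_function(...),
    additive_linear = .tf_additive_linear(...)
  )
}

.tf_ishigami <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  list(
    f = function(x) sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1]),
    bounds = factor_bounds(c("x1", "x2", "x3"), rep(-pi, 3), rep(pi, 3)),
    true_S1 = stats::setNames(c(V1, V2, 0) / V, c("x1", "x2", "x3")),
    true_ST = stats::setNames(c(V1 + V13, V2, V13) / V, c("x1", "x2", "x3")),
    variance = V
  )
}

.tf_g_function <- function(a = c(0, 1)) {
  D <- length(a)
  Vi <- (1 / 3) / (1 + a)^2
  V <- prod(1 + Vi) - 1
  STi <- Vi * vapply(seq_len(D), function(i) prod(1 + Vi[-i]), 0)
  nms <- paste0("x", seq_len(D))
  list(
    f = function(x) {
      out <- rep(1, nrow(x))
      for (i in seq_len(D)) {
        out <- out * (abs(4 * x[, i] - 2) + a[i]) / (1 + a[i])
      }
      out
    },
    bounds = factor_bounds(nms, rep(0, D), rep(1, D)),
    true_S1 = stats::setNames(Vi / V, nms),
    true_ST = stats::setNames(STi / V, nms),
    variance = V
  )
}

.tf_additive_linear <- function(coef = c(1, 1)) {
  D <- length(coef)
  Vi <- coef^2 / 12
  nms <- paste0("x", seq_len(D))
  list(
    f = function(x) as.numeric(x %*% coef),
    bounds = factor_bounds(nms, rep(0, D), rep(1, D)),
    true_S1 = stats::setNames(Vi / sum(Vi), nms),
    true_ST = stats::setNames(Vi / sum(Vi), nms),
    variance = sum(Vi)
  )
}
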