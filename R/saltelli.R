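#' Saltelli sampling design for variance-based sensitivity analysis
#'
#' Builds the paired-matrix design used to estimate first-order and
#' total-order Sobol indices from `N * (D + 2)` model evaluations: two
#' independent `N x D` factor matrices `A` and `B`, plus `D` hybrid
#' matrices `AB_i` equal to `A` with column `i` replaced by column `i`
#' of `B`. Points are drawn from a seeded Sobol' low-discrepancy sequence
#' in `2 * D` dimensions (first `D` columns feed `A`, last `D` feed `B`)
#' and mapped affinely onto the factor bounds.
#'
#' The serialized evaluation order, used everywhere a response vector is
#' aligned to the design, is: the `N` rows of `A`, then the `N` rows of
#' `B`, then the rows of `AB_1`, ..., `AB_D`.
#'
#' @param bounds A `factor_bounds` configuration (see [default_bounds()]),
#'   or anything [factor_bounds()] accepts via a named list of ranges.
#' @param N Base sample count (`N >= 1`). Powers of two preserve the
#'   balance properties of the underlying sequence; other values are
#'   accepted with a warning.
#' @param seed Integer seed controlling the digital-shift scramble of the
#'   quasi-random stream. The configuration default used throughout the
#'   package is 2021.
#' @return A `saltelli_design` object with elements `A`, `B`, `AB` (list
#'   of `D` matrices), `bounds`, `N`, `D`, `seed`.
#' @examples
#' d <- saltelli_sample(default_bounds(), N = 256, seed = 2021)
#' nrow(design_matrix(d))  # 256 * 7 = 1792
#' @seealso [design_matrix()], [estimate_sobol()]
#' @export
saltelli_sample <- function(bounds, N, seed = 2021L) {
  bounds <- as_factor_bounds(bounds)
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != floor(N)) {
    stop("N must be a positive integer", call. = FALSE)
  }
  N <- as.integer(N)
  D <- nrow(bounds)
  if (bitwAnd(N, N - 1L) != 0L) {
    warning("N = ", N, " is not a power of two; ",
            "balance properties of the Sobol' sequence are degraded",
            call. = FALSE)
  }
  if (2L * D > 10L) {
    stop("saltelli_sample supports at most 5 factors", call. = FALSE)
  }
  u <- sobol_points(N, 2L * D, seed = seed)
  lo <- bounds$lo
  hi <- bounds$hi
  scale_cols <- function(m) {
    for (j in seq_len(D)) m[, j] <- lo[j] + (hi[j] - lo[j]) * m[, j]
    colnames(m) <- bounds$name
    m
  }
  A <- scale_cols(u[, seq_len(D), drop = FALSE])
  B <- scale_cols(u[, D + seq_len(D), drop = FALSE])
  AB <- lapply(seq_len(D), function(i) {
    m <- A
    m[, i] <- B[, i]
    m
  })
  structure(
    list(A = A, B = B, AB = AB, bounds = bounds, N = N, D = D,
         seed = as.integer(seed)),
    class = "saltelli_design"
  )
}

#' Serialize a Saltelli design to its evaluation-order matrix
#'
#' @param design A `saltelli_design`.
#' @return An `N * (D + 2) x D` matrix: rows of `A`, then `B`, then
#'   `AB_1`, ..., `AB_D`; columns named after the factors.
#' @export
design_matrix <- function(design) {
  stopifnot(inherits(design, "saltelli_design"))
  do.call(rbind, c(list(design$A, design$B), design$AB))
}

#' @export
print.saltelli_design <- function(x, ...) {
  cat("Saltelli design: N =", x$N, ", D =", x$D,
      "->", x$N * (x$D + 2L), "evaluation rows (seed", x$seed, ")\n")
  cat("factors:", paste(x$bounds$name, collapse = ", "), "\n")
  invisible(x)
}

#' Write a design and optional response vector to CSV
#'
#' Rows follow the documented evaluation order (`A`, `B`, `AB_1..AB_D`).
#'
#' @param design A `saltelli_design`.
#' @param path Output CSV path.
#' @param y Optional response vector aligned to the evaluation order,
#'   written as a final `y` column.
#' @export
write_design_csv <- function(design, path, y = NULL) {
  m <- design_matrix(design)
  df <- as.data.frame(m)
  if (!is.null(y)) {
    stopifnot(length(y) == nrow(m))
    df$y <- y
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
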