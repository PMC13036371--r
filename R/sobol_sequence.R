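# Gray-code generator for the Sobol' low-discrepancy sequence, with an
# optional per-dimension digital-shift (XOR) scramble keyed by a seed.
# Direction numbers are the Joe & Kuo D(6) set for dimensions 2..10
# (dimension 1 is the van der Corput sequence in base 2); ten dimensions
# cover the paired-matrix sampling needed for Saltelli designs at D = 5.

.sobol_dirs <- list(
  # each entry: list(s = polynomial degree, a = coefficient bits, m = initial m_k)
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))
)

.sobol_nbits <- 30L

# direction integers V[k] = v_k * 2^(nbits - k), k = 1..nbits, for one dimension
.sobol_direction_integers <- function(dim) {
  L <- .sobol_nbits
  V <- integer(L)
  if (dim == 1L) {
    V <- bitwShiftL(1L, L - seq_len(L))
    return(V)
  }
  d <- .sobol_dirs[[dim - 1L]]
  s <- d$s
  m <- d$m
  a <- d$a
  for (k in seq_len(min(s, L))) V[k] <- bitwShiftL(m[k], L - k)
  if (L > s) {
    for (k in (s + 1L):L) {
      V[k] <- bitwXor(V[k - s], bitwShiftR(V[k - s], s))
      if (s > 1L) {
        for (i in seq_len(s - 1L)) {
          if (bitwAnd(bitwShiftR(a, s - 1L - i), 1L) == 1L) {
            V[k] <- bitwXor(V[k], V[k - i])
          }
        }
      }
    }
  }
  V
}

# index (1-based) of the lowest zero bit of integer i (i >= 0)
.lowest_zero_bit <- function(i) {
  c <- 1L
  while (bitwAnd(i, 1L) == 1L) {
    i <- bitwShiftR(i, 1L)
    c <- c + 1L
  }
  c
}

#' Sobol' low-discrepancy points on the unit hypercube
#'
#' Generates the first `n` points of a `d`-dimensional Sobol' sequence
#' (gray-code order, 30-bit precision). When `seed` is non-`NULL` each
#' dimension is scrambled by a seeded random digital shift (bitwise XOR
#' with a fixed random integer), which decorrelates runs with different
#' seeds while preserving the digital-net structure of the point set.
#' Identical `(n, d, seed)` always yield bitwise-identical points.
#'
#' @param n Number of points (`n >= 1`).
#' @param d Dimension (`1 <= d <= 10`).
#' @param seed Integer seed for the digital-shift scramble, or `NULL` for
#'   the unscrambled sequence (whose first point is the origin).
#' @return An `n x d` matrix with entries in `[0, 1)`.
#' @export
sobol_points <- function(n, d, seed = NULL) {
  stopifnot(n >= 1, d >= 1)
  if (d > 10L) {
    stop("sobol_points supports at most 10 dimensions", call. = FALSE)
  }
  n <- as.integer(n)
  d <- as.integer(d)
  V <- vapply(seq_len(d), .sobol_direction_integers, integer(.sobol_nbits))
  X <- matrix(0L, nrow = n, ncol = d)     # integer states
  state <- integer(d)
  X[1L, ] <- state
  if (n > 1L) {
    for (i in 2L:n) {
      cbit <- .lowest_zero_bit(i - 2L)    # gray-code flip bit for point i-1 -> i
      state <- bitwXor(state, V[cbit, ])
      X[i, ] <- state
    }
  }
  if (!is.null(seed)) {
    shifts <- .seeded_digital_shifts(seed, d)
    for (j in seq_len(d)) X[, j] <- bitwXor(X[, j], shifts[j])
  }
  X / 2^.sobol_nbits
}

# d random 30-bit integers drawn reproducibly from `seed` without touching
# the caller's RNG state
.seeded_digital_shifts <- function(seed, d) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  hi <- sample.int(32768L, d, replace = TRUE) - 1L   # 15 high bits
  lo <- sample.int(32768L, d, replace = TRUE) - 1L   # 15 low bits
  bitwOr(bitwShiftL(hi, 15L), lo)
}
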