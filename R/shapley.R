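#' Fit a tree-ensemble surrogate of the perturbation-response relation
#'
#' Trains a random-forest regressor mapping the five photometric factors
#' to the predicted probability, on the perturbation-response table
#' harvested during a GSA run (`run_image_gsa(..., return_responses =
#' TRUE)`). A seeded 80/20 split provides an out-of-sample R-squared as
#' fit quality. A (numerically) constant response cannot support
#' attribution: a warning is raised and a skipped surrogate returned.
#'
#' @param table Data frame with one column per factor plus `y`.
#' @param seed Integer seed (split and forest are deterministic in it).
#' @param num_trees Number of trees.
#' @return A `surrogate_model`: `model` (ranger object or `NULL`),
#'   `factors`, `r2_holdout`, `skipped`.
#' @export
fit_surrogate <- function(table, seed = 1L, num_trees = 300L) {
  stopifnot(is.data.frame(table), "y" %in% names(table))
  factors <- setdiff(names(table), "y")
  if (nrow(table) < 50L) {
    stop("surrogate fitting needs at least 50 rows", call. = FALSE)
  }
  if (stats::var(table$y) < 1e-12) {
    warning("degenerate (constant) response; attribution skipped",
            call. = FALSE)
    return(structure(list(model = NULL, factors = factors,
                          r2_holdout = NA_real_, skipped = TRUE),
                     class = "surrogate_model"))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- nrow(table)
  test_idx <- sample(n, max(1L, round(0.2 * n)))
  train <- table[-test_idx, , drop = FALSE]
  test <- table[test_idx, , drop = FALSE]
  fit <- ranger::ranger(
    x = train[, factors, drop = FALSE], y = train$y,
    num.trees = num_trees, seed = as.integer(seed), num.threads = 1L
  )
  pred <- stats::predict(fit, data = test[, factors, drop = FALSE],
                         num.threads = 1L)$predictions
  ss_res <- sum((test$y - pred)^2)
  ss_tot <- sum((test$y - mean(train$y))^2)
  structure(
    list(model = fit, factors = factors,
         r2_holdout = 1 - ss_res / ss_tot, skipped = FALSE),
    class = "surrogate_model"
  )
}

surrogate_predict <- function(surrogate, X) {
  X <- as.data.frame(X)[, surrogate$factors, drop = FALSE]
  if (!is.null(surrogate$predict_fn)) return(surrogate$predict_fn(X))
  stats::predict(surrogate$model, data = X, num.threads = 1L)$predictions
}

# analytic stand-in for a fitted surrogate (axiom tests)
analytic_surrogate <- function(fn, factors) {
  structure(list(model = NULL, predict_fn = fn, factors = factors,
                 r2_holdout = 1, skipped = FALSE),
            class = "surrogate_model")
}

#' Exact interventional Shapley values on a surrogate
#'
#' Computes per-factor Shapley values for a single factor sample by
#' exact enumeration of all `2^D` coalitions. The value of a coalition
#' `C` is the surrogate prediction averaged over background rows with
#' the coordinates in `C` fixed to `x`; marginal contributions are
#' combined with the exact Shapley weights `|C|! (D - |C| - 1)! / D!`.
#' Satisfies efficiency (values sum to `f(x)` minus the background mean
#' prediction), symmetry and the dummy axiom up to the surrogate's own
#' numerics.
#'
#' @param surrogate A fitted `surrogate_model`.
#' @param x Named numeric vector (one value per factor).
#' @param background Data frame of background factor rows (the
#'   perturbation-response table's own rows are the natural choice).
#' @return Named numeric vector of Shapley values.
#' @export
exact_shapley <- function(surrogate, x, background) {
  stopifnot(inherits(surrogate, "surrogate_model"), !surrogate$skipped)
  factors <- surrogate$factors
  D <- length(factors)
  if (D > 12L) {
    stop("exact enumeration is limited to 12 factors (2^D coalitions); ",
         "use a sampling approximation for larger D", call. = FALSE)
  }
  phi <- exact_shapley_batch(surrogate,
                             as.data.frame(as.list(x[factors])), background)
  stats::setNames(phi[1L, ], factors)
}

#' Exact Shapley values for many factor samples at once
#'
#' Same computation as [exact_shapley()] for a whole matrix of samples,
#' batched into a single surrogate prediction call (coalitions x
#' background x samples), which is what makes per-image attribution of
#' hundreds of rows affordable.
#'
#' @inheritParams exact_shapley
#' @param X Data frame or matrix of factor samples (one row each).
#' @return Matrix `nrow(X) x D` of Shapley values.
#' @export
exact_shapley_batch <- function(surrogate, X, background) {
  stopifnot(inherits(surrogate, "surrogate_model"), !surrogate$skipped)
  factors <- surrogate$factors
  D <- length(factors)
  if (D > 12L) {
    stop("exact enumeration is limited to 12 factors (2^D coalitions); ",
         "use a sampling approximation for larger D", call. = FALSE)
  }
  X <- as.matrix(as.data.frame(X)[, factors, drop = FALSE])
  bg <- as.matrix(as.data.frame(background)[, factors, drop = FALSE])
  nbg <- nrow(bg)
  nx <- nrow(X)
  n_coal <- 2L^D
  # block layout: for sample k, coalition mask m, background row b:
  # row index ((k-1) * n_coal + m) * nbg + b
  big <- bg[rep(seq_len(nbg), n_coal * nx), , drop = FALSE]
  for (k in seq_len(nx)) {
    for (mask in 0:(n_coal - 1L)) {
      rows <- ((k - 1L) * n_coal + mask) * nbg + seq_len(nbg)
      for (i in seq_len(D)) {
        if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) {
          big[rows, i] <- X[k, i]
        }
      }
    }
  }
  pred <- surrogate_predict(surrogate, big)
  # coalition means: one row per (sample, mask)
  v <- rowMeans(matrix(pred, nrow = nx * n_coal, ncol = nbg, byrow = TRUE))
  out <- matrix(0, nrow = nx, ncol = D, dimnames = list(NULL, factors))
  for (k in seq_len(nx)) {
    out[k, ] <- .shapley_from_coalitions(v[(k - 1L) * n_coal + seq_len(n_coal)],
                                         D, factors)
  }
  out
}

.shapley_from_coalitions <- function(v, D, factors) {
  sizes <- vapply(0:(2L^D - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(D - 1L))) != 0L), 0)
  # weight |C|! (D-|C|-1)! / D!; the full coalition never appears as a
  # "without i" set, so its weight is irrelevant (and undefined)
  w <- ifelse(sizes < D,
              factorial(sizes) * factorial(pmax(D - sizes - 1L, 0L)) /
                factorial(D),
              0)
  phi <- numeric(D)
  for (i in seq_len(D)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(2L^D - 1L), bit) == 0L) - 1L
    phi[i] <- sum(w[without + 1L] * (v[bitwOr(without, bit) + 1L] - v[without + 1L]))
  }
  stats::setNames(phi, factors)
}

#' Permutation-sampling Shapley estimate (cross-check)
#'
#' Monte-Carlo estimate of the same interventional Shapley values by
#' averaging marginal contributions over random factor permutations;
#' used in tests to cross-check the exact enumeration.
#'
#' @inheritParams exact_shapley
#' @param n_perm Number of sampled permutations.
#' @param seed Seed for the permutation draws.
#' @return Named numeric vector of Shapley value estimates.
#' @export
sampling_shapley <- function(surrogate, x, background, n_perm = 200L,
                             seed = 1L) {
  stopifnot(inherits(surrogate, "surrogate_model"), !surrogate$skipped)
  factors <- surrogate$factors
  D <- length(factors)
  x <- x[factors]
  bg <- as.data.frame(background)[, factors, drop = FALSE]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  phi <- stats::setNames(numeric(D), factors)
  nbg <- nrow(bg)
  for (p in seq_len(n_perm)) {
    perm <- sample(D)
    cur <- bg
    v_prev <- mean(surrogate_predict(surrogate, cur))
    for (i in perm) {
      cur[, i] <- x[[factors[i]]]
      v_new <- mean(surrogate_predict(surrogate, cur))
      phi[factors[i]] <- phi[factors[i]] + (v_new - v_prev)
      v_prev <- v_new
    }
  }
  phi / n_perm
}

#' Surrogate Shapley attribution for a set of GSA runs
#'
#' For each image's perturbation-response table, fits a surrogate,
#' explains a seeded subset of its rows by exact Shapley enumeration
#' against a seeded background drawn from the table itself, and records
#' the per-factor mean absolute Shapley value. Images whose surrogate is
#' skipped (degenerate response) are excluded and counted.
#'
#' @param results List of `per_image_sensitivity` carrying `responses`
#'   (run with `return_responses = TRUE`).
#' @param seed Integer seed.
#' @param n_background Background rows per image (cap, drawn without
#'   replacement).
#' @param n_explain Explained rows per image (cap).
#' @param strata Optional grouping vector aligned to `results` (or named
#'   by image id) for per-stratum tables.
#' @return A `shapley_attribution`: `overall` (data frame: factor,
#'   mean_abs_shap, sd_abs_shap), `by_stratum`, `per_image` (matrix of
#'   per-image mean |phi|), `r2_holdout` (per image), `n_skipped`.
#' @export
shapley_attribution <- function(results, seed = 1L, n_background = 200L,
                                n_explain = 50L, strata = NULL) {
  stopifnot(length(results) >= 1L)
  if (inherits(results, "per_image_sensitivity")) results <- list(results)
  ids <- vapply(results, function(r) r$image_id, "")
  if (!is.null(strata) && !is.null(names(strata)) &&
      all(ids %in% names(strata))) {
    strata <- strata[ids]
  }
  per_image <- list()
  r2 <- numeric(0)
  skipped <- 0L
  keep_idx <- integer(0)
  for (k in seq_along(results)) {
    tab <- results[[k]]$responses
    if (is.null(tab)) {
      stop("results must carry responses (run_image_gsa with ",
           "return_responses = TRUE)", call. = FALSE)
    }
    sur <- withCallingHandlers(
      fit_surrogate(tab, seed = seed),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (sur$skipped) {
      skipped <- skipped + 1L
      next
    }
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed) + k)
    bg <- tab[sample(nrow(tab), min(n_background, nrow(tab))), , drop = FALSE]
    expl <- tab[sample(nrow(tab), min(n_explain, nrow(tab))), , drop = FALSE]
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    phis <- exact_shapley_batch(sur, expl[, sur$factors, drop = FALSE], bg)
    per_image[[length(per_image) + 1L]] <- colMeans(abs(phis))
    r2 <- c(r2, sur$r2_holdout)
    keep_idx <- c(keep_idx, k)
  }
  if (length(per_image) == 0L) {
    stop("all surrogates were skipped; no attribution available",
         call. = FALSE)
  }
  m <- do.call(rbind, per_image)
  rownames(m) <- ids[keep_idx]
  tab_of <- function(mm) {
    data.frame(factor = colnames(mm),
               mean_abs_shap = colMeans(mm),
               sd_abs_shap = if (nrow(mm) > 1L) apply(mm, 2, stats::sd)
                             else rep(0, ncol(mm)),
               n_images = nrow(mm), row.names = NULL)
  }
  by_stratum <- NULL
  if (!is.null(strata)) {
    s <- as.character(strata)[keep_idx]
    parts <- lapply(unique(s), function(g) {
      t <- tab_of(m[s == g, , drop = FALSE])
      t$stratum <- g
      t
    })
    by_stratum <- do.call(rbind, parts)
  }
  structure(
    list(overall = tab_of(m), by_stratum = by_stratum, per_image = m,
         r2_holdout = stats::setNames(r2, ids[keep_idx]),
         n_skipped = skipped),
    class = "shapley_attribution"
  )
}

#' @export
print.shapley_attribution <- function(x, digits = 4, ...) {
  cat("surrogate Shapley attribution (", nrow(x$per_image), " images, ",
      x$n_skipped, " skipped; median holdout R2 = ",
      round(stats::median(x$r2_holdout), 3), ")\n", sep = "")
  df <- x$overall
  df[-1] <- lapply(df[-1], round, digits)
  print(df)
  invisible(x)
}

#' Concordance between Sobol and Shapley factor rankings
#'
#' @param sobol An `aggregate_report` (ranking by mean total-order
#'   index) or `per_image_sensitivity`.
#' @param shap A `shapley_attribution` (ranking by mean absolute Shapley
#'   value).
#' @return List: `tau` (Kendall), `table` (factor, ST rank, Shapley
#'   rank), `top1_agree`.
#' @export
rank_concordance <- function(sobol, shap) {
  if (inherits(sobol, "per_image_sensitivity")) {
    st <- sobol$ST
  } else {
    st <- stats::setNames(sobol$overall$mean_ST, sobol$overall$factor)
  }
  sh <- stats::setNames(shap$overall$mean_abs_shap, shap$overall$factor)
  common <- intersect(names(st), names(sh))
  if (length(common) != length(st) || length(common) != length(sh)) {
    stop("factor sets differ between the two rankings", call. = FALSE)
  }
  st <- st[common]
  sh <- sh[common]
  tau <- stats::cor(st, sh, method = "kendall")
  tab <- data.frame(
    factor = common,
    st_rank = rank(-st, ties.method = "first"),
    shap_rank = rank(-sh, ties.method = "first"),
    mean_ST = as.numeric(st),
    mean_abs_shap = as.numeric(sh),
    row.names = NULL
  )
  list(tau = tau, table = tab[order(tab$st_rank), ],
       top1_agree = names(which.max(st)) == names(which.max(sh)))
}
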