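#' Per-image global sensitivity analysis
#'
#' Runs the full perturb-predict-estimate chain for one image: every row
#' of the Saltelli design (in the documented order `A`, `B`,
#' `AB_1..AB_D`) is turned into a perturbed variant of the image, the
#' predictor is evaluated on each variant (in batches), and first-order
#' and total-order Sobol indices are estimated from the responses. The
#' baseline probability is the prediction on the nominal perturbation
#' (byte-identical to the resized image). Per-image decision-stability
#' summaries (flip rate and Gini dispersion of the thresholded perturbed
#' predictions) are recorded alongside.
#'
#' @param img An `rgb_image` or `image_record`.
#' @param predictor A `predictor` (see [as_predictor()]).
#' @param bounds Factor bounds configuration; defaults to
#'   [default_bounds()].
#' @param N Base sample count (default 256, i.e. `256 * 7 = 1792`
#'   predictor evaluations for five factors).
#' @param seed Seed for the sampling design (default 2021). Ignored when
#'   `design` is supplied.
#' @param design Optional pre-built `saltelli_design` to reuse across
#'   images, making per-image differences attributable to the images
#'   rather than to sampling noise.
#' @param side Working image resolution.
#' @param threshold Decision threshold for the per-image flip rate and
#'   Gini dispersion.
#' @param batch_size Number of perturbed variants per predictor call.
#' @param return_responses Keep the perturbation-response table (factor
#'   values plus predicted probability per design row), needed for
#'   surrogate Shapley attribution.
#' @return A `per_image_sensitivity`: image id, `S1`, `ST` (and clipped
#'   views), `degenerate` flag, `baseline_p`, `flip_rate`, `gini`,
#'   `n_eval`, and optionally `responses`.
#' @export
run_image_gsa <- function(img, predictor, bounds = default_bounds(),
                          N = 256L, seed = 2021L, design = NULL,
                          side = 128L, threshold = 0.5, batch_size = 64L,
                          return_responses = FALSE) {
  res <- run_image_gsa_multi(img, list(predictor), bounds = bounds, N = N,
                             seed = seed, design = design, side = side,
                             threshold = threshold, batch_size = batch_size,
                             return_responses = return_responses)
  res[[1L]]
}

#' Per-image GSA for several predictors sharing one set of perturbations
#'
#' Generating the perturbed image variants dominates the cost of a GSA
#' run, so when several predictors must be audited on the same design
#' (e.g. the probe-predictor battery) the variants are computed once and
#' every predictor is evaluated on each batch.
#'
#' @inheritParams run_image_gsa
#' @param predictors List of `predictor` objects (optionally named).
#' @return A list of `per_image_sensitivity`, one per predictor.
#' @export
run_image_gsa_multi <- function(img, predictors, bounds = default_bounds(),
                                N = 256L, seed = 2021L, design = NULL,
                                side = 128L, threshold = 0.5,
                                batch_size = 64L, return_responses = FALSE) {
  image <- as_rgb_image(img)
  bounds <- as_factor_bounds(bounds)
  if (is.null(design)) {
    design <- saltelli_sample(bounds, N = N, seed = seed)
  } else {
    stopifnot(inherits(design, "saltelli_design"))
  }
  stopifnot(length(predictors) >= 1L)
  m <- design_matrix(design)
  n_rows <- nrow(m)
  resized <- resize_image(image, side = side)
  baseline <- vapply(predictors, function(p) predict_batch(p, list(resized)), 0)

  y <- matrix(NA_real_, nrow = n_rows, ncol = length(predictors))
  start <- 1L
  while (start <= n_rows) {
    end <- min(start + batch_size - 1L, n_rows)
    variants <- lapply(start:end, function(r) {
      apply_perturbation(resized, m[r, ], side = side)
    })
    for (k in seq_along(predictors)) {
      y[start:end, k] <- predict_batch(predictors[[k]], variants)
    }
    start <- end + 1L
  }

  out <- lapply(seq_along(predictors), function(k) {
    sob <- withCallingHandlers(
      estimate_sobol(design, y[, k]),
      warning = function(w) invokeRestart("muffleWarning")
    )
    labs <- y[, k] >= threshold
    structure(
      list(image_id = image_id(image),
           predictor = attr(predictors[[k]], "name") %||% "predictor",
           S1 = sob$S1, ST = sob$ST,
           S1_clipped = sob$S1_clipped, ST_clipped = sob$ST_clipped,
           Vy = sob$Vy, degenerate = sob$degenerate,
           baseline_p = baseline[k],
           flip_rate = mean(labs != (baseline[k] >= threshold)),
           gini = {
             phat <- mean(labs)
             2 * phat * (1 - phat)
           },
           threshold = threshold,
           n_eval = n_rows,
           responses = if (return_responses) {
             data.frame(m, y = y[, k], check.names = FALSE)
           } else NULL),
      class = "per_image_sensitivity")
  })
  names(out) <- names(predictors)
  out
}

#' @export
print.per_image_sensitivity <- function(x, digits = 3, ...) {
  cat("per-image sensitivity for '", x$image_id, "' (", x$n_eval,
      " evaluations", if (x$degenerate) ", DEGENERATE" else "", ")\n",
      sep = "")
  print(round(rbind(S1 = x$S1, ST = x$ST), digits))
  cat("baseline p =", round(x$baseline_p, digits),
      "; flip rate =", round(x$flip_rate, digits),
      "; Gini =", round(x$gini, digits), "\n")
  invisible(x)
}

#' Aggregate per-image sensitivity indices across a dataset
#'
#' Unweighted arithmetic mean and sample standard deviation (n - 1
#' denominator) of the per-image indices, with normal-approximation 95%
#' confidence half-widths (`1.96 * SD / sqrt(M)`) and the interaction
#' column `mean ST - mean S1`. Degenerate images (flat predictor
#' response) are excluded from the means and counted.
#'
#' @param results List of `per_image_sensitivity`.
#' @param strata Optional grouping: a vector (character/factor) aligned
#'   to `results`, or a named vector keyed by image id. Produces
#'   per-stratum tables alongside the overall one; empty strata are
#'   omitted with a warning.
#' @return An `aggregate_report` with elements `overall` (data frame:
#'   factor, mean_S1, sd_S1, ci_S1, mean_ST, sd_ST, ci_ST, interaction),
#'   `by_stratum` (long data frame or `NULL`), and the exclusion
#'   accounting `n_input`, `n_used`, `n_degenerate`.
#' @export
aggregate_sensitivity <- function(results, strata = NULL) {
  if (length(results) == 0L) {
    stop("cannot aggregate an empty result list", call. = FALSE)
  }
  if (inherits(results, "per_image_sensitivity")) results <- list(results)
  degen <- vapply(results, function(r) isTRUE(r$degenerate), TRUE)
  used <- results[!degen]
  if (length(used) == 0L) {
    stop("all results are degenerate; nothing to aggregate", call. = FALSE)
  }
  if (!is.null(strata)) {
    if (!is.null(names(strata))) {
      ids <- vapply(results, function(r) r$image_id, "")
      if (all(ids %in% names(strata))) strata <- strata[ids]
    }
    stopifnot(length(strata) == length(results))
    strata_used <- as.character(strata)[!degen]
  }

  tab <- function(rs) {
    S1 <- do.call(rbind, lapply(rs, function(r) r$S1))
    ST <- do.call(rbind, lapply(rs, function(r) r$ST))
    M <- nrow(S1)
    sdv <- function(x) if (M > 1L) stats::sd(x) else 0
    data.frame(
      factor = colnames(S1),
      mean_S1 = colMeans(S1),
      sd_S1 = apply(S1, 2, sdv),
      ci_S1 = 1.96 * apply(S1, 2, sdv) / sqrt(M),
      mean_ST = colMeans(ST),
      sd_ST = apply(ST, 2, sdv),
      ci_ST = 1.96 * apply(ST, 2, sdv) / sqrt(M),
      interaction = colMeans(ST) - colMeans(S1),
      n_images = M,
      row.names = NULL
    )
  }

  by_stratum <- NULL
  if (!is.null(strata)) {
    levs <- if (is.factor(strata)) levels(strata) else unique(strata_used)
    parts <- list()
    for (g in levs) {
      rs <- used[strata_used == g]
      if (length(rs) == 0L) {
        warning("stratum '", g, "' has no usable images; omitted",
                call. = FALSE)
        next
      }
      t <- tab(rs)
      t$stratum <- g
      parts[[g]] <- t
    }
    by_stratum <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  }

  structure(
    list(overall = tab(used), by_stratum = by_stratum,
         n_input = length(results), n_used = length(used),
         n_degenerate = sum(degen)),
    class = "aggregate_report"
  )
}

#' @export
print.aggregate_report <- function(x, digits = 3, ...) {
  cat("aggregate sensitivity report:", x$n_used, "of", x$n_input,
      "images used (", x$n_degenerate, "degenerate )\n")
  df <- x$overall
  df[-1] <- lapply(df[-1], round, digits)
  print(df)
  invisible(x)
}

#' Ranking of factors by aggregated total-order index
#'
#' @param report An `aggregate_report` (or `per_image_sensitivity`).
#' @return Character vector of factor names, most influential first.
#' @export
st_ranking <- function(report) {
  if (inherits(report, "per_image_sensitivity")) {
    return(names(sort(report$ST, decreasing = TRUE)))
  }
  df <- report$overall
  df$factor[order(df$mean_ST, decreasing = TRUE)]
}

#' Stability of the aggregated factor ranking under subsampling
#'
#' Draws repeated stratified subsamples of the per-image results at each
#' fraction, recomputes the aggregated total-order ranking, and reports
#' the fraction of replicates whose ranking equals the full-data ranking
#' together with the mean Kendall tau to the full-data ranking.
#'
#' @param results List of `per_image_sensitivity`.
#' @param fractions Subsample fractions in `(0, 1]`; default `0.1` to
#'   `0.8` in steps of `0.1`.
#' @param n_rep Replicates per fraction (default 20).
#' @param seed Seed for the subsample draws.
#' @param stratify_on Optional label vector aligned to `results` (or
#'   named by image id); sampling is stratified on it. Replicates in
#'   which a stratum empties are dropped from the denominator with a
#'   warning.
#' @return Data frame: `fraction`, `rank_agreement`, `mean_tau`,
#'   `n_rep_used`.
#' @export
subsample_stability <- function(results, fractions = seq(0.1, 0.8, by = 0.1),
                                n_rep = 20L, seed = 1L, stratify_on = NULL) {
  if (n_rep < 1L) stop("n_rep must be >= 1", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  full <- aggregate_sensitivity(results)
  full_st <- full$overall$mean_ST
  names(full_st) <- full$overall$factor
  full_rank <- st_ranking(full)

  n <- length(results)
  if (!is.null(stratify_on)) {
    if (!is.null(names(stratify_on))) {
      ids <- vapply(results, function(r) r$image_id, "")
      if (all(ids %in% names(stratify_on))) stratify_on <- stratify_on[ids]
    }
    stopifnot(length(stratify_on) == n)
    groups <- split(seq_len(n), as.character(stratify_on))
  } else {
    groups <- list(all = seq_len(n))
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  rows <- lapply(fractions, function(f) {
    agree <- taus <- numeric(0)
    for (rep in seq_len(n_rep)) {
      idx <- unlist(lapply(groups, function(g) {
        k <- round(f * length(g))
        if (k < 1L) integer(0) else sample(g, k)
      }))
      counts <- vapply(groups, function(g) round(f * length(g)), 0)
      if (any(counts < 1L)) {
        warning("fraction ", f, ": a stratum emptied; replicate dropped",
                call. = FALSE)
        next
      }
      sub <- aggregate_sensitivity(results[idx])
      sub_st <- sub$overall$mean_ST[match(names(full_st),
                                          sub$overall$factor)]
      agree <- c(agree, identical(st_ranking(sub), full_rank))
      taus <- c(taus, stats::cor(full_st, sub_st, method = "kendall"))
    }
    data.frame(fraction = f,
               rank_agreement = if (length(agree)) mean(agree) else NA_real_,
               mean_tau = if (length(taus)) mean(taus) else NA_real_,
               n_rep_used = length(agree))
  })
  do.call(rbind, rows)
}
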