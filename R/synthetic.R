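#' Specification for a synthetic dermoscopy-like dataset
#'
#' Controls the fixture generator used to exercise the toolkit without
#' any real images: number of images, resolution, melanoma fraction and
#' lesion-appearance parameters. Defaults produce skin-tone backgrounds
#' with one elliptical pigmented blob per image; melanoma-labelled blobs
#' are darker and more variegated.
#'
#' @param n_images Number of images (`>= 1`).
#' @param image_side Side length in pixels.
#' @param melanoma_fraction Proportion of melanoma-labelled records in
#'   `[0, 1]`; the realized count is `round(n_images * melanoma_fraction)`.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param hue_center,hue_spread Center/spread of the background skin hue
#'   (normalized hue units).
#' @param brightness_base Mean background value level (0-255 scale).
#' @param ecc_range Range of blob axis ratios (minor / major).
#' @param texture_amp Amplitude (0-255 scale) of the fine-grained skin
#'   micro-texture; without it images are unrealistically smooth and the
#'   sharpness factor has nothing to act on.
#' @param hair_prob Probability that an image carries dark hair strokes.
#' @return A `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_images = 8L, image_side = 128L,
                                   melanoma_fraction = 0.25, seed = 2021L,
                                   hue_center = 0.07, hue_spread = 0.015,
                                   brightness_base = 165,
                                   ecc_range = c(0.6, 0.95),
                                   texture_amp = 8,
                                   hair_prob = 0.3) {
  stopifnot(n_images >= 1, image_side >= 16,
            melanoma_fraction >= 0, melanoma_fraction <= 1,
            length(ecc_range) == 2L, hair_prob >= 0, hair_prob <= 1)
  structure(
    list(n_images = as.integer(n_images), image_side = as.integer(image_side),
         melanoma_fraction = melanoma_fraction, seed = as.integer(seed),
         hue_center = hue_center, hue_spread = hue_spread,
         brightness_base = brightness_base, ecc_range = ecc_range,
         texture_amp = texture_amp, hair_prob = hair_prob),
    class = "synthetic_dataset_spec"
  )
}

# categorical vocabularies of the public dermoscopy metadata schema
.dx_benign <- c("nv", "bkl", "bcc", "akiec", "vasc", "df")
.dx_type_vocab <- c("histo", "follow_up", "consensus", "confocal")
.sex_vocab <- c("male", "female", "unknown")
.localization_vocab <- c("back", "lower extremity", "trunk",
                         "upper extremity", "abdomen", "face", "chest",
                         "foot", "neck", "scalp", "hand", "ear", "unknown")

#' Generate a synthetic dermoscopy-like dataset
#'
#' Each image is a smooth skin-tone background (slight global gradient
#' plus low-frequency mottling) carrying one elliptical pigmented blob
#' with a soft radial edge; melanoma-labelled blobs use darker base
#' colors with angular color variegation. A seeded fraction of images
#' receives thin dark hair strokes. Metadata columns are sampled from
#' the standard dermoscopy vocabulary; `label` is 1 exactly when
#' `dx == "mel"`. Identical specs yield byte-identical datasets.
#'
#' @param spec A [synthetic_dataset_spec()].
#' @return A `synthetic_dataset`: list with `records` (list of
#'   `image_record`) and `metadata` (data frame in the 7-column schema
#'   plus `label`).
#' @export
generate_synthetic_dataset <- function(spec = synthetic_dataset_spec()) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_images
  n_mel <- round(n * spec$melanoma_fraction)
  labels <- sample(c(rep(1L, n_mel), rep(0L, n - n_mel)))
  records <- vector("list", n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    melanoma <- labels[i] == 1L
    img <- .synth_image(spec, melanoma, id = sprintf("SYN_%07d", i))
    dx <- if (melanoma) "mel" else sample(.dx_benign, 1L, prob =
      c(0.55, 0.2, 0.1, 0.06, 0.05, 0.04))
    rec <- structure(
      list(image = img,
           lesion_id = sprintf("HAM_%07d", i),
           image_id = sprintf("SYN_%07d", i),
           dx = dx,
           dx_type = sample(.dx_type_vocab, 1L, prob = c(0.55, 0.25, 0.15, 0.05)),
           age = sample(seq(5, 85, by = 5), 1L),
           sex = sample(.sex_vocab, 1L, prob = c(0.5, 0.45, 0.05)),
           localization = sample(.localization_vocab, 1L),
           label = labels[i]),
      class = "image_record")
    records[[i]] <- rec
    meta[[i]] <- as.data.frame(rec[c("lesion_id", "image_id", "dx", "dx_type",
                                     "age", "sex", "localization", "label")])
  }
  structure(list(records = records, metadata = do.call(rbind, meta),
                 spec = spec),
            class = "synthetic_dataset")
}

# one synthetic lesion image; relies on the caller's seeded RNG state
.synth_image <- function(spec, melanoma, id) {
  side <- spec$image_side
  xs <- matrix(rep(seq_len(side), each = side), nrow = side)   # column index
  ys <- matrix(rep(seq_len(side), times = side), nrow = side)  # row index

  # skin background: warm tone from a sampled hue, global linear gradient,
  # low-frequency sinusoidal mottling
  hue <- stats::rnorm(1, spec$hue_center, spec$hue_spread)
  v0 <- spec$brightness_base + stats::rnorm(1, 0, 6)
  sat0 <- stats::runif(1, 0.25, 0.38)
  base <- .hsv_to_rgb_real(hue, sat0, v0 / 255) * 255
  ang <- stats::runif(1, 0, 2 * pi)
  grad_amp <- stats::runif(1, 4, 12)
  grad <- grad_amp * ((cos(ang) * xs + sin(ang) * ys) / side - 0.5)
  mott <- 3 * sin(2 * pi * xs / side * stats::runif(1, 1, 3) +
                    stats::runif(1, 0, 2 * pi)) *
    sin(2 * pi * ys / side * stats::runif(1, 1, 3) + stats::runif(1, 0, 2 * pi))
  # fine-grained micro-texture (pigment network / skin grain)
  texture <- matrix(stats::rnorm(side * side, 0, spec$texture_amp), side) +
    0.6 * spec$texture_amp *
      sin(2 * pi * xs / stats::runif(1, 3, 5)) *
      sin(2 * pi * ys / stats::runif(1, 3, 5))

  # elliptical pigmented blob with soft radial edge
  cx <- side * stats::runif(1, 0.42, 0.58)
  cy <- side * stats::runif(1, 0.42, 0.58)
  a <- side * stats::runif(1, 0.16, 0.3)
  b <- a * stats::runif(1, spec$ecc_range[1], spec$ecc_range[2])
  th <- stats::runif(1, 0, pi)
  xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  d <- sqrt((xr / a)^2 + (yr / b)^2)
  edge <- 1 / (1 + exp((d - 1) / 0.07))   # 1 inside, 0 outside

  if (melanoma) {
    core <- c(82, 52, 46) + stats::rnorm(3, 0, 8)
    varieg_amp <- stats::runif(1, 18, 35)
  } else {
    core <- c(145, 95, 72) + stats::rnorm(3, 0, 8)
    varieg_amp <- stats::runif(1, 2, 8)
  }
  phi <- atan2(yr, xr)
  varieg <- varieg_amp * sin(2 * phi + stats::runif(1, 0, 2 * pi)) *
    pmin(d, 1)
  radial <- 1 - 0.35 * pmin(d, 1)^2      # darker core, lighter rim

  px <- array(0, dim = c(side, side, 3L))
  for (ch in 1:3) {
    blob_col <- core[ch] * radial + varieg
    bg <- base[ch] + grad + mott
    px[, , ch] <- edge * blob_col + (1 - edge) * bg + texture
  }

  # optional dark hair strokes (thin quadratic arcs)
  if (stats::runif(1) < spec$hair_prob) {
    for (k in seq_len(sample(1:3, 1L))) {
      t <- seq(0, 1, length.out = 4L * side)
      p0 <- stats::runif(2, 0, side)
      p1 <- stats::runif(2, 0, side)
      pc <- stats::runif(2, 0, side)
      hx <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * pc[1] + t^2 * p1[1]
      hy <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * pc[2] + t^2 * p1[2]
      ii <- pmin(pmax(round(hy), 1), side)
      jj <- pmin(pmax(round(hx), 1), side)
      for (ch in 1:3) {
        idx <- cbind(ii, jj, ch)
        px[idx] <- c(45, 35, 30)[ch]
      }
    }
  }
  rgb_image(pmin(pmax(px, 0), 255), id = id)
}

# real-valued HSV -> RGB on [0,1] (background color synthesis only)
.hsv_to_rgb_real <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  switch(as.character(i),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), c(v, p, q))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic dermoscopy-like dataset:", length(x$records), "images,",
      sum(x$metadata$label), "melanoma-labelled\n")
  invisible(x)
}

.metadata_columns <- c("lesion_id", "image_id", "dx", "dx_type", "age",
                       "sex", "localization")

#' Read / write a dermoscopy metadata table
#'
#' The on-disk format is the 7-column CSV schema `lesion_id, image_id,
#' dx, dx_type, age, sex, localization`. Reading derives the binary
#' `label` column (`1` iff `dx == "mel"`); unknown `dx` codes are
#' preserved verbatim and labelled 0. An optional row filter (for
#' instance restricting to histopathologically verified lesions) can be
#' applied at read time.
#'
#' @param path CSV path.
#' @param filter Optional predicate `function(data.frame) -> logical
#'   vector` applied after reading; rows where it returns `FALSE` are
#'   dropped.
#' @return A data frame with the 7 schema columns plus `label`.
#' @export
read_metadata <- function(path, filter = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.metadata_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("metadata schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, .metadata_columns]
  df$label <- as.integer(df$dx == "mel")
  if (!is.null(filter)) {
    keep <- filter(df)
    stopifnot(is.logical(keep), length(keep) == nrow(df))
    df <- df[keep, , drop = FALSE]
  }
  df
}

#' @rdname read_metadata
#' @param records A data frame containing the schema columns, or a
#'   `synthetic_dataset`, or a list of `image_record`s.
#' @export
write_metadata <- function(records, path) {
  df <- if (is.data.frame(records)) {
    records
  } else if (inherits(records, "synthetic_dataset")) {
    records$metadata
  } else {
    do.call(rbind, lapply(records, function(r) {
      as.data.frame(r[.metadata_columns])
    }))
  }
  missing_cols <- setdiff(.metadata_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("metadata schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(df[, .metadata_columns], path, row.names = FALSE)
  invisible(path)
}
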