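test_that("the generator honors count, fraction, size and labelling rules", {
  ds <- generate_synthetic_dataset(
    synthetic_dataset_spec(n_images = 10L, melanoma_fraction = 0.3,
                           seed = 7L, image_side = 64L))
  expect_length(ds$records, 10L)
  expect_identical(sum(ds$metadata$label), 3L)
  expect_true(all(vapply(ds$records, function(r)
    identical(dim(r$image), c(64L, 64L, 3L)), TRUE)))
  expect_identical(ds$metadata$label,
                   as.integer(ds$metadata$dx == "mel"))
  expect_true(all(ds$metadata$dx_type %in%
                    c("histo", "follow_up", "consensus", "confocal")))
  expect_true(all(ds$metadata$sex %in% c("male", "female", "unknown")))
})

test_that("identical specs generate byte-identical datasets", {
  spec <- synthetic_dataset_spec(n_images = 4L, seed = 99L, image_side = 32L)
  a <- generate_synthetic_dataset(spec)
  b <- generate_synthetic_dataset(spec)
  expect_identical(lapply(a$records, function(r) unclass(r$image)),
                   lapply(b$records, function(r) unclass(r$image)))
  expect_identical(a$metadata, b$metadata)
  c <- generate_synthetic_dataset(
    synthetic_dataset_spec(n_images = 4L, seed = 100L, image_side = 32L))
  expect_false(identical(unclass(a$records[[1]]$image),
                         unclass(c$records[[1]]$image)))
})

test_that("melanoma-labelled blobs are darker than benign ones on average", {
  ds <- fixture_dataset(n = 8L)
  mel <- vapply(ds$records[ds$metadata$label == 1L],
                function(r) mean(r$image), 0)
  ben <- vapply(ds$records[ds$metadata$label == 0L],
                function(r) mean(r$image), 0)
  expect_lt(mean(mel), mean(ben))
})

test_that("metadata survives a CSV round trip", {
  ds <- generate_synthetic_dataset(
    synthetic_dataset_spec(n_images = 6L, seed = 3L, image_side = 32L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metadata(ds, path)
  back <- read_metadata(path)
  expect_equal(back[names(back) != "label"],
               ds$metadata[names(ds$metadata) != "label"],
               ignore_attr = TRUE)
  expect_identical(back$label, ds$metadata$label)
})

test_that("schema violations and label derivation behave as documented", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(lesion_id = "L1", image_id = "I1", dx = "nv",
                   dx_type = "histo", age = 50, sex = "male",
                   localization = "back")
  write.csv(df, path, row.names = FALSE)
  back <- read_metadata(path)
  expect_identical(back$label, 0L)
  # unknown dx codes are preserved verbatim, labelled 0
  df$dx <- "experimental_code"
  write.csv(df, path, row.names = FALSE)
  expect_identical(read_metadata(path)$dx, "experimental_code")
  expect_identical(read_metadata(path)$label, 0L)
  df$dx <- "mel"
  write.csv(df, path, row.names = FALSE)
  expect_identical(read_metadata(path)$label, 1L)
  # missing required column
  write.csv(df[, names(df) != "dx"], path, row.names = FALSE)
  expect_error(read_metadata(path), "schema error.*dx")
})

test_that("an optional row filter restricts at read time", {
  ds <- generate_synthetic_dataset(
    synthetic_dataset_spec(n_images = 12L, seed = 21L, image_side = 32L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metadata(ds, path)
  histo <- read_metadata(path, filter = function(df) df$dx_type == "histo")
  expect_true(all(histo$dx_type == "histo"))
  expect_identical(nrow(histo), sum(ds$metadata$dx_type == "histo"))
})

test_that("images survive a PNG round trip byte-for-byte", {
  img <- fixture_images(n = 2L, side = 64L)[[1L]]
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path)
  expect_identical(dim(back), dim(img))
  expect_true(all(unclass(back) == unclass(img)))
})
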