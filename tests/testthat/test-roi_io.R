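test_that("roi_image validates its invariants", {
  expect_error(roi_image(matrix(-1L, 8, 8)), "0, 16383")
  expect_error(roi_image(matrix(16384L, 8, 8)), "0, 16383")
  expect_error(roi_image(matrix(0L, 4, 8)), "8x8")
  expect_error(roi_image(matrix(0.5, 8, 8)), "integer")
  expect_error(roi_image(matrix(0L, 8, 8), group = "sick"), "unknown group")
  img <- roi_image(matrix(0L, 8, 8), group = " case ",
                   compartment = "MEDIAL")
  expect_identical(img$group, "Case")
  expect_identical(img$compartment, "Medial")
})

test_that("16-bit TIFF write/read round-trips the pixel grid exactly", {
  img <- generate_texture(small_spec(seed = 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_roi_image(img, path)
  back <- read_roi_image(path, id = img$id, group = img$group,
                         compartment = img$compartment)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$bit_depth, 16L)
  expect_lte(max(back$pixels), 16383L)
})

test_that("8-bit PNG round-trips and is flagged by bit depth", {
  px <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  img <- roi_image(px, id = "p8")
  path <- withr::local_tempfile(fileext = ".png")
  write_roi_image(img, path)
  back <- read_roi_image(path)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$bit_depth, 8L)
})

test_that("multi-channel images are rejected as format errors", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(8 * 8 * 3), c(8, 8, 3)), path)
  expect_error(read_roi_image(path), "multi-channel")
})

test_that("gray levels above the 14-bit maximum are rejected", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(30000 / 65535, 8, 8), path, bits.per.sample = 16L)
  expect_error(read_roi_image(path), "16383")
})

test_that("brightness_stats pools pixels with the population sd", {
  const <- roi_image(matrix(100L, 8, 8))
  bs <- brightness_stats(const)
  expect_equal(bs$mean, 100)
  expect_equal(bs$sigma, 0)
  expect_equal(bs$n_pixels, 64L)

  # two images holding {0,2} and {4,6} in equal numbers: pooled mean 3,
  # population sigma sqrt(5)
  a <- roi_image(matrix(c(0L, 2L), 8, 8), id = "a")
  b <- roi_image(matrix(c(4L, 6L), 8, 8), id = "b")
  bs2 <- brightness_stats(list(a, b))
  expect_equal(bs2$mean, 3)
  expect_equal(bs2$sigma, sqrt(5))
})

test_that("brightness_stats is invariant to ordering and regrouping", {
  imgs <- small_dataset(3, 3, seed = 9)$images
  ref <- brightness_stats(imgs)
  expect_equal(brightness_stats(rev(imgs)), ref)
  # split/merge with the same pooled multiset
  merged <- c(brightness_stats(imgs[1:2])$n_pixels,
              brightness_stats(imgs[3:6])$n_pixels)
  expect_equal(sum(merged), ref$n_pixels)
})

test_that("manifest round-trip preserves images and stratum counts", {
  ds <- small_dataset(3, 2, seed = 4)
  dir <- withr::local_tempdir()
  man <- write_dataset_dir(ds, dir)
  back <- load_dataset_manifest(man)
  expect_length(back$images, 5L)
  counts <- back$strata
  expect_equal(counts$n[counts$group == "Case"], 3L)
  expect_equal(counts$n[counts$group == "Control"], 2L)
  expect_identical(back$images[[1]]$pixels, ds$images[[1]]$pixels)
})

test_that("manifest labels are trimmed and case-normalized", {
  ds <- small_dataset(2, 2, seed = 8)
  dir <- withr::local_tempdir()
  man <- write_dataset_dir(ds, dir)
  tab <- read.csv(man, stringsAsFactors = FALSE)
  tab$group[1] <- " case "
  tab$compartment[2] <- "LATERAL"
  write.csv(tab, man, row.names = FALSE)
  back <- load_dataset_manifest(man)
  expect_identical(back$images[[1]]$group, "Case")
})

test_that("bad manifests fail loudly", {
  dir <- withr::local_tempdir()
  man <- file.path(dir, "manifest.csv")
  # empty manifest
  write.csv(data.frame(id = character(), filepath = character(),
                       group = character(), compartment = character()),
            man, row.names = FALSE)
  expect_error(load_dataset_manifest(man), "empty")
  # duplicate ids
  ds <- small_dataset(2, 2, seed = 2)
  man <- write_dataset_dir(ds, dir)
  tab <- read.csv(man, stringsAsFactors = FALSE)
  tab$id <- rep(tab$id[1], nrow(tab))
  write.csv(tab, man, row.names = FALSE)
  expect_error(load_dataset_manifest(man), "duplicate")
  # missing column
  write.csv(data.frame(id = "a", path = "x.tif"), man, row.names = FALSE)
  expect_error(load_dataset_manifest(man), "columns")
})
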