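#' ROI image patch
#'
#' Construct an ROI (region-of-interest) image: a single-channel grid of
#' non-negative integer gray levels cut from the lateral or medial tibial
#' compartment of a knee radiograph, with its group and compartment labels.
#' Detectors in the source study deliver a 14-bit dynamic range, so pixel
#' values must lie in `[0, 16383]`.
#'
#' @param pixels integer (or whole-number numeric) matrix of gray levels.
#' @param id character scalar, unique image identifier.
#' @param group `"Case"` or `"Control"` (case-insensitive, whitespace
#'   trimmed).
#' @param compartment `"Lateral"` or `"Medial"` (case-insensitive,
#'   whitespace trimmed).
#' @param bit_depth integer, bit depth of the source encoding (8 or 16);
#'   recorded as provenance, not used in computation.
#' @return An object of class `roi_image` with fields `pixels`, `id`,
#'   `group`, `compartment`, `bit_depth`.
#' @examples
#' img <- roi_image(matrix(0:3, 2, 2), id = "a", group = "Case",
#'                  compartment = "Lateral")
#' dim(img$pixels)
#' @export
roi_image <- function(pixels, id = "roi", group = "Control",
                      compartment = "Lateral", bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(pixels != round(pixels)))
    stop("pixel values must be integers")
  if (any(pixels < 0) || any(pixels > 16383))
    stop("pixel values must lie in [0, 16383] (14-bit range)")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("ROI patches must be at least 8x8; texture features are ",
         "undefined on degenerate patches")
  structure(
    list(pixels = matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
         id = as.character(id),
         group = normalize_group(group),
         compartment = normalize_compartment(compartment),
         bit_depth = as.integer(bit_depth)),
    class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image '%s'> %dx%d px, %d-bit source, %s / %s\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$group, x$compartment))
  invisible(x)
}

normalize_group <- function(x) {
  g <- tolower(trimws(as.character(x)))
  if (!g %in% c("case", "control"))
    stop("unknown group label: '", x, "' (expected Case or Control)")
  if (g == "case") "Case" else "Control"
}

normalize_compartment <- function(x) {
  g <- tolower(trimws(as.character(x)))
  if (!g %in% c("lateral", "medial"))
    stop("unknown compartment label: '", x,
         "' (expected Lateral or Medial)")
  if (g == "lateral") "Lateral" else "Medial"
}

#' Read an ROI patch from a PNG or TIFF file
#'
#' Decodes a single-channel 8- or 16-bit grayscale image losslessly into an
#' [roi_image]. Multi-channel images and images with gray levels above the
#' 14-bit maximum 16383 are rejected as format errors. 8-bit sources are
#' accepted and flagged through the `bit_depth` provenance field.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param id,group,compartment metadata attached to the patch.
#' @return An [roi_image].
#' @export
read_roi_image <- function(path, id = basename(path), group = "Control",
                           compartment = "Lateral") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- info$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  } else {
    stop("unsupported image format: .", ext, " (PNG and TIFF are accepted)")
  }
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] > 1L)
      stop("multi-channel image: ", path,
           " (single-channel grayscale required)")
    arr <- arr[, , 1L]
  }
  # readPNG/readTIFF scale to [0, 1] against the encoding's full range
  px <- round(arr * (2^bits - 1))
  if (any(px > 16383))
    stop("gray levels exceed the 14-bit maximum 16383 in ", path)
  roi_image(px, id = id, group = group, compartment = compartment,
            bit_depth = as.integer(bits))
}

#' Write an ROI patch to disk
#'
#' 16-bit output uses TIFF (`bits.per.sample = 16`); PNG output is 8-bit and
#' requires all gray levels to fit in `[0, 255]`. Either path round-trips
#' losslessly through [read_roi_image()].
#'
#' @param image an [roi_image].
#' @param path destination ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_roi_image <- function(image, path) {
  stopifnot(inherits(image, "roi_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (any(image$pixels > 255))
      stop("PNG output is 8-bit; gray levels exceed 255 (use TIFF for ",
           "14-bit data)")
    png::writePNG(image$pixels / 255, path)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' Load a dataset from a CSV manifest
#'
#' The manifest must have columns `id,filepath,group,compartment`; relative
#' file paths are resolved against the manifest's directory. Group and
#' compartment labels are trimmed and case-normalized on ingest.
#'
#' @param path CSV manifest path.
#' @return An object of class `roi_dataset`: a list with `images` (named
#'   list of [roi_image]) and `strata` (a data.frame of per
#'   group x compartment counts).
#' @export
load_dataset_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "filepath", "group", "compartment")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  if (nrow(man) == 0L) stop("empty manifest: no images listed")
  man$id <- trimws(as.character(man$id))
  if (anyDuplicated(man$id))
    stop("duplicate image ids in manifest: ",
         paste(unique(man$id[duplicated(man$id)]), collapse = ", "))
  base <- dirname(normalizePath(path))
  imgs <- lapply(seq_len(nrow(man)), function(i) {
    fp <- man$filepath[i]
    if (!file.exists(fp)) fp <- file.path(base, man$filepath[i])
    read_roi_image(fp, id = man$id[i], group = man$group[i],
                   compartment = man$compartment[i])
  })
  names(imgs) <- man$id
  roi_dataset(imgs)
}

#' Bundle ROI images into a dataset
#'
#' @param images list of [roi_image] with unique ids.
#' @return An object of class `roi_dataset`.
#' @export
roi_dataset <- function(images) {
  stopifnot(length(images) > 0L,
            all(vapply(images, inherits, TRUE, "roi_image")))
  ids <- vapply(images, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate image ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(images) <- ids
  grp <- vapply(images, `[[`, "", "group")
  cmp <- vapply(images, `[[`, "", "compartment")
  strata <- as.data.frame(table(group = grp, compartment = cmp),
                          responseName = "n")
  strata <- strata[strata$n > 0L, , drop = FALSE]
  rownames(strata) <- NULL
  structure(list(images = images, strata = strata), class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset> %d images\n", length(x$images)))
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' @export
length.roi_dataset <- function(x) length(x$images)

#' Pooled brightness statistics of a set of ROI patches
#'
#' Mean and population standard deviation (divide by N) over the pixels of
#' all listed images pooled into one sample, the convention under which one
#' stratum of images yields one number per statistic. Invariant to image
#' ordering and to any regrouping that preserves the pooled pixel multiset.
#'
#' @param images a list of [roi_image], a single [roi_image], or a
#'   `roi_dataset`.
#' @return A list with `mean`, `sigma` (gray levels) and `n_pixels`.
#' @examples
#' a <- roi_image(matrix(100L, 8, 8), id = "a")
#' brightness_stats(a)  # mean 100, sigma 0
#' @export
brightness_stats <- function(images) {
  if (inherits(images, "roi_dataset")) images <- images$images
  if (inherits(images, "roi_image")) images <- list(images)
  if (length(images) == 0L) stop("empty image list")
  px <- unlist(lapply(images, function(im) as.vector(im$pixels)),
               use.names = FALSE)
  n <- length(px)
  m <- mean(px)
  list(mean = m, sigma = sqrt(sum((px - m)^2) / n), n_pixels = n)
}

# Subset a dataset's image list by predicate on metadata.
dataset_subset <- function(dataset, group = NULL, compartment = NULL) {
  imgs <- dataset$images
  if (!is.null(group))
    imgs <- Filter(function(im) im$group == group, imgs)
  if (!is.null(compartment))
    imgs <- Filter(function(im) im$compartment == compartment, imgs)
  imgs
}
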