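#' Specification of a synthetic textured patch
#'
#' Parameters of a Gaussian-random-field texture: target brightness mean and
#' standard deviation (gray levels), a spectral power-law exponent `beta`
#' that controls spatial correlation (amplitude of the field scales as
#' frequency^(-beta/2); `beta = 0` is white noise, larger `beta` gives
#' smoother, longer-range texture), patch size, and a seed.
#'
#' The class defaults mirror the brightness statistics observed in the
#' lateral-compartment strata of the motivating study (Case mean 1735.5,
#' sigma 205.8; Control mean 1901.5, sigma 251.1); the spectral exponents
#' (3.0 vs 2.6) are synthetic choices that add a spatial-correlation
#' difference on top of the brightness difference, not estimates from data.
#'
#' @param mean target gray-level mean.
#' @param sigma target gray-level standard deviation, `> 0`.
#' @param beta spectral exponent, `>= 0`.
#' @param size integer vector `c(height, width)`, both `>= 8`.
#' @param seed integer seed.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(mean = 1735.5, sigma = 205.8, beta = 3.0,
                         size = c(150L, 150L), seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 8L), beta >= 0, sigma > 0)
  if (mean - 4 * sigma < 0 || mean + 4 * sigma > 16383)
    stop("mean +/- 4*sigma must stay within the 14-bit range [0, 16383]")
  structure(list(mean = mean, sigma = sigma, beta = beta,
                 size = as.integer(size), seed = as.integer(seed)),
            class = "texture_spec")
}

#' Default class specs matching the studied strata
#'
#' @param class `"Case"` or `"Control"`.
#' @param compartment `"Lateral"` or `"Medial"`.
#' @param ... overrides passed to [texture_spec()].
#' @return A `texture_spec`.
#' @export
default_texture_spec <- function(class = c("Case", "Control"),
                                 compartment = c("Lateral", "Medial"), ...) {
  class <- match.arg(class)
  compartment <- match.arg(compartment)
  tab <- list(
    Case_Lateral    = c(1735.5, 205.8),
    Case_Medial     = c(1723.9, 222.1),
    Control_Lateral = c(1901.5, 251.1),
    Control_Medial  = c(1917.2, 224.0))
  ms <- tab[[paste(class, compartment, sep = "_")]]
  beta <- if (class == "Case") 3.0 else 2.6
  args <- list(mean = ms[1], sigma = ms[2], beta = beta)
  args[names(list(...))] <- list(...)
  do.call(texture_spec, args)
}

#' Generate a textured ROI patch
#'
#' Builds a Gaussian random field by shaping white noise in the frequency
#' domain with amplitude proportional to `frequency^(-beta/2)` (the DC
#' component is zeroed), affinely rescales the field to the target mean and
#' standard deviation, clips into `[0, 16383]` and rounds to integers.
#' Deterministic given the spec's seed.
#'
#' @param spec a [texture_spec()].
#' @param id,group,compartment metadata for the resulting patch.
#' @return An [roi_image].
#' @examples
#' img <- generate_texture(texture_spec(seed = 1))
#' round(brightness_stats(img)$mean)
#' @export
generate_texture <- function(spec, id = "synthetic", group = "Control",
                             compartment = "Lateral") {
  stopifnot(inherits(spec, "texture_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  field <- with_seed(spec$seed, {
    noise <- matrix(rnorm(h * w), h, w)
    fx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / w
    fy <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1)) / h
    freq <- sqrt(outer(fy^2, fx^2, `+`))
    amp <- ifelse(freq > 0, freq^(-spec$beta / 2), 0)
    Re(fft(fft(noise) * amp, inverse = TRUE)) / (h * w)
  })
  # affine rescale to the target moments before clipping/rounding
  s <- sd(as.vector(field)) * sqrt((h * w - 1) / (h * w))  # population sd
  field <- if (s > 0) (field - mean(field)) / s else field * 0
  px <- round(pmax(pmin(spec$mean + spec$sigma * field, 16383), 0))
  roi_image(px, id = id, group = group, compartment = compartment)
}

#' Generate a two-class synthetic dataset
#'
#' Per-image seeds are derived deterministically from the master seed, so
#' the whole dataset is reproducible from `(specs, seed)`.
#'
#' @param n_case,n_control stratum sizes, `>= 1`.
#' @param case_spec,control_spec [texture_spec()]s for the two classes
#'   (their own seeds are ignored; per-image seeds come from `seed`).
#' @param seed master integer seed.
#' @param compartment compartment label given to every image.
#' @return A `roi_dataset` with `n_case + n_control` images.
#' @export
generate_dataset <- function(n_case = 20L, n_control = 20L,
                             case_spec = default_texture_spec("Case"),
                             control_spec = default_texture_spec("Control"),
                             seed = 1L, compartment = "Lateral") {
  stopifnot(n_case >= 1L, n_control >= 1L)
  make <- function(spec, class, k) {
    sp <- spec
    sp$seed <- derive_seed(seed, k)
    generate_texture(sp, id = sprintf("%s_%03d", tolower(class), k),
                     group = class, compartment = compartment)
  }
  imgs <- c(
    lapply(seq_len(n_case), function(k) make(case_spec, "Case", k)),
    lapply(seq_len(n_control),
           function(k) make(control_spec, "Control", n_case + k)))
  roi_dataset(imgs)
}

#' Rotate a square patch by quarter turns
#'
#' Exact counter-clockwise rotation by `quarter_turns` times 90 degrees,
#' with no interpolation: the pixel multiset is preserved exactly, which
#' makes quarter turns the reference transform for rotation-invariance
#' checks of moment features.
#'
#' @param image a square [roi_image].
#' @param quarter_turns integer (any sign; taken modulo 4).
#' @return The rotated [roi_image].
#' @export
rotate_texture <- function(image, quarter_turns = 1L) {
  stopifnot(inherits(image, "roi_image"))
  m <- image$pixels
  if (nrow(m) != ncol(m)) stop("quarter-turn rotation requires a square patch")
  k <- ((quarter_turns %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1L, , drop = FALSE]
  out <- image
  out$pixels <- m
  out
}

#' Write a synthetic dataset to a directory with a manifest
#'
#' Writes one 16-bit TIFF per image plus `manifest.csv` in the layout
#' consumed by [load_dataset_manifest()].
#'
#' @param dataset a `roi_dataset`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset_dir <- function(dataset, dir) {
  stopifnot(inherits(dataset, "roi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset$images, function(im) {
    fn <- paste0(im$id, ".tif")
    write_roi_image(im, file.path(dir, fn))
    data.frame(id = im$id, filepath = fn, group = im$group,
               compartment = im$compartment, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}
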