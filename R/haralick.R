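#' Quantize an image to a fixed number of gray levels
#'
#' Linear binning of the image's own `[min, max]` range into `levels` bins
#' numbered `0 .. levels-1`. A constant image maps entirely to bin 0.
#'
#' @param image an [roi_image] or numeric matrix.
#' @param levels number of gray levels, `>= 2`.
#' @return An integer matrix of bin indexes.
#' @export
quantize_image <- function(image, levels = 64L) {
  f <- if (inherits(image, "roi_image")) image$pixels else image
  stopifnot(is.matrix(f))
  if (levels < 2L) stop("levels must be >= 2")
  lo <- min(f); hi <- max(f)
  if (hi == lo) return(matrix(0L, nrow(f), ncol(f)))
  q <- floor((f - lo) / (hi - lo) * levels)
  matrix(as.integer(pmin(q, levels - 1L)), nrow(f), ncol(f))
}

# Pixel offsets (drow, dcol) for the standard GLCM angles at distance d.
glcm_offsets <- function(d, angles) {
  lapply(angles, function(a) switch(as.character(a),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("unsupported GLCM angle: ", a,
         " (0, 45, 90, 135 degrees supported)")))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs at pixel offset `distance` along the
#' listed `angles`, accumulated into a single matrix. With
#' `symmetric = TRUE` the transpose is added (each pair counted in both
#' orders); with `normalized = TRUE` entries are scaled to sum to 1.
#'
#' @param quantized integer matrix of gray-level bins `0 .. levels-1`, as
#'   produced by [quantize_image()].
#' @param levels number of gray levels G (matrix is G x G).
#' @param distance pixel offset length, `>= 1` and smaller than both image
#'   dimensions.
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @param symmetric,normalized flags (both default `TRUE`).
#' @return An object of class `glcm`: the G x G `matrix` plus the
#'   parameters.
#' @examples
#' g <- glcm(matrix(c(0L, 1L, 0L, 1L), 2, 2), levels = 2, angles = 0)
#' g$matrix
#' @export
glcm <- function(quantized, levels = max(quantized) + 1L, distance = 1L,
                 angles = c(0, 45, 90, 135), symmetric = TRUE,
                 normalized = TRUE) {
  stopifnot(is.matrix(quantized), all(quantized >= 0L),
            all(quantized < levels))
  h <- nrow(quantized); w <- ncol(quantized)
  if (distance >= h || distance >= w)
    stop("distance must be smaller than both image dimensions")
  G <- as.integer(levels)
  counts <- matrix(0, G, G)
  for (off in glcm_offsets(as.integer(distance), angles)) {
    rows <- seq_len(h)[(seq_len(h) + off[1]) >= 1L &
                       (seq_len(h) + off[1]) <= h]
    cols <- seq_len(w)[(seq_len(w) + off[2]) >= 1L &
                       (seq_len(w) + off[2]) <= w]
    a <- quantized[rows, cols, drop = FALSE]
    b <- quantized[rows + off[1], cols + off[2], drop = FALSE]
    tab <- tabulate(a * G + b + 1L, nbins = G * G)
    counts <- counts + matrix(tab, G, G, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  if (total == 0) stop("no pixel pairs at the requested offset")
  if (normalized) counts <- counts / total
  structure(list(matrix = counts, levels = G, distance = distance,
                 angles = angles, symmetric = symmetric,
                 normalized = normalized),
            class = "glcm")
}

#' Names of the 14 Haralick statistics
#'
#' @return Character vector of length 14 in canonical order.
#' @export
haralick_names <- function() {
  c("energy", "contrast", "correlation", "variance", "homogeneity",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "difference_variance", "difference_entropy", "imc1", "imc2",
    "max_correlation_coefficient")
}

# Base-2 entropy with the 0 * log 0 := 0 convention.
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' The 14 Haralick texture statistics of a normalized GLCM
#'
#' Classical definitions over a normalized co-occurrence matrix `p(i, j)`
#' with gray levels indexed `0 .. G-1`: angular second moment (energy),
#' contrast, correlation, variance, inverse difference moment (homogeneity),
#' sum average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, the two information measures of correlation, and the
#' maximal correlation coefficient (square root of the second-largest
#' eigenvalue of the Q matrix). Entropies use log base 2. Sum variance is
#' centered on the sum average (the standard correction of the original
#' paper's typo). When a marginal standard deviation is zero the
#' correlation-type statistics are returned as 0 with a warning instead of
#' NaN.
#'
#' @param g a normalized [glcm()].
#' @return A named numeric vector of length 14, in [haralick_names()]
#'   order.
#' @export
haralick_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  if (!g$normalized) stop("haralick_features requires a normalized GLCM")
  p <- g$matrix
  G <- g$levels
  i <- matrix(rep(0:(G - 1L), G), G)          # row gray level
  j <- t(i)                                    # column gray level
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(G - 1L)) * px); muy <- sum((0:(G - 1L)) * py)
  sdx <- sqrt(sum(((0:(G - 1L)) - mux)^2 * px))
  sdy <- sqrt(sum(((0:(G - 1L)) - muy)^2 * py))

  # distributions of i + j (support 0 .. 2G-2) and |i - j| (0 .. G-1)
  psum <- vapply(0:(2L * G - 2L), function(k) sum(p[i + j == k]), 0)
  pdif <- vapply(0:(G - 1L), function(k) sum(p[abs(i - j) == k]), 0)

  energy <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  degenerate <- sdx == 0 || sdy == 0
  if (degenerate)
    warning("degenerate GLCM (zero marginal sd); ",
            "correlation-type features set to 0")
  correlation <- if (degenerate) 0 else
    (sum(i * j * p) - mux * muy) / (sdx * sdy)
  mu <- sum(i * p)  # grand mean of the row marginal weighting
  variance <- sum((i - mu)^2 * p)
  homogeneity <- sum(p / (1 + (i - j)^2))
  sum_average <- sum((0:(2L * G - 2L)) * psum)
  sum_variance <- sum(((0:(2L * G - 2L)) - sum_average)^2 * psum)
  sum_entropy <- entropy2(psum)
  ent <- entropy2(p)
  dif_average <- sum((0:(G - 1L)) * pdif)
  difference_variance <- sum(((0:(G - 1L)) - dif_average)^2 * pdif)
  difference_entropy <- entropy2(pdif)

  hx <- entropy2(px); hy <- entropy2(py)
  pxpy <- outer(px, py)
  ok <- p > 0 & pxpy > 0
  hxy1 <- -sum(p[ok] * log2(pxpy[ok]))
  hxy2 <- entropy2(pxpy)
  imc1 <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))

  mcc <- if (degenerate) 0 else {
    nz <- px > 0 & py > 0
    q <- matrix(0, G, G)
    pn <- p[nz, nz, drop = FALSE]
    q[nz, nz] <- (pn / px[nz]) %*% (t(pn) / py[nz])
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) < 2L) 0 else sqrt(max(0, ev[2]))
  }

  stats::setNames(
    c(energy, contrast, correlation, variance, homogeneity, sum_average,
      sum_variance, sum_entropy, ent, difference_variance,
      difference_entropy, imc1, imc2, mcc),
    haralick_names())
}

#' Haralick feature vector of an ROI patch
#'
#' Convenience wrapper: quantize, accumulate the symmetric normalized GLCM
#' over the four standard directions, and compute the 14 statistics.
#'
#' @param image an [roi_image].
#' @param levels gray levels for quantization (default 64).
#' @param distance pixel offset (default 1).
#' @param angles directions in degrees (default all four).
#' @param subset optional integer or character vector selecting statistics
#'   (the full 14-vector by default).
#' @return Named numeric vector, names prefixed `h_`.
#' @export
haralick_vector <- function(image, levels = 64L, distance = 1L,
                            angles = c(0, 45, 90, 135), subset = NULL) {
  q <- quantize_image(image, levels)
  v <- haralick_features(glcm(q, levels = levels, distance = distance,
                              angles = angles))
  names(v) <- sprintf("h_%d", seq_along(v))
  if (!is.null(subset)) v[subset] else v
}
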