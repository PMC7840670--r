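# Shared fixtures and independent oracles for the test suite.

# Small textured patch; 32x32 keeps pooled-pixel tests fast.
small_spec <- function(mean = 1735.5, sigma = 205.8, beta = 3.0,
                       seed = 1L, size = c(32L, 32L)) {
  texture_spec(mean = mean, sigma = sigma, beta = beta, size = size,
               seed = seed)
}

small_dataset <- function(n_case = 4L, n_control = 4L, seed = 1L,
                          size = c(32L, 32L),
                          case_mean = 1735.5, control_mean = 1901.5) {
  generate_dataset(
    n_case, n_control,
    case_spec = small_spec(mean = case_mean, sigma = 205.8, beta = 3.0,
                           size = size),
    control_spec = small_spec(mean = control_mean, sigma = 251.1,
                              beta = 2.6, size = size),
    seed = seed)
}

# Brute-force two-sample KS distance: evaluate both ECDFs at every
# breakpoint of either sample.
ks_bruteforce <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), 0)
  Fb <- vapply(pts, function(t) mean(b <= t), 0)
  max(abs(Fa - Fb))
}

# Independent normal-equations solver for a two-input polynomial neuron.
neuron_oracle <- function(x1, x2, y, fit_idx, interaction = TRUE) {
  D <- cbind(1, x1, x2, if (interaction) x1 * x2)
  Df <- D[fit_idx, , drop = FALSE]
  w <- solve(t(Df) %*% Df, t(Df) %*% y[fit_idx])
  ext <- setdiff(seq_along(y), fit_idx)
  list(w = as.numeric(w),
       delta = sqrt(sum((D[ext, , drop = FALSE] %*% w - y[ext])^2)))
}

# Direct evaluation of the radial polynomial with plain factorials
# (safe up to n = 16 in double precision).
radial_oracle <- function(n, m, rho) {
  m <- abs(m)
  s <- 0
  for (k in 0:((n - m) / 2)) {
    s <- s + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) *
         factorial((n - m) / 2 - k)) * rho^(n - 2 * k)
  }
  s
}

# Bilinear rotation of a matrix about its center by `deg` degrees
# (counter-clockwise in the right-handed image frame); source samples are
# clamped to the grid (edge replication), the usual padding of image
# rotation routines.
rotate_bilinear <- function(m, deg) {
  h <- nrow(m); w <- ncol(m)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  a <- deg * pi / 180
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      # inverse map: rotate target coords by -a around the center
      x <- (c - 1) - cx; y <- cy - (r - 1)
      xs <- cos(-a) * x - sin(-a) * y
      ys <- sin(-a) * x + cos(-a) * y
      sc <- min(max(xs + cx, 0), w - 1)
      sr <- min(max(cy - ys, 0), h - 1)
      r0 <- min(floor(sr), h - 2); c0 <- min(floor(sc), w - 2)
      fr <- sr - r0; fc <- sc - c0
      out[r, c] <-
        (1 - fr) * ((1 - fc) * m[r0 + 1, c0 + 1] +
                      fc * m[r0 + 1, c0 + 2]) +
        fr * ((1 - fc) * m[r0 + 2, c0 + 1] + fc * m[r0 + 2, c0 + 2])
    }
  }
  out
}

# A smooth band-limited patch: a superposition of long-wavelength plane
# waves (every wavelength >= lam_min pixels), so bilinear resampling
# under rotation barely perturbs it while all low-order moments carry
# substantial energy.
smooth_fixture <- function(size = 300L, seed = 7L, nmodes = 40L,
                           lam_min = 40) {
  h <- w <- size
  set.seed(seed)
  xs <- matrix(rep(0:(w - 1), each = h), h)
  ys <- matrix(rep(0:(h - 1), w), h)
  f <- matrix(6000, h, w)
  for (i in seq_len(nmodes)) {
    lam <- runif(1, lam_min, 3 * lam_min)
    ang <- runif(1, 0, pi)
    ph <- runif(1, 0, 2 * pi)
    k <- 2 * pi / lam
    f <- f + (2000 / sqrt(nmodes)) *
      cos(k * (cos(ang) * xs + sin(ang) * ys) + ph)
  }
  roi_image(round(f), id = "smooth")
}

# A binary-feature fixture whose target is exactly representable by one
# polynomial neuron (the AND of the first two features).
and_fixture <- function(n = 40L, m = 2L, seed = 5L) {
  X <- matrix(rbinom(n * m, 1, 0.5), n, m)
  # ensure all four (x1, x2) combinations appear
  X[1:4, 1] <- c(0, 0, 1, 1)
  X[1:4, 2] <- c(0, 1, 0, 1)
  list(X = X, y = X[, 1] * X[, 2])
}
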