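#' GMDH training configuration
#'
#' Hyperparameters of the self-organizing polynomial network. The freedom
#' of choice `F` is the maximum number of neurons propagated from one layer
#' to the next (default: the number of input features). `F0` is the
#' stopping threshold: growth stops when fewer than `F0` neurons survive
#' selection. The training rows are split into a fit subset A, on which
#' neuron coefficients are least-squares estimated, and an external subset
#' that the fit never sees; by default the external subset holds a
#' `external_frac` share of the rows (with 39 training rows and the
#' default 0.2 this is the 31/8 split), drawn stratified by class from the
#' training seed. The selection error `delta` of a candidate is, by
#' default, the norm of its residuals over the entire training data
#' (which includes the external rows unseen by the fit);
#' `delta_on = "external"` restricts it to the held-out subset only, the
#' classic GMDH external criterion. Candidate neurons whose evaluation
#' outputs correlate above `rho_max` with an already-kept neuron are
#' excluded from selection.
#'
#' @param F freedom of choice; `NULL` means "number of input features".
#' @param F0 minimal surviving-neuron threshold, `>= 1` (default 2).
#' @param external_frac fraction of training rows held out as the external
#'   subset (ignored when `n_external` is given).
#' @param n_external fixed external-subset size, or `NULL`.
#' @param rho_max correlation-pruning threshold in `(0, 1]` (default
#'   0.999: only near-duplicate neurons are dropped).
#' @param min_improve minimum relative improvement of the layer-best
#'   external error required to grow another layer (default 0.01). With
#'   thousands of candidate neurons scored on a small external subset, the
#'   layer-best error essentially always creeps down by selection noise
#'   alone; requiring a defined improvement stops growth once real
#'   structure stops being added.
#' @param max_layers hard cap on depth (default 20).
#' @param interaction include the `x1*x2` term in the neuron polynomial
#'   `a0 + a1 x1 + a2 x2 + a3 x1 x2` (default `TRUE`).
#' @param delta_on `"all"` (default) measures `delta` on every training
#'   row -- the fit subset plus the rows the fit never saw;
#'   `"external"` measures it on the held-out subset only (classic
#'   GMDH). With only 8 external rows the external-only ranking of
#'   thousands of candidates is dominated by selection noise, so the
#'   whole-data error is the steadier criterion.
#' @param standardize z-score the feature columns from the training rows
#'   before fitting (default `TRUE`; recommended for raw-gray-level
#'   features whose magnitudes differ by orders of magnitude).
#' @return An object of class `gmdh_config`.
#' @export
gmdh_config <- function(F = NULL, F0 = 2L, external_frac = 0.2,
                        n_external = NULL, rho_max = 0.999,
                        min_improve = 0.01, max_layers = 20L,
                        interaction = TRUE,
                        delta_on = c("all", "external"),
                        standardize = TRUE) {
  delta_on <- match.arg(delta_on)
  stopifnot(F0 >= 1L, external_frac > 0, external_frac < 1,
            rho_max > 0, rho_max <= 1, min_improve >= 0,
            max_layers >= 1L)
  structure(list(F = F, F0 = as.integer(F0),
                 external_frac = external_frac, n_external = n_external,
                 rho_max = rho_max, min_improve = min_improve,
                 max_layers = as.integer(max_layers),
                 interaction = interaction, delta_on = delta_on,
                 standardize = standardize),
            class = "gmdh_config")
}

#' Fit a single two-input polynomial neuron
#'
#' Least-squares fit of `y ~ a0 + a1 x1 + a2 x2 (+ a3 x1 x2)` on the rows
#' in `fit_idx`; the external error `delta` is the Euclidean norm of the
#' residuals on `eval_idx` (by default the complement of `fit_idx`).
#' Collinear inputs make the design rank deficient; the neuron is then
#' marked unfit (`delta = Inf`).
#'
#' @param x1,x2 input columns (equal length `n`).
#' @param y targets, length `n`.
#' @param fit_idx row indexes of the fit subset A (at least 5 rows).
#' @param eval_idx rows on which `delta` is measured; default
#'   `setdiff(1:n, fit_idx)`.
#' @param interaction include the product term (default `TRUE`).
#' @return A list with `w` (coefficients: bias, x1, x2, and the
#'   interaction when enabled), `delta`, `yhat` (outputs on all rows) and
#'   `unfit` flag.
#' @export
fit_neuron <- function(x1, x2, y, fit_idx,
                       eval_idx = setdiff(seq_along(y), fit_idx),
                       interaction = TRUE) {
  n <- length(y)
  stopifnot(length(x1) == n, length(x2) == n,
            all(fit_idx >= 1L), all(fit_idx <= n))
  if (length(fit_idx) < 5L) stop("fit subset A must have at least 5 rows")
  if (length(eval_idx) == 0L) eval_idx <- fit_idx
  res <- gmdh_fit_layer(cbind(x1, x2), as.numeric(y),
                        matrix(c(1L, 2L), 1L), as.integer(fit_idx),
                        as.integer(eval_idx), interaction)
  unfit <- !is.finite(res$delta[1])
  if (unfit) warning("rank-deficient design (collinear inputs); ",
                     "neuron marked unfit")
  w <- as.numeric(res$coef[, 1L])
  yhat <- w[1L] + w[2L] * x1 + w[3L] * x2 +
    (if (interaction) w[4L] * x1 * x2 else 0)
  list(w = w, delta = res$delta[1], yhat = yhat, unfit = unfit)
}

# Greedy external-criterion selection: order candidates by delta ascending
# (ties by candidate index), keep up to `F`, skipping candidates whose
# eval-row outputs correlate above rho_max (absolute Pearson) with an
# already-kept neuron. Constant-output candidates are mutually treated as
# perfectly correlated. Returns the kept candidate indexes in selection
# order. Columns are pre-normalized so each correlation is one dot
# product.
select_best <- function(delta, yhat_eval, F, rho_max) {
  K <- length(delta)
  ord <- order(delta, seq_len(K))
  ord <- ord[is.finite(delta[ord])]
  if (!length(ord)) return(integer(0))
  ne <- nrow(yhat_eval)
  ctr <- sweep(yhat_eval, 2L, colMeans(yhat_eval))
  nrm <- sqrt(colSums(ctr^2))
  nz <- nrm > 0
  ctr[, nz] <- sweep(ctr[, nz, drop = FALSE], 2L, nrm[nz], "/")
  kept <- integer(0)
  B <- matrix(0, ne, 0L)   # unit-norm centered outputs of kept neurons
  any_const <- FALSE
  for (k in ord) {
    if (length(kept) >= F) break
    if (!nz[k]) {
      dup <- any_const
    } else {
      dup <- ncol(B) > 0L &&
        max(abs(crossprod(B, ctr[, k]))) > rho_max
    }
    if (!dup) {
      kept <- c(kept, k)
      if (nz[k]) B <- cbind(B, ctr[, k]) else any_const <- TRUE
    }
  }
  kept
}

# Stratified split of training rows into fit subset A and external subset.
split_external <- function(y, config, seed) {
  n <- length(y)
  n_ext <- if (!is.null(config$n_external)) config$n_external
           else max(1L, round(config$external_frac * n))
  if (n - n_ext < 5L) stop("too few rows for the fit subset A")
  ext <- with_seed(seed, {
    idx0 <- which(y == 0); idx1 <- which(y == 1)
    k1 <- round(n_ext * length(idx1) / n)
    k1 <- min(max(k1, 0L), length(idx1) - 1L)
    k0 <- n_ext - k1
    k0 <- min(max(k0, 0L), length(idx0) - 1L)
    sort(c(sample(idx0, k0), sample(idx1, k1)))
  })
  list(fit = setdiff(seq_len(n), ext), ext = ext)
}

#' Train a GMDH-type polynomial network
#'
#' Grows a layered network of two-input polynomial neurons. The first layer
#' fits all `m(m-1)/2` feature pairs; each later layer fits all pairs of
#' columns of `Z = [selected outputs | original features]`
#' (`m_r = F_r + m` columns, `K_r = m_r(m_r-1)/2` candidates). Neurons are
#' fitted on the A rows and ranked by their external error `delta`; the
#' best up-to-`F` uncorrelated neurons survive. Growth stops when fewer
#' than `F0` neurons survive or when the layer-best `delta` stops strictly
#' improving; the best layer seen is retained and its minimum-`delta`
#' neuron becomes the output. Deterministic given `(X, y, config, seed)`.
#'
#' @param X numeric feature matrix, `n >= 10` rows, `m >= 2` columns.
#' @param y 0/1 targets (1 = Case), both classes present.
#' @param config a [gmdh_config()].
#' @param seed integer seed for the A-split.
#' @return An object of class `gmdh_network` with `layers` (each holding
#'   the selected neurons' input pairs, coefficients and deltas),
#'   `output_delta`, standardization constants, the split, and the config.
#' @export
gmdh_train <- function(X, y, config = gmdh_config(), seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  if (n < 10L) stop("at least 10 samples required")
  if (m < 2L) stop("at least 2 features required")
  if (!all(y %in% c(0, 1))) stop("targets must be encoded 0/1")
  if (length(unique(y)) < 2L) stop("degenerate targets: only one class")
  Fmax <- if (is.null(config$F)) m else config$F

  center <- rep(0, m); scale <- rep(1, m)
  if (config$standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, sd)
    scale[scale == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  }

  sp <- split_external(y, config, seed)
  eval_idx <- if (config$delta_on == "all") seq_len(n) else sp$ext

  layers <- list()
  Z <- X
  best_delta <- Inf; best_layer <- 0L
  prev_best <- Inf
  repeat {
    r <- length(layers) + 1L
    m_r <- ncol(Z)
    pairs <- t(combn(m_r, 2L))
    storage.mode(pairs) <- "integer"
    fit <- gmdh_fit_layer(Z, y, pairs, as.integer(sp$fit),
                          as.integer(eval_idx), config$interaction)
    if (!any(is.finite(fit$delta))) {
      if (r == 1L) stop("no fit neurons in the first layer ",
                        "(all candidate designs rank deficient)")
      break
    }
    kept <- select_best(fit$delta, fit$yhat_eval, Fmax, config$rho_max)
    F_r <- length(kept)
    if (F_r == 0L) break
    layer <- list(r = r, m_r = m_r, K_r = nrow(pairs), F_r = F_r,
                  pairs = pairs[kept, , drop = FALSE],
                  coef = fit$coef[, kept, drop = FALSE],
                  delta = fit$delta[kept],
                  prev_F = if (r == 1L) 0L else layers[[r - 1L]]$F_r)
    layers[[r]] <- layer
    this_best <- layer$delta[1L]
    if (this_best < best_delta) {
      best_delta <- this_best
      best_layer <- r
    }
    if (F_r < config$F0) break                       # too few survivors
    if (this_best <= 1e-10) break                    # perfect external fit
    # grow only while the external error improves by the defined value
    if (r > 1L && this_best >= prev_best * (1 - config$min_improve)) break
    if (r >= config$max_layers) break
    prev_best <- this_best
    Z <- cbind(layer_outputs(layer, Z, config$interaction), X)
  }
  if (best_layer == 0L) stop("network failed to grow a usable layer")
  layers <- layers[seq_len(best_layer)]

  structure(list(layers = layers, m = m, feature_names = colnames(X),
                 center = center, scale = scale,
                 output_delta = best_delta, split = sp,
                 config = config, seed = as.integer(seed)),
            class = "gmdh_network")
}

#' @export
print.gmdh_network <- function(x, ...) {
  cat(sprintf(
    "<gmdh_network> %d input features, %d layer(s), external delta %.4g\n",
    x$m, length(x$layers), x$output_delta))
  for (l in x$layers)
    cat(sprintf("  layer %d: m_r=%d, K_r=%d candidates, F_r=%d kept\n",
                l$r, l$m_r, l$K_r, l$F_r))
  invisible(x)
}

# Evaluate the kept neurons of one layer on input matrix Z.
layer_outputs <- function(layer, Z, interaction) {
  Y <- matrix(0, nrow(Z), layer$F_r)
  for (j in seq_len(layer$F_r)) {
    z1 <- Z[, layer$pairs[j, 1L]]
    z2 <- Z[, layer$pairs[j, 2L]]
    w <- layer$coef[, j]
    Y[, j] <- w[1L] + w[2L] * z1 + w[3L] * z2 +
      (if (interaction) w[4L] * z1 * z2 else 0)
  }
  Y
}

#' Predict from a trained GMDH network
#'
#' Propagates rows of `X_new` through the retained layers; the raw score is
#' the output of the network's output neuron (the minimum-delta neuron of
#' the best layer) and the label is 1 (Case) when the score is `>= 0.5`.
#'
#' @param object a [gmdh_train()] network.
#' @param X_new feature matrix with the training column count.
#' @param ... unused.
#' @return A data.frame with `score` and `label`.
#' @export
predict.gmdh_network <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != object$m)
    stop("X_new has ", ncol(X_new), " columns; the network was trained ",
         "on ", object$m)
  X <- sweep(sweep(X_new, 2L, object$center), 2L, object$scale, "/")
  Z <- X
  inter <- object$config$interaction
  for (l in object$layers) {
    Y <- layer_outputs(l, Z, inter)
    Z <- cbind(Y, X)
  }
  score <- Y[, 1L]
  data.frame(score = score, label = as.integer(score >= 0.5))
}

#' Feature importance of a GMDH network
#'
#' Traverses the ancestry subgraph of the output neuron (the part of the
#' network that actually feeds the prediction) and counts, for each input
#' feature, how often it appears as a leaf input of a neuron in that
#' subgraph; counts are normalized to sum to 1. Features outside the
#' subgraph score 0.
#'
#' @param net a trained [gmdh_train()] network.
#' @return A numeric vector of length `m` summing to 1, named by feature.
#' @export
gmdh_importance <- function(net) {
  stopifnot(inherits(net, "gmdh_network"))
  R <- length(net$layers)
  counts <- numeric(net$m)
  # nodes are (layer, kept-position); start from the output neuron
  seen <- new.env(parent = emptyenv())
  queue <- list(c(R, 1L))
  assign(paste(R, 1L), TRUE, envir = seen)
  while (length(queue)) {
    nd <- queue[[1L]]; queue <- queue[-1L]
    l <- net$layers[[nd[1L]]]
    for (col in l$pairs[nd[2L], ]) {
      if (nd[1L] > 1L && col <= l$prev_F) {
        key <- paste(nd[1L] - 1L, col)
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          queue <- c(queue, list(c(nd[1L] - 1L, col)))
        }
      } else {
        feat <- if (nd[1L] > 1L) col - l$prev_F else col
        counts[feat] <- counts[feat] + 1
      }
    }
  }
  imp <- counts / sum(counts)
  names(imp) <- net$feature_names
  imp
}
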