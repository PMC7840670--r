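#' Leave-one-out cross-validation
#'
#' Runs `n` rounds; in each, the trainer (and every data-dependent
#' preprocessing step it contains) is refit on the `n - 1` remaining rows
#' and the held-out row is predicted. Round seeds are derived
#' deterministically from `seed`, so the whole evaluation is reproducible.
#'
#' @param X numeric feature matrix (`n >= 3` rows).
#' @param y 0/1 targets with both classes present.
#' @param trainer `function(X_train, y_train, seed)` returning a model
#'   whose `predict(model, X_new)` yields a data.frame with a `label`
#'   column (and optionally `score`).
#' @param seed master integer seed.
#' @param importance optional `function(model)` returning a per-feature
#'   importance vector (defaults to [gmdh_importance()] for GMDH models);
#'   `FALSE` disables importance collection.
#' @return An object of class `cv_result`: `predictions` (round, true,
#'   predicted, score), `accuracy` (%), `importance` (rounds x m matrix or
#'   `NULL`), `n_rounds`, `seed`.
#' @export
loocv <- function(X, y, trainer, seed = 1L, importance = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("LOOCV needs at least 3 samples")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  imp_rows <- list()
  preds <- lapply(seq_len(n), function(i) {
    model <- trainer(X[-i, , drop = FALSE], y[-i], derive_seed(seed, i))
    out <- predict(model, X[i, , drop = FALSE])
    if (is.null(importance) && inherits(model, "gmdh_network"))
      imp_rows[[i]] <<- gmdh_importance(model)
    else if (is.function(importance))
      imp_rows[[i]] <<- importance(model)
    data.frame(round = i, true = y[i], predicted = out$label[1L],
               score = if ("score" %in% names(out)) out$score[1L]
                       else NA_real_)
  })
  preds <- do.call(rbind, preds)
  imp <- if (length(imp_rows)) do.call(rbind, imp_rows) else NULL
  structure(list(predictions = preds,
                 accuracy = 100 * mean(preds$predicted == preds$true),
                 importance = imp, n_rounds = n, seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d LOOCV rounds, accuracy %.1f%%\n",
              x$n_rounds, x$accuracy))
  invisible(x)
}

#' Trainer adapter for [loocv()] around [gmdh_train()]
#'
#' @param config a [gmdh_config()].
#' @return A `function(X, y, seed)` suitable for [loocv()].
#' @export
gmdh_trainer <- function(config = gmdh_config()) {
  function(X, y, seed) gmdh_train(X, y, config = config, seed = seed)
}

#' Aggregate feature importance across cross-validation rounds
#'
#' Mean per-feature importance over rounds plus the fraction of rounds in
#' which each feature was used at all. Rows keep the input feature order,
#' which for Zernike features is the (n, m) index order.
#'
#' @param cv a [loocv()] result carrying per-round importances.
#' @param feature_names optional names (defaults to the importance matrix
#'   column names).
#' @return A data.frame with `feature`, `mean_importance`,
#'   `used_fraction`.
#' @export
importance_report <- function(cv, feature_names = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  if (is.null(cv$importance))
    stop("cross-validation result carries no per-round importances")
  imp <- cv$importance
  if (is.null(feature_names)) feature_names <- colnames(imp)
  if (is.null(feature_names))
    feature_names <- sprintf("f%d", seq_len(ncol(imp)))
  data.frame(feature = feature_names,
             mean_importance = colMeans(imp),
             used_fraction = colMeans(imp > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Reference classifiers under the identical LOOCV protocol
#'
#' Thin adapters over established implementations, provided as context for
#' the GMDH results, not as part of the core method: random forest (200
#' trees, minimum node size 3, 80% of attributes per split, 70% sample
#' rate), RBF-kernel SVM with the kernel width chosen by internal
#' cross-validation, and a single-hidden-layer logistic network (7 hidden
#' units, weight decay as the regularizer). Methods whose package is not
#' installed are skipped with a warning.
#'
#' @param X feature matrix; `y` 0/1 targets.
#' @param y 0/1 targets.
#' @param methods subset of `c("rf", "svm", "ann")`.
#' @param seed master seed shared across methods (same LOOCV splits).
#' @return Named list of [loocv()] results.
#' @export
run_reference_classifiers <- function(X, y,
                                      methods = c("rf", "svm", "ann"),
                                      seed = 1L) {
  adapters <- list(
    rf = function() {
      if (!requireNamespace("randomForest", quietly = TRUE)) return(NULL)
      function(Xt, yt, s) {
        model <- with_seed(s, randomForest::randomForest(
          Xt, factor(yt, levels = c(0, 1)), ntree = 200,
          nodesize = 3, mtry = max(1L, round(0.8 * ncol(Xt))),
          sampsize = ceiling(0.7 * nrow(Xt))))
        structure(list(fit = model), class = "bonetex_rf")
      }
    },
    svm = function() {
      if (!requireNamespace("e1071", quietly = TRUE)) return(NULL)
      function(Xt, yt, s) {
        gammas <- (1 / ncol(Xt)) * c(0.25, 1, 4)
        acc <- vapply(gammas, function(g) with_seed(s, {
          fit <- e1071::svm(Xt, factor(yt, levels = c(0, 1)),
                            kernel = "radial", gamma = g, cross = 5,
                            scale = TRUE)
          fit$tot.accuracy
        }), 0)
        model <- with_seed(s, e1071::svm(
          Xt, factor(yt, levels = c(0, 1)), kernel = "radial",
          gamma = gammas[which.max(acc)], scale = TRUE))
        structure(list(fit = model), class = "bonetex_svm")
      }
    },
    ann = function() {
      if (!requireNamespace("nnet", quietly = TRUE)) return(NULL)
      function(Xt, yt, s) {
        ctr <- colMeans(Xt); scl <- apply(Xt, 2, sd); scl[scl == 0] <- 1
        Xs <- sweep(sweep(Xt, 2, ctr), 2, scl, "/")
        model <- with_seed(s, nnet::nnet(
          Xs, yt, size = 7, decay = 0.1, maxit = 200, trace = FALSE))
        structure(list(fit = model, center = ctr, scale = scl),
                  class = "bonetex_ann")
      }
    })
  out <- list()
  for (mth in match.arg(methods, several.ok = TRUE)) {
    trainer <- adapters[[mth]]()
    if (is.null(trainer)) {
      warning("adapter package for '", mth, "' unavailable; skipped")
      next
    }
    out[[mth]] <- loocv(X, y, trainer, seed = seed, importance = FALSE)
  }
  out
}

#' @export
predict.bonetex_rf <- function(object, X_new, ...) {
  lab <- as.integer(as.character(predict(object$fit, X_new)))
  data.frame(label = lab)
}

#' @export
predict.bonetex_svm <- function(object, X_new, ...) {
  lab <- as.integer(as.character(predict(object$fit, X_new)))
  data.frame(label = lab)
}

#' @export
predict.bonetex_ann <- function(object, X_new, ...) {
  Xs <- sweep(sweep(as.matrix(X_new), 2, object$center), 2,
              object$scale, "/")
  sc <- as.numeric(predict(object$fit, Xs))
  data.frame(score = sc, label = as.integer(sc >= 0.5))
}
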