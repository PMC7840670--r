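#' Extract texture features for every image in a dataset
#'
#' One row per image: metadata columns `id`, `group`, `compartment`
#' followed by the named feature columns (`z_<n>_<m>` for Zernike,
#' `h_1 .. h_14` for Haralick).
#'
#' @param dataset a `roi_dataset`.
#' @param method `"zernike"` or `"haralick"`.
#' @param ... passed on to [zernike_features()] or [haralick_vector()].
#' @return A data.frame of features.
#' @export
extract_features <- function(dataset, method = c("zernike", "haralick"),
                             ...) {
  stopifnot(inherits(dataset, "roi_dataset"))
  method <- match.arg(method)
  fn <- switch(method, zernike = zernike_features,
               haralick = haralick_vector)
  rows <- lapply(dataset$images, function(im) {
    v <- fn(im, ...)
    cbind(data.frame(id = im$id, group = im$group,
                     compartment = im$compartment,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split a feature table into a matrix and 0/1 targets
#'
#' @param features a data.frame from [extract_features()] (or with the
#'   same metadata columns).
#' @return A list with `X` (numeric matrix), `y` (1 = Case, 0 = Control)
#'   and `ids`.
#' @export
feature_matrix <- function(features) {
  meta <- c("id", "group", "compartment")
  stopifnot(all(meta %in% names(features)))
  X <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  list(X = X, y = as.integer(features$group == "Case"),
       ids = features$id)
}
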