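#' Pooled pixel-brightness distribution of a group
#'
#' Pools the pixels of all listed images into one sorted sample: the
#' empirical brightness distribution of the group, against which individual
#' images are tested.
#'
#' @param images list of [roi_image] (or a `roi_dataset`).
#' @param group label to attach (defaults to the first image's group).
#' @return An object of class `group_distribution` with sorted `values`,
#'   `group`, and pooled pixel count `n`.
#' @export
pooled_ecdf <- function(images, group = NULL) {
  if (inherits(images, "roi_dataset")) images <- images$images
  if (inherits(images, "roi_image")) images <- list(images)
  if (length(images) == 0L) stop("empty image list")
  v <- sort(unlist(lapply(images, function(im) as.vector(im$pixels)),
                   use.names = FALSE))
  if (is.null(group)) group <- images[[1L]]$group
  structure(list(values = v, group = group, n = length(v)),
            class = "group_distribution")
}

#' @export
print.group_distribution <- function(x, ...) {
  cat(sprintf("<group_distribution %s> n = %d pooled pixels\n",
              x$group, x$n))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The sup-norm distance between the empirical distribution functions of
#' two samples, `D = sup_t |F_a(t) - F_b(t)|`, in `[0, 1]`. Ties are
#' handled exactly (the ECDF difference is evaluated only where both step
#' functions have settled).
#'
#' @param a,b numeric samples (non-empty; order irrelevant).
#' @return `D` in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 2, 3), c(2, 3, 4))  # 1/3
#' @export
ks_statistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both samples must be non-empty")
  w <- c(a, b)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= na, 1 / na, -1 / nb))
  ws <- w[ord]
  keep <- c(diff(ws) != 0, TRUE)  # evaluate after each distinct value
  max(abs(z[keep]))
}

#' Asymptotic two-sample Kolmogorov-Smirnov p-value
#'
#' The limiting Kolmogorov distribution evaluated at
#' `sqrt(n1 n2 / (n1 + n2)) * D`:
#' `p = 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)`. Appropriate here
#' because pooled pixel counts are of order 1e4-1e5.
#'
#' @param D KS distance in `[0, 1]`.
#' @param n1,n2 sample sizes.
#' @return p-value in `[0, 1]`.
#' @export
ks_pvalue <- function(D, n1, n2) {
  stopifnot(D >= 0, D <= 1, n1 > 0, n2 > 0)
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * D
  if (lambda == 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Classify one image against the two group distributions
#'
#' Computes the KS distances `D0` (to Control) and `D1` (to Case) between
#' the image's pixel sample and the pooled group distributions, assigns the
#' group with the minimal distance (ties go to Control, with a message),
#' and flags rejection when both p-values fall below `alpha` -- the image
#' is then recognized as belonging to neither group at that significance
#' level, though it still receives the minimum-distance label.
#'
#' @param image an [roi_image].
#' @param c0 Control [pooled_ecdf()] distribution.
#' @param c1 Case [pooled_ecdf()] distribution.
#' @param alpha significance level (default 0.05).
#' @return An object of class `ks_decision`: `D0`, `D1`, `p0`, `p1`,
#'   `predicted`, `rejected`, `alpha`.
#' @export
classify_image <- function(image, c0, c1, alpha = 0.05) {
  stopifnot(inherits(image, "roi_image"),
            inherits(c0, "group_distribution"),
            inherits(c1, "group_distribution"))
  px <- as.vector(image$pixels)
  D0 <- ks_statistic(px, c0$values)
  D1 <- ks_statistic(px, c1$values)
  p0 <- ks_pvalue(D0, length(px), c0$n)
  p1 <- ks_pvalue(D1, length(px), c1$n)
  if (D0 == D1) message("KS tie for image '", image$id,
                        "'; assigning Control")
  predicted <- if (D0 <= D1) "Control" else "Case"
  structure(list(D0 = D0, D1 = D1, p0 = p0, p1 = p1,
                 predicted = predicted,
                 rejected = (p0 < alpha && p1 < alpha), alpha = alpha),
            class = "ks_decision")
}

#' Leave-one-out evaluation of the KS baseline rule
#'
#' For each image (per compartment), pools the brightness distributions of
#' the two groups from the *other* images -- the test image's own pixels are
#' excluded from its group's pool -- classifies it by minimum KS distance,
#' and records the rejection flag. Reports accuracy over all images
#' (rejected images keep their minimum-distance label) and the rejection
#' rate, per compartment.
#'
#' @param dataset a `roi_dataset` with both groups present.
#' @param alpha significance level (default 0.05).
#' @return A list with `per_compartment` (data.frame: compartment,
#'   accuracy %, rejection %, n) and `decisions` (per-image data.frame
#'   with D0/D1/p0/p1/predicted/rejected).
#' @export
evaluate_ks_baseline <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "roi_dataset"))
  comps <- unique(vapply(dataset$images, `[[`, "", "compartment"))
  rows <- list(); summaries <- list()
  for (cm in comps) {
    imgs <- dataset_subset(dataset, compartment = cm)
    grp <- vapply(imgs, `[[`, "", "group")
    if (sum(grp == "Case") < 2L || sum(grp == "Control") < 2L)
      stop("each group needs at least 2 images in compartment ", cm)
    dec <- lapply(seq_along(imgs), function(i) {
      others <- imgs[-i]
      og <- vapply(others, `[[`, "", "group")
      c0 <- pooled_ecdf(others[og == "Control"], group = "Control")
      c1 <- pooled_ecdf(others[og == "Case"], group = "Case")
      d <- classify_image(imgs[[i]], c0, c1, alpha)
      data.frame(id = imgs[[i]]$id, compartment = cm, true = grp[i],
                 D0 = d$D0, D1 = d$D1, p0 = d$p0, p1 = d$p1,
                 predicted = d$predicted, rejected = d$rejected,
                 stringsAsFactors = FALSE)
    })
    dec <- do.call(rbind, dec)
    rows[[cm]] <- dec
    summaries[[cm]] <- data.frame(
      compartment = cm,
      accuracy = 100 * mean(dec$predicted == dec$true),
      rejection = 100 * mean(dec$rejected),
      n = nrow(dec), stringsAsFactors = FALSE)
  }
  list(per_compartment = do.call(rbind, c(summaries,
                                          list(make.row.names = FALSE))),
       decisions = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
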