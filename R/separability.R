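#' Class-separability score of a set of planes against a label map
#'
#' Quantifies how well a rendering separates labeled tissue classes:
#' each pixel contributes a vector of plane values, and the score is
#' `trace(S_b) / trace(S_w)`, where `S_b` is the between-class scatter of
#' the class mean vectors (weighted by class pixel counts) and `S_w` the
#' pooled within-class covariance. The trace ratio is preferred over a
#' determinant ratio because it stays defined when a plane is (near)
#' constant within classes. The score is 0 when all class means coincide;
#' when the within-class scatter is exactly zero but class means differ
#' (constant-per-class planes) the score is `Inf`, a documented sentinel.
#'
#' @param planes A list of numeric matrices sharing the label map's
#'   geometry, an `rgb_composite`, or a single matrix.
#' @param labels Integer (or factor-like) matrix of class labels.
#' @return An object of class `separability_report`: `score`,
#'   `per_class_means` (classes x planes matrix), `class_sizes`,
#'   `n_classes`, `n_planes`.
#' @export
separability <- function(planes, labels) {
  if (inherits(planes, "rgb_composite")) planes <- planes$planes
  if (is.matrix(planes)) planes <- list(planes)
  if (inherits(planes, "eigen_image_set")) planes <- planes$components
  stopifnot(is.list(planes), length(planes) >= 1L)
  if (!all(vapply(planes, is.matrix, logical(1)))) {
    stop("`planes` must be matrices", call. = FALSE)
  }
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != nrow(labels)) || any(dims[2, ] != ncol(labels))) {
    stop("planes and label map must share geometry", call. = FALSE)
  }
  lab <- as.vector(labels)
  classes <- sort(unique(lab))
  if (length(classes) < 2L) {
    stop("separability is undefined with fewer than 2 classes", call. = FALSE)
  }
  d <- length(planes)
  X <- vapply(planes, as.vector, numeric(length(lab)))  # n x d
  if (d == 1L) X <- matrix(X, ncol = 1L)

  n <- length(lab)
  sizes <- tabulate(match(lab, classes))
  grp <- match(lab, classes)

  means <- matrix(0, length(classes), d)
  within <- 0
  for (g in seq_along(classes)) {
    Xg <- X[grp == g, , drop = FALSE]
    means[g, ] <- colMeans(Xg)
    # population within-class variance, weighted by class size
    within <- within + sum(sweep(Xg, 2L, means[g, ])^2)
  }
  mu <- colSums(means * sizes) / n
  between <- sum(sizes * rowSums(sweep(means, 2L, mu)^2))

  tr_b <- between / n
  tr_w <- within / n
  score <- if (tr_w == 0) {
    if (tr_b > 0) Inf else 0
  } else tr_b / tr_w

  tissue_names <- attr(labels, "tissues")
  rn <- if (!is.null(tissue_names) && length(tissue_names) >= max(classes)) {
    tissue_names[classes]
  } else as.character(classes)
  dimnames(means) <- list(rn, names(planes) %||% paste0("plane", seq_len(d)))

  structure(list(score = score, per_class_means = means,
                 class_sizes = stats::setNames(sizes, rn),
                 n_classes = length(classes), n_planes = d),
            class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf("<separability_report> %d classes, %d plane(s), score %s\n",
              x$n_classes, x$n_planes,
              if (is.infinite(x$score)) "Inf" else sprintf("%.4f", x$score)))
  invisible(x)
}

#' Separability of the best single raw channel
#'
#' Convenience baseline for the enhancement comparison: the maximum
#' separability score achieved by any single channel of a cube, against
#' the same label map.
#'
#' @param cube A `spectral_cube`.
#' @param labels Label map as in [separability()].
#' @return Named numeric vector of per-channel scores.
#' @export
channel_separability <- function(cube, labels) {
  stopifnot(inherits(cube, "spectral_cube"))
  scores <- vapply(cube$channels,
                   function(im) separability(im$pixels, labels)$score,
                   numeric(1))
  stats::setNames(scores, cube$channel_names)
}
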