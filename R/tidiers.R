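#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the channel loadings of an eigen-image decomposition
#'
#' @param x An `eigen_image_set`.
#' @param ... Unused.
#' @return A tibble with one row per component x channel: `component`,
#'   `channel`, `loading`.
#' @method tidy eigen_image_set
#' @export
tidy.eigen_image_set <- function(x, ...) {
  L <- x$loadings
  tibble::tibble(
    component = rep(seq_len(nrow(L)), times = ncol(L)),
    channel = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L)
  )
}

#' One-row summary of an eigen-image decomposition
#'
#' @param x An `eigen_image_set`.
#' @param ... Unused.
#' @return A one-row tibble: `branch`, `n_components`, `evr_1..k` and
#'   `evr_total`.
#' @method glance eigen_image_set
#' @export
glance.eigen_image_set <- function(x, ...) {
  evr <- x$explained_variance_ratio
  out <- tibble::tibble(branch = x$branch, n_components = length(x$components))
  for (i in seq_along(evr)) out[[paste0("evr_", i)]] <- evr[i]
  out$evr_total <- sum(evr)
  out
}

#' Tidy per-class plane means of a separability report
#'
#' @param x A `separability_report`.
#' @param ... Unused.
#' @return A tibble with `class`, `plane`, `mean`, `n_pixels`.
#' @method tidy separability_report
#' @export
tidy.separability_report <- function(x, ...) {
  m <- x$per_class_means
  tibble::tibble(
    class = rep(rownames(m), times = ncol(m)),
    plane = rep(colnames(m), each = nrow(m)),
    mean = as.vector(m),
    n_pixels = rep(unname(x$class_sizes), times = ncol(m))
  )
}

#' One-row summary of a separability report
#'
#' @param x A `separability_report`.
#' @param ... Unused.
#' @return A one-row tibble: `score`, `n_classes`, `n_planes`.
#' @method glance separability_report
#' @export
glance.separability_report <- function(x, ...) {
  tibble::tibble(score = x$score, n_classes = x$n_classes,
                 n_planes = x$n_planes)
}

composite_to_df <- function(x) {
  h <- x$height; w <- x$width
  data.frame(
    x = rep(seq_len(w), each = h),
    y = rep(seq_len(h), times = w),
    fill = grDevices::rgb(as.vector(x$planes[[1]]),
                          as.vector(x$planes[[2]]),
                          as.vector(x$planes[[3]]), maxColorValue = 255)
  )
}

#' Plot an RGB false-color composite
#'
#' @param object An `rgb_composite`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rgb_composite
#' @export
autoplot.rgb_composite <- function(object, ...) {
  df <- composite_to_df(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = sprintf("sPCA composite (%s branch)", object$branch),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot the eigen-images of a decomposition as gray-scale facets
#'
#' @param object An `eigen_image_set`.
#' @param ... Unused.
#' @return A ggplot object faceted by component, each min-max stretched.
#' @method autoplot eigen_image_set
#' @export
autoplot.eigen_image_set <- function(object, ...) {
  h <- object$height; w <- object$width
  dfs <- lapply(seq_along(object$components), function(i) {
    v <- normalize_to_255(object$components[[i]])
    data.frame(
      x = rep(seq_len(w), each = h),
      y = rep(seq_len(h), times = w),
      value = as.vector(v),
      component = sprintf("PC%d (%.1f%%)", i,
                          100 * object$explained_variance_ratio[i])
    )
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::facet_wrap(~component, nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot per-class plane means of a separability report
#'
#' @param object A `separability_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of class means per plane.
#' @method autoplot separability_report
#' @export
autoplot.separability_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$mean,
                                   fill = .data$plane)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tissue class", y = "mean plane intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
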